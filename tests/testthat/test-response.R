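test_that("Jacobian entries match direct differentiation of the forces", {
  # two-state asymmetric, m = 1: rows (1->2), (2->1); cols (edge, node)
  fra <- build_frame(net2a())
  A <- as.matrix(build_jacobian(net2a(), fra)$A)
  expect_close(A, matrix(c(0.5, 0.5, 2, -1), 2, 2))

  # unit rates
  frs <- build_frame(net2s())
  As <- as.matrix(build_jacobian(net2s(), frs)$A)
  expect_close(As, matrix(c(0.5, 0.5, 1, -1), 2, 2))

  # ring: +-1/2 pattern in edge and cycle blocks, k-valued node block,
  # structural zeros elsewhere
  fr3 <- build_frame(net3c())
  jac3 <- build_jacobian(net3c(), fr3)
  A3 <- as.matrix(jac3$A)
  b3 <- fr3$basis
  edge_block <- A3[, b3$type == "traffic"]
  expect_true(all(edge_block %in% c(0, 0.5)))
  expect_equal(colSums(edge_block != 0), rep(2, 3), ignore_attr = TRUE)
  cyc_block <- A3[, b3$type == "cycle", drop = FALSE]
  expect_true(all(cyc_block %in% c(-0.5, 0, 0.5)))
  node_block <- A3[, b3$type == "dwell"]
  k3 <- frame_rates_for_test(net3c(), fr3)
  for (d in seq_len(nrow(fr3$directed))) {
    i <- fr3$directed$from[d]
    for (cix in seq_len(ncol(node_block))) {
      n <- b3$state[b3$type == "dwell"][cix]
      expected <- k3[d] * ((i == fr3$reference) - (i == n))
      expect_equal(node_block[d, cix], expected)
    }
  }
  # caliber gradient: k_mj on rows leaving the reference
  expect_equal(jac3$grad_c,
               ifelse(fr3$directed$from == fr3$reference, k3, 0),
               ignore_attr = TRUE)
})

test_that("Jacobian inversion is exact on small systems", {
  fra <- build_frame(net2a())
  inv <- invert_jacobian(build_jacobian(net2a(), fra))
  expect_close(inv$Ainv, matrix(c(2 / 3, 1 / 3, 4 / 3, -1 / 3), 2, 2))

  fr3 <- build_frame(net3c())
  jac <- build_jacobian(net3c(), fr3)
  inv3 <- invert_jacobian(jac)
  expect_close(as.matrix(jac$A) %*% inv3$Ainv, diag(6), tol = 1e-12)
  expect_close(inv3$Ainv %*% as.matrix(jac$A), diag(6), tol = 1e-12)
})

test_that("RIM responses reproduce two-state closed forms", {
  fra <- build_frame(net2a())
  R <- response_matrix(net2a(), fra)$R
  # tau12 = 2 k12 k21/(k12+k21); pi2 = k12/(k12+k21), at (2,1)
  expect_close(R["traffic:1-2", "1->2"], 4 / 9)
  expect_close(R["traffic:1-2", "2->1"], 8 / 9)
  expect_close(R["dwell:2", "1->2"], 2 / 9)
  expect_close(R["dwell:2", "2->1"], -2 / 9)

  frs <- build_frame(net2s())
  Rs <- response_matrix(net2s(), frs)$R
  expect_close(Rs["dwell:2", "1->2"], 1 / 4)
})

test_that("analytic responses match finite differences on random networks", {
  for (seed in 1:20) {
    V <- 3 + seed %% 6   # 3..8 states
    E <- min(V - 1 + seed %% 3, V * (V - 1) / 2)
    net <- random_ergodic_network(V, E, seed = 100 + seed)
    fr <- build_frame(net)
    R <- response_matrix(net, fr)$R
    R_fd <- fd_response_matrix(net, fr)
    # relative to the entry, floored at 1e-3 of the matrix scale so that
    # near-zero entries (FD roundoff-limited) are compared absolutely
    scale <- pmax(abs(R_fd), 1e-3 * max(abs(R_fd)))
    expect_lt(max(abs(R - R_fd) / scale), 1e-6)
  }
})

test_that("force susceptibility is symmetric with positive diagonal", {
  for (seed in 1:6) {
    net <- random_ergodic_network(5, 8, seed = seed)
    fr <- build_frame(net)
    S <- force_susceptibility(net, fr)
    expect_lt(max(abs(S - t(S))), 1e-8)
    expect_true(all(diag(S) > 0))
  }
})

test_that("physical responses are invariant to reference node and tree", {
  net <- random_ergodic_network(6, 9, seed = 17)
  st <- net_states(net)
  fr1 <- build_frame(net, reference = st[1])
  fr2 <- build_frame(net, reference = st[4],
                     avoid_tree_edges = list(c(st[1], st[2])))
  for (r in seq_len(nrow(fr1$edges))) {
    i <- fr1$edges$i[r]; j <- fr1$edges$j[r]
    for (obs_of in list(obs_traffic, edge_flux_observable)) {
      g1 <- observable_gradient(net, fr1, obs_of(fr1, i, j))
      g2 <- observable_gradient(net, fr2, obs_of(fr2, i, j))
      key1 <- paste(g1$from, g1$to)
      key2 <- paste(g2$from, g2$to)
      expect_lt(max(abs(g1$d_dlnk - g2$d_dlnk[match(key1, key2)])), 1e-10)
    }
  }
  # dwell responses for a state that is non-reference in both frames
  g1 <- observable_gradient(net, fr1, obs_dwell(fr1, st[5]))
  g2 <- observable_gradient(net, fr2, obs_dwell(fr2, st[5]))
  expect_lt(max(abs(g1$d_dlnk - g2$d_dlnk[match(paste(g1$from, g1$to),
                                               paste(g2$from, g2$to))])),
            1e-10)
})

test_that("site-energy and barrier responses obey their closed-form laws", {
  # dtau_uv/dE_n = pi_n tau_uv and dJ_c/dE_n = pi_n J_c
  net <- net3c()
  fr <- build_frame(net)
  ss <- steady_observables(net, fr)
  eb_tau <- energy_barrier_responses(net, fr, obs_traffic(fr, "1", "2"))
  expect_close(eb_tau$nodes$dE, ss$pi * ss$edges$tau[1], tol = 1e-10)
  eb_J <- energy_barrier_responses(net, fr, obs_cycle(fr, 1))
  expect_close(eb_J$nodes$dE, ss$pi * ss$J_cycle[1], tol = 1e-10)
  expect_close(eb_J$nodes$dE, rep(1 / 9, 3), tol = 1e-10)

  # a locally equilibrated edge (J = 0) gives zero barrier response for
  # observables other than its own traffic: NET2A has J12 = 0
  net2 <- net2a()
  fr2 <- build_frame(net2)
  eb <- energy_barrier_responses(net2, fr2, obs_dwell(fr2, "2"))
  expect_close(eb$edges$dB, 0, tol = 1e-12)
})
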