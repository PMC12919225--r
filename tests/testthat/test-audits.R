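test_that("node, edge and cycle identities hold with their printed constants", {
  # two-state closed-form entries
  net <- net2a()
  fr <- build_frame(net)
  sy <- symmetry_residuals(net, fr)

  edge_own <- sy[sy$identity == "edge" & sy$observable == "traffic:1-2", ]
  expect_equal(edge_own$expected, 2)
  expect_lt(abs(edge_own$lhs - 2), 1e-10)

  node_own <- sy[sy$identity == "node" & sy$unit == "node:2" &
                   sy$observable == "dwell:2", ]
  expect_equal(node_own$expected, 1)
  expect_lt(abs(node_own$lhs - 1), 1e-10)

  # ring cycle identity: 2 for the cycle's own flux, 0 for traffic
  net3 <- net3c()
  fr3 <- build_frame(net3)
  sy3 <- symmetry_residuals(net3, fr3)
  cyc <- sy3[sy3$identity == "cycle", ]
  own <- cyc[grepl("^cycle:", cyc$observable), ]
  expect_close(own$lhs, 2, tol = 1e-10)
  others <- cyc[grepl("^traffic:", cyc$observable), ]
  expect_close(others$lhs, 0, tol = 1e-10)
})

test_that("all symmetry residuals vanish on random networks, dense included", {
  for (seed in 1:20) {
    V <- 3 + seed %% 6
    E_max <- V * (V - 1) / 2
    E <- if (seed %% 4 == 0) E_max else min(V + seed %% 3, E_max)
    net <- random_ergodic_network(V, E, seed = 400 + seed)
    fr <- build_frame(net)
    sy <- symmetry_residuals(net, fr)
    expect_lt(max(abs(sy$residual)), 1e-8)
  }
})

test_that("delta/nabla coefficients match closed forms and constraints", {
  net <- net2a()
  fr <- build_frame(net)
  dn <- delta_nabla_coefficients(net, fr)
  r12 <- dn[dn$from == "1" & dn$to == "2", ]
  # dJ12/dk12 = 0 on the single-edge network => Delta = 1
  expect_close(r12$Delta, 1)
  # dtau12/dk12 = 2/9, pi1 = 1/3 => nabla = 2/3 - 1 = -1/3
  expect_close(r12$nabla, -1 / 3)

  for (seed in 1:8) {
    net <- random_ergodic_network(4, 5, seed = 500 + seed)
    fr <- build_frame(net)
    dn <- delta_nabla_coefficients(net, fr)
    expect_true(all(dn$Delta >= -1e-10 & dn$Delta <= 1 + 1e-10))
    expect_true(all(dn$nabla <= dn$Delta + 1e-10))
  }
})

test_that("kinetic hierarchy holds, with saturation exactly at zero flux", {
  net <- net2a()
  fr <- build_frame(net)
  bh <- bound_hierarchy_check(net, fr)
  r12 <- bh[bh$from == "1" & bh$to == "2", ]
  expect_close(r12$pi_i, 1 / 3)
  expect_close(r12$dp_fwd, 1 / 9)
  expect_close(r12$dp_rev, 1 / 9)
  expect_true(r12$saturated)  # middle equality since J12 = 0

  for (seed in 1:30) {
    net <- random_ergodic_network(4, 5, seed = 600 + seed)
    fr <- build_frame(net)
    bh <- bound_hierarchy_check(net, fr)  # hard-errors on violation
    expect_true(all(bh$pi_i >= bh$dp_fwd - 1e-10))
    expect_true(all(bh$dp_fwd >= bh$dp_rev - 1e-10))
    expect_true(all(bh$dp_rev >= -1e-10))
    # saturation forces zero net flux; with generic random rates the only
    # zero-flux edges are structural (bridges), so the two sets coincide
    expect_equal(bh$saturated, abs(bh$J) <= 1e-10)
  }
})

test_that("saturation means insensitive net flux, not detailed balance", {
  # every edge of a detailed-balanced cycle has J = 0, yet a single-rate
  # perturbation creates first-order net flux, so the middle bound is strict
  sym <- rate_network(data.frame(
    from = c("1", "2", "2", "3", "3", "1"),
    to = c("2", "1", "3", "2", "1", "3"), rate = 1))
  bh <- bound_hierarchy_check(sym, build_frame(sym))
  expect_close(bh$J, 0, tol = 1e-14)
  expect_false(any(bh$saturated))
  expect_close(bh$dp_fwd, 2 / 9, tol = 1e-12)
  expect_close(bh$dp_rev, 1 / 9, tol = 1e-12)
})

test_that("population-depletion bound saturates as the rate vanishes", {
  net <- random_ergodic_network(4, 5, seed = 9)
  scaled <- net
  scaled$rate[1] <- scaled$rate[1] * 1e-6
  fr <- build_frame(scaled)
  bh <- bound_hierarchy_check(scaled, fr)
  row <- bh[bh$from == scaled$from[1] & bh$to == scaled$to[1], ]
  expect_lt(abs(row$dp_fwd - row$pi_i) / row$pi_i, 1e-4)
})

test_that("ensemble scatter stays inside the response triangle", {
  sc <- ensemble_bound_scatter(V = 4, count = 120, seed = 21)
  expect_true(all(sc$x <= 1 + 1e-10))
  expect_true(all(sc$x >= sc$y - 1e-10))
  expect_true(all(sc$y >= -1e-10))

  # detailed-balance ensemble still obeys the hierarchy, with the one-way
  # fluxes themselves equal (p_ij = p_ji) on every edge
  db <- ensemble_bound_scatter(V = 4, count = 30, seed = 22,
                               detailed_balance = TRUE)
  expect_true(all(db$x <= 1 + 1e-10 & db$x >= db$y - 1e-10 & db$y >= -1e-10))

  # a bridge edge (two-state fixture) sits on the diagonal
  fr <- build_frame(net2a())
  bh <- bound_hierarchy_check(net2a(), fr)
  expect_close(bh$dp_fwd / bh$pi_i, bh$dp_rev / bh$pi_i)
})

test_that("node identity reproduces the occupancy-proportional flux scalings", {
  net <- random_ergodic_network(5, 7, seed = 33)
  fr <- build_frame(net)
  ss <- steady_observables(net, fr)
  # dtau_uv/dE_n = pi_n tau_uv for every node and edge
  for (e in c(1L, nrow(fr$edges))) {
    eb <- energy_barrier_responses(net, fr,
                                   obs_traffic(fr, fr$edges$i[e],
                                               fr$edges$j[e]))
    expect_close(eb$nodes$dE, ss$pi * ss$edges$tau[e], tol = 1e-10)
  }
  # dJ_c/dE_n = pi_n J_c
  eb <- energy_barrier_responses(net, fr, obs_cycle(fr, 1))
  expect_close(eb$nodes$dE, ss$pi * ss$J_cycle[1], tol = 1e-10)
})
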