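test_that("Jacobian derivative has the stated single-row node-column support", {
  net <- net2a()
  fr <- build_frame(net)
  # edge (1->2) leaves the reference: +k12 on the node-2 column
  dA12 <- as.matrix(jacobian_derivative(net, fr, "1", "2"))
  expect_equal(sum(dA12 != 0), 1L)
  expect_equal(dA12[1, 2], 2)
  # edge (2->1): -k21 on the node-2 column
  dA21 <- as.matrix(jacobian_derivative(net, fr, "2", "1"))
  expect_equal(sum(dA21 != 0), 1L)
  expect_equal(dA21[2, 2], -1)
  # edge- and cycle-force columns are rate-independent
  b <- fr$basis
  expect_true(all(dA12[, b$type != "dwell"] == 0))

  # closure identity: d(A A^-1) = 0
  net5 <- random_ergodic_network(5, 7, seed = 4)
  fr5 <- build_frame(net5)
  jac <- build_jacobian(net5, fr5)
  Ainv <- invert_jacobian(jac)$Ainv
  h <- 1e-7
  d <- 3L  # probe one directed edge
  from <- fr5$directed$from[d]; to <- fr5$directed$to[d]
  dA <- as.matrix(jacobian_derivative(net5, fr5, from, to))
  net_up <- net5
  hit <- net_up$from == from & net_up$to == to
  net_up$rate[hit] <- net_up$rate[hit] * exp(h)
  net_dn <- net5
  net_dn$rate[hit] <- net_dn$rate[hit] * exp(-h)
  dAinv_fd <- (invert_jacobian(build_jacobian(net_up, fr5))$Ainv -
                 invert_jacobian(build_jacobian(net_dn, fr5))$Ainv) / (2 * h)
  expect_lt(max(abs(dA %*% Ainv + as.matrix(jac$A) %*% dAinv_fd)), 1e-6)
  expect_lt(max(abs(dAinv_fd + Ainv %*% dA %*% Ainv)), 1e-6)
})

test_that("variance gradient matches the two-state closed form", {
  # D_dwell2 = 2 k12 k21 / (k12+k21)^3
  net <- net2a()
  fr <- build_frame(net)
  cg <- covariance_gradient(net, fr, obs_dwell(fr, "2"))
  g12 <- cg$d_var_dlnk[cg$from == "1" & cg$to == "2"]
  g21 <- cg$d_var_dlnk[cg$from == "2" & cg$to == "1"]
  expect_close(g12, -4 / 27)
  expect_close(g21, 0)  # 2 k12 (k12 - 2 k21)/(k12+k21)^4 * k21 = 0 at (2,1)
})

test_that("analytic variance and randomness gradients match finite differences", {
  fd_var_grad <- function(net, fr, obs, h = 1e-6) {
    vapply(seq_len(nrow(fr$directed)), function(d) {
      v <- function(fac) {
        n2 <- net
        hit <- n2$from == fr$directed$from[d] & n2$to == fr$directed$to[d]
        n2$rate[hit] <- n2$rate[hit] * fac
        cm <- covariance_matrix(n2, fr)
        drop(obs$weights %*% cm$D %*% obs$weights)
      }
      (v(1 + h) - v(1 - h)) / (2 * h)
    }, numeric(1))
  }
  fd_r_grad <- function(net, fr, flux, h = 1e-6) {
    vapply(seq_len(nrow(fr$directed)), function(d) {
      v <- function(fac) {
        n2 <- net
        hit <- n2$from == fr$directed$from[d] & n2$to == fr$directed$to[d]
        n2$rate[hit] <- n2$rate[hit] * fac
        as.numeric(randomness_parameter(n2, fr, flux))
      }
      (v(1 + h) - v(1 - h)) / (2 * h)
    }, numeric(1))
  }

  for (seed in 1:10) {
    V <- 4 + seed %% 3
    net <- random_ergodic_network(V, V + 1, seed = 300 + seed)
    fr <- build_frame(net)
    flux <- obs_cycle(fr, 1)
    cg <- covariance_gradient(net, fr, flux)
    fd <- fd_var_grad(net, fr, flux)
    expect_lt(max(abs(cg$d_var_dlnk - fd) / pmax(abs(fd), 1e-6)), 1e-5)
    rg <- randomness_gradient(net, fr, flux)
    fdr <- fd_r_grad(net, fr, flux)
    expect_lt(max(abs(rg$d_r_dlnk - fdr) / pmax(abs(fdr), 1e-6)), 1e-5)
  }

  # Theta benchmark topology
  th <- theta_motor_network(5)
  frt <- build_frame(th)
  mech <- attr(th, "mechanical_edge")
  flux <- edge_flux_observable(frt, mech[1], mech[2])
  rg <- randomness_gradient(th, frt, flux)
  fdr <- fd_r_grad(th, frt, flux)
  expect_lt(max(abs(rg$d_r_dlnk - fdr) / pmax(abs(fdr), 1e-6)), 1e-5)
})

test_that("uniform forward-rate rescaling leaves the ring's randomness fixed", {
  # r ~ 1/N is invariant under a joint scaling of all forward rates, so the
  # directional derivative along that perturbation vanishes
  ring <- ring_network(5, fwd = 1, rev = 1e-6)
  fr <- build_frame(ring)
  rg <- randomness_gradient(ring, fr, obs_cycle(fr, 1))
  fwd_rows <- paste(rg$from, rg$to) %in% paste(1:5, c(2:5, 1))
  directional <- sum(rg$d_r_dlnk[fwd_rows])
  expect_lt(abs(directional), 1e-4)
})

test_that("design steps move the objective the right way", {
  net <- random_ergodic_network(4, 5, seed = 8)
  fr <- build_frame(net)
  flux <- obs_cycle(fr, 1)

  stepped <- design_step(net, fr, "min_randomness", flux, step = 1e-3)
  expect_lt(attr(stepped, "objective_delta"), 0)

  up <- design_step(net, fr, "max_flux", flux, step = 1e-3)
  expect_gt(attr(up, "objective_delta"), 0)

  # zero step: identical network
  same <- design_step(net, fr, "min_randomness", flux, step = 0)
  expect_equal(same$rate, net$rate)

  # all edges constrained: unchanged, with a warning
  all_edges <- lapply(seq_len(nrow(net)), function(r) c(net$from[r], net$to[r]))
  expect_warning(
    frozen <- design_step(net, fr, "min_randomness", flux, step = 1e-3,
                          fixed_edges = all_edges),
    "constrained")
  expect_equal(frozen$rate, net$rate)

  expect_error(design_step(net, fr, "min_randomness", flux, step = -1),
               "step")
})
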