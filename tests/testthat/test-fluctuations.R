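test_that("two-state covariances match renewal/telegraph closed forms", {
  fr <- build_frame(net2a())
  D <- covariance_matrix(net2a(), fr)$D
  # telegraph occupancy: 2 pi1 pi2 / (k12 + k21)
  expect_close(D["dwell:2", "dwell:2"], 4 / 27)
  # alternating renewal traffic: 4 sigma^2 / mu^3,
  # mu = 1/k12 + 1/k21, sigma^2 = 1/k12^2 + 1/k21^2
  expect_close(D["traffic:1-2", "traffic:1-2"], 40 / 27)
  expect_close(D["traffic:1-2", "dwell:2"], -4 / 27)
})

test_that("covariance matrix is symmetric PSD and equals the susceptibility", {
  for (seed in 1:6) {
    V <- 4 + seed %% 3
    net <- random_ergodic_network(V, min(V + 2, V * (V - 1) / 2), seed = seed)
    fr <- build_frame(net)
    D <- covariance_matrix(net, fr)$D
    expect_lt(max(abs(D - t(D))), 1e-12)
    expect_gt(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    # fluctuation-response duality
    S <- force_susceptibility(net, fr)
    expect_lt(max(abs(D - S)), 1e-8)
  }
})

test_that("noise projections square-sum to the variance rate", {
  net <- net2a()
  fr <- build_frame(net)
  pr_tau <- noise_projections(net, fr, obs_traffic(fr, "1", "2"))
  expect_close(sum(pr_tau$squared), 40 / 27)

  pr_dw <- noise_projections(net, fr, obs_dwell(fr, "2"))
  # A^-1 dwell row (1/3, -1/3), weights pi_i k_ij = 2/3 on both edges
  expect_close(sort(pr_dw$projection),
               sort(c(sqrt(2 / 3) / 3, -sqrt(2 / 3) / 3)))
  expect_close(sum(pr_dw$squared), 4 / 27)

  expect_equal(noise_projections(net, fr, obs_zero(fr))$projection, c(0, 0))

  # general property: projections of any observable reproduce D_ww
  net5 <- random_ergodic_network(5, 7, seed = 3)
  fr5 <- build_frame(net5)
  D5 <- covariance_matrix(net5, fr5)$D
  for (b in c(1, 4, 7)) {
    w <- as.numeric(seq_len(nrow(fr5$basis)) == b)
    obs <- observable(fr5, w)
    expect_close(sum(noise_projections(net5, fr5, obs)$squared), D5[b, b],
                 tol = 1e-10)
  }
})

test_that("randomness parameter approaches 1/N on near-deterministic rings", {
  for (N in c(5, 10)) {
    ring <- ring_network(N, fwd = 1, rev = 1e-6)
    fr <- build_frame(ring)
    r <- as.numeric(randomness_parameter(ring, fr, obs_cycle(fr, 1)))
    expect_lt(abs(r - 1 / N), 1e-3)
  }
  # spectral cross-check on the driven 3-ring
  ring3 <- net3c()
  fr3 <- build_frame(ring3)
  flux <- obs_cycle(fr3, 1)
  r3 <- randomness_parameter(ring3, fr3, flux)
  tc <- tilted_cumulants(ring3, as_counting_weights(fr3, flux))
  expect_close(attr(r3, "mean_flux"), tc[["mean"]], tol = 1e-8)
  expect_close(attr(r3, "var_rate"), tc[["var"]], tol = 1e-6)
  expect_close(as.numeric(r3), tc[["var"]] / tc[["mean"]], tol = 1e-6)
})

test_that("stalled flux is rejected", {
  # detailed-balance network: every flux observable has zero mean
  net <- random_ergodic_network(4, 5, seed = 2, detailed_balance = TRUE)
  fr <- build_frame(net)
  expect_error(randomness_parameter(net, fr, obs_cycle(fr, 1)), "stalled")
})

test_that("randomness decomposition sums exactly to r and respects groups", {
  # exact partition on any fixture
  kin <- kinesin6()
  fr <- build_frame(kin)
  mech <- edge_flux_observable(fr, "2", "5")
  dec <- randomness_decomposition(kin, fr, mech)
  r <- as.numeric(randomness_parameter(kin, fr, mech))
  expect_true(all(dec$contribution >= 0))
  expect_lt(abs(sum(dec$contribution) - r), 1e-10 * r)

  # group sums match summing the per-edge table
  gs <- attr(dec, "group_summary")
  for (g in gs$group) {
    expect_equal(gs$contribution[gs$group == g],
                 sum(dec$contribution[!is.na(dec$group) & dec$group == g]))
  }
  expect_error(randomness_decomposition(kin, fr, mech, groups = "nope"),
               "unknown group")

  # near-deterministic ring: forward steps carry equal shares, backward none
  ring <- ring_network(5, fwd = 1, rev = 1e-6)
  frr <- build_frame(ring)
  dr <- randomness_decomposition(ring, frr, obs_cycle(frr, 1))
  fwd <- dr$contribution[paste(dr$from, dr$to) %in%
                           paste(1:5, c(2:5, 1))]
  bwd <- dr$contribution[!(paste(dr$from, dr$to) %in% paste(1:5, c(2:5, 1)))]
  expect_lt(max(abs(fwd - mean(fwd))) / mean(fwd), 1e-3)
  expect_lt(sum(bwd), 1e-4 * sum(fwd))
})

test_that("covariances agree with the spectral oracle on random networks", {
  withr::local_seed(99)
  for (seed in 1:10) {
    V <- 3 + seed %% 4
    net <- random_ergodic_network(V, min(V + 1, V * (V - 1) / 2),
                                  seed = 200 + seed)
    fr <- build_frame(net)
    D <- covariance_matrix(net, fr)$D
    ss <- steady_observables(net, fr)
    for (probe in 1:3) {
      sel <- sample(nrow(net), min(3, nrow(net)))
      w <- data.frame(from = net$from[sel], to = net$to[sel],
                      weight = rnorm(length(sel)))
      obs <- counting_observable(fr, w)
      tc <- tilted_cumulants(net, w)
      m_an <- evaluate_observable(obs, ss)
      v_an <- drop(obs$weights %*% D %*% obs$weights)
      expect_lt(abs(m_an - tc[["mean"]]) / max(abs(tc[["mean"]]), 1e-8), 1e-6)
      expect_lt(abs(v_an - tc[["var"]]) / max(abs(tc[["var"]]), 1e-8), 1e-6)
    }
  }
})
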