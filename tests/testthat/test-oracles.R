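test_that("gillespie counts are reproducible and match stationary rates", {
  net <- net2s()
  tr1 <- gillespie_simulate(net, 1e4, seed = 5)
  tr2 <- gillespie_simulate(net, 1e4, seed = 5)
  expect_identical(tr1$N, tr2$N)

  # one-way flux p12 = 1/2: N12/t within 3 SE (renewal SE ~ sqrt(p/t))
  expect_lt(abs(tr1$N["1", "2"] / 1e4 - 0.5), 3 * sqrt(0.5 / 1e4) * 2)

  neta <- net2a()
  tra <- gillespie_simulate(neta, 1e4, seed = 7)
  expect_lt(abs(tra$T_dwell["2"] / 1e4 - 2 / 3), 0.02)
  expect_lt(abs(sum(tra$T_dwell) - 1e4), 1e-6)

  # zero-duration trajectory
  tr0 <- gillespie_simulate(neta, 0, seed = 1)
  expect_equal(sum(tr0$N), 0)
  expect_equal(sum(tr0$T_dwell), 0)
})

test_that("noise sources are diagonal with variance pi_i k_ij", {
  net <- net2a()
  fr <- build_frame(net)
  es <- ensemble_statistics(net, fr, t = 2e3, n_traj = 400, seed = 13)

  # diagonal law: t Var(lambda_12) = pi_1 k_12 = 2/3
  v12 <- es$lambda_cov["1->2", "1->2"]
  se12 <- es$lambda_cov_se["1->2", "1->2"]
  expect_lt(abs(v12 - 2 / 3), 3 * se12)
  # off-diagonal vanishes
  c12 <- es$lambda_cov["1->2", "2->1"]
  se_c <- es$lambda_cov_se["1->2", "2->1"]
  expect_lt(abs(c12), 3 * max(se_c, 1e-3))
  # observable covariance brackets the analytic D
  expect_lt(abs(es$x_cov["dwell:2", "dwell:2"] - 4 / 27),
            3 * es$x_cov_se["dwell:2", "dwell:2"])
  expect_lt(abs(es$x_cov["traffic:1-2", "traffic:1-2"] - 40 / 27),
            3 * es$x_cov_se["traffic:1-2", "traffic:1-2"])
  # means
  m <- es$means
  expect_lt(abs(m$mean[m$observable == "dwell:2"] - 2 / 3),
            3 * m$se[m$observable == "dwell:2"])
})

test_that("noise map residual decays like 1/t", {
  net <- net2a()
  fr <- build_frame(net)
  res <- vapply(c(1e2, 1e3, 1e4), function(t) {
    ensemble_statistics(net, fr, t = t, n_traj = 30, seed = 3)$eq_residual[["max"]]
  }, numeric(1))
  # two decades of t: residual falls by roughly 100x; demand at least 10x
  expect_lt(res[3], res[1] / 10)
})

test_that("tilted-generator cumulants match renewal and steady-state values", {
  net <- net2a()
  st <- net_states(net)
  w <- matrix(0, 2, 2, dimnames = list(st, st))
  w["1", "2"] <- 1; w["2", "1"] <- 1
  tc <- tilted_cumulants(net, w)
  expect_close(tc[["mean"]], 4 / 3, tol = 1e-8)
  expect_close(tc[["var"]], 40 / 27, tol = 1e-6)

  # signed weights count net flux: J12 = 1/3 on the driven ring
  net3 <- net3c()
  w3 <- data.frame(from = c("1", "2"), to = c("2", "1"), weight = c(1, -1))
  tc3 <- tilted_cumulants(net3, w3)
  expect_close(tc3[["mean"]], 1 / 3, tol = 1e-8)

  # zero weights: untilted generator, both cumulants vanish
  tc0 <- tilted_cumulants(net, matrix(0, 2, 2, dimnames = list(st, st)))
  expect_close(tc0[["mean"]], 0, tol = 1e-10)
  expect_close(tc0[["var"]], 0, tol = 1e-8)
})

test_that("finite-difference responses reproduce closed forms", {
  net <- net2a()
  fr <- build_frame(net)
  expect_close(
    finite_difference_response(net, fr, obs_traffic(fr, "1", "2"), "1", "2"),
    4 / 9, tol = 1e-8)
  expect_close(
    finite_difference_response(net, fr, obs_dwell(fr, "2"), "2", "1"),
    -2 / 9, tol = 1e-8)
  expect_error(
    finite_difference_response(net, fr, obs_dwell(fr, "2"), "1", "2", h = 2),
    "h")
})

test_that("full audit passes on fixtures and reports render losslessly", {
  rep <- run_full_audit(net2a(), seed = 2)
  expect_true(rep$pass)
  rep6 <- run_full_audit(random_ergodic_network(6, 8, seed = 6), seed = 3)
  expect_true(rep6$pass)

  js <- render_report(rep, format = "json")
  parsed <- jsonlite::fromJSON(js)
  expect_true(parsed$pass)
  expect_equal(nrow(parsed$stages), length(rep$stages))
  tsv <- render_report(rep, format = "tsv")
  expect_true(grepl("stage\tpass", tsv))
  txt <- render_report(rep, format = "text")
  expect_true(grepl("overall: PASS", txt))
})

test_that("benchmark harness reports growing advantage for the analytic route", {
  bm <- benchmark_gradient_scaling(substeps = c(2L, 16L), seed = 1,
                                   min_time = 0.1)
  expect_equal(nrow(bm), 2L)
  expect_true(all(bm$ratio > 1))
  expect_gt(bm$ratio[2], bm$ratio[1])
})
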