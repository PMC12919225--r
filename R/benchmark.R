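#' Benchmark analytic vs brute-force flux-randomness gradients
#'
#' Times the full gradient of the randomness parameter over all rate
#' constants on Theta-shaped substep networks of growing size, comparing the
#' analytic inverse-Jacobian route (one factorization for all parameters)
#' against the brute-force baseline: central finite differences of the
#' tilted-generator dominant eigenvalue, recomputed for every parameter
#' perturbation.  Absolute timings are hardware-dependent; the informative
#' quantity is the cost ratio, which grows with system size.
#'
#' @param substeps Integer vector of substep counts `N`.
#' @param seed Seed (used only for reproducible timing-loop ordering).
#' @param min_time Minimum wall time per timing loop, seconds.
#' @return Tibble with `substeps`, `n_states`, `n_directed`, `t_analytic`,
#'   `t_bruteforce` (seconds per gradient) and `ratio`.
#' @export
benchmark_gradient_scaling <- function(substeps = c(4L, 8L, 16L, 32L, 64L),
                                       seed = 1L, min_time = 0.2) {
  withr::local_seed(seed)
  rows <- lapply(substeps, function(N) {
    net <- theta_motor_network(N)
    frame <- build_frame(net)
    mech <- attr(net, "mechanical_edge")
    flux <- edge_flux_observable(frame, mech[1], mech[2])
    W <- as_counting_weights(frame, flux)

    t_an <- time_per_run(function() randomness_gradient(net, frame, flux),
                         min_time)
    t_bf <- time_per_run(function() brute_force_randomness_gradient(net, W),
                         min_time)
    tibble::tibble(substeps = N, n_states = length(frame$states),
                   n_directed = nrow(frame$directed),
                   t_analytic = t_an, t_bruteforce = t_bf,
                   ratio = t_bf / t_an)
  })
  dplyr::bind_rows(rows)
}

# median per-run wall time after a discarded warmup; repeats until the
# accumulated time passes min_time so fast calls are averaged over many reps
time_per_run <- function(f, min_time) {
  f()  # warmup (JIT, allocator)
  times <- numeric(0)
  repeat {
    t0 <- proc.time()[["elapsed"]]
    f()
    times <- c(times, proc.time()[["elapsed"]] - t0)
    if (sum(times) >= min_time && length(times) >= 3L) break
    if (length(times) >= 200L) break
  }
  stats::median(times)
}

# brute-force baseline: for each directed rate, recompute r = var/|mean| from
# tilted-generator eigenvalues under k -> k (1 +/- h)
brute_force_randomness_gradient <- function(net, W, h = 1e-6) {
  r_of <- function(net2) {
    tc <- tilted_r_plain(net2, W)
    tc[["var"]] / abs(tc[["mean"]])
  }
  vapply(seq_len(nrow(net)), function(row) {
    up <- net; up$rate[row] <- up$rate[row] * (1 + h)
    dn <- net; dn$rate[row] <- dn$rate[row] * (1 - h)
    (r_of(up) - r_of(dn)) / (2 * h)
  }, numeric(1))
}

# plain (non-Richardson) spectral cumulants: the per-evaluation cost driver
tilted_r_plain <- function(net, W, s_step = 1e-4) {
  K <- rate_matrix(net)
  st <- rownames(K)
  W <- W[st, st, drop = FALSE]
  esc <- rowSums(K)
  lead <- function(s) {
    L <- K * exp(s * W)
    diag(L) <- diag(L) - esc
    max(Re(eigen(L, only.values = TRUE)$values))
  }
  lp <- lead(s_step); lm <- lead(-s_step); l0 <- lead(0)
  c(mean = (lp - lm) / (2 * s_step), var = (lp - 2 * l0 + lm) / s_step^2)
}
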