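#' Gillespie simulation with counting statistics
#'
#' Exact-jump stochastic simulation of the network for a duration `t`,
#' returning the transition counts per directed edge and the dwell time per
#' state (`sum(T) == t` exactly; the final dwell is truncated at `t`).  The
#' compiled kernel draws from R's RNG, so runs are reproducible under a seed.
#'
#' @param net A [rate_network()].
#' @param t Duration (`>= 0`).
#' @param seed Optional RNG seed.
#' @param state0 Starting state label; default samples from the stationary
#'   distribution (so finite-time averages are unbiased).
#' @return A [trajectory_counts()].
#' @export
gillespie_simulate <- function(net, t, seed = NULL, state0 = NULL) {
  stopifnot(t >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  K <- rate_matrix(net)
  st <- rownames(K)
  if (is.null(state0)) {
    pi <- stationary_distribution(net)
    state0 <- sample(st, 1L, prob = pi)
  }
  res <- ssa_counts(K, match(as.character(state0), st) - 1L, t)
  N <- res$N
  dimnames(N) <- list(st, st)
  trajectory_counts(N, setNames(res$T, st), t)
}

#' Ensemble statistics of counting observables and noise sources
#'
#' Simulates `n_traj` independent trajectories, evaluates the empirical
#' basis observables `x` and the per-transition noise sources
#' `lambda_ij = (N_ij - k_ij T_i)/t` on each, and returns their means and
#' scaled covariances `t Cov` with standard errors (batch means over
#' `n_batch` batches).  Also reports the per-trajectory residual of the
#' linear noise map `lambda ~ A x - grad c`, which vanishes as `1/t`.
#'
#' @inheritParams forces_from_rates
#' @param t Duration per trajectory.
#' @param n_traj Number of trajectories (`>= 2`).
#' @param seed RNG seed (one stream, trajectories drawn sequentially; the
#'   same `(seed, n_traj)` always reproduces the same statistics).
#' @param n_batch Batches for covariance standard errors.
#' @return A `caliber_ensemble` with tibble `means` (per observable), arrays
#'   `x_cov`/`x_cov_se` (scaled covariances of basis observables),
#'   `lambda_cov`/`lambda_cov_se`, and `eq_residual` (max and mean of the
#'   noise-map residual).
#' @export
ensemble_statistics <- function(net, frame, t, n_traj, seed = 1L,
                                n_batch = 20L) {
  stopifnot(n_traj >= 2)
  withr::local_seed(seed)
  K <- rate_matrix(net)
  st <- frame$states
  dirs <- frame$directed
  k_dir <- frame_rates(net, frame)
  nd <- nrow(dirs)
  pi <- stationary_distribution(net)

  jac <- build_jacobian(net, frame)
  A <- as.matrix(jac$A)

  X <- matrix(0, n_traj, nd)
  L <- matrix(0, n_traj, nd)
  resid <- numeric(n_traj)
  for (r in seq_len(n_traj)) {
    s0 <- sample(st, 1L, prob = pi)
    res <- ssa_counts(K, match(s0, st) - 1L, t)
    N <- res$N; dimnames(N) <- list(st, st)
    cnt <- structure(list(N = N, T_dwell = setNames(res$T, st), t = t),
                     class = "trajectory_counts")
    x <- empirical_observables(frame, cnt)
    lam <- (N[cbind(dirs$from, dirs$to)] -
              k_dir * res$T[match(dirs$from, st)]) / t
    X[r, ] <- x
    L[r, ] <- lam
    resid[r] <- max(abs(lam - (drop(A %*% x) - jac$grad_c)))
  }

  batch <- rep(seq_len(n_batch), length.out = n_traj)
  cov_batches <- function(M) {
    per <- lapply(seq_len(n_batch), function(b) t * cov(M[batch == b, ,
                                                           drop = FALSE]))
    arr <- simplify2array(per)
    list(mean = apply(arr, c(1, 2), mean),
         se = apply(arr, c(1, 2), sd) / sqrt(n_batch))
  }
  xc <- cov_batches(X)
  lc <- cov_batches(L)
  labels <- frame$basis$label
  dimnames(xc$mean) <- dimnames(xc$se) <- list(labels, labels)
  dl <- paste(dirs$from, dirs$to, sep = "->")
  dimnames(lc$mean) <- dimnames(lc$se) <- list(dl, dl)

  means <- tibble::tibble(
    observable = labels,
    mean = colMeans(X),
    se = apply(X, 2L, sd) / sqrt(n_traj)
  )
  structure(list(means = means, x_cov = xc$mean, x_cov_se = xc$se,
                 lambda_cov = lc$mean, lambda_cov_se = lc$se,
                 eq_residual = c(max = max(resid), mean = mean(resid)),
                 t = t, n_traj = n_traj, n_batch = n_batch, seed = seed),
            class = "caliber_ensemble")
}

#' @export
print.caliber_ensemble <- function(x, ...) {
  cat(sprintf(
    "# caliber_ensemble: %d trajectories of t = %g (noise-map residual max %.3g)\n",
    x$n_traj, x$t, x$eq_residual["max"]))
  print(x$means)
  invisible(x)
}

#' Tilted-generator cumulants of a counting observable
#'
#' The spectral oracle: builds the tilted generator with off-diagonal
#' entries `k_ij exp(s w_ij)` and differentiates its dominant eigenvalue at
#' `s = 0` by Richardson-extrapolated central differences.  The first and
#' second derivatives are the asymptotic mean and variance rates of the
#' counting functional `sum_ij w_ij N_ij / t`.
#'
#' @param net A [rate_network()].
#' @param weights V x V matrix of per-transition counting weights (dimnames
#'   = states), or a data frame with columns `from`, `to`, `weight`.
#' @param step Base finite-difference step in `s`.
#' @return Named vector `c(mean, var)`.
#' @export
tilted_cumulants <- function(net, weights, step = 5e-3) {
  K <- rate_matrix(net)
  st <- rownames(K)
  if (is.data.frame(weights)) {
    W <- matrix(0, nrow(K), ncol(K), dimnames = dimnames(K))
    W[cbind(as.character(weights$from), as.character(weights$to))] <-
      weights$weight
  } else {
    W <- weights[st, st, drop = FALSE]
  }
  esc <- rowSums(K)
  lead <- function(s) {
    L <- K * exp(s * W)
    diag(L) <- diag(L) - esc
    ev <- eigen(L, only.values = TRUE)$values
    max(Re(ev))
  }
  d1 <- function(h) (lead(h) - lead(-h)) / (2 * h)
  d2 <- function(h) (lead(h) - 2 * lead(0) + lead(-h)) / h^2
  h <- step
  mean_rate <- (4 * d1(h / 2) - d1(h)) / 3
  var_rate <- (4 * d2(h / 2) - d2(h)) / 3
  c(mean = mean_rate, var = var_rate)
}

#' Finite-difference response oracle
#'
#' Central difference of the recomputed stationary mean observable under
#' `k_edge -> k_edge (1 +/- h)`; approximates `d<x>/d log k` to `O(h^2)`.
#'
#' @inheritParams observable_gradient
#' @param from,to Directed edge to perturb.
#' @param h Relative step (must keep rates positive).
#' @return Scalar `d<x>/d log k_(from,to)`.
#' @export
finite_difference_response <- function(net, frame, obs, from, to, h = 1e-6) {
  stopifnot(h > 0, h < 1)
  val <- function(fac) {
    net2 <- net
    hit <- net2$from == from & net2$to == to
    if (!any(hit)) stop("edge (", from, ",", to, ") not found", call. = FALSE)
    net2$rate[hit] <- net2$rate[hit] * fac
    evaluate_observable(obs, steady_observables(net2, frame))
  }
  (val(1 + h) - val(1 - h)) / (2 * h)
}

#' Full finite-difference gradient of a mean observable
#'
#' Convenience wrapper applying [finite_difference_response()] to every
#' directed edge.
#'
#' @inheritParams observable_gradient
#' @param h Relative step.
#' @return Tibble per directed edge with `d_dlnk`.
#' @export
finite_difference_gradient <- function(net, frame, obs, h = 1e-6) {
  dirs <- frame$directed
  d <- vapply(seq_len(nrow(dirs)), function(r) {
    finite_difference_response(net, frame, obs, dirs$from[r], dirs$to[r], h)
  }, numeric(1))
  tibble::tibble(from = dirs$from, to = dirs$to, d_dlnk = d)
}
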