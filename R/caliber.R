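#' Caliber forces conjugate to the observable basis
#'
#' The forces are the derivatives of the trajectory path entropy (log path
#' probability ratio against the unit-rate reference process) with respect to
#' the counting observables:
#' \itemize{
#'   \item edge force `F_edge,ij = (1/2) log(k_ij * k_ji)`, conjugate to the
#'     symmetric edge traffic;
#'   \item node force `F_node,n = eps_m - eps_n`, where
#'     `eps_i = sum_j (k_ij - 1)` is the excess escape rate of node `i`
#'     relative to the unit-rate reference, conjugate to the dwell fraction;
#'   \item cycle force (affinity)
#'     `F_cycle,c = (1/2) log(prod forward rates / prod reverse rates)` around
#'     the oriented fundamental cycle, conjugate to the cycle net flux.
#' }
#' The edge force uses the rate *product* (symmetric combination): it is the
#' conjugate of traffic, while the antisymmetric log-ratio enters only through
#' the cycle affinities.  Both conventions are validated numerically against
#' closed-form two-state responses in the test suite.
#'
#' @param net A [rate_network()].
#' @param frame A [build_frame()] result on `net`.
#' @return Tibble with the basis table and a `force` column; the raw numeric
#'   vector (basis order) is in attribute `"force"`.
#' @export
forces_from_rates <- function(net, frame) {
  K <- rate_matrix(net)
  st <- frame$states
  eps <- rowSums(K - (K > 0))      # sum_j (k_ij - 1) over present edges
  e_tab <- frame$edges
  F_edge <- 0.5 * log(K[cbind(e_tab$i, e_tab$j)] * K[cbind(e_tab$j, e_tab$i)])
  F_node <- eps[frame$reference] - eps[st[-frame$m]]
  F_cycle <- vapply(seq_along(frame$cycles), function(ci) {
    0.5 * cycle_affinity(net, frame, ci)
  }, numeric(1))
  f <- c(F_edge, F_node, F_cycle)
  names(f) <- frame$basis$label
  out <- frame$basis
  out$force <- unname(f)
  attr(out, "force") <- f
  out
}

#' Caliber rate
#'
#' `c(k) = sum_{j != m} (k_mj - 1)`: the excess escape rate of the reference
#' node `m` relative to the unit-rate reference process.  It plays the role of
#' a log dynamical partition function per unit time: the asymptotic path
#' entropy is `F . x - c`.
#'
#' @inheritParams forces_from_rates
#' @return Scalar.
#' @export
caliber_rate <- function(net, frame) {
  out <- net[net$from == frame$reference, ]
  sum(out$rate - 1)
}

force_vector <- function(force) {
  if (is.data.frame(force)) {
    f <- attr(force, "force")
    if (is.null(f)) f <- force$force
    as.numeric(f)
  } else as.numeric(force)
}

#' Recover rates from forces
#'
#' Inverts the map `k -> F(k)` on a fixed frame by Newton iteration in
#' `log k`, using the analytic Jacobian `A = dF/d log k`.  The map is a
#' bijection for strictly positive rates; the iteration starts from the
#' unit-rate reference (all rates 1) unless a guess is supplied.
#'
#' @param force Target forces: the tibble from [forces_from_rates()] or a bare
#'   numeric vector in basis order.
#' @param frame A `cycle_frame` (fixes topology, basis and reference).
#' @param initial_guess Optional `rate_network` or numeric rates (directed
#'   index order) to start from.
#' @param tol Convergence tolerance on `max|F(k) - F_target|`.
#' @param max_iter Maximum Newton iterations.
#' @return A [rate_network()] whose forces reproduce `force`.
#' @export
rates_from_forces <- function(force, frame, initial_guess = NULL,
                              tol = 1e-10, max_iter = 100L) {
  f_target <- force_vector(force)
  stopifnot(length(f_target) == nrow(frame$basis))
  dirs <- frame$directed
  if (is.null(initial_guess)) {
    lnk <- numeric(nrow(dirs))
  } else if (inherits(initial_guess, "rate_network")) {
    lnk <- log(frame_rates(initial_guess, frame))
  } else {
    lnk <- log(as.numeric(initial_guess))
  }
  net_of <- function(lnk) {
    rate_network(tibble::tibble(from = dirs$from, to = dirs$to,
                                rate = exp(lnk)),
                 states = frame$states, reference_state = frame$reference)
  }
  # Newton in log k with a trust-region style cap on the step: the edge and
  # cycle forces are linear in log k, the node forces linear in k, so a
  # damped iteration converges from the unit-rate start
  for (it in seq_len(max_iter)) {
    net <- net_of(lnk)
    f_cur <- force_vector(forces_from_rates(net, frame))
    resid <- f_target - f_cur
    if (max(abs(resid)) <= tol) return(net)
    A <- build_jacobian(net, frame)$A
    delta <- as.numeric(Matrix::solve(Matrix::t(A), resid))
    cap <- max(abs(delta))
    if (cap > 2) delta <- delta * (2 / cap)
    lnk <- lnk + delta
  }
  stop("rates_from_forces did not converge: residual ",
       format(max(abs(resid))), call. = FALSE)
}

#' Trajectory counting statistics
#'
#' Container for the raw counts of a jump trajectory: `N[i, j]` transitions
#' `i -> j`, dwell times `T` per state, total duration `t` (with
#' `sum(T) == t`).
#'
#' @param N V x V count matrix with state dimnames, or a data frame with
#'   columns `from`, `to`, `count`.
#' @param T_dwell Named dwell-time vector.
#' @param t Total duration.
#' @return A `trajectory_counts` object.
#' @export
trajectory_counts <- function(N, T_dwell, t) {
  if (is.data.frame(N)) {
    st <- names(T_dwell)
    M <- matrix(0, length(st), length(st), dimnames = list(st, st))
    M[cbind(as.character(N$from), as.character(N$to))] <- N$count
    N <- M
  }
  stopifnot(abs(sum(T_dwell) - t) <= 1e-9 * max(t, 1))
  structure(list(N = N, T_dwell = T_dwell, t = t),
            class = "trajectory_counts")
}

#' @export
print.trajectory_counts <- function(x, ...) {
  cat(sprintf("# trajectory_counts: %d jumps over t = %g\n", sum(x$N), x$t))
  invisible(x)
}

#' Path entropy rate of a trajectory, raw and caliber form
#'
#' The raw form is the exact log path-probability ratio per unit time against
#' the unit-rate reference,
#' `[sum_ij N_ij log k_ij - sum_i T_i eps_i] / t`.  The caliber form is the
#' asymptotically equivalent expression `F . x - c` in the orthogonal
#' observable basis, with `x` the empirical rate observables read off the
#' counts.  The two differ by a boundary term of order `1/t` (Kirchhoff
#' imbalance and incomplete cycles at the trajectory ends).
#'
#' @inheritParams forces_from_rates
#' @param counts A [trajectory_counts()] on `net`'s support.
#' @return Tibble with columns `raw`, `caliber_form`, `gap`.
#' @export
path_entropy_rate <- function(net, frame, counts) {
  K <- rate_matrix(net)
  st <- frame$states
  extra <- setdiff(rownames(counts$N), st)
  if (length(extra) &&
      (sum(counts$N[extra, ]) + sum(counts$N[, extra])) > 0) {
    stop("counts on edges absent from the network", call. = FALSE)
  }
  N <- counts$N[st, st, drop = FALSE]
  if (any(N[K == 0] != 0)) {
    stop("counts on edges absent from the network", call. = FALSE)
  }
  eps <- rowSums(K - (K > 0))
  nz <- which(K > 0)
  raw <- (sum(N[nz] * log(K[nz])) - sum(counts$T_dwell[st] * eps)) / counts$t

  x <- empirical_observables(frame, counts)
  f <- force_vector(forces_from_rates(net, frame))
  caliber_form <- sum(f * x) - caliber_rate(net, frame)
  tibble::tibble(raw = raw, caliber_form = caliber_form,
                 gap = raw - caliber_form)
}

# empirical basis observables (rates) from trajectory counts
empirical_observables <- function(frame, counts) {
  N <- counts$N[frame$states, frame$states, drop = FALSE]
  t <- counts$t
  e_tab <- frame$edges
  phi <- (N[cbind(e_tab$i, e_tab$j)] + N[cbind(e_tab$j, e_tab$i)]) / t
  f_dwell <- counts$T_dwell[frame$states[-frame$m]] / t
  psi <- vapply(frame$chords, function(ch) {
    (N[e_tab$i[ch], e_tab$j[ch]] - N[e_tab$j[ch], e_tab$i[ch]]) / t
  }, numeric(1))
  out <- c(phi, f_dwell, psi)
  names(out) <- frame$basis$label
  out
}
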