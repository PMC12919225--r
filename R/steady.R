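#' Stationary distribution of a rate network
#'
#' Solves the master-equation global balance `pi^T Q = 0`, `sum(pi) = 1`,
#' by LU factorization of the rate matrix with one balance row replaced by the
#' normalization row.  No eigen-iteration is used, so the result is
#' deterministic to solver precision.
#'
#' @param net A [rate_network()].
#' @param tol Relative residual tolerance on global balance.
#' @return Named probability vector over the states.
#' @export
stationary_distribution <- function(net, tol = 1e-12) {
  K <- rate_matrix(net)
  V <- nrow(K)
  Q <- K - diag(rowSums(K))
  M <- t(Q)
  M[V, ] <- 1
  b <- c(rep(0, V - 1L), 1)
  if (rcond(M) < 1e-14) stop("degenerate network: singular balance system",
                             call. = FALSE)
  pi <- drop(solve(M, b))
  resid <- max(abs(drop(pi %*% Q))) / max(K)
  if (!all(is.finite(pi)) || resid > tol) {
    stop("degenerate network: balance residual ", format(resid), call. = FALSE)
  }
  if (any(pi <= 0)) stop("degenerate network: non-positive stationary mass",
                         call. = FALSE)
  setNames(pi, rownames(K))
}

#' Steady-state rate observables
#'
#' Computes every mean observable of the caliber basis at stationarity: the
#' stationary distribution `pi`, one-way fluxes `p_ij = pi_i k_ij`, traffic
#' `tau_ij = p_ij + p_ji`, net edge fluxes `J_ij = p_ij - p_ji`, fundamental
#' cycle fluxes (the net flux on each chord, signed by the chord's canonical
#' direction), and the caliber rate `c = sum_{j != m} (k_mj - 1)`, the excess
#' escape rate of the reference node relative to the unit-rate reference
#' process.
#'
#' @param net A [rate_network()].
#' @param frame A [build_frame()] result on `net`.
#' @return A `caliber_steady` object; see [tidy.caliber_steady()] for the
#'   per-edge table and `$mean_x` for the mean observable vector in basis
#'   order (traffic, dwell, cycle blocks).
#' @export
steady_observables <- function(net, frame) {
  pi <- stationary_distribution(net)
  k_dir <- frame_rates(net, frame)
  dirs <- frame$directed
  p_dir <- pi[dirs$from] * k_dir

  E <- nrow(frame$edges)
  p_fwd <- p_dir[dirs$canonical]
  p_rev <- p_dir[!dirs$canonical]
  tau <- p_fwd + p_rev
  J <- p_fwd - p_rev

  J_cycle <- J[frame$chords]
  caliber <- caliber_rate(net, frame)

  mean_x <- c(tau, pi[frame$states[-frame$m]], J_cycle)
  names(mean_x) <- frame$basis$label

  structure(list(
    pi = pi,
    edges = tibble::tibble(e = frame$edges$e, i = frame$edges$i,
                           j = frame$edges$j, p_fwd = unname(p_fwd),
                           p_rev = unname(p_rev), tau = unname(tau),
                           J = unname(J)),
    p_dir = setNames(unname(p_dir), paste(dirs$from, dirs$to, sep = "->")),
    J_cycle = unname(J_cycle),
    caliber_rate = caliber,
    mean_x = mean_x,
    frame = frame
  ), class = "caliber_steady")
}

#' @export
print.caliber_steady <- function(x, ...) {
  cat(sprintf("# steady state: %d states, caliber rate c = %.6g\n",
              length(x$pi), x$caliber_rate))
  print(x$edges)
  invisible(x)
}

#' @rdname steady_observables
#' @param x A `caliber_steady` object.
#' @param ... Unused.
#' @export
tidy.caliber_steady <- function(x, ...) x$edges

#' @export
glance.caliber_steady <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$pi),
    caliber_rate = x$caliber_rate,
    total_traffic = sum(x$edges$tau),
    max_cycle_flux = if (length(x$J_cycle)) max(abs(x$J_cycle)) else 0,
    balance_residual = max(abs(
      vapply(names(x$pi), function(n) {
        out <- sum(x$p_dir[startsWith(names(x$p_dir), paste0(n, "->"))])
        inn <- sum(x$p_dir[endsWith(names(x$p_dir), paste0("->", n))])
        out - inn
      }, numeric(1))))
  )
}

#' Net-flux observable of a directed edge
#'
#' Expresses the stationary net flux through a given directed edge as a signed
#' combination of the fundamental-cycle flux coordinates: a chord maps to the
#' unit vector on its own cycle, a tree edge to the signed incidence over all
#' cycles that traverse it (Kirchhoff decomposition).  Evaluating the
#' coefficients against a steady state reproduces `p_ij - p_ji`.
#'
#' @param frame A `cycle_frame`.
#' @param from,to State labels of the directed edge.
#' @return A `cft_observable` coefficient vector.
#' @export
edge_flux_observable <- function(frame, from, to) {
  e_tab <- frame$edges
  hit <- which((e_tab$i == from & e_tab$j == to) |
                 (e_tab$i == to & e_tab$j == from))
  if (!length(hit)) stop("edge (", from, ",", to, ") not found", call. = FALSE)
  e <- hit[1L]
  w <- numeric(nrow(frame$basis))
  for (ci in seq_along(frame$cycles)) {
    cyc <- frame$cycles[[ci]]
    rows <- which(cyc$e == e)
    for (s in rows) {
      sgn <- if (cyc$from[s] == from && cyc$to[s] == to) 1 else -1
      w[basis_index(frame, "cycle", cycle = ci)] <-
        w[basis_index(frame, "cycle", cycle = ci)] + sgn
    }
  }
  new_observable(frame, w, paste0("edgeflux:", from, "->", to))
}
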