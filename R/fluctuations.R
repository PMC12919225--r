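#' Asymptotic covariance matrix of the basis observables
#'
#' Each transition `i -> j` carries an independent noise source
#' `lambda_ij = (N_ij - k_ij T_i)/t` with asymptotic variance `pi_i k_ij / t`
#' and vanishing cross-covariances.  Projecting the basis observables onto
#' these orthogonal axes gives the scaled asymptotic covariances
#' `D = A^-1 diag(pi_i k_ij) A^-T`, where
#' `D[alpha, beta] = lim t Cov(x_alpha, x_beta)`.  `D` is symmetric positive
#' semidefinite and equals the force-susceptibility matrix (fluctuation
#' equals response).
#'
#' @inheritParams forces_from_rates
#' @return A `caliber_covariance` with dense `D` and index maps.
#' @export
covariance_matrix <- function(net, frame) {
  core <- compute_core(net, frame)
  Ainv <- core$inv$Ainv
  if (is.null(Ainv)) Ainv <- t(core$inv$solve_t(diag(nrow(core$jac$A))))
  B <- sweep(Ainv, 2L, sqrt(core$pk), `*`)
  D <- tcrossprod(B)
  D <- (D + t(D)) / 2
  dimnames(D) <- list(frame$basis$label, frame$basis$label)
  structure(list(D = D, steady = core$ss, pk = core$pk, Ainv = Ainv,
                 frame = frame),
            class = "caliber_covariance")
}

#' @export
print.caliber_covariance <- function(x, ...) {
  cat(sprintf("# caliber_covariance: %d x %d scaled asymptotic covariances\n",
              nrow(x$D), ncol(x$D)))
  invisible(x)
}

#' @rdname covariance_matrix
#' @param x A `caliber_covariance`.
#' @param ... Unused.
#' @export
tidy.caliber_covariance <- function(x, ...) {
  tibble::tibble(
    observable_1 = rep(rownames(x$D), times = ncol(x$D)),
    observable_2 = rep(colnames(x$D), each = nrow(x$D)),
    t_cov = as.vector(x$D)
  )
}

#' Force-susceptibility matrix
#'
#' The susceptibility of every mean observable to every conjugate force,
#' `S[alpha, beta] = d<x_alpha>/dF_beta`, obtained by pushing the rate
#' responses back through the Jacobian chain rule: `S = R A^-T`.  By the
#' fluctuation-response duality `S` equals the covariance matrix `D`; it is
#' symmetric (generalized Maxwell-Onsager reciprocity far from equilibrium)
#' with strictly positive diagonal (monotonic own-force response).
#'
#' @inheritParams forces_from_rates
#' @return Dense matrix with basis labels on both dimensions.
#' @export
force_susceptibility <- function(net, frame) {
  resp <- response_matrix(net, frame)
  S <- resp$R %*% t(resp$Ainv)
  dimnames(S) <- list(frame$basis$label, frame$basis$label)
  S
}

#' Covariance of a quantity (variance of an observable)
#' @param cov_mat A `caliber_covariance`.
#' @param obs,obs2 Observables; `obs2` defaults to `obs`.
#' @return Scalar scaled covariance `lim t Cov(x_obs, x_obs2)`.
#' @export
observable_covariance <- function(cov_mat, obs, obs2 = obs) {
  drop(obs$weights %*% cov_mat$D %*% obs2$weights)
}

#' Projections of an observable onto the independent noise sources
#'
#' For the unit-variance noise source at transition `i -> j`, the projection
#' is `sqrt(t) Cov(x, lambda-hat_ij) = sqrt(pi_i k_ij) [A^-T w]_(ij)`.  The
#' squared projections sum to the scaled variance rate of the observable —
#' a per-transition variance budget.
#'
#' @inheritParams observable_gradient
#' @return Tibble per directed edge with `projection` and `squared`.
#' @export
noise_projections <- function(net, frame, obs) {
  core <- compute_core(net, frame)
  g <- as.numeric(core$inv$solve_t(obs$weights))
  proj <- sqrt(core$pk) * g
  tibble::tibble(from = frame$directed$from, to = frame$directed$to,
                 projection = proj, squared = proj^2)
}

# internal: mean, variance rate and per-edge variance shares of a flux obs
flux_statistics <- function(net, frame, flux_obs) {
  core <- compute_core(net, frame)
  mean_psi <- sum(flux_obs$weights * core$ss$mean_x)
  g <- as.numeric(core$inv$solve_t(flux_obs$weights))
  shares <- core$pk * g^2
  list(core = core, mean = mean_psi, var = sum(shares), shares = shares)
}

#' Randomness parameter (Fano factor) of a net flux
#'
#' The ratio `lim t Var(psi) / <psi>`: the long-time variance-to-mean ratio of a
#' counting flux: 1 for a Poisson process, `1/N` for a cycle of `N`
#' near-deterministic sequential steps.  The flux is oriented so its mean is
#' positive; `r` is reported positive.
#'
#' @inheritParams observable_gradient
#' @param flux_obs A flux observable (e.g. [obs_cycle()] or
#'   [edge_flux_observable()]).
#' @param tol Mean-flux magnitude below which the flux counts as stalled.
#' @return Scalar `r`, with attributes `mean_flux` and `var_rate`.
#' @export
randomness_parameter <- function(net, frame, flux_obs, tol = 1e-12) {
  fs <- flux_statistics(net, frame, flux_obs)
  if (abs(fs$mean) <= tol) {
    stop("stalled flux: mean is zero, randomness parameter undefined",
         call. = FALSE)
  }
  structure(fs$var / abs(fs$mean), mean_flux = fs$mean, var_rate = fs$var)
}

#' Per-transition decomposition of the randomness parameter
#'
#' Exact identity: r equals `(1/<psi>) sum_ij (k_ij / pi_i) (d<psi>/dk_ij)^2`.
#' Each directed transition contributes its squared flux sensitivity,
#' weighted by its intrinsic noise level — a highly responsive step amplifies
#' its own noise into the flux variance.  Contributions are non-negative and
#' sum to `r` exactly (up to float).  Optional metadata group labels give
#' stacked group sums.
#'
#' @inheritParams randomness_parameter
#' @param groups Optional character vector of group labels to include in the
#'   group summary; defaults to all labels found on the network's edges.
#' @return Tibble per directed edge (`from`, `to`, `group`, `contribution`,
#'   `share`) with attributes `r`, `mean_flux` and `group_summary` (a
#'   tibble of group sums); `glance()` returns the one-row summary.
#' @export
randomness_decomposition <- function(net, frame, flux_obs, groups = NULL) {
  fs <- flux_statistics(net, frame, flux_obs)
  if (abs(fs$mean) <= 1e-12) {
    stop("stalled flux: mean is zero, randomness parameter undefined",
         call. = FALSE)
  }
  contrib <- fs$shares / abs(fs$mean)
  key_net <- paste(net$from, net$to, sep = "\r")
  key_dir <- paste(frame$directed$from, frame$directed$to, sep = "\r")
  grp <- net$group[match(key_dir, key_net)]
  valid <- unique(grp[!is.na(grp)])
  if (!is.null(groups)) {
    unknown <- setdiff(groups, valid)
    if (length(unknown)) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           "; valid labels: ",
           if (length(valid)) paste(valid, collapse = ", ") else "(none)",
           call. = FALSE)
    }
    valid <- groups
  }
  out <- tibble::tibble(from = frame$directed$from, to = frame$directed$to,
                        group = grp, contribution = contrib,
                        share = contrib / sum(contrib))
  gs <- dplyr::summarise(
    dplyr::group_by(out[!is.na(out$group) & out$group %in% valid, ],
                    .data$group),
    contribution = sum(.data$contribution), .groups = "drop")
  attr(out, "r") <- sum(contrib)
  attr(out, "mean_flux") <- fs$mean
  attr(out, "group_summary") <- gs
  class(out) <- c("caliber_decomposition", class(out))
  out
}

#' @export
glance.caliber_decomposition <- function(x, ...) {
  tibble::tibble(r = attr(x, "r"), mean_flux = attr(x, "mean_flux"),
                 n_transitions = nrow(x),
                 top_transition = paste(x$from[which.max(x$contribution)],
                                        x$to[which.max(x$contribution)],
                                        sep = "->"))
}

#' @export
autoplot.caliber_decomposition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$transition <- paste(df$from, df$to, sep = "→")
  df$transition <- factor(df$transition,
                          levels = df$transition[order(-df$contribution)])
  df$group <- ifelse(is.na(df$group), "(ungrouped)", df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$transition,
                                   y = .data$contribution,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "transition", y = "contribution to r",
                  title = sprintf("randomness parameter r = %.4g",
                                  attr(object, "r"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
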