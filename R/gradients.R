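#' Derivative of the Jacobian with respect to one log-rate
#'
#' `dA / d log k_ab` is nonzero only in row `(a->b)`, restricted to the
#' node-force columns: the edge- and cycle-force columns are rate-independent
#' constants.  The nonzero entries are `k_ab (delta_{a,m} - delta_{a,n})`.
#'
#' @inheritParams forces_from_rates
#' @param from,to State labels of the directed edge.
#' @return Sparse 2E x 2E matrix.
#' @export
jacobian_derivative <- function(net, frame, from, to) {
  d0 <- frame_d_index(frame, from, to)
  k <- edge_rate(net, from, to)
  b <- frame$basis
  nd <- nrow(frame$directed)
  node_cols <- which(b$type == "dwell")
  if (from == frame$reference) {
    cols <- node_cols
    vals <- rep(k, length(node_cols))
  } else {
    cols <- node_cols[b$state[node_cols] == from]
    vals <- rep(-k, length(cols))
  }
  Matrix::sparseMatrix(i = rep(d0, length(cols)), j = cols, x = vals,
                       dims = c(nd, nd))
}

# analytic gradient of D_ww (scaled variance of obs) over all log-rates.
# Uses the closure dA^-1 = -A^-1 (dA) A^-1 and the RIM derivative of the
# noise weights pi_i k_ij; everything comes from one factorization.
variance_gradient_core <- function(net, frame, obs, core = NULL) {
  if (is.null(core)) core <- compute_core(net, frame)
  fr <- frame
  dirs <- fr$directed
  nd <- nrow(dirs)
  g <- as.numeric(core$inv$solve_t(obs$weights))      # A^-T w, per directed edge
  h <- as.numeric(core$inv$solve(core$pk * g))        # A^-1 (pk o g), per basis

  # d pi_i / d ln k_ab for every state i (V x 2E) via RIM
  dw_idx <- which(fr$basis$type == "dwell")
  Ainv <- core$inv$Ainv
  if (is.null(Ainv)) Ainv <- t(core$inv$solve_t(diag(nd)))
  R_dwell <- sweep(Ainv[dw_idx, , drop = FALSE], 2L, core$pk, `*`)
  dpi <- matrix(0, length(fr$states), nd, dimnames = list(fr$states, NULL))
  dpi[fr$basis$state[dw_idx], ] <- R_dwell
  dpi[fr$reference, ] <- -colSums(R_dwell)

  # term 1: d(pk) o g^2, with d(pi_i k_ij)/dlnk_ab = pk delta + k_ij dpi_i
  s_node <- vapply(fr$states, function(i) {
    rows <- which(dirs$from == i)
    sum(core$jac$k_dir[rows] * g[rows]^2)
  }, numeric(1))
  term1 <- core$pk * g^2 + drop(s_node %*% dpi)

  # term 2: -2 v^T h per edge, v supported on node-force coordinates
  h_node <- setNames(h[dw_idx], fr$basis$state[dw_idx])
  H <- sum(h_node)
  vterm <- ifelse(dirs$from == fr$reference,
                  core$jac$k_dir * g * H,
                  -core$jac$k_dir * g * h_node[dirs$from])
  term2 <- -2 * as.numeric(vterm)

  term1 + term2
}

#' Analytic gradient of an observable's scaled variance
#'
#' Gradient of `D_ww = lim t Var(x_w)` with respect to every rate, assembled
#' from the algebraic closure `dA^-1 = -A^-1 (dA) A^-1` plus the RIM
#' derivative of the per-transition noise weights `pi_i k_ij`.  A single
#' factorization of `A` serves all `2E` partial derivatives.
#'
#' @inheritParams observable_gradient
#' @return Tibble per directed edge with `d_var_dlnk` and `d_var_dk`; the
#'   attribute `"method"` is `"analytic"`.
#' @export
covariance_gradient <- function(net, frame, obs) {
  core <- compute_core(net, frame)
  grad <- variance_gradient_core(net, frame, obs, core)
  out <- tibble::tibble(from = frame$directed$from, to = frame$directed$to,
                        rate = core$jac$k_dir, d_var_dlnk = grad,
                        d_var_dk = grad / core$jac$k_dir)
  attr(out, "method") <- "analytic"
  out
}

#' Analytic gradient of the randomness parameter
#'
#' `grad r = (grad D_psi - r grad <psi>) / <psi>` with both pieces analytic;
#' the full vector over all rates comes from one factorization of `A`.
#'
#' @inheritParams randomness_parameter
#' @return Tibble per directed edge with `d_r_dlnk` and `d_r_dk`, attribute
#'   `"r"` carrying the current value.
#' @export
randomness_gradient <- function(net, frame, flux_obs) {
  fs <- flux_statistics(net, frame, flux_obs)
  if (abs(fs$mean) <= 1e-12) {
    stop("stalled flux: mean is zero, randomness parameter undefined",
         call. = FALSE)
  }
  obs <- flux_obs
  sgn <- 1
  if (fs$mean < 0) {   # orient the flux positively
    obs <- new_observable(frame, -flux_obs$weights, flux_obs$label)
    sgn <- -1
  }
  mean_psi <- abs(fs$mean)
  r <- fs$var / mean_psi
  grad_var <- variance_gradient_core(net, frame, obs, fs$core)
  g <- as.numeric(fs$core$inv$solve_t(obs$weights))
  grad_mean <- fs$core$pk * g
  grad_r <- (grad_var - r * grad_mean) / mean_psi
  out <- tibble::tibble(from = frame$directed$from, to = frame$directed$to,
                        rate = fs$core$jac$k_dir, d_r_dlnk = grad_r,
                        d_r_dk = grad_r / fs$core$jac$k_dir)
  attr(out, "r") <- r
  attr(out, "orientation") <- sgn
  out
}

#' One projected gradient step on the rates
#'
#' A fixed-step design primitive: moves `log k` along the gradient of the
#' chosen objective (`"max_flux"` ascends the mean flux, `"min_randomness"`
#' descends the randomness parameter), leaving constrained edges untouched.
#' For sufficiently small steps the objective cannot move in the forbidden
#' direction.
#'
#' @inheritParams randomness_parameter
#' @param objective `"max_flux"` or `"min_randomness"`.
#' @param step Positive step size in `log k`.
#' @param fixed_edges Optional list of directed edges (length-2 character
#'   vectors `c(from, to)`) to hold fixed.
#' @return The updated [rate_network()], with attribute `"objective_delta"`
#'   (new minus old objective value).
#' @export
design_step <- function(net, frame, objective = c("min_randomness", "max_flux"),
                        flux_obs, step, fixed_edges = NULL) {
  objective <- match.arg(objective)
  if (!is.numeric(step) || step < 0) stop("step must be >= 0", call. = FALSE)
  dirs <- frame$directed
  if (objective == "min_randomness") {
    gr <- randomness_gradient(net, frame, flux_obs)
    direction <- -gr$d_r_dlnk
    value <- function(n) as.numeric(randomness_parameter(n, frame, flux_obs))
  } else {
    og <- observable_gradient(net, frame, flux_obs)
    mean0 <- evaluate_observable(flux_obs, steady_observables(net, frame))
    direction <- if (mean0 < 0) -og$d_dlnk else og$d_dlnk
    value <- function(n) abs(evaluate_observable(
      flux_obs, steady_observables(n, frame)))
  }
  free <- rep(TRUE, nrow(dirs))
  for (fe in fixed_edges) {
    free[dirs$from == fe[1] & dirs$to == fe[2]] <- FALSE
  }
  if (!any(free)) {
    warning("all edges constrained: network unchanged", call. = FALSE)
    direction[] <- 0
  }
  direction[!free] <- 0
  lnk <- log(frame_rates(net, frame)) + step * direction
  key_net <- paste(net$from, net$to, sep = "\r")
  key_dir <- paste(dirs$from, dirs$to, sep = "\r")
  new_net <- net
  new_net$rate <- exp(lnk)[match(key_net, key_dir)]
  v0 <- value(net); v1 <- value(new_net)
  attr(new_net, "objective_delta") <- v1 - v0
  new_net
}
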