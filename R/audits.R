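#' Universal response-symmetry residuals
#'
#' Evaluates, for every basis observable, the three universal identities that
#' follow from `A^-1 A = I`:
#' \itemize{
#'   \item node escaping: `sum_l (k_ml/pi_m) d<x>/dk_ml -
#'     sum_j (k_nj/pi_n) d<x>/dk_nj = 1` if `<x>` is node `n`'s own occupancy,
#'     else 0;
#'   \item edge reciprocity: `(1/pi_i) d<x>/dk_ij + (1/pi_j) d<x>/dk_ji = 2`
#'     if `<x>` is the edge's own traffic, else 0;
#'   \item cycle symmetry: the oriented sum around a fundamental cycle of
#'     `(1/pi_i) d<x>/dk_ij` minus the reverse-oriented sum of
#'     `(1/pi_j) d<x>/dk_ji` equals 2 if `<x>` is that cycle's own net flux,
#'     else 0.
#' }
#' Because `d<x_alpha>/dk_ij = pi_i k_ij [A^-1]_{alpha,(ij)} / k_ij`, each
#' left-hand side is a signed sum of inverse-Jacobian entries, so the
#' residuals test the implementation's internal consistency at solver
#' precision.
#'
#' @param resp A `caliber_response` from [response_matrix()], or a
#'   [rate_network()] (with `frame`) from which one is computed.
#' @param frame Required when `resp` is a network.
#' @return Tibble with columns `identity`, `unit`, `observable`, `lhs`,
#'   `expected`, `residual`.
#' @export
symmetry_residuals <- function(resp, frame = NULL) {
  if (inherits(resp, "rate_network")) {
    stopifnot(!is.null(frame))
    resp <- response_matrix(resp, frame)
  }
  fr <- resp$frame
  Ainv <- resp$Ainv
  b <- fr$basis
  dirs <- fr$directed
  obs_labels <- b$label
  rows <- list()

  # node identity: (1/pi_m) sum_l R[a,(ml)] - (1/pi_n) sum_j R[a,(nj)]
  pi <- resp$steady$pi
  for (n in fr$states[-fr$m]) {
    r_m <- which(dirs$from == fr$reference)
    r_n <- which(dirs$from == n)
    lhs <- (rowSums(resp$R[, r_m, drop = FALSE]) / pi[fr$reference]) -
      (rowSums(resp$R[, r_n, drop = FALSE]) / pi[n])
    expected <- as.numeric(b$type == "dwell" & !is.na(b$state) & b$state == n)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      identity = "node", unit = paste0("node:", n), observable = obs_labels,
      lhs = unname(lhs), expected = expected, residual = unname(lhs) - expected)
  }

  # edge identity: [A^-1]_{a,(ij)} + [A^-1]_{a,(ji)}
  for (e in seq_len(nrow(fr$edges))) {
    d_f <- 2L * e - 1L; d_r <- 2L * e
    lhs <- Ainv[, d_f] + Ainv[, d_r]
    expected <- as.numeric(b$type == "traffic" & !is.na(b$edge) & b$edge == e)
    expected <- 2 * expected
    rows[[length(rows) + 1L]] <- tibble::tibble(
      identity = "edge",
      unit = paste0("edge:", fr$edges$i[e], "-", fr$edges$j[e]),
      observable = obs_labels, lhs = unname(lhs), expected = expected,
      residual = unname(lhs) - expected)
  }

  # cycle identity: oriented sum of [A^-1]_{a,(ij)} - reverse of [A^-1]_{a,(ji)}
  for (ci in seq_along(fr$cycles)) {
    cyc <- fr$cycles[[ci]]
    lhs <- numeric(nrow(b))
    for (s in seq_len(nrow(cyc))) {
      d_f <- frame_d_index(fr, cyc$from[s], cyc$to[s])
      d_r <- frame_d_index(fr, cyc$to[s], cyc$from[s])
      lhs <- lhs + Ainv[, d_f] - Ainv[, d_r]
    }
    expected <- 2 * as.numeric(b$type == "cycle" & !is.na(b$cycle) &
                                 b$cycle == ci)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      identity = "cycle", unit = paste0("cycle:", ci),
      observable = obs_labels, lhs = unname(lhs), expected = expected,
      residual = unname(lhs) - expected)
  }
  dplyr::bind_rows(rows)
}

#' Delta/nabla response coefficients per edge
#'
#' The net-flux and traffic self-responses of an edge define the
#' coefficients `Delta_ij = 1 - (1/pi_i) dJ_ij/dk_ij` and
#' `nabla_ij = (1/pi_i) dtau_ij/dk_ij - 1`, which obey the algebraic
#' constraints `0 <= Delta_ij <= 1` and `nabla_ij <= Delta_ij` on every
#' ergodic network.
#'
#' @inheritParams symmetry_residuals
#' @return Tibble per directed edge with `Delta`, `nabla`, `J`.
#' @export
delta_nabla_coefficients <- function(resp, frame = NULL) {
  if (inherits(resp, "rate_network")) {
    stopifnot(!is.null(frame))
    resp <- response_matrix(resp, frame)
  }
  bh <- bound_hierarchy_check(resp, check = FALSE)
  dtau <- bh$dp_fwd + bh$dp_rev
  dJ <- bh$dp_fwd - bh$dp_rev
  tibble::tibble(from = bh$from, to = bh$to,
                 Delta = 1 - dJ / bh$pi_i,
                 nabla = dtau / bh$pi_i - 1,
                 J = bh$J)
}

#' Kinetic bound hierarchy on one-way flux responses
#'
#' For every directed edge, computes the self- and cross-responses of the
#' one-way fluxes, `dp_ij/dk_ij = pi_i + k_ij dpi_i/dk_ij` and
#' `dp_ji/dk_ij = k_ji dpi_j/dk_ij`, and checks the hierarchy
#' `pi_i >= dp_ij/dk_ij >= dp_ji/dk_ij >= 0` (population depletion,
#' causality, Le Chatelier-like compensation).  The middle inequality is
#' tight when the edge's net flux cannot respond to its forward rate
#' (`dJ_ij/dk_ij = 0`), which forces `J_ij = 0`; structurally this is the
#' topological-bridge case.  Note the converse fails: an edge of a
#' detailed-balanced cycle has `J_ij = 0`, yet a single-rate perturbation
#' breaks detailed balance and creates first-order net flux.
#'
#' @inheritParams symmetry_residuals
#' @param tol Violation tolerance; exceeding it raises an error naming the
#'   edge (it indicates an implementation bug, not a physical possibility).
#' @param check If `FALSE`, skip the hard assertion and just return the table.
#' @return Tibble per directed edge with `pi_i`, `dp_fwd` (`dp_ij/dk_ij`),
#'   `dp_rev` (`dp_ji/dk_ij`), `J`, and `saturated` (middle equality flag).
#' @export
bound_hierarchy_check <- function(resp, frame = NULL, tol = 1e-10,
                                  check = TRUE) {
  if (inherits(resp, "rate_network")) {
    stopifnot(!is.null(frame))
    resp <- response_matrix(resp, frame)
  }
  fr <- resp$frame
  dirs <- fr$directed
  pi <- resp$steady$pi
  dpi <- dpi_matrix(resp)           # d pi_s / d ln k_(ab), V x 2E
  k_dir <- resp$k_dir
  nd <- nrow(dirs)

  # reverse directed index of each directed edge
  rev_idx <- ifelse(dirs$canonical, dirs$d + 1L, dirs$d - 1L)
  pi_i <- pi[dirs$from]
  # dp_ij/dk_ij = pi_i + k_ij dpi_i/dk_ij; dpi/dk = dpi/dlnk / k
  dpi_own <- dpi[cbind(match(dirs$from, fr$states), dirs$d)]
  dp_fwd <- pi_i + dpi_own
  dpi_cross <- dpi[cbind(match(dirs$to, fr$states), dirs$d)]
  dp_rev <- k_dir[rev_idx] * dpi_cross / k_dir
  p_dir <- pi_i * k_dir
  J_dir <- p_dir - pi[dirs$to] * k_dir[rev_idx]

  out <- tibble::tibble(from = dirs$from, to = dirs$to,
                        pi_i = unname(pi_i), dp_fwd = unname(dp_fwd),
                        dp_rev = unname(dp_rev), J = unname(J_dir),
                        saturated = abs(unname(dp_fwd) - unname(dp_rev)) <= tol)
  if (check) {
    viol <- which(out$pi_i < out$dp_fwd - tol | out$dp_fwd < out$dp_rev - tol |
                    out$dp_rev < -tol)
    if (length(viol)) {
      v <- viol[1L]
      stop("kinetic bound hierarchy violated on edge (", out$from[v], ",",
           out$to[v], "): this indicates an implementation bug",
           call. = FALSE)
    }
  }
  out
}

#' Ensemble scatter of normalized one-way flux responses
#'
#' Samples random connected reversible networks and records, for every
#' directed edge, the pair `x = (1/pi_i) dp_ij/dk_ij`,
#' `y = (1/pi_i) dp_ji/dk_ij`.  All points lie in the triangle
#' `1 >= x >= y >= 0`; bridge edges (zero structural net flux) sit on the
#' diagonal `x = y`.
#'
#' @param V States per network.
#' @param count Number of networks.
#' @param seed RNG seed.
#' @param E Undirected edges per network; default samples uniformly in
#'   `[V-1, V(V-1)/2]` per network.
#' @param rate_bounds Log-uniform rate bounds.
#' @param detailed_balance If `TRUE`, rates are built from node potentials
#'   and symmetric edge factors so every cycle affinity vanishes.
#' @return A `caliber_bound_scatter` tibble with columns `network`, `from`,
#'   `to`, `x`, `y`.
#' @export
ensemble_bound_scatter <- function(V, count, seed, E = NULL,
                                   rate_bounds = c(0.1, 10),
                                   detailed_balance = FALSE) {
  stopifnot(count >= 1)
  withr::local_seed(seed)
  rows <- vector("list", count)
  for (s in seq_len(count)) {
    Es <- if (is.null(E)) sample(seq(V - 1L, V * (V - 1L) / 2L), 1L) else E
    net <- random_ergodic_network(V, Es, seed = NULL,
                                  rate_bounds = rate_bounds,
                                  detailed_balance = detailed_balance)
    fr <- build_frame(net)
    bh <- bound_hierarchy_check(net, fr)
    rows[[s]] <- tibble::tibble(network = s, from = bh$from, to = bh$to,
                                x = bh$dp_fwd / bh$pi_i,
                                y = bh$dp_rev / bh$pi_i)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("caliber_bound_scatter", class(out))
  out
}

#' @export
autoplot.caliber_bound_scatter <- function(object, ...) {
  tri <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 0))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, colour = "grey40", linetype = 2) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = expression((1 / pi[i]) * partialdiff * p[ij] / partialdiff * k[ij]),
      y = expression((1 / pi[i]) * partialdiff * p[ji] / partialdiff * k[ij]),
      title = "Kinetic bound hierarchy: feasible response triangle") +
    ggplot2::theme_minimal()
}
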