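#' Sparse Jacobian from log-rates to forces
#'
#' Builds `A[(ij), beta] = dF_beta / d log k_ij`: rows indexed by directed
#' edges, columns by basis forces.  The structure is exact and sparse:
#' \itemize{
#'   \item edge-force column of edge `{a,b}`: +1/2 on rows `(a->b)` and
#'     `(b->a)`;
#'   \item node-force column `n`: `k_ij * (delta_{i,m} - delta_{i,n})` on row
#'     `(i->j)` — i.e. `+k_mj` on rows leaving the reference, `-k_nj` on rows
#'     leaving `n`;
#'   \item cycle-force column `c`: +1/2 on rows traversed forward by the
#'     cycle, -1/2 on their reverses.
#' }
#' The caliber-rate gradient `d c / d log k_ij` (equal to `k_mj` on rows
#' leaving the reference, zero elsewhere) is returned alongside; it shifts the
#' noise sources on reference-row transitions but does not enter covariances
#' or responses.
#'
#' @inheritParams forces_from_rates
#' @return A `caliber_jacobian` with sparse `A` (2E x 2E), `grad_c` (length
#'   2E) and the frame.
#' @export
build_jacobian <- function(net, frame) {
  dirs <- frame$directed
  nd <- nrow(dirs)
  k_dir <- frame_rates(net, frame)
  b <- frame$basis
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)

  # edge-force block
  for (idx in which(b$type == "traffic")) {
    e <- b$edge[idx]
    r <- which(dirs$e == e)
    rows <- c(rows, r); cols <- c(cols, rep(idx, 2L)); vals <- c(vals, 0.5, 0.5)
  }
  # node-force block
  m_lab <- frame$reference
  for (idx in which(b$type == "dwell")) {
    n_lab <- b$state[idx]
    r_m <- which(dirs$from == m_lab)
    r_n <- which(dirs$from == n_lab)
    rows <- c(rows, r_m, r_n)
    cols <- c(cols, rep(idx, length(r_m) + length(r_n)))
    vals <- c(vals, k_dir[r_m], -k_dir[r_n])
  }
  # cycle-force block
  for (idx in which(b$type == "cycle")) {
    cyc <- frame$cycles[[b$cycle[idx]]]
    for (s in seq_len(nrow(cyc))) {
      r_f <- frame_d_index(frame, cyc$from[s], cyc$to[s])
      r_b <- frame_d_index(frame, cyc$to[s], cyc$from[s])
      rows <- c(rows, r_f, r_b)
      cols <- c(cols, idx, idx)
      vals <- c(vals, 0.5, -0.5)
    }
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nd, nd))
  grad_c <- ifelse(dirs$from == m_lab, k_dir, 0)
  structure(list(A = A, grad_c = unname(grad_c), frame = frame,
                 k_dir = unname(k_dir)),
            class = "caliber_jacobian")
}

#' @export
print.caliber_jacobian <- function(x, ...) {
  cat(sprintf("# caliber_jacobian: %d x %d, %d structural nonzeros\n",
              nrow(x$A), ncol(x$A), Matrix::nnzero(x$A)))
  invisible(x)
}

#' Invert the Jacobian
#'
#' Returns a solve handle.  For small systems (dimension <= `dense_limit`)
#' the full dense inverse is formed once; above that an LU factorization is
#' kept and rows of the inverse are extracted on demand by transposed solves.
#'
#' @param jac A `caliber_jacobian` from [build_jacobian()].
#' @param dense_limit Dimension up to which the dense inverse is formed.
#' @return A `caliber_jacobian_inverse` with fields `Ainv` (dense matrix or
#'   `NULL`), `solve_t(w)` returning `A^-T w`, `solve(b)` returning `A^-1 b`,
#'   and `rcond` (reciprocal condition estimate).
#' @export
invert_jacobian <- function(jac, dense_limit = 400L) {
  A <- jac$A
  n <- nrow(A)
  rc <- if (n <= dense_limit) {
    rcond(as.matrix(A))
  } else {
    1 / Matrix::condest(A)$est
  }
  if (!is.finite(rc) || rc < 1e-15) {
    stop("degenerate frame/network: Jacobian is singular", call. = FALSE)
  }
  if (n <= dense_limit) {
    Ainv <- solve(as.matrix(A))
    structure(list(
      Ainv = Ainv,
      solve = function(b) Ainv %*% b,
      solve_t = function(w) crossprod(Ainv, w),
      rcond = rc
    ), class = "caliber_jacobian_inverse")
  } else {
    luA <- Matrix::lu(A)
    luAt <- Matrix::lu(Matrix::t(A))
    structure(list(
      Ainv = NULL,
      solve = function(b) as.matrix(Matrix::solve(luA, b)),
      solve_t = function(w) as.matrix(Matrix::solve(luAt, w)),
      rcond = rc
    ), class = "caliber_jacobian_inverse")
  }
}

# shared computational core: steady state, Jacobian, inverse, noise weights
compute_core <- function(net, frame, dense_limit = 400L) {
  ss <- steady_observables(net, frame)
  jac <- build_jacobian(net, frame)
  inv <- invert_jacobian(jac, dense_limit)
  pk <- ss$pi[frame$directed$from] * jac$k_dir   # pi_i k_ij per directed edge
  list(ss = ss, jac = jac, inv = inv, pk = unname(pk))
}

#' Exact response matrix (RIM relation)
#'
#' Computes every steady-state response `R[alpha, (ij)] =
#' d<x_alpha> / d log k_ij = pi_i k_ij [A^-1]_{alpha,(ij)}` — the
#' response-inverse-matrix relation.  Rows are basis observables, columns
#' directed edges.
#'
#' @inheritParams forces_from_rates
#' @return A `caliber_response` with dense `R`, the inverse Jacobian, the
#'   steady state and index maps.
#' @export
response_matrix <- function(net, frame) {
  core <- compute_core(net, frame)
  Ainv <- core$inv$Ainv
  if (is.null(Ainv)) Ainv <- t(core$inv$solve_t(diag(nrow(core$jac$A))))
  R <- sweep(Ainv, 2L, core$pk, `*`)
  dimnames(R) <- list(frame$basis$label,
                      paste(frame$directed$from, frame$directed$to,
                            sep = "->"))
  structure(list(R = R, Ainv = Ainv, steady = core$ss, pk = core$pk,
                 k_dir = core$jac$k_dir, frame = frame),
            class = "caliber_response")
}

#' @export
print.caliber_response <- function(x, ...) {
  cat(sprintf("# caliber_response: %d observables x %d directed edges\n",
              nrow(x$R), ncol(x$R)))
  invisible(x)
}

#' @rdname response_matrix
#' @param x A `caliber_response`.
#' @param ... Unused.
#' @export
tidy.caliber_response <- function(x, ...) {
  fr <- x$frame
  tibble::tibble(
    observable = rep(rownames(x$R), times = ncol(x$R)),
    from = rep(fr$directed$from, each = nrow(x$R)),
    to = rep(fr$directed$to, each = nrow(x$R)),
    d_dlnk = as.vector(x$R),
    d_dk = as.vector(sweep(x$R, 2L, x$k_dir, `/`))
  )
}

# derivative of every state's stationary probability wrt log k (V x 2E),
# including the reference via normalization
dpi_matrix <- function(resp) {
  fr <- resp$frame
  dw_rows <- which(fr$basis$type == "dwell")
  D <- resp$R[dw_rows, , drop = FALSE]
  full <- matrix(0, length(fr$states), ncol(D),
                 dimnames = list(fr$states, colnames(resp$R)))
  full[fr$basis$state[dw_rows], ] <- D
  full[fr$reference, ] <- -colSums(D)
  full
}

#' Gradient of an observable's mean over all rates
#'
#' Returns both `d<x>/d log k_ij` and `d<x>/d k_ij` for every directed edge,
#' as the observable-weighted combination of response-matrix rows (one
#' transposed solve; the full matrix is not required).
#'
#' @inheritParams forces_from_rates
#' @param obs A `cft_observable` built on `frame`.
#' @return Tibble with columns `from`, `to`, `rate`, `d_dlnk`, `d_dk`.
#' @export
observable_gradient <- function(net, frame, obs) {
  stopifnot(length(obs$weights) == nrow(frame$basis))
  core <- compute_core(net, frame)
  g <- as.numeric(core$inv$solve_t(obs$weights))
  d_dlnk <- core$pk * g
  tibble::tibble(from = frame$directed$from, to = frame$directed$to,
                 rate = core$jac$k_dir, d_dlnk = d_dlnk,
                 d_dk = d_dlnk / core$jac$k_dir)
}

#' Responses to site-energy and barrier perturbations
#'
#' In an Arrhenius parameterization `k_nj ~ exp(E_n)`, `k_ij, k_ji ~
#' exp(-B_ij)`, the site energy `E_n` scales all rates leaving node `n`
#' jointly and the barrier `B_ij` scales both directions of edge `{i,j}`
#' jointly.  The induced responses are
#' `d<x>/dE_n = sum_j k_nj d<x>/dk_nj` and
#' `d<x>/dB_ij = -k_ij d<x>/dk_ij - k_ji d<x>/dk_ji`.
#' Site-energy perturbations scale fluxes in proportion to the local
#' occupancy; barrier perturbations act only through the net edge flux and
#' vanish (for observables other than the edge's own traffic) when the edge
#' is locally equilibrated.
#'
#' @inheritParams observable_gradient
#' @return List of tibbles `nodes` (`state`, `dE`) and `edges`
#'   (`i`, `j`, `dB`).
#' @export
energy_barrier_responses <- function(net, frame, obs) {
  gr <- observable_gradient(net, frame, obs)
  nodes <- dplyr::summarise(dplyr::group_by(gr, state = .data$from),
                            dE = sum(.data$d_dlnk), .groups = "drop")
  nodes <- nodes[order(match(nodes$state, frame$states)), ]
  e_tab <- frame$edges
  dB <- vapply(seq_len(nrow(e_tab)), function(e) {
    fwd <- gr$d_dlnk[gr$from == e_tab$i[e] & gr$to == e_tab$j[e]]
    rev <- gr$d_dlnk[gr$from == e_tab$j[e] & gr$to == e_tab$i[e]]
    -(fwd + rev)
  }, numeric(1))
  list(nodes = nodes,
       edges = tibble::tibble(i = e_tab$i, j = e_tab$j, dB = dB))
}
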