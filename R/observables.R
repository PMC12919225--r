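#' Observable coefficient vectors
#'
#' A CFT observable is a linear combination of the basis rate observables
#' fixed by a frame: traffic per undirected edge, dwell fraction per
#' non-reference node, net flux per fundamental cycle.  Coefficients are
#' stored in basis order (traffic block, dwell block, cycle block).
#'
#' @param frame A `cycle_frame`.
#' @param weights Numeric vector of length `2E` in basis order.
#' @param label Free-text label.
#' @return A `cft_observable`.
#' @export
observable <- function(frame, weights, label = "custom") {
  stopifnot(length(weights) == nrow(frame$basis), all(is.finite(weights)))
  new_observable(frame, as.numeric(weights), label)
}

new_observable <- function(frame, weights, label) {
  structure(list(weights = as.numeric(weights), label = label,
                 basis = frame$basis), class = "cft_observable")
}

#' @export
print.cft_observable <- function(x, ...) {
  nz <- which(x$weights != 0)
  cat("# observable:", x$label, "\n")
  if (length(nz)) {
    print(tibble::tibble(coordinate = x$basis$label[nz],
                         weight = x$weights[nz]))
  } else cat("(zero observable)\n")
  invisible(x)
}

basis_index <- function(frame, type, edge = NULL, state = NULL, cycle = NULL) {
  b <- frame$basis
  hit <- switch(type,
    traffic = which(b$type == "traffic" & b$edge == edge),
    dwell = which(b$type == "dwell" & b$state == state),
    cycle = which(b$type == "cycle" & b$cycle == cycle)
  )
  if (!length(hit)) stop("basis coordinate not found", call. = FALSE)
  hit[1L]
}

#' @rdname observable
#' @param from,to State labels of an edge.
#' @export
obs_traffic <- function(frame, from, to) {
  e_tab <- frame$edges
  hit <- which((e_tab$i == from & e_tab$j == to) |
                 (e_tab$i == to & e_tab$j == from))
  if (!length(hit)) stop("edge (", from, ",", to, ") not found", call. = FALSE)
  w <- numeric(nrow(frame$basis))
  w[basis_index(frame, "traffic", edge = hit[1L])] <- 1
  new_observable(frame, w, paste0("traffic:", e_tab$i[hit[1L]], "-",
                                  e_tab$j[hit[1L]]))
}

#' @rdname observable
#' @param state A non-reference state label.
#' @export
obs_dwell <- function(frame, state) {
  if (identical(as.character(state), frame$reference)) {
    stop("reference node has no dwell coordinate", call. = FALSE)
  }
  w <- numeric(nrow(frame$basis))
  w[basis_index(frame, "dwell", state = as.character(state))] <- 1
  new_observable(frame, w, paste0("dwell:", state))
}

#' @rdname observable
#' @param cycle Fundamental-cycle index (1-based, chord order).
#' @export
obs_cycle <- function(frame, cycle) {
  if (cycle < 1L || cycle > length(frame$chords)) {
    stop("cycle index out of range", call. = FALSE)
  }
  w <- numeric(nrow(frame$basis))
  w[basis_index(frame, "cycle", cycle = cycle)] <- 1
  ch <- frame$chords[cycle]
  new_observable(frame, w, paste0("cycle:", frame$edges$i[ch], "-",
                                  frame$edges$j[ch]))
}

#' @rdname observable
#' @export
obs_zero <- function(frame) {
  new_observable(frame, numeric(nrow(frame$basis)), "zero")
}

#' Counting observable from per-transition weights
#'
#' Maps an arbitrary linear counting functional `sum_ij w_ij N_ij / t` onto
#' the basis: each directed count decomposes asymptotically as
#' `N_ij/t ~ (traffic_e + netflux_ij)/2`, with the net flux expanded over the
#' cycle coordinates via [edge_flux_observable()].  Used to compare covariance
#' predictions against tilted-generator cumulants for any jump-counting
#' observable.
#'
#' @param frame A `cycle_frame`.
#' @param w Either a V x V matrix (dimnames = states) of per-transition
#'   weights, or a data frame with columns `from`, `to`, `weight`.
#' @return A `cft_observable`.
#' @export
counting_observable <- function(frame, w) {
  if (is.matrix(w)) {
    idx <- which(w != 0, arr.ind = TRUE)
    tab <- tibble::tibble(from = rownames(w)[idx[, 1]],
                          to = colnames(w)[idx[, 2]],
                          weight = w[idx])
  } else {
    tab <- tibble::as_tibble(w)
  }
  out <- numeric(nrow(frame$basis))
  for (r in seq_len(nrow(tab))) {
    tr <- obs_traffic(frame, tab$from[r], tab$to[r])
    fl <- edge_flux_observable(frame, tab$from[r], tab$to[r])
    out <- out + tab$weight[r] * 0.5 * (tr$weights + fl$weights)
  }
  new_observable(frame, out, "counting")
}

#' Per-transition counting weights of an observable
#'
#' Inverse of [counting_observable()] for jump-representable observables:
#' traffic maps to weight +1 on both directions of its edge, a cycle flux to
#' +1/-1 on its chord.  Dwell coordinates have no jump representation; if the
#' observable has any dwell weight the function returns `NULL`.
#'
#' @param frame A `cycle_frame`.
#' @param obs A `cft_observable`.
#' @return A V x V weight matrix, or `NULL` if not jump-representable.
#' @export
as_counting_weights <- function(frame, obs) {
  b <- frame$basis
  if (any(obs$weights[b$type == "dwell"] != 0)) return(NULL)
  st <- frame$states
  W <- matrix(0, length(st), length(st), dimnames = list(st, st))
  for (idx in which(obs$weights != 0)) {
    wt <- obs$weights[idx]
    if (b$type[idx] == "traffic") {
      e <- b$edge[idx]
      i <- frame$edges$i[e]; j <- frame$edges$j[e]
      W[i, j] <- W[i, j] + wt
      W[j, i] <- W[j, i] + wt
    } else {
      ch <- frame$chords[b$cycle[idx]]
      i <- frame$edges$i[ch]; j <- frame$edges$j[ch]
      W[i, j] <- W[i, j] + wt
      W[j, i] <- W[j, i] - wt
    }
  }
  W
}

#' Evaluate an observable's stationary mean
#'
#' @param obs A `cft_observable`.
#' @param steady A `caliber_steady` from [steady_observables()].
#' @return Scalar mean rate.
#' @export
evaluate_observable <- function(obs, steady) {
  sum(obs$weights * steady$mean_x)
}
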