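#' Build the spanning-tree / fundamental-cycle frame
#'
#' Fixes the complete observable basis used throughout the package: edge
#' traffic per undirected edge, dwell fraction per node other than the
#' reference `m`, and net flux per fundamental cycle.  The basis has dimension
#' `2E` (E undirected edges, V states, E - V + 1 chords/cycles), matching the
#' number of directed transitions.
#'
#' Construction is deterministic: undirected edges are oriented `(i, j)` with
#' `i` before `j` in state-list order; the spanning tree is grown
#' breadth-first from the reference node visiting neighbours in state-list
#' order; chords keep canonical orientation and each fundamental cycle is the
#' oriented edge sequence starting with its chord's canonical direction and
#' returning through the tree.  Physical results downstream (stationary
#' distribution, traffic, edge fluxes, their responses and covariances) are
#' invariant to the choice of reference node and tree; only the coordinates
#' change.
#'
#' If the network labels a mechanical edge, that edge is kept out of the tree
#' whenever the remaining graph is still connected, so the mechanical flux is
#' itself a cycle coordinate.
#'
#' @param net A [rate_network()].
#' @param reference Reference state label `m`; defaults to the network's
#'   `reference_state` attribute, else the first listed state.
#' @param avoid_tree_edges Optional list/length-2 vectors of edges to keep out
#'   of the tree if possible; defaults to the mechanical edge.
#' @return A `cycle_frame` object with fields `states`, `reference`, `edges`
#'   (undirected edge table with `tree` flag), `chords` (edge indices),
#'   `cycles` (list of oriented step tibbles), `directed` (directed-edge
#'   index table) and `basis` (basis index table).
#' @export
build_frame <- function(net, reference = NULL, avoid_tree_edges = NULL) {
  st <- net_states(net)
  V <- length(st)
  if (is.null(reference)) reference <- attr(net, "reference_state")
  if (is.null(reference)) reference <- st[1L]
  reference <- as.character(reference)
  if (!reference %in% st) {
    stop("reference node '", reference, "' not in state list", call. = FALSE)
  }
  m <- match(reference, st)

  und <- undirected_edges(net)
  E <- nrow(und)
  ei <- match(und$i, st); ej <- match(und$j, st)

  if (is.null(avoid_tree_edges)) {
    me <- attr(net, "mechanical_edge")
    if (!is.null(me)) avoid_tree_edges <- list(me)
  }
  avoid <- rep(FALSE, E)
  for (a in avoid_tree_edges) {
    a <- as.character(a)
    hit <- (und$i == a[1] & und$j == a[2]) | (und$i == a[2] & und$j == a[1])
    avoid <- avoid | hit
  }
  # only honour the avoidance if the graph minus those edges stays connected
  if (any(avoid) && !edges_connected(V, ei[!avoid], ej[!avoid])) {
    avoid <- rep(FALSE, E)
  }

  # BFS spanning tree from m, neighbours visited in state-list order
  nbr <- lapply(seq_len(V), function(v) {
    rows <- which((ei == v | ej == v) & !avoid)
    other <- ifelse(ei[rows] == v, ej[rows], ei[rows])
    o <- order(other)
    cbind(edge = rows[o], node = other[o])
  })
  parent <- rep(NA_integer_, V); parent_edge <- rep(NA_integer_, V)
  seen <- rep(FALSE, V); seen[m] <- TRUE
  queue <- m
  tree <- rep(FALSE, E)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    cand <- nbr[[v]]
    for (r in seq_len(nrow(cand))) {
      w <- cand[r, "node"]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        parent_edge[w] <- cand[r, "edge"]
        tree[cand[r, "edge"]] <- TRUE
        queue <- c(queue, w)
      }
    }
  }

  chords <- which(!tree)
  cycles <- lapply(chords, function(ce) {
    a <- ei[ce]; b <- ej[ce]          # canonical chord direction a -> b
    pa <- path_to_root(a, parent); pb <- path_to_root(b, parent)
    common <- intersect(pa, pb)
    lca <- common[which.min(match(common, pa))]
    up_b <- pb[seq_len(match(lca, pb))]          # b, ..., lca
    down_a <- rev(pa[seq_len(match(lca, pa))])   # lca, ..., a
    seq_nodes <- c(a, up_b, down_a[-1L])         # a, b, ..., lca, ..., a
    steps_from <- seq_nodes[-length(seq_nodes)]
    steps_to <- seq_nodes[-1L]
    e_of <- vapply(seq_along(steps_from), function(s) {
      lookup_edge(ei, ej, steps_from[s], steps_to[s])
    }, integer(1))
    tibble::tibble(
      from = st[steps_from], to = st[steps_to], e = e_of,
      dir = ifelse(ei[e_of] == steps_from, 1L, -1L)
    )
  })

  directed <- tibble::tibble(
    d = seq_len(2L * E),
    e = rep(seq_len(E), each = 2L),
    from = as.vector(rbind(und$i, und$j)),
    to = as.vector(rbind(und$j, und$i)),
    canonical = rep(c(TRUE, FALSE), E)
  )

  dwell_states <- st[-m]
  basis <- tibble::tibble(
    b = seq_len(2L * E),
    type = c(rep("traffic", E), rep("dwell", V - 1L),
             rep("cycle", length(chords))),
    edge = c(seq_len(E), rep(NA_integer_, V - 1L + length(chords))),
    state = c(rep(NA_character_, E), dwell_states,
              rep(NA_character_, length(chords))),
    cycle = c(rep(NA_integer_, E + V - 1L), seq_along(chords)),
    label = c(paste0("traffic:", und$i, "-", und$j),
              paste0("dwell:", dwell_states),
              if (length(chords)) {
                paste0("cycle:", und$i[chords], "-", und$j[chords])
              })
  )

  structure(list(
    states = st,
    reference = reference,
    m = m,
    edges = tibble::tibble(e = und$e, i = und$i, j = und$j, tree = tree),
    chords = chords,
    cycles = cycles,
    directed = directed,
    basis = basis
  ), class = "cycle_frame")
}

edges_connected <- function(V, ei, ej) {
  seen <- rep(FALSE, V); seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- unique(c(ej[ei == v], ei[ej == v]))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

path_to_root <- function(v, parent) {
  out <- v
  while (!is.na(parent[v])) {
    v <- parent[v]
    out <- c(out, v)
  }
  out
}

lookup_edge <- function(ei, ej, a, b) {
  hit <- which((ei == a & ej == b) | (ei == b & ej == a))
  if (!length(hit)) stop("internal: edge lookup failed", call. = FALSE)
  hit[1L]
}

#' @export
print.cycle_frame <- function(x, ...) {
  E <- nrow(x$edges)
  cat(sprintf(
    "# cycle_frame: %d states, %d edges, %d cycles; reference m = %s; basis dim %d\n",
    length(x$states), E, length(x$chords), x$reference, 2L * E))
  invisible(x)
}

# directed-edge index for (from, to); error if absent
frame_d_index <- function(frame, from, to) {
  hit <- which(frame$directed$from == from & frame$directed$to == to)
  if (!length(hit)) {
    stop("edge (", from, ",", to, ") not found in frame", call. = FALSE)
  }
  hit[1L]
}

# rates aligned with frame$directed rows
frame_rates <- function(net, frame) {
  key_net <- paste(net$from, net$to, sep = "\r")
  key_dir <- paste(frame$directed$from, frame$directed$to, sep = "\r")
  idx <- match(key_dir, key_net)
  if (anyNA(idx)) stop("network does not match frame topology", call. = FALSE)
  net$rate[idx]
}

#' @export
tidy.cycle_frame <- function(x, ...) x$basis

# affinity (half log rate-product ratio doubled): sum over cycle steps of
# ln(k_fwd / k_rev); zero iff the cycle satisfies detailed balance
cycle_affinity <- function(net, frame, cycle_index) {
  cyc <- frame$cycles[[cycle_index]]
  sum(vapply(seq_len(nrow(cyc)), function(s) {
    log(edge_rate(net, cyc$from[s], cyc$to[s]) /
          edge_rate(net, cyc$to[s], cyc$from[s]))
  }, numeric(1)))
}
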