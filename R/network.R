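#' Construct a rate network
#'
#' A rate network is a continuous-time Markov jump process on a finite set of
#' states, given as a tibble of directed edges with strictly positive rates.
#' Every transition must be reversible (if `i -> j` is present so is `j -> i`),
#' there are no self-loops or parallel edges, and the undirected support graph
#' must be connected, so the chain is ergodic.  Rates are dimensionless
#' multiples of the unit-rate reference process.
#'
#' The returned object is a tibble subclass with one row per *directed* edge
#' (columns `from`, `to`, `rate`, `group`) carrying the ordered state list and
#' optional metadata (a labelled mechanical edge, a preferred reference state)
#' as attributes.  The state-list order fixes every downstream convention:
#' undirected edges are oriented `(i, j)` with `i` before `j` in state order,
#' and rows are sorted accordingly.
#'
#' @param edges A data frame with columns `from`, `to`, `rate` and optionally
#'   `group` (free-text functional-group label per edge).
#' @param states Optional character vector fixing the state order; defaults to
#'   order of first appearance in `edges`.
#' @param mechanical_edge Optional length-2 character vector naming the edge
#'   that carries the mechanical (stepping) transition.
#' @param reference_state Optional state label preferred as the reference node
#'   when a frame is built.
#' @param description Optional free-text description.
#' @return A `rate_network` tibble.
#' @examples
#' net <- rate_network(data.frame(from = c("1", "2"), to = c("2", "1"),
#'                                rate = c(2, 1)))
#' glance(net)
#' @export
rate_network <- function(edges, states = NULL, mechanical_edge = NULL,
                         reference_state = NULL, description = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("from", "to", "rate")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns from, to, rate", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$rate <- as.numeric(edges$rate)
  if (!"group" %in% names(edges)) edges$group <- NA_character_
  edges <- edges[, c("from", "to", "rate", "group")]

  if (is.null(states)) {
    states <- unique(c(rbind(edges$from, edges$to)))
  } else {
    states <- as.character(states)
    extra <- setdiff(unique(c(edges$from, edges$to)), states)
    if (length(extra)) {
      stop("edge endpoints not in `states`: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  edges <- edges[order(match(edges$from, states), match(edges$to, states)), ]

  net <- tibble::new_tibble(edges, states = states,
                            mechanical_edge = mechanical_edge,
                            reference_state = reference_state,
                            description = description,
                            class = "rate_network")
  assert_valid_network(net)
  net
}

#' @export
print.rate_network <- function(x, ...) {
  st <- net_states(x)
  cat(sprintf("# rate_network: %d states, %d directed edges\n",
              length(st), nrow(x)))
  me <- attr(x, "mechanical_edge")
  if (!is.null(me)) cat("# mechanical edge:", paste(me, collapse = "-"), "\n")
  NextMethod()
}

#' State labels of a rate network
#' @param net A `rate_network`.
#' @return Character vector of state labels in canonical order.
#' @export
net_states <- function(net) attr(net, "states")

#' Dense rate matrix of a network
#'
#' @param net A `rate_network`.
#' @return A V x V matrix `K` with `K[i, j] = k_ij` and zero diagonal,
#'   dimnames set to the state labels.
#' @export
rate_matrix <- function(net) {
  st <- net_states(net)
  V <- length(st)
  K <- matrix(0, V, V, dimnames = list(st, st))
  K[cbind(match(net$from, st), match(net$to, st))] <- net$rate
  K
}

# connectivity of the undirected support graph, BFS in state order
support_connected <- function(net) {
  st <- net_states(net)
  V <- length(st)
  if (V == 0L) return(FALSE)
  adj <- matrix(FALSE, V, V)
  i <- match(net$from, st); j <- match(net$to, st)
  adj[cbind(i, j)] <- TRUE
  adj <- adj | t(adj)
  seen <- rep(FALSE, V)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

assert_valid_network <- function(net) {
  st <- net_states(net)
  if (length(st) < 2L) stop("network needs at least 2 states", call. = FALSE)
  if (anyDuplicated(st)) stop("duplicate state labels", call. = FALSE)
  if (any(!is.finite(net$rate)) || any(net$rate <= 0)) {
    bad <- net[!is.finite(net$rate) | net$rate <= 0, ]
    stop("non-positive rate on edge (", bad$from[1], ",", bad$to[1], ")",
         call. = FALSE)
  }
  if (any(net$from == net$to)) stop("self-loop not allowed", call. = FALSE)
  key <- paste(net$from, net$to, sep = "\r")
  if (anyDuplicated(key)) stop("parallel (duplicate) directed edge", call. = FALSE)
  rev_key <- paste(net$to, net$from, sep = "\r")
  miss <- !(rev_key %in% key)
  if (any(miss)) {
    b <- which(miss)[1L]
    stop("irreversible edge (", net$from[b], ",", net$to[b],
         "): reverse rate missing", call. = FALSE)
  }
  if (!support_connected(net)) {
    stop("support graph is disconnected: not ergodic", call. = FALSE)
  }
  invisible(net)
}

#' Diagnostic report for a network
#'
#' Report-only validation: counts states, undirected edges and independent
#' cycles (E - V + 1), checks connectivity, the rate range, and whether the
#' network satisfies detailed balance (all fundamental-cycle affinities
#' vanish, i.e. the Kolmogorov cycle criterion).
#'
#' @param net A `rate_network`.
#' @param tol Tolerance on cycle affinities for the detailed-balance flag.
#' @return One-row tibble with columns `n_states`, `n_edges`, `n_cycles`,
#'   `connected`, `min_rate`, `max_rate`, `detailed_balance`.
#' @export
validate_network <- function(net, tol = 1e-12) {
  st <- net_states(net)
  und <- undirected_edges(net)
  V <- length(st); E <- nrow(und)
  fr <- build_frame(net)
  aff <- vapply(seq_along(fr$cycles), function(ci) cycle_affinity(net, fr, ci),
                numeric(1))
  tibble::tibble(
    n_states = V,
    n_edges = E,
    n_cycles = E - V + 1L,
    connected = support_connected(net),
    min_rate = min(net$rate),
    max_rate = max(net$rate),
    detailed_balance = length(aff) == 0L || all(abs(aff) <= tol)
  )
}

# undirected edge table in canonical order: (i, j) with i before j in state order
undirected_edges <- function(net) {
  st <- net_states(net)
  fi <- match(net$from, st); ti <- match(net$to, st)
  fwd <- which(fi < ti)
  fwd <- fwd[order(fi[fwd], ti[fwd])]
  tibble::tibble(e = seq_along(fwd), i = net$from[fwd], j = net$to[fwd])
}

#' Look up a directed rate
#' @param net A `rate_network`.
#' @param from,to State labels of the directed edge.
#' @return The rate `k_from,to` (error if the edge is absent).
#' @export
edge_rate <- function(net, from, to) {
  hit <- net$from == from & net$to == to
  if (!any(hit)) stop("edge (", from, ",", to, ") not found", call. = FALSE)
  net$rate[hit]
}

#' Replace rates, keeping topology and metadata
#' @param net A `rate_network`.
#' @param rates Numeric vector aligned with the rows of `net`.
#' @return A `rate_network` with the new rates.
#' @export
set_rates <- function(net, rates) {
  stopifnot(length(rates) == nrow(net))
  net$rate <- as.numeric(rates)
  assert_valid_network(net)
  net
}

#' Repair missing or zero reverse rates
#'
#' Takes a raw edge table (not yet a valid network) and adds rate `epsilon`
#' for every reverse transition that is missing or non-positive, with a
#' warning naming the repaired edges.  Forces diverge logarithmically at zero
#' rates, so a strictly positive floor is required; this helper makes the
#' repair explicit, never silent.
#'
#' @param edges Data frame with columns `from`, `to`, `rate`.
#' @param epsilon Positive rate assigned to repaired reverse edges.
#' @param ... Passed on to [rate_network()].
#' @return A valid `rate_network`.
#' @export
regularize <- function(edges, epsilon = 1e-8, ...) {
  stopifnot(epsilon > 0)
  edges <- tibble::as_tibble(edges)
  if (!"group" %in% names(edges)) edges$group <- NA_character_
  edges$rate <- as.numeric(edges$rate)
  bad <- !is.finite(edges$rate) | edges$rate <= 0
  repaired <- character(0)
  if (any(bad)) {
    repaired <- paste0("(", edges$from[bad], ",", edges$to[bad], ")")
    edges$rate[bad] <- epsilon
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  rev_key <- paste(edges$to, edges$from, sep = "\r")
  miss <- which(!(key %in% rev_key))
  if (length(miss)) {
    add <- edges[miss, ]
    repaired <- c(repaired, paste0("(", add$to, ",", add$from, ")"))
    add <- tibble::tibble(from = add$to, to = add$from, rate = epsilon,
                          group = add$group)
    edges <- dplyr::bind_rows(edges, add)
  }
  if (length(repaired)) {
    warning("regularized edges with rate ", format(epsilon), ": ",
            paste(repaired, collapse = " "), call. = FALSE)
  }
  rate_network(edges, ...)
}

#' @export
tidy.rate_network <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @export
glance.rate_network <- function(x, ...) validate_network(x)

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attr(x, "states") <- NULL
  attr(x, "mechanical_edge") <- NULL
  attr(x, "reference_state") <- NULL
  attr(x, "description") <- NULL
  x
}
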