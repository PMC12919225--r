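#' Random ergodic reversible network
#'
#' A random connected graph (uniform random spanning tree attachment plus
#' extra edges sampled without replacement) with both one-way rates drawn
#' log-uniformly from `rate_bounds`.  Seeded draws are integer-indexed, so
#' the same seed always yields the same network.
#'
#' @param V Number of states (`>= 2`).
#' @param E Number of undirected edges, `V-1 <= E <= V(V-1)/2`.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param rate_bounds Positive bounds for the log-uniform rate draw.
#' @param detailed_balance If `TRUE`, rates are `k_ij = s_ij exp(E_i)` with
#'   symmetric `s` and node potentials `E`, so all cycle affinities vanish.
#' @return A [rate_network()] with states `"1" ... "V"`.
#' @export
random_ergodic_network <- function(V, E, seed = NULL,
                                   rate_bounds = c(0.1, 10),
                                   detailed_balance = FALSE) {
  stopifnot(V >= 2)
  if (E < V - 1L || E > V * (V - 1L) / 2L) {
    stop("E must be in [V-1, V(V-1)/2]", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  st <- as.character(seq_len(V))

  # random spanning tree: attach each node to a uniform earlier node in a
  # random order
  perm <- sample.int(V)
  pairs <- matrix(0L, nrow = E, ncol = 2L)
  for (idx in 2:V) {
    a <- perm[idx]
    b <- perm[sample.int(idx - 1L, 1L)]
    pairs[idx - 1L, ] <- c(min(a, b), max(a, b))
  }
  n_extra <- E - (V - 1L)
  if (n_extra > 0L) {
    all_pairs <- which(upper.tri(matrix(0, V, V)), arr.ind = TRUE)
    key <- all_pairs[, 1L] * (V + 1L) + all_pairs[, 2L]
    used <- pairs[seq_len(V - 1L), 1L] * (V + 1L) + pairs[seq_len(V - 1L), 2L]
    avail <- which(!(key %in% used))
    pick <- avail[sample.int(length(avail), n_extra)]
    pairs[V - 1L + seq_len(n_extra), ] <- all_pairs[pick, , drop = FALSE]
  }
  o <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[o, , drop = FALSE]

  lo <- log(rate_bounds[1L]); hi <- log(rate_bounds[2L])
  if (detailed_balance) {
    pot <- runif(V, lo, hi) / 2
    sym <- exp(runif(E, lo, hi))
    k_fwd <- sym * exp(pot[pairs[, 1L]])
    k_rev <- sym * exp(pot[pairs[, 2L]])
  } else {
    k_fwd <- exp(runif(E, lo, hi))
    k_rev <- exp(runif(E, lo, hi))
  }
  rate_network(tibble::tibble(
    from = st[c(pairs[, 1L], pairs[, 2L])],
    to = st[c(pairs[, 2L], pairs[, 1L])],
    rate = c(k_fwd, k_rev)
  ), states = st)
}

kinesin6_default_rates <- tibble::tibble(
  from = c("1", "2", "2", "3", "3", "4", "4", "5", "5", "6", "6", "1",
           "2", "5"),
  to = c("2", "1", "3", "2", "4", "3", "5", "4", "6", "5", "1", "6",
         "5", "2"),
  rate = c(100, 5, 150, 10, 80, 2, 120, 15, 100, 5, 90, 2,
           500, 1),
  group = c(rep("chemical", 12), "mechanical", "mechanical")
)

#' Six-state kinesin-like network
#'
#' The classic chemomechanical topology for a kinesin-style motor: a 6-state
#' ring `1-2-3-4-5-6-1` of chemical transitions plus the mechanical stepping
#' edge `2-5` as a chord, giving `E = 7` undirected edges and two fundamental
#' cycles (a forward and a backward chemomechanical cycle sharing the
#' mechanical edge).  Edges carry group metadata (`"chemical"` /
#' `"mechanical"`) and the mechanical edge is labelled so that frames keep it
#' as a chord.
#'
#' The default rate table is ILLUSTRATIVE ONLY — plausible orders of
#' magnitude chosen so the motor runs forward with well-separated chemical
#' and mechanical timescales.  It is not a fit to any measured kinesin data;
#' substitute your own 14-rate table for quantitative work.
#'
#' @param rates Optional replacement table with columns `from`, `to`, `rate`
#'   (all 14 directed rates of this topology).
#' @return A [rate_network()].
#' @export
kinesin6 <- function(rates = NULL) {
  tab <- kinesin6_default_rates
  if (!is.null(rates)) {
    rates <- tibble::as_tibble(rates)
    key_def <- paste(tab$from, tab$to, sep = "\r")
    key_new <- paste(as.character(rates$from), as.character(rates$to),
                     sep = "\r")
    if (nrow(rates) != 14L || !setequal(key_def, key_new)) {
      stop("`rates` must provide exactly the 14 directed rates of the ",
           "6-state ring + chord {2,5} topology", call. = FALSE)
    }
    tab$rate <- rates$rate[match(key_def, key_new)]
  }
  rate_network(tab, states = as.character(1:6),
               mechanical_edge = c("2", "5"),
               reference_state = "1",
               description = paste("6-state kinesin-like fixture;",
                                   "default rates are illustrative only"))
}

#' Theta-shaped substep benchmark network
#'
#' Extends [kinesin6()] by replacing the single mechanical hop `2 -> 5` with
#' a biased random walk across `N` substeps through `N - 1` inserted lattice
#' states, modelling a diffusive mechanical swing.  For `N = 1` the network
#' reduces exactly to `kinesin6`.  The cycle count stays 2 for every `N`
#' (the graph is a Theta shape).
#'
#' Default substep rates preserve the original edge's thermodynamic force:
#' each hop gets forward rate `N * k_fwd` and log rate ratio
#' `log(k_fwd/k_rev) / N`, so the chain's total affinity matches the single
#' hop it replaces.
#'
#' @param N Number of substeps (`>= 1`).
#' @param rates Optional backbone rate table passed to [kinesin6()].
#' @param substep_fwd,substep_rev Optional explicit substep rates.
#' @return A [rate_network()] with `V = 6 + N - 1` states.
#' @export
theta_motor_network <- function(N, rates = NULL, substep_fwd = NULL,
                                substep_rev = NULL) {
  if (!is.numeric(N) || N < 1 || N != round(N)) {
    stop("N must be a positive integer", call. = FALSE)
  }
  N <- as.integer(N)
  base <- kinesin6(rates)
  if (N == 1L) return(base)
  k_f <- edge_rate(base, "2", "5")
  k_r <- edge_rate(base, "5", "2")
  if (is.null(substep_fwd)) substep_fwd <- N * k_f
  if (is.null(substep_rev)) {
    substep_rev <- substep_fwd * (k_r / k_f)^(1 / N)
  }
  inserted <- paste0("s", seq_len(N - 1L))
  chain <- c("2", inserted, "5")
  backbone <- tibble::as_tibble(base)[!(base$from %in% c("2", "5") &
                                          base$to %in% c("5", "2")), ]
  sub <- tibble::tibble(
    from = c(chain[-length(chain)], chain[-1L]),
    to = c(chain[-1L], chain[-length(chain)]),
    rate = c(rep(substep_fwd, N), rep(substep_rev, N)),
    group = "mechanical"
  )
  rate_network(dplyr::bind_rows(backbone, sub),
               states = c(as.character(1:6), inserted),
               mechanical_edge = c("2", inserted[1L]),
               reference_state = "1",
               description = sprintf(
                 "Theta-shaped substep benchmark, N = %d substeps", N))
}
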