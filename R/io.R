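#' Read a rate network from disk
#'
#' Two plain-text formats are supported.  The JSON document
#' (`"schema": "caliberflow-net-1"`) stores one entry per *undirected* edge
#' with both one-way rates plus optional metadata (group labels, a mechanical
#' edge, a preferred reference state).  The TSV dialect is a minimal edge list
#' with header `source  target  rate`, one *directed* rate per row, UTF-8,
#' `.` decimal separator; it carries no metadata.  Invalid input is rejected,
#' never repaired: a missing reverse rate raises an "irreversible edge" error,
#' a non-positive rate raises "non-positive rate", a disconnected support
#' graph raises "not ergodic".
#'
#' @param path File path.
#' @param format `"json"`, `"tsv"`, or `"auto"` (from the file extension).
#' @return A validated [rate_network()].
#' @export
read_network <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") read_network_json(path) else read_network_tsv(path)
}

read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema) || !identical(doc$schema, "caliberflow-net-1")) {
    stop("unrecognized schema (expected \"caliberflow-net-1\")", call. = FALSE)
  }
  states <- as.character(unlist(doc$states))
  ed <- doc$edges
  if (is.null(ed) || !length(ed)) stop("no edges in document", call. = FALSE)
  rows <- purrr::map_dfr(ed, function(e) {
    if (is.null(e$source) || is.null(e$target) ||
        is.null(e$rate_fwd) || is.null(e$rate_rev)) {
      stop("edge entry must have source, target, rate_fwd, rate_rev",
           call. = FALSE)
    }
    grp <- if (is.null(e$group)) NA_character_ else as.character(e$group)
    tibble::tibble(
      from = as.character(c(e$source, e$target)),
      to = as.character(c(e$target, e$source)),
      rate = as.numeric(c(e$rate_fwd, e$rate_rev)),
      group = grp
    )
  })
  mech <- if (!is.null(doc$mechanical_edge)) {
    as.character(unlist(doc$mechanical_edge))
  }
  ref <- if (!is.null(doc$reference_state)) as.character(doc$reference_state)
  rate_network(rows, states = states, mechanical_edge = mech,
               reference_state = ref,
               description = if (!is.null(doc$description)) doc$description)
}

read_network_tsv <- function(path) {
  # rate parsed via as.numeric (strtod): correctly rounded, bit-exact
  # round-trips of the %.17g serialization
  tab <- readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(),
    target = readr::col_character(),
    rate = readr::col_character()
  ), progress = FALSE)
  tab$rate <- as.numeric(tab$rate)
  if (!all(c("source", "target", "rate") %in% names(tab))) {
    stop("TSV must have header: source target rate", call. = FALSE)
  }
  rate_network(tibble::tibble(from = tab$source, to = tab$target,
                              rate = tab$rate))
}

#' Write a rate network to disk
#'
#' Rates are serialized at full double precision so that
#' `read_network(write_network(net))` reproduces them bit-exactly.
#'
#' @param net A `rate_network`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (TSV drops metadata).
#' @return `net`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "json") write_network_json(net, path) else write_network_tsv(net, path)
  invisible(net)
}

num_chr <- function(x) sprintf("%.17g", x)

# JSON is assembled directly so rates carry all 17 significant digits
# (bit-exact round trips); jsonlite caps numeric output at 15.
write_network_json <- function(net, path) {
  st <- net_states(net)
  und <- undirected_edges(net)
  qt <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  edges <- vapply(seq_len(nrow(und)), function(r) {
    i <- und$i[r]; j <- und$j[r]
    grp <- net$group[net$from == i & net$to == j]
    fields <- c(
      paste0('"source": ', qt(i)),
      paste0('"target": ', qt(j)),
      paste0('"rate_fwd": ', num_chr(edge_rate(net, i, j))),
      paste0('"rate_rev": ', num_chr(edge_rate(net, j, i))),
      if (!is.na(grp)) paste0('"group": ', qt(grp))
    )
    paste0("    {", paste(fields, collapse = ", "), "}")
  }, character(1))
  lines <- c(
    "{",
    '  "schema": "caliberflow-net-1",',
    paste0('  "states": [', paste(qt(st), collapse = ", "), "],"),
    '  "edges": [',
    paste0(edges, collapse = ",\n")
  )
  tailers <- character(0)
  ref <- attr(net, "reference_state")
  if (!is.null(ref)) tailers <- c(tailers, paste0('  "reference_state": ', qt(ref)))
  mech <- attr(net, "mechanical_edge")
  if (!is.null(mech)) {
    tailers <- c(tailers, paste0('  "mechanical_edge": [',
                                 paste(qt(mech), collapse = ", "), "]"))
  }
  desc <- attr(net, "description")
  if (!is.null(desc)) tailers <- c(tailers, paste0('  "description": ', qt(desc)))
  close_edges <- if (length(tailers)) "  ]," else "  ]"
  lines <- c(lines, close_edges,
             if (length(tailers)) paste0(tailers, collapse = ",\n"),
             "}")
  writeLines(lines, path, useBytes = TRUE)
}

write_network_tsv <- function(net, path) {
  tab <- tibble::tibble(source = net$from, target = net$to,
                        rate = num_chr(net$rate))
  readr::write_tsv(tab, path, progress = FALSE)
}
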