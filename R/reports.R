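#' End-to-end audit of a network
#'
#' Runs the full pipeline on a network — validation, steady state, response
#' matrix, covariances — then audits every internal-consistency identity:
#' response symmetries, the kinetic bound hierarchy, the
#' fluctuation-response duality, the response matrix against finite
#' differences, and the covariance matrix against the tilted-generator
#' spectral oracle.  With `deep = TRUE` a sampling (Gillespie) cross-check
#' of the noise-diagonality law is added.
#'
#' @param net A [rate_network()] or a path readable by [read_network()].
#' @param seed Seed for the random probes and the optional sampling stage.
#' @param deep If `TRUE`, run the (slower) simulation cross-check.
#' @param tolerances Named list: `audit` (symmetry/duality/bounds),
#'   `oracle` (relative, FD and spectral), `sigma` (sampling, in standard
#'   errors).
#' @return A `caliber_report`; `render_report()` serializes it.
#' @export
run_full_audit <- function(net, seed = 1L, deep = FALSE,
                           tolerances = list(audit = 1e-8, oracle = 1e-6,
                                             sigma = 3)) {
  input <- if (is.character(net)) net else "<in-memory network>"
  if (is.character(net)) net <- read_network(net)
  withr::local_seed(seed)
  stages <- list()
  tol <- tolerances

  val <- validate_network(net)
  stages$validation <- list(pass = val$connected, detail = val)

  frame <- build_frame(net)
  ss <- steady_observables(net, frame)
  bal <- glance(ss)$balance_residual
  kirchhoff <- kirchhoff_residual(ss, frame)
  stages$steady_state <- list(
    pass = bal <= 1e-10 && kirchhoff <= 1e-10,
    detail = tibble::tibble(balance_residual = bal,
                            kirchhoff_residual = kirchhoff))

  resp <- response_matrix(net, frame)
  sym <- symmetry_residuals(resp)
  sym_max <- max(abs(sym$residual))
  stages$symmetries <- list(pass = sym_max <= tol$audit,
                            detail = tibble::tibble(max_residual = sym_max))

  bh <- tryCatch(bound_hierarchy_check(resp, tol = 1e-10),
                 error = function(e) e)
  stages$bounds <- list(
    pass = !inherits(bh, "error"),
    detail = if (inherits(bh, "error")) conditionMessage(bh) else
      tibble::tibble(n_edges = nrow(bh), n_saturated = sum(bh$saturated)))

  D <- covariance_matrix(net, frame)$D
  S <- force_susceptibility(net, frame)
  dual_max <- max(abs(D - S))
  stages$duality <- list(pass = dual_max <= tol$audit,
                         detail = tibble::tibble(max_deviation = dual_max))

  # finite-difference probes of the response matrix
  dirs <- frame$directed
  probes <- head(seq_len(nrow(dirs)), 4L)
  fd_err <- vapply(probes, function(d) {
    alpha <- sample.int(nrow(frame$basis), 1L)
    obs <- observable(frame, as.numeric(seq_len(nrow(frame$basis)) == alpha))
    fd <- finite_difference_response(net, frame, obs, dirs$from[d],
                                     dirs$to[d])
    an <- resp$R[alpha, d]
    abs(an - fd) / max(abs(fd), 1e-8)
  }, numeric(1))
  stages$response_vs_fd <- list(pass = max(fd_err) <= tol$oracle,
                                detail = tibble::tibble(
                                  max_rel_err = max(fd_err)))

  # spectral probes of the covariance matrix
  spec_err <- vapply(seq_len(3L), function(i) {
    w <- matrix(0, length(frame$states), length(frame$states),
                dimnames = list(frame$states, frame$states))
    sel <- sample.int(nrow(dirs), min(3L, nrow(dirs)))
    w[cbind(dirs$from[sel], dirs$to[sel])] <- rnorm(length(sel))
    obs <- counting_observable(frame, w)
    tc <- tilted_cumulants(net, w)
    an_var <- observable_covariance(covariance_matrix(net, frame), obs)
    abs(an_var - tc[["var"]]) / max(abs(tc[["var"]]), 1e-8)
  }, numeric(1))
  stages$spectral_oracle <- list(pass = max(spec_err) <= tol$oracle,
                                 detail = tibble::tibble(
                                   max_rel_err = max(spec_err)))

  if (deep) {
    ens <- ensemble_statistics(net, frame, t = 500, n_traj = 200,
                               seed = seed)
    k_dir <- frame_rates(net, frame)
    target <- ss$pi[dirs$from] * k_dir
    dev <- abs(diag(ens$lambda_cov) - target) /
      pmax(diag(ens$lambda_cov_se), 1e-12)
    stages$sampling <- list(
      pass = mean(dev <= tol$sigma) >= 0.9,
      detail = tibble::tibble(frac_within = mean(dev <= tol$sigma),
                              max_sigma = max(dev)))
  }

  structure(list(
    version = as.character(utils::packageVersion("caliberflow")),
    input = input,
    seed = seed,
    tolerances = tol,
    frame = tibble::tibble(states = length(frame$states),
                           edges = nrow(frame$edges),
                           cycles = length(frame$chords),
                           reference = frame$reference),
    stages = stages,
    pass = all(vapply(stages, function(s) isTRUE(s$pass), logical(1)))
  ), class = "caliber_report")
}

kirchhoff_residual <- function(ss, frame) {
  # tree-edge net flux must equal the signed sum of cycle fluxes through it
  tree_e <- which(frame$edges$tree)
  if (!length(tree_e) || !length(frame$chords)) return(0)
  max(vapply(tree_e, function(e) {
    pred <- 0
    for (ci in seq_along(frame$cycles)) {
      cyc <- frame$cycles[[ci]]
      hit <- which(cyc$e == e)
      for (s in hit) pred <- pred + cyc$dir[s] * ss$J_cycle[ci]
    }
    abs(pred - ss$edges$J[e])
  }, numeric(1)))
}

#' @export
print.caliber_report <- function(x, ...) {
  cat(render_report(x, format = "text"))
  invisible(x)
}

#' Serialize an audit report
#'
#' @param report A `caliber_report`.
#' @param format `"json"` (lossless), `"tsv"` (flat stage table) or
#'   `"text"` (human summary).
#' @return A character scalar.
#' @export
render_report <- function(report, format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  stage_tab <- dplyr::bind_rows(lapply(names(report$stages), function(nm) {
    s <- report$stages[[nm]]
    det <- if (is.data.frame(s$detail)) {
      paste(names(s$detail), vapply(s$detail, function(c) format(c[[1]]),
                                    character(1)),
            sep = "=", collapse = "; ")
    } else as.character(s$detail)
    tibble::tibble(stage = nm, pass = isTRUE(s$pass), detail = det)
  }))
  switch(format,
    json = jsonlite::toJSON(list(
      version = report$version, input = report$input, seed = report$seed,
      tolerances = report$tolerances, frame = report$frame,
      stages = stage_tab, pass = report$pass), auto_unbox = TRUE,
      digits = NA, pretty = TRUE),
    tsv = readr::format_tsv(stage_tab),
    text = paste0(
      sprintf("caliberflow audit (v%s) on %s [seed %d]\n", report$version,
              report$input, report$seed),
      sprintf("  frame: %d states, %d edges, %d cycles (reference %s)\n",
              report$frame$states, report$frame$edges, report$frame$cycles,
              report$frame$reference),
      paste(sprintf("  [%s] %-16s %s", ifelse(stage_tab$pass, "ok", "FAIL"),
                    stage_tab$stage, stage_tab$detail), collapse = "\n"),
      sprintf("\n  overall: %s\n", if (report$pass) "PASS" else "FAIL"))
  )
}
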