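#' Run the full screening and mediation pipeline
#'
#' End-to-end orchestration: forward screen of every exposure against the
#' outcome, reverse-causality screen and Bayesian confirmation of the
#' hits, then mediator screening and mediation decomposition for every
#' exposure that survived all three gates (tier `significant`,
#' `reverse_clear`, `bayes_confirmed`). Writes four artifacts into
#' `out_dir`:
#'
#' * `screen.tsv` — one row per exposure ([screen_summary()]);
#' * `mediation.tsv` — one row per exposure-mediator-outcome link;
#' * `diagnostics.json` — per-exposure heterogeneity/pleiotropy tests and
#'   leave-one-out flags;
#' * `manifest.json` — thresholds, seeds, package version and input labels,
#'   sufficient to reproduce every result file exactly.
#'
#' Reruns with identical inputs and config produce byte-identical files.
#'
#' @param exposures list of exposure [trait_table()]s.
#' @param outcome outcome [trait_table()].
#' @param mediator_panel optional list of mediator [trait_table()]s; when
#'   `NULL` the mediation step is skipped.
#' @param ld an [ld_info()].
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `records`, `screen` (data frame),
#'   `mediation` (data frame or `NULL`) and the artifact paths.
#' @export
run_pipeline <- function(exposures, outcome, mediator_panel = NULL,
                         ld = ld_info(), config = run_config(),
                         out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  records <- forward_screen(exposures, outcome, ld, config)
  records <- reverse_screen(records, outcome, exposures, ld, config)
  records <- bayes_validate(records, config)
  screen <- screen_summary(records)

  med_links <- NULL
  if (!is.null(mediator_panel)) {
    passed <- which(screen$tier == "significant" &
                      screen$reverse_clear %in% TRUE &
                      screen$bayes_confirmed %in% TRUE)
    med_list <- lapply(passed, function(i)
      find_mediators(records[[i]], exposures[[i]], mediator_panel, outcome,
                     ld, config))
    if (length(med_list)) med_links <- do.call(rbind, med_list)
  }

  screen_path <- file.path(out_dir, "screen.tsv")
  num_cols <- vapply(screen, is.numeric, logical(1))
  screen_out <- screen
  screen_out[num_cols] <- lapply(screen[num_cols], .fmt_num)
  utils::write.table(screen_out, screen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")

  mediation_path <- file.path(out_dir, "mediation.tsv")
  if (!is.null(med_links) && nrow(med_links)) {
    write_mediation(med_links, mediation_path, candidates_only = FALSE)
  } else {
    writeLines(paste(c("exposure", "mediator", "outcome", "total_beta",
                       "mediation_beta", "proportion"), collapse = "\t"),
               mediation_path)
  }

  diag_path <- file.path(out_dir, "diagnostics.json")
  diag <- lapply(records, function(r) {
    if (is.null(r$diagnostics)) return(list(exposure = r$exposure_id,
                                            available = FALSE))
    d <- r$diagnostics
    list(exposure = r$exposure_id, available = TRUE,
         q_ivw = d$q_ivw, q_df = d$q_df, q_p = d$q_p,
         q_egger = d$q_egger, q_egger_df = d$q_egger_df,
         q_egger_p = d$q_egger_p,
         egger_intercept = d$egger_intercept,
         egger_intercept_se = d$egger_intercept_se,
         egger_intercept_p = d$egger_intercept_p,
         no_heterogeneity = d$no_heterogeneity,
         no_pleiotropy = d$no_pleiotropy,
         influential_snps = d$loo$left_out[d$loo$influential])
  })
  jsonlite::write_json(diag, diag_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    config = unclass(config),
    exposures = vapply(exposures, function(x) attr(x, "trait_id"), character(1)),
    outcome = attr(outcome, "trait_id"),
    mediators = if (!is.null(mediator_panel))
      vapply(mediator_panel, function(x) attr(x, "trait_id"), character(1))
    else character(0),
    n_ld_pairs = nrow(ld$pairs),
    artifacts = c("screen.tsv", "mediation.tsv", "diagnostics.json",
                  "manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(records = records, screen = screen, mediation = med_links,
                 paths = c(screen = screen_path, mediation = mediation_path,
                           diagnostics = diag_path, manifest = manifest_path)))
}
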