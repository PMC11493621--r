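#' Pipeline configuration
#'
#' Collects every threshold and seed of the screening/mediation pipeline.
#' Defaults are the conventional two-sample MR screening settings:
#' instrument p < 1e-5, clumping r2 < 0.001 within 10,000 kb, F >= 10,
#' forward-significance tiers at p < 0.05 (suggestive) and p < 0.01
#' (significant), reverse-causality clearance at reverse p > 0.05 and
#' Bayesian confirmation at p < 0.05. All threshold comparisons are strict.
#'
#' @param p_instrument instrument selection threshold.
#' @param clump_r2,clump_kb LD clumping parameters.
#' @param f_min weak-instrument F cutoff.
#' @param tier_suggestive,tier_significant forward-screen tiers.
#' @param reverse_clear_p reverse-screen clearance threshold.
#' @param bayes_confirm_p Bayesian confirmation threshold.
#' @param n_boot bootstrap replicates for median/mode estimators.
#' @param seed base RNG seed for stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(p_instrument = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
                       f_min = 10, tier_suggestive = 0.05,
                       tier_significant = 0.01, reverse_clear_p = 0.05,
                       bayes_confirm_p = 0.05, n_boot = 1000, seed = 1L) {
  cfg <- list(p_instrument = p_instrument, clump_r2 = clump_r2,
              clump_kb = clump_kb, f_min = f_min,
              tier_suggestive = tier_suggestive,
              tier_significant = tier_significant,
              reverse_clear_p = reverse_clear_p,
              bayes_confirm_p = bayes_confirm_p,
              n_boot = as.integer(n_boot), seed = as.integer(seed))
  probs <- c("p_instrument", "tier_suggestive", "tier_significant",
             "reverse_clear_p", "bayes_confirm_p")
  for (nm in probs)
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop(nm, " must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are an error; absent keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

# tier from the primary (IVW) p-value; strict thresholds
.tier <- function(p, cfg) {
  if (is.na(p)) "rejected"
  else if (p < cfg$tier_significant) "significant"
  else if (p < cfg$tier_suggestive) "suggestive"
  else "rejected"
}

.screen_one <- function(exposure, outcome, ld, cfg, direction = "forward",
                        with_diagnostics = TRUE) {
  rec <- list(exposure_id = attr(exposure, "trait_id"),
              outcome_id = attr(outcome, "trait_id"),
              direction = direction, estimates = NULL, diagnostics = NULL,
              instruments = NULL, tier = "rejected", ivw_p = NA_real_,
              ivw_beta = NA_real_, reverse_clear = NA, reverse_p = NA_real_,
              bayes_confirmed = NA, bayes_p = NA_real_,
              failure_reason = NA_character_)
  iv <- select_instruments(exposure, ld, p_threshold = cfg$p_instrument,
                           r2_threshold = cfg$clump_r2,
                           window_kb = cfg$clump_kb)
  iv <- filter_weak(iv, cfg$f_min)
  rec$instruments <- iv
  if (iv$k == 0L) {
    rec$failure_reason <- iv$exclusion_reason %||% "no_instruments"
    if (is.na(rec$failure_reason)) rec$failure_reason <- "no_instruments"
    return(structure(rec, class = "screen_record"))
  }
  h <- tryCatch(harmonize(iv$snps, outcome), error = function(e) e)
  if (inherits(h, "error")) {
    rec$failure_reason <- "harmonization_empty"
    return(structure(rec, class = "screen_record"))
  }
  est <- mr_run_all(h, n_boot = cfg$n_boot, seed = cfg$seed)
  rec$estimates <- est
  ivw_row <- est[est$method == "ivw", , drop = FALSE]
  if (nrow(ivw_row) == 1L) {
    rec$ivw_p <- ivw_row$pvalue
    rec$ivw_beta <- ivw_row$beta
    rec$tier <- .tier(ivw_row$pvalue, cfg)
  } else {
    rec$failure_reason <- "ivw_failed"
  }
  if (with_diagnostics && nrow(h) >= 3)
    rec$diagnostics <- mr_diagnostics(h)
  structure(rec, class = "screen_record")
}

#' Forward MR screen across a batch of exposures
#'
#' Runs the full instrument-selection, harmonization, estimation and
#' diagnostics pipeline of one exposure against the outcome, for every
#' exposure in the batch. Failures (no instruments after selection, weak
#' instrument set, empty harmonization) are recorded per exposure with a
#' reason; the batch never aborts. Each record is tiered on the IVW
#' p-value: `significant` (p < 0.01), `suggestive` (p < 0.05), else
#' `rejected`.
#'
#' @param exposures list of exposure [trait_table()]s (full tables, not yet
#'   instrument-filtered).
#' @param outcome outcome [trait_table()].
#' @param ld an [ld_info()].
#' @param config a [run_config()].
#' @return A `screen_batch`: list of `screen_record`s, one per exposure, in
#'   input order.
#' @export
forward_screen <- function(exposures, outcome, ld = ld_info(),
                           config = run_config()) {
  if (length(exposures) == 0L) stop("no exposures supplied", call. = FALSE)
  records <- lapply(exposures, function(ex)
    .screen_one(ex, outcome, ld, config, direction = "forward"))
  structure(records, class = "screen_batch")
}

#' Reverse-causality screen
#'
#' For every forward record at `suggestive` tier or better, runs the
#' reverse MR (outcome as exposure, exposure as outcome) with instruments
#' re-selected for the outcome trait under the same selection rules, and
#' sets `reverse_clear = TRUE` when the reverse IVW p-value exceeds
#' `config$reverse_clear_p` (no evidence of reverse causation).
#'
#' @param records a `screen_batch` from [forward_screen()].
#' @param outcome outcome [trait_table()] (full table).
#' @param exposures the same list of exposure tables (used as reverse
#'   outcomes), named or ordered as in the forward screen.
#' @param ld an [ld_info()].
#' @param config a [run_config()].
#' @return The updated `screen_batch`.
#' @export
reverse_screen <- function(records, outcome, exposures, ld = ld_info(),
                           config = run_config()) {
  ids <- vapply(exposures, function(x) attr(x, "trait_id"), character(1))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (!rec$tier %in% c("suggestive", "significant")) next
    ex <- exposures[[match(rec$exposure_id, ids)]]
    rev <- .screen_one(outcome, ex, ld, config, direction = "reverse",
                       with_diagnostics = FALSE)
    rec$reverse_p <- rev$ivw_p
    # a reverse leg with no usable instruments cannot show reverse causation
    rec$reverse_clear <- if (is.na(rev$ivw_p)) TRUE
      else rev$ivw_p > config$reverse_clear_p
    records[[i]] <- rec
  }
  records
}

#' Bayesian confirmation of screened signals
#'
#' Re-tests every `significant`-tier record with the Bayesian weighted
#' estimator; records whose Bayesian p-value is not strictly below
#' `config$bayes_confirm_p` are demoted to `suggestive` with reason
#' `bayes_unconfirmed`. Convergence failures count as unconfirmed.
#'
#' @param records a `screen_batch`.
#' @param config a [run_config()].
#' @return The updated `screen_batch`.
#' @export
bayes_validate <- function(records, config = run_config()) {
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (rec$tier != "significant") next
    bw <- rec$estimates[rec$estimates$method == "bwmr", , drop = FALSE]
    if (nrow(bw) == 1L) {
      rec$bayes_p <- bw$pvalue
      rec$bayes_confirmed <- bw$pvalue < config$bayes_confirm_p
    } else {
      rec$bayes_confirmed <- FALSE
    }
    if (!rec$bayes_confirmed) {
      rec$tier <- "suggestive"
      rec$failure_reason <- "bayes_unconfirmed"
    }
    records[[i]] <- rec
  }
  records
}

#' Summarize a screen batch as a data frame
#'
#' One row per exposure with the IVW summary, tier, reverse-clearance and
#' Bayesian confirmation flags, diagnostics p-values and a
#' Benjamini-Hochberg adjusted IVW p-value column (informational only; the
#' tiering itself uses raw p-values).
#'
#' @param records a `screen_batch`.
#' @return A data frame.
#' @export
screen_summary <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(exposure = r$exposure_id, outcome = r$outcome_id,
               direction = r$direction,
               nsnp = if (!is.null(r$instruments)) r$instruments$k else NA_integer_,
               f_stat = if (!is.null(r$instruments)) r$instruments$f_stat else NA_real_,
               ivw_beta = r$ivw_beta, ivw_p = r$ivw_p, tier = r$tier,
               reverse_p = r$reverse_p, reverse_clear = r$reverse_clear,
               bayes_p = r$bayes_p, bayes_confirmed = r$bayes_confirmed,
               q_p = if (!is.null(r$diagnostics)) r$diagnostics$q_p else NA_real_,
               egger_intercept_p = if (!is.null(r$diagnostics))
                 r$diagnostics$egger_intercept_p else NA_real_,
               failure_reason = r$failure_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ivw_p_bh <- stats::p.adjust(out$ivw_p, method = "BH")
  rownames(out) <- NULL
  out
}
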