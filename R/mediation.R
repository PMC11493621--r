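#' Product-of-coefficients mediation decomposition
#'
#' Two-step MR mediation arithmetic: the indirect (mediated) effect is the
#' product of the exposure-to-mediator effect (`beta1`) and the
#' mediator-to-outcome effect (`beta2`); the direct effect is the total
#' effect minus the mediated effect; the proportion mediated is
#' `100 * beta1 * beta2 / total_beta` percent. The proportion is reported
#' only when the mediated and total effects share sign; on a sign mismatch
#' it is `NA` (printed as `/`), the mediated path then running opposite to
#' the overall trend. A proportion above 100% (mediated effect exceeding
#' the total) is kept and flagged.
#'
#' @param total_beta total exposure-to-outcome effect.
#' @param beta1 exposure-to-mediator effect.
#' @param beta2 mediator-to-outcome effect.
#' @param se1,se2 optional standard errors of `beta1`/`beta2`; when given,
#'   a delta-method standard error of the mediated effect
#'   (`sqrt(beta2^2 se1^2 + beta1^2 se2^2)`, an extension beyond the plain
#'   product arithmetic) is attached.
#' @return A `mediation_result` one-row data frame: `total_beta`, `beta1`,
#'   `beta2`, `mediation_beta`, `direct_beta`, `proportion_pct`,
#'   `proportion_label`, `mediation_se`.
#' @export
mediation_decompose <- function(total_beta, beta1, beta2, se1 = NULL,
                                se2 = NULL) {
  stopifnot(is.finite(total_beta), is.finite(beta1), is.finite(beta2))
  mediation_beta <- beta1 * beta2
  direct_beta <- total_beta - mediation_beta
  sign_ok <- total_beta != 0 && mediation_beta != 0 &&
    sign(mediation_beta) == sign(total_beta)
  proportion <- if (sign_ok) 100 * mediation_beta / total_beta else NA_real_
  label <- if (mediation_beta == 0) "0%"   # null mediated path
    else if (!sign_ok) "/"
    else if (proportion > 100) sprintf(">100%% (%.2f%%)", proportion)
    else sprintf("%.2f%%", proportion)
  med_se <- if (!is.null(se1) && !is.null(se2))
    mediation_se(beta1, se1, beta2, se2) else NA_real_
  structure(data.frame(total_beta = total_beta, beta1 = beta1, beta2 = beta2,
                       mediation_beta = mediation_beta,
                       direct_beta = direct_beta,
                       proportion_pct = proportion,
                       proportion_label = label,
                       mediation_se = med_se,
                       stringsAsFactors = FALSE),
            class = c("mediation_result", "data.frame"))
}

#' Delta-method standard error of a mediated effect
#'
#' First-order standard error of the product `beta1 * beta2`:
#' `sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)` (the two legs come from
#' non-overlapping samples and are treated as independent).
#'
#' @param beta1,se1 exposure-to-mediator effect and standard error.
#' @param beta2,se2 mediator-to-outcome effect and standard error.
#' @return The standard error (vectorized).
#' @export
mediation_se <- function(beta1, se1, beta2, se2) {
  stopifnot(all(se1 >= 0), all(se2 >= 0))
  sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
}

#' Screen a mediator panel and decompose mediation effects
#'
#' Mediator candidacy for one screened exposure follows the two-step
#' design: (1) the exposure must causally affect the mediator
#' (exposure-to-mediator IVW p < `alpha`, effect `beta1`); (2) the mediator
#' must causally affect the outcome (mediator-to-outcome IVW p < `alpha`,
#' effect `beta2`, instruments re-selected for the mediator); both legs
#' must additionally pass Bayesian confirmation (Bayesian-weighted p <
#' `config$bayes_confirm_p`) when `bayes_gate` is on. Every candidate link
#' is decomposed against the exposure's total effect.
#'
#' @param exposure_record a `screen_record` from the forward screen (must
#'   carry the exposure's total IVW effect).
#' @param exposure the exposure's full [trait_table()].
#' @param mediator_panel list of mediator [trait_table()]s.
#' @param outcome outcome [trait_table()].
#' @param ld an [ld_info()].
#' @param config a [run_config()]; `tier_suggestive` is the candidacy
#'   `alpha` for both legs.
#' @param bayes_gate require Bayesian confirmation of both legs
#'   (default `TRUE`).
#' @return A data frame with one row per mediator panel member:
#'   identifiers, per-leg effects and p-values, candidacy flag with reason,
#'   and (for candidates) the mediation decomposition columns.
#' @export
find_mediators <- function(exposure_record, exposure, mediator_panel, outcome,
                           ld = ld_info(), config = run_config(),
                           bayes_gate = TRUE) {
  stopifnot(inherits(exposure_record, "screen_record"))
  total_beta <- exposure_record$ivw_beta
  if (is.na(total_beta))
    stop("exposure record carries no total effect (screen failed)",
         call. = FALSE)
  alpha <- config$tier_suggestive
  rows <- lapply(mediator_panel, function(med) {
    mid <- attr(med, "trait_id")
    out <- data.frame(exposure = exposure_record$exposure_id, mediator = mid,
                      outcome = exposure_record$outcome_id,
                      beta1 = NA_real_, se1 = NA_real_, p1 = NA_real_,
                      beta2 = NA_real_, se2 = NA_real_, p2 = NA_real_,
                      candidate = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    # leg 1: exposure -> mediator, exposure's instruments
    leg1 <- .screen_one(exposure, med, ld, config, with_diagnostics = FALSE)
    if (is.na(leg1$ivw_p)) {
      out$reason <- paste0("leg1_", leg1$failure_reason)
      return(out)
    }
    ivw1 <- leg1$estimates[leg1$estimates$method == "ivw", ]
    out$beta1 <- ivw1$beta; out$se1 <- ivw1$se; out$p1 <- ivw1$pvalue
    if (!(ivw1$pvalue < alpha)) {
      out$reason <- "leg1_not_significant"
      return(out)
    }
    # leg 2: mediator -> outcome, mediator's own instruments
    leg2 <- .screen_one(med, outcome, ld, config, with_diagnostics = FALSE)
    if (is.na(leg2$ivw_p)) {
      out$reason <- paste0("leg2_", leg2$failure_reason)
      return(out)
    }
    ivw2 <- leg2$estimates[leg2$estimates$method == "ivw", ]
    out$beta2 <- ivw2$beta; out$se2 <- ivw2$se; out$p2 <- ivw2$pvalue
    if (!(ivw2$pvalue < alpha)) {
      out$reason <- "leg2_not_significant"
      return(out)
    }
    if (bayes_gate) {
      for (leg in list(c("leg1", "1"), c("leg2", "2"))) {
        est <- (if (leg[2] == "1") leg1 else leg2)$estimates
        bw <- est[est$method == "bwmr", , drop = FALSE]
        ok <- nrow(bw) == 1L && bw$pvalue < config$bayes_confirm_p
        if (!ok) {
          out$reason <- paste0(leg[1], "_bayes_unconfirmed")
          return(out)
        }
      }
    }
    out$candidate <- TRUE
    out
  })
  links <- do.call(rbind, rows)
  rownames(links) <- NULL
  dec <- lapply(seq_len(nrow(links)), function(i) {
    if (!links$candidate[i])
      return(data.frame(mediation_beta = NA_real_, direct_beta = NA_real_,
                        proportion_pct = NA_real_,
                        proportion_label = NA_character_,
                        mediation_se = NA_real_, stringsAsFactors = FALSE))
    d <- mediation_decompose(total_beta, links$beta1[i], links$beta2[i],
                             links$se1[i], links$se2[i])
    d[c("mediation_beta", "direct_beta", "proportion_pct",
        "proportion_label", "mediation_se")]
  })
  cbind(links, do.call(rbind, dec), total_beta = total_beta)
}

#' Write a mediation table
#'
#' Table with one row per candidate link: exposure, mediator, outcome,
#' total effect, mediated effect and proportion label (`/` for
#' sign-discordant decompositions).
#'
#' @param links data frame from [find_mediators()].
#' @param path output TSV path.
#' @param candidates_only keep only candidate rows (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mediation <- function(links, path, candidates_only = TRUE) {
  df <- if (candidates_only) links[links$candidate, , drop = FALSE] else links
  out <- data.frame(exposure = df$exposure, mediator = df$mediator,
                    outcome = df$outcome,
                    total_beta = .fmt_num(df$total_beta),
                    mediation_beta = .fmt_num(df$mediation_beta),
                    proportion = df$proportion_label,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
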