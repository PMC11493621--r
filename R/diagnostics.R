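#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j * (ratio_j - beta)^2)` with per-SNP Wald ratios
#' `ratio_j = by_j / bx_j` and weights `w_j = (bx_j / se_y_j)^2`;
#' `Q` is referred to a chi-square distribution with `k - 1` degrees of
#' freedom. Evaluated at the fixed-effect IVW estimate `Q` is minimal over
#' `beta`.
#'
#' @param h a `harmonized_set` with `k >= 2`.
#' @param beta causal estimate at which to evaluate `Q`; defaults to the
#'   fixed-effect IVW estimate.
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(h, beta = NULL) {
  d <- .hs(h)
  if (d$k < 2L) stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  if (is.null(beta)) beta <- mr_ivw(h, model = "fixed")$beta
  w <- (d$bx / d$se_y)^2
  q <- sum(w * (d$by / d$bx - beta)^2)
  df <- d$k - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' The intercept row of the [mr_egger()] fit: a nonzero intercept indicates
#' directional pleiotropy (average direct effect of the instruments on the
#' outcome not through the exposure).
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @return List with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(h) {
  e <- attr(mr_egger(h), "extra")
  list(intercept = e$intercept, se = e$intercept_se, p = e$intercept_p)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect with each instrument removed in turn.
#' A SNP is flagged influential when its omission flips the sign of the
#' estimate or moves it by more than one reported (full-set) standard
#' error.
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @param ivw_model passed to [mr_ivw()].
#' @return Data frame with one row per left-out SNP: `left_out`, `beta`,
#'   `se`, `pvalue`, `influential`.
#' @export
leave_one_out <- function(h, ivw_model = "multiplicative_random") {
  d <- .hs(h)
  if (d$k < 3L) stop("leave-one-out requires at least 3 instruments",
                     call. = FALSE)
  full <- mr_ivw(h, model = ivw_model)
  rows <- lapply(seq_len(d$k), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], model = ivw_model)
    data.frame(left_out = h$snp_id[j], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue,
               influential = sign(fit$beta) != sign(full$beta) ||
                 abs(fit$beta - full$beta) > full$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-SNP (Wald ratio) analysis
#'
#' Per-instrument causal estimates, the tabular twin of a forest plot.
#'
#' @param h a `harmonized_set`.
#' @return Data frame with one row per SNP: `snp_id`, `beta`, `se`, `pvalue`.
#' @export
single_snp <- function(h) {
  rows <- lapply(seq_len(nrow(h)), function(j) {
    fit <- mr_wald_ratio(h[j, , drop = FALSE])
    data.frame(snp_id = h$snp_id[j], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full diagnostics report
#'
#' Bundles the sensitivity analyses reported alongside every main fit:
#' Cochran's Q at the IVW estimate, the residual heterogeneity of the
#' MR-Egger fit (`k - 2` df), the Egger intercept test, leave-one-out and
#' single-SNP estimates, plus the conventional `p > 0.05` "no significant
#' heterogeneity / pleiotropy" booleans. The booleans annotate, they never
#' filter.
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @param ivw_model passed to [mr_ivw()].
#' @return A `diagnostics_report` list.
#' @export
mr_diagnostics <- function(h, ivw_model = "multiplicative_random") {
  d <- .hs(h)
  if (d$k < 3L) stop("diagnostics require at least 3 instruments", call. = FALSE)
  qi <- cochran_q(h)
  eg <- attr(mr_egger(h), "extra")
  q_egger_p <- stats::pchisq(eg$q_egger, eg$q_egger_df, lower.tail = FALSE)
  structure(list(
    q_ivw = qi$q, q_df = qi$df, q_p = qi$p,
    q_egger = eg$q_egger, q_egger_df = eg$q_egger_df, q_egger_p = q_egger_p,
    egger_intercept = eg$intercept, egger_intercept_se = eg$intercept_se,
    egger_intercept_p = eg$intercept_p,
    no_heterogeneity = qi$p > 0.05,
    no_pleiotropy = eg$intercept_p > 0.05,
    loo = leave_one_out(h, ivw_model),
    single_snp = single_snp(h)
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("<diagnostics_report> Q=%.3f (df=%d, p=%.3g); Egger Q=%.3f (df=%d)\n",
              x$q_ivw, x$q_df, x$q_p, x$q_egger, x$q_egger_df))
  cat(sprintf("  Egger intercept %.4g (se %.4g, p=%.3g)\n",
              x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  cat(sprintf("  heterogeneity absent: %s; pleiotropy absent: %s\n",
              x$no_heterogeneity, x$no_pleiotropy))
  flagged <- x$loo$left_out[x$loo$influential]
  if (length(flagged))
    cat("  influential SNPs:", paste(flagged, collapse = ", "), "\n")
  invisible(x)
}
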