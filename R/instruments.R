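#' Filter a trait table by association p-value
#'
#' Retains SNPs with `pvalue < threshold` (strict), preserving row order.
#' The genome-wide suggestive threshold 1e-5 is the conventional cutoff for
#' instrumenting molecular and microbial traits whose GWAS are underpowered
#' for the 5e-8 genome-wide line.
#'
#' @param table a [trait_table()].
#' @param threshold significance threshold (default `1e-5`).
#' @return The subset as a [trait_table()] (possibly empty).
#' @export
select_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "trait_table"))
  out <- as.data.frame(table)[as.data.frame(table)$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = attr(table, "trait_id"),
            trait_type = attr(table, "trait_type"),
            dropped = attr(table, "dropped"),
            class = c("trait_table", "data.frame"))
}

#' Greedy LD clumping
#'
#' Classic clumping pass: SNPs are visited in order of ascending p-value
#' (ties broken by `snp_id`, making the result invariant to input row
#' order); a SNP is accepted iff no already-accepted SNP on the same
#' chromosome lies within `window_kb` kilobases with LD `r2 >= r2_threshold`.
#' Pairs absent from `ld` are treated as r2 = 0.
#'
#' @param table a [trait_table()] whose rows carry `chrom`/`pos`.
#' @param ld an [ld_info()] object.
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return The clumped [trait_table()] in original row order.
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "trait_table"))
  df <- as.data.frame(table)
  if (nrow(df) == 0L) return(table)
  ord <- order(df$pvalue, df$snp_id)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (a in accepted) {
      if (df$chrom[a] != df$chrom[i]) next
      if (abs(df$pos[a] - df$pos[i]) > window_kb * 1000) next
      if (ld_r2(ld, df$snp_id[a], df$snp_id[i]) >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  out <- df[sort(accepted), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_id = attr(table, "trait_id"),
            trait_type = attr(table, "trait_type"),
            dropped = attr(table, "dropped"),
            class = c("trait_table", "data.frame"))
}

#' Variance in exposure explained by one instrument
#'
#' For a standardized trait the variance explained by a SNP is
#' `2 * MAF * (1 - MAF) * beta^2` with `MAF = min(eaf, 1 - eaf)`. Some
#' summary-statistics workflows instead divide by the squared standard
#' error (`2 * MAF * (1-MAF) * beta^2 / se^2`, proportional to the chi-square
#' statistic); that variant is available via `formula = "beta_over_se"` and
#' requires `se`. The choice is deliberately explicit: the two conventions
#' differ by orders of magnitude and silently mixing them corrupts
#' F-statistics.
#'
#' @param eaf effect-allele frequency in (0, 1); `NA` yields 0 with a warning
#'   (the SNP cannot contribute to explained variance without a frequency).
#' @param beta per-allele effect on the standardized trait.
#' @param formula `"standardized"` (default) or `"beta_over_se"`.
#' @param se standard error, required for `"beta_over_se"`.
#' @return Per-SNP R-squared (vectorized).
#' @export
snp_r2 <- function(eaf, beta, formula = c("standardized", "beta_over_se"),
                   se = NULL) {
  formula <- match.arg(formula)
  out <- numeric(length(beta))
  miss <- is.na(eaf)
  if (any(miss))
    warning(sum(miss), " SNP(s) without eaf contribute 0 to explained variance")
  maf <- pmin(eaf, 1 - eaf)
  base <- 2 * maf * (1 - maf) * beta^2
  if (formula == "beta_over_se") {
    if (is.null(se)) stop("`se` is required for formula = 'beta_over_se'",
                          call. = FALSE)
    base <- base / se^2
  }
  out[!miss] <- base[!miss]
  out
}

#' Instrument-strength F-statistic
#'
#' `F = ((N - k - 1) / k) * (R2 / (1 - R2))`, where `N` is the exposure GWAS
#' sample size, `k` the number of instruments and `R2` the total variance in
#' the exposure explained by them (sum of per-SNP [snp_r2()] values).
#' `F < 10` conventionally flags weak-instrument bias.
#'
#' @param n exposure GWAS sample size (`n > k + 1`).
#' @param k number of instruments (`k >= 1`).
#' @param r2_total total explained variance, in `[0, 1)`.
#' @return The F-statistic (scalar).
#' @export
f_statistic <- function(n, k, r2_total) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k + 1) stop("n must exceed k + 1", call. = FALSE)
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must lie in [0, 1)",
                                          call. = FALSE)
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Assemble an instrument set for one trait
#'
#' Runs the full instrument-selection pipeline on one exposure (or mediator,
#' or outcome-as-exposure) trait: p-value threshold, greedy LD clumping,
#' per-SNP R-squared and the trait-level F-statistic.
#'
#' @param table full [trait_table()] for the trait.
#' @param ld an [ld_info()] object.
#' @param p_threshold instrument p-value threshold (default 1e-5).
#' @param r2_threshold,window_kb clumping parameters (defaults 0.001, 10000).
#' @param r2_formula passed to [snp_r2()].
#' @return An `instrument_set`: list with `trait_id`, `snps` (clumped
#'   [trait_table()]), `r2_per_snp` (named vector), `r2_total`, `f_stat`,
#'   `k`, `n`, and `exclusion_reason` (`NA` unless empty).
#' @export
select_instruments <- function(table, ld, p_threshold = 1e-5,
                               r2_threshold = 0.001, window_kb = 10000,
                               r2_formula = "standardized") {
  sel <- select_by_pvalue(table, p_threshold)
  if (nrow(sel) == 0L)
    return(structure(list(trait_id = attr(table, "trait_id"), snps = sel,
                          r2_per_snp = numeric(0), r2_total = 0,
                          f_stat = NA_real_, k = 0L, n = NA_integer_,
                          exclusion_reason = "no_instruments"),
                     class = "instrument_set"))
  clumped <- ld_clump(sel, ld, r2_threshold = r2_threshold, window_kb = window_kb)
  df <- as.data.frame(clumped)
  r2 <- suppressWarnings(snp_r2(df$eaf, df$beta, formula = r2_formula, se = df$se))
  names(r2) <- df$snp_id
  r2_total <- min(sum(r2), 1 - 1e-12)
  n <- max(df$n)
  k <- nrow(df)
  f <- if (n > k + 1) f_statistic(n, k, r2_total) else NA_real_
  structure(list(trait_id = attr(table, "trait_id"), snps = clumped,
                 r2_per_snp = r2, r2_total = r2_total, f_stat = f, k = k,
                 n = n, exclusion_reason = NA_character_),
            class = "instrument_set")
}

#' Exclude weak instrument sets
#'
#' Applied per trait: a trait whose F-statistic falls below `f_min` has its
#' whole instrument set excluded (reason `"weak_instruments"`). The boundary
#' is strict: `F` exactly equal to `f_min` is retained, matching the
#' convention that `F < 10` flags weakness.
#'
#' @param iv an `instrument_set` from [select_instruments()].
#' @param f_min minimum F-statistic (default 10).
#' @return The instrument set, emptied with an exclusion reason if weak.
#' @export
filter_weak <- function(iv, f_min = 10) {
  stopifnot(inherits(iv, "instrument_set"))
  if (iv$k == 0L || is.na(iv$f_stat)) return(iv)
  if (iv$f_stat < f_min) {
    iv$snps <- iv$snps[0, , drop = FALSE]
    iv$r2_per_snp <- numeric(0)
    iv$k <- 0L
    iv$exclusion_reason <- "weak_instruments"
  }
  iv
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: k=%d, R2=%.4g, F=%.4g%s\n", x$trait_id,
              x$k, x$r2_total, x$f_stat,
              if (!is.na(x$exclusion_reason))
                paste0(" [excluded: ", x$exclusion_reason, "]") else ""))
  invisible(x)
}
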