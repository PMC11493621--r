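.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complement_allele <- function(x) {
  # complementing is only defined for single-base alleles
  ifelse(nchar(x) == 1L & x %in% names(.COMPLEMENT), .COMPLEMENT[x], NA_character_)
}

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1L & nchar(oa) == 1L & !is.na(.complement_allele(ea)) &
    .complement_allele(ea) == oa
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared SNP to the exposure's
#' effect allele, producing the per-SNP (bx, se_x, by, se_y) quadruples all
#' estimators consume. SNPs are matched on `snp_id` only. Rules, applied per
#' SNP:
#'
#' * identical allele pair: kept as is;
#' * swapped allele pair (outcome effect allele = exposure other allele):
#'   outcome beta sign flipped, outcome eaf complemented;
#' * strand-complement matches (single-base alleles only): resolved as the
#'   corresponding direct or swapped match;
#' * palindromic SNPs (A/T or C/G): strand cannot be resolved from alleles,
#'   so the SNP is kept only when both allele frequencies lie outside
#'   `0.5 +/- palindrome_eaf_window` and agree on which allele is minor;
#'   otherwise dropped (`palindromic_ambiguous` / `palindromic_discordant`);
#' * anything else dropped as `allele_mismatch`; SNPs absent from the
#'   outcome dropped as `not_in_outcome`.
#'
#' Multi-base (indel) alleles are matched exactly or as an exact swap, never
#' strand-complemented. All drop counts are retained in the `"dropped"`
#' attribute of the result.
#'
#' @param exposure exposure (or mediator) [trait_table()], already
#'   instrument-filtered.
#' @param outcome outcome [trait_table()].
#' @param palindrome_eaf_window half-width of the ambiguity window around
#'   eaf = 0.5 inside which palindromic SNPs are dropped (default 0.08).
#' @return A `harmonized_set`: data frame with columns `snp_id`, `bx`,
#'   `se_x`, `by`, `se_y`, `eaf_x` and attributes `exposure_id`,
#'   `outcome_id`, `dropped`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "trait_table"), inherits(outcome, "trait_table"))
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  dropped <- c(not_in_outcome = 0L, allele_mismatch = 0L,
               palindromic_ambiguous = 0L, palindromic_discordant = 0L)

  idx <- match(ex$snp_id, ou$snp_id)
  dropped["not_in_outcome"] <- sum(is.na(idx))
  keep <- !is.na(idx)
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[idx[keep], , drop = FALSE]

  n <- nrow(ex)
  take <- logical(n)
  by <- numeric(n)
  eaf_y <- numeric(n)
  for (j in seq_len(n)) {
    ea_x <- ex$effect_allele[j]; oa_x <- ex$other_allele[j]
    ea_y <- ou$effect_allele[j]; oa_y <- ou$other_allele[j]
    pal <- .is_palindromic(ea_x, oa_x)
    direct <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    if (!direct && !swapped && !pal &&
        nchar(ea_x) == 1L && nchar(oa_x) == 1L &&
        nchar(ea_y) == 1L && nchar(oa_y) == 1L) {
      # try the complementary strand for non-palindromic single-base SNPs
      cea <- unname(.complement_allele(ea_y)); coa <- unname(.complement_allele(oa_y))
      if (!is.na(cea) && !is.na(coa)) {
        direct <- cea == ea_x && coa == oa_x
        swapped <- cea == oa_x && coa == ea_x
      }
    }
    if (!direct && !swapped) {
      dropped["allele_mismatch"] <- dropped["allele_mismatch"] + 1L
      next
    }
    b <- ou$beta[j]
    f <- ou$eaf[j]
    if (swapped) {
      b <- -b
      f <- 1 - f
    }
    if (pal) {
      fx <- ex$eaf[j]
      lo <- 0.5 - palindrome_eaf_window
      hi <- 0.5 + palindrome_eaf_window
      if (is.na(fx) || is.na(f) || (fx >= lo && fx <= hi) || (f >= lo && f <= hi)) {
        dropped["palindromic_ambiguous"] <- dropped["palindromic_ambiguous"] + 1L
        next
      }
      if ((fx < 0.5) != (f < 0.5)) {
        dropped["palindromic_discordant"] <- dropped["palindromic_discordant"] + 1L
        next
      }
    }
    take[j] <- TRUE
    by[j] <- b
    eaf_y[j] <- if (is.na(f)) NA_real_ else f
  }

  out <- data.frame(snp_id = ex$snp_id[take],
                    bx = ex$beta[take], se_x = ex$se[take],
                    by = by[take], se_y = ou$se[take],
                    eaf_x = ex$eaf[take],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    stop("no SNPs survived harmonization (",
         paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "), ")",
         call. = FALSE)
  structure(out,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            dropped = dropped,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d SNPs\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  dropped <- attr(x, "dropped")
  if (sum(dropped) > 0)
    cat("  dropped:",
        paste(sprintf("%s=%d", names(dropped)[dropped > 0], dropped[dropped > 0]),
              collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

# build a harmonized_set directly from vectors; used by tests and simulations
#' Construct a harmonized set from effect vectors
#'
#' Low-level constructor used when instrument-exposure and
#' instrument-outcome effects are already aligned to a common effect allele
#' (e.g. simulated data).
#'
#' @param bx,se_x exposure effects and standard errors.
#' @param by,se_y outcome effects and standard errors.
#' @param snp_id optional SNP identifiers.
#' @param eaf_x optional exposure effect-allele frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(bx, se_x, by, se_y, snp_id = NULL, eaf_x = NULL,
                           exposure_id = "exposure", outcome_id = "outcome") {
  k <- length(bx)
  stopifnot(length(se_x) == k, length(by) == k, length(se_y) == k, k >= 1)
  if (any(se_x <= 0) || any(se_y <= 0))
    stop("all standard errors must be > 0", call. = FALSE)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(k))
  if (is.null(eaf_x)) eaf_x <- rep(NA_real_, k)
  structure(data.frame(snp_id = as.character(snp_id), bx = bx, se_x = se_x,
                       by = by, se_y = se_y, eaf_x = eaf_x,
                       stringsAsFactors = FALSE),
            exposure_id = exposure_id, outcome_id = outcome_id,
            dropped = c(not_in_outcome = 0L, allele_mismatch = 0L,
                        palindromic_ambiguous = 0L, palindromic_discordant = 0L),
            class = c("harmonized_set", "data.frame"))
}
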