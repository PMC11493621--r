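#' @keywords internal
"_PACKAGE"

# Canonical column set every trait table carries internally.
.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")

# Header mappings for the supported file dialects. Names are canonical
# columns, values the header used in the file.
.DIALECTS <- list(
  generic = c(snp_id = "SNP", chrom = "CHR", pos = "POS",
              effect_allele = "EA", other_allele = "OA", eaf = "EAF",
              beta = "BETA", se = "SE", pvalue = "P", n = "N"),
  gwas_catalog = c(snp_id = "variant_id", chrom = "chromosome",
                   pos = "base_pair_location", effect_allele = "effect_allele",
                   other_allele = "other_allele",
                   eaf = "effect_allele_frequency", beta = "beta",
                   se = "standard_error", pvalue = "p_value", n = "n"),
  # FinnGen reports the ALT allele as the effect allele.
  finngen = c(snp_id = "rsids", chrom = "#chrom", pos = "pos",
              effect_allele = "alt", other_allele = "ref",
              eaf = "af_alt", beta = "beta", se = "sebeta",
              pvalue = "pval", n = "n")
)

#' Construct a trait table from a data frame
#'
#' A trait table is an ordered data frame of per-SNP summary statistics for a
#' single GWAS trait, with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`. Validation drops rows
#' violating the record invariants (`se > 0`, alleles distinct, `pvalue` in
#' (0, 1], `n > 0`) and resolves duplicated `snp_id`s by keeping the record
#' with the smallest p-value.
#'
#' @param df data frame holding the canonical columns.
#' @param trait_id nonempty string identifying the trait (e.g. a GWAS
#'   accession or a simulation label).
#' @param trait_type one of `"exposure"`, `"mediator"`, `"outcome"`.
#' @param validate drop invalid rows (default `TRUE`). The numbers dropped,
#'   by reason, are stored in the `"dropped"` attribute.
#' @return A `trait_table` object (a data frame with `trait_id`,
#'   `trait_type` and `dropped` attributes).
#' @export
trait_table <- function(df, trait_id, trait_type = c("exposure", "mediator", "outcome"),
                        validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!is.character(trait_id) || length(trait_id) != 1L || !nzchar(trait_id))
    stop("`trait_id` must be a nonempty string", call. = FALSE)
  missing_cols <- setdiff(.SUMSTATS_COLS, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[.SUMSTATS_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  for (col in c("eaf", "beta", "se", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(round(as.numeric(df$n)))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  dropped <- c(invalid_se = 0L, same_alleles = 0L, invalid_p = 0L,
               invalid_n = 0L, missing_core = 0L, duplicate_snp = 0L)
  if (validate) {
    # p = 0 is clamped rather than dropped: it only breaks log-domain code.
    p0 <- !is.na(df$pvalue) & df$pvalue == 0
    if (any(p0)) {
      warning(sum(p0), " p-value(s) of 0 clamped to 1e-300")
      df$pvalue[p0] <- 1e-300
    }
    core_na <- is.na(df$snp_id) | !nzchar(df$snp_id) | is.na(df$beta) |
      is.na(df$se) | is.na(df$pvalue) | is.na(df$n)
    dropped["missing_core"] <- sum(core_na)
    df <- df[!core_na, , drop = FALSE]
    bad_se <- df$se <= 0
    dropped["invalid_se"] <- sum(bad_se)
    df <- df[!bad_se, , drop = FALSE]
    same <- df$effect_allele == df$other_allele
    dropped["same_alleles"] <- sum(same)
    df <- df[!same, , drop = FALSE]
    bad_p <- df$pvalue <= 0 | df$pvalue > 1
    dropped["invalid_p"] <- sum(bad_p)
    df <- df[!bad_p, , drop = FALSE]
    bad_n <- df$n <= 0
    dropped["invalid_n"] <- sum(bad_n)
    df <- df[!bad_n, , drop = FALSE]
    bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
    if (any(bad_eaf)) df$eaf[bad_eaf] <- NA_real_
    if (anyDuplicated(df$snp_id)) {
      # keep the most significant record per rsID, mirroring clumping logic
      ord <- order(df$pvalue, df$snp_id)
      df <- df[ord, , drop = FALSE]
      dup <- duplicated(df$snp_id)
      dropped["duplicate_snp"] <- sum(dup)
      df <- df[!dup, , drop = FALSE]
      df <- df[order(as.integer(rownames(df))), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, trait_id = trait_id, trait_type = trait_type,
            dropped = dropped, class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %s (%s): %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && sum(dropped) > 0)
    cat("  dropped at load:",
        paste(sprintf("%s=%d", names(dropped)[dropped > 0], dropped[dropped > 0]),
              collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Supports three header dialects: `generic` (columns
#' `SNP CHR POS EA OA EAF BETA SE P N`), `gwas_catalog`
#' (`variant_id`, `chromosome`, `base_pair_location`, `effect_allele`,
#' `other_allele`, `effect_allele_frequency`, `beta`, `standard_error`,
#' `p_value`) and `finngen` (`#chrom`, `pos`, `ref`, `alt`, `rsids`,
#' `af_alt`, `beta`, `sebeta`, `pval`; `alt` is the effect allele).
#' `"."` or empty fields are read as missing. Rows failing validation are
#' dropped and counted (see [trait_table()]); an input with zero valid rows
#' is an error.
#'
#' @param path path to a tab- (or whitespace-) delimited file with a header.
#' @param dialect column dialect, see above.
#' @param trait_id trait identifier to attach; defaults to the file name.
#' @param trait_type `"exposure"`, `"mediator"` or `"outcome"`.
#' @param n GWAS sample size used for every row when the file carries no
#'   sample-size column (FinnGen and GWAS-Catalog exports often omit it);
#'   ignored if the file has one.
#' @return A [trait_table()].
#' @export
read_sumstats <- function(path, dialect = c("generic", "gwas_catalog", "finngen"),
                          trait_id = NULL,
                          trait_type = c("exposure", "mediator", "outcome"),
                          n = NULL) {
  dialect <- match.arg(dialect)
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           na.strings = c(".", "", "NA"),
                           colClasses = "character", stringsAsFactors = FALSE)
  map <- .DIALECTS[[dialect]]
  # sample size and frequency may be absent in FinnGen/GWAS-Catalog exports
  optional <- c("n", if (dialect != "generic") "eaf")
  missing_cols <- setdiff(map[setdiff(names(map), optional)], names(raw))
  if (length(missing_cols))
    stop(sprintf("dialect '%s': missing mandatory column(s): %s", dialect,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(map)) {
    src <- map[[canon]]
    df[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  if (all(is.na(df$n))) {
    if (is.null(n))
      stop(sprintf("file %s has no sample-size column; supply `n`", path),
           call. = FALSE)
    df$n <- as.integer(n)
  }
  tab <- trait_table(df, trait_id = trait_id, trait_type = trait_type)
  if (nrow(tab) == 0L)
    stop("no valid summary-statistic rows in ", path, call. = FALSE)
  tab
}

#' Write a trait table as generic TSV
#'
#' Inverse of [read_sumstats()] with the `generic` dialect; numeric fields
#' are written with 15 significant digits so a write/read round trip
#' reproduces them well past 10 significant digits.
#'
#' @param table a [trait_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  df <- as.data.frame(table)
  out <- data.frame(SNP = df$snp_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    EAF = .fmt_num(df$eaf), BETA = .fmt_num(df$beta),
                    SE = .fmt_num(df$se), P = .fmt_num(df$pvalue), N = df$n,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

.fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                               formatC(x, digits = 15, format = "g"))

#' Write MR estimates to a TSV file
#'
#' @param estimates a data frame of MR estimates as returned by
#'   [mr_run_all()] (or a row-bound collection of them); may have zero rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  cols <- c("method", "exposure", "outcome", "nsnp", "beta", "se", "or_",
            "ci_low", "ci_high", "pvalue")
  if (is.null(estimates) || nrow(as.data.frame(estimates)) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  df <- as.data.frame(estimates)
  for (col in cols) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[cols]
  for (col in c("beta", "se", "or_", "ci_low", "ci_high", "pvalue"))
    df[[col]] <- .fmt_num(as.numeric(df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read an MR results TSV written by [write_results()]
#' @param path file path.
#' @return data frame of estimates.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = c(".", "NA"), stringsAsFactors = FALSE)
}

#' Construct an LD information object
#'
#' Stores pairwise LD r-squared values with an unordered lookup key;
#' the diagonal (r2 of a SNP with itself) is implied and never stored.
#'
#' @param pairs data frame with columns `snp_a`, `snp_b`, `r2`.
#' @return An `ld_info` object.
#' @export
ld_info <- function(pairs = data.frame(snp_a = character(), snp_b = character(),
                                       r2 = numeric())) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  pairs$snp_a <- as.character(pairs$snp_a)
  pairs$snp_b <- as.character(pairs$snp_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(pairs$r2 < 0 | pairs$r2 > 1))
    stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  pairs <- pairs[pairs$snp_a != pairs$snp_b, , drop = FALSE]
  key <- .ld_key(pairs$snp_a, pairs$snp_b)
  # keep the last value per unordered pair
  lookup <- numeric(0)
  if (nrow(pairs)) {
    lookup <- pairs$r2
    names(lookup) <- key
    lookup <- lookup[!duplicated(names(lookup), fromLast = TRUE)]
  }
  structure(list(pairs = pairs, lookup = lookup), class = "ld_info")
}

.ld_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Look up pairwise LD
#'
#' Pairs absent from the table are reported as r2 = 0: pairwise LD files are
#' sparse and omission means below the reporting threshold.
#'
#' @param ld an [ld_info()] object.
#' @param a,b SNP identifier vectors (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_info"))
  out <- unname(ld$lookup[.ld_key(as.character(a), as.character(b))])
  out[is.na(out)] <- 0
  out[as.character(a) == as.character(b)] <- 1
  out
}

#' Read LD information from a file
#'
#' Two dialects: `pairwise` (whitespace-separated `SNP_A SNP_B R2`, with or
#' without a header line) and `square_matrix` (tab-separated matrix whose row
#' labels in the first column equal the column labels, in the same order).
#' Asymmetries beyond 1e-6 in a square matrix are a format error; the
#' diagonal is ignored.
#'
#' @param path file path.
#' @param dialect `"pairwise"` or `"square_matrix"`.
#' @return An [ld_info()] object.
#' @export
read_ld <- function(path, dialect = c("pairwise", "square_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "pairwise") {
    first <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
    header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
    df <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("pairwise LD file needs 3 columns: SNP_A SNP_B R2",
                           call. = FALSE)
    df <- df[1:3]
    names(df) <- c("snp_a", "snp_b", "r2")
    if (any(is.na(df$r2)) || any(df$r2 < 0 | df$r2 > 1))
      stop("LD r2 values must lie in [0, 1]", call. = FALSE)
    return(ld_info(df))
  }
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(m)
  if (!identical(rownames(m), colnames(m)))
    stop("square_matrix LD: row and column labels must be identical and ordered alike",
         call. = FALSE)
  if (any(abs(m - t(m)) > 1e-6))
    stop("square_matrix LD: matrix is not symmetric (tolerance 1e-6)",
         call. = FALSE)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ld_info(data.frame(snp_a = rownames(m)[idx[, 1]],
                     snp_b = colnames(m)[idx[, 2]],
                     r2 = m[idx], stringsAsFactors = FALSE))
}
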