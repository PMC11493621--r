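test_that("generic TSV loads identically and invalid rows are rejected with counts", {
  df <- sumstats_df()
  tab <- read_sumstats(write_generic_tsv(df), "generic", trait_id = "t1")
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$beta, df$beta)
  expect_equal(attr(tab, "trait_id"), "t1")

  df$se[2] <- 0
  tab <- read_sumstats(write_generic_tsv(df), "generic")
  expect_equal(nrow(tab), 2L)
  expect_equal(unname(attr(tab, "dropped")["invalid_se"]), 1L)

  df <- sumstats_df()
  df$other_allele[3] <- "A"   # EA == OA
  tab <- read_sumstats(write_generic_tsv(df), "generic")
  expect_equal(nrow(tab), 2L)
  expect_equal(unname(attr(tab, "dropped")["same_alleles"]), 1L)
  expect_false("rs3" %in% tab$snp_id)
})

test_that("missing mandatory columns and empty inputs raise informative errors", {
  df <- sumstats_df()
  path <- write_generic_tsv(df)
  lines <- readLines(path)
  lines[1] <- sub("\tSE\t", "\tXX\t", lines[1])
  writeLines(lines, path)
  expect_error(read_sumstats(path, "generic"), "SE")

  df$se <- 0   # every row invalid
  expect_error(read_sumstats(write_generic_tsv(df), "generic"), "no valid")
})

test_that("duplicate snp ids keep the most significant record", {
  df <- sumstats_df(snp_id = c("rs1", "rs2", "rs2"), pvalue = c(1e-6, 1e-4, 1e-8))
  tab <- trait_table(df, "t", "exposure")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$pvalue[tab$snp_id == "rs2"], 1e-8)
  expect_equal(unname(attr(tab, "dropped")["duplicate_snp"]), 1L)
})

test_that("p-values of zero are clamped, not dropped", {
  df <- sumstats_df(pvalue = c(0, 1e-4, 0.5))
  expect_warning(tab <- trait_table(df, "t", "exposure"), "clamped")
  expect_equal(nrow(tab), 3L)
  expect_equal(min(tab$pvalue), 1e-300)
})

test_that("the three dialects load the same data identically", {
  df <- sumstats_df(eaf = c(0.1, 0.5, 0.9), beta = c(-0.2, 0.05, 0.3))
  generic <- read_sumstats(write_generic_tsv(df), "generic", trait_id = "t")

  gc_path <- tempfile(fileext = ".tsv")
  gc <- data.frame(variant_id = df$snp_id, chromosome = df$chrom,
                   base_pair_location = df$pos, effect_allele = df$effect_allele,
                   other_allele = df$other_allele,
                   effect_allele_frequency = df$eaf, beta = df$beta,
                   standard_error = df$se, p_value = df$pvalue, n = df$n)
  write.table(gc, gc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  catalog <- read_sumstats(gc_path, "gwas_catalog", trait_id = "t")

  fg_path <- tempfile(fileext = ".tsv")
  fg <- data.frame(`#chrom` = df$chrom, pos = df$pos, ref = df$other_allele,
                   alt = df$effect_allele, rsids = df$snp_id,
                   af_alt = df$eaf, beta = df$beta, sebeta = df$se,
                   pval = df$pvalue, check.names = FALSE)
  write.table(fg, fg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  finngen <- read_sumstats(fg_path, "finngen", trait_id = "t", n = df$n[1])

  expect_equal(as.data.frame(generic), as.data.frame(catalog))
  expect_equal(as.data.frame(generic), as.data.frame(finngen))
})

test_that("write/read round trip preserves 10 significant digits", {
  df <- sumstats_df(beta = c(0.123456789012, -1.23456789012e-3, 3.3),
                    se = c(0.0123456789012, 0.2, 0.02),
                    eaf = c(0.123456789, NA, 0.5))
  tab <- trait_table(df, "t", "exposure")
  path <- write_sumstats(tab, tempfile(fileext = ".tsv"))
  back <- read_sumstats(path, "generic", trait_id = "t")
  expect_equal(back$beta, tab$beta, tolerance = 1e-10)
  expect_equal(back$se, tab$se, tolerance = 1e-10)
  expect_equal(back$eaf, tab$eaf, tolerance = 1e-10)
})

test_that("MR results files round-trip and handle the empty case", {
  path <- tempfile(fileext = ".tsv")
  write_results(NULL, path)
  expect_equal(length(readLines(path)), 1L)   # header only

  est <- mr_estimate("ivw", beta = -0.216, se = 0.065, nsnp = 12,
                     exposure = "GCST90027751", outcome = "CPH")
  write_results(as.data.frame(est), path)
  back <- read_results(path)
  expect_equal(back$beta, -0.216, tolerance = 1e-10)
  expect_equal(back$exposure, "GCST90027751")

  ests <- do.call(rbind, lapply(1:5, function(i)
    as.data.frame(mr_estimate("ivw", beta = i / 10, se = 0.1, nsnp = i))))
  write_results(ests, path)
  expect_equal(length(readLines(path)), 6L)
})

test_that("LD dialects agree, are symmetric, and reject invalid r2", {
  mat_path <- tempfile(fileext = ".tsv")
  writeLines(c("\ta\tb", "a\t1\t0.5", "b\t0.5\t1"), mat_path)
  from_mat <- read_ld(mat_path, "square_matrix")

  pw_path <- tempfile(fileext = ".txt")
  writeLines("a b 0.5", pw_path)
  from_pw <- read_ld(pw_path, "pairwise")

  expect_equal(ld_r2(from_mat, "a", "b"), 0.5)
  expect_equal(ld_r2(from_pw, "a", "b"), 0.5)
  expect_equal(ld_r2(from_pw, "b", "a"), 0.5)   # symmetric lookup
  expect_equal(ld_r2(from_pw, "a", "zzz"), 0)   # absent pair => 0
  expect_equal(ld_r2(from_pw, "a", "a"), 1)

  writeLines("a b 1.2", pw_path)
  expect_error(read_ld(pw_path, "pairwise"), "\\[0, 1\\]")

  writeLines(c("\ta\tb", "a\t1\t0.5", "b\t0.1\t1"), mat_path)
  expect_error(read_ld(mat_path, "square_matrix"), "symmetric")
})
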