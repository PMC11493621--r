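# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from checked-in data files.

sumstats_df <- function(snp_id = c("rs1", "rs2", "rs3"),
                        chrom = "1",
                        pos = c(1000L, 2000L, 3000L),
                        ea = "A", oa = "G",
                        eaf = 0.3, beta = 0.1, se = 0.02,
                        pvalue = 1e-6, n = 7738L) {
  k <- length(snp_id)
  data.frame(snp_id = snp_id, chrom = rep_len(chrom, k), pos = rep_len(pos, k),
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = rep_len(beta, k),
             se = rep_len(se, k), pvalue = rep_len(pvalue, k),
             n = rep_len(n, k), stringsAsFactors = FALSE)
}

make_table <- function(..., trait_id = "trait", trait_type = "exposure") {
  trait_table(sumstats_df(...), trait_id = trait_id, trait_type = trait_type)
}

write_generic_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- data.frame(SNP = df$snp_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    EAF = df$eaf, BETA = df$beta, SE = df$se,
                    P = df$pvalue, N = df$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  path
}

# a random harmonized set with positive-definite noise scales
random_hset <- function(k, seed) {
  set.seed(seed)
  harmonized_set(bx = rnorm(k, 0, 0.2) + sign(rnorm(k)) * 0.05,
                 se_x = runif(k, 0.005, 0.05),
                 by = rnorm(k, 0, 0.1),
                 se_y = runif(k, 0.005, 0.05))
}

# independent oracle for the centered weighted-percentile rule
oracle_weighted_median <- function(b, w, prob = 0.5) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  cum <- 0
  s <- numeric(length(b))
  for (i in seq_along(b)) {
    s[i] <- (cum + w[i] / 2) / sum(w)
    cum <- cum + w[i]
  }
  if (prob <= s[1]) return(b[1])
  if (prob >= s[length(s)]) return(b[length(b)])
  i <- max(which(s <= prob))
  b[i] + (b[i + 1] - b[i]) * (prob - s[i]) / (s[i + 1] - s[i])
}

# independent oracle: argmax of the weighted normal-kernel density on a grid
oracle_weighted_mode <- function(b, w, bw) {
  grid <- seq(min(b) - 3 * bw, max(b) + 3 * bw, length.out = 20000)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, b, bw)), numeric(1))
  grid[which.max(dens)]
}
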