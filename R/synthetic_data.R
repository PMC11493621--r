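#' Configuration for the synthetic summary-statistics generator
#'
#' Defines a two-sample GWAS simulation with known causal truth. Instrument
#' effects on the exposure are `gamma_j ~ N(0, gamma_sd^2)`; allele
#' frequencies are uniform on `maf_range`; standard errors follow the
#' standardized-trait approximation `se = 1 / sqrt(2 * maf * (1 - maf) * n)`;
#' observed effects add sampling noise at those standard errors. The outcome
#' association of SNP `j` is `theta * gamma_j + alpha_j` plus noise, where
#' the direct (pleiotropic) effect `alpha_j` follows the chosen regime.
#' Default sample sizes mirror a microbiome-scale exposure GWAS (7,738) and
#' a biobank-scale binary outcome (412,181).
#'
#' @param n_snps number of candidate instruments (default 100).
#' @param n_exposure exposure GWAS sample size (default 7738).
#' @param n_outcome outcome GWAS sample size (default 412181).
#' @param theta true causal effect of exposure on outcome (default 0).
#' @param gamma_sd scale of true instrument effects (default 0.08, sized so
#'   instruments clear the suggestive threshold at `n_exposure` while
#'   per-SNP explained variance stays realistic for a molecular trait).
#' @param pleiotropy one of `pleiotropy_none()`, `pleiotropy_balanced(sd)`,
#'   `pleiotropy_directional(mean, sd)`.
#' @param maf_range range of simulated minor-allele frequencies, within
#'   (0, 0.5] (default c(0.05, 0.5)).
#' @param ld_blocks list of `c(size, r2)` pairs: each block duplicates one
#'   causal signal across `size` co-located SNPs with pairwise LD `r2`.
#' @param mediation optional `list(beta1, beta2, direct_theta, n_mediator_snps,
#'   n_mediator)` enabling [simulate_mediation_triple()].
#' @param invalid_frac fraction of instruments made invalid (their
#'   pleiotropic effect drawn from the pleiotropy regime; the rest get
#'   alpha = 0). Default 1: under `pleiotropy_none()` it is irrelevant.
#' @param gamma_positive orient every SNP to its exposure-increasing allele
#'   (`gamma_j = |N(0, gamma_sd^2)|`). Directional pleiotropy is defined
#'   relative to that orientation, so directional designs should set this
#'   (default `FALSE`).
#' @param seed mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 100, n_exposure = 7738, n_outcome = 412181,
                       theta = 0, gamma_sd = 0.08,
                       pleiotropy = pleiotropy_none(),
                       maf_range = c(0.05, 0.5), ld_blocks = list(),
                       mediation = NULL, invalid_frac = 1,
                       gamma_positive = FALSE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_snps >= 1, gamma_sd >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            invalid_frac >= 0, invalid_frac <= 1)
  structure(list(n_snps = as.integer(n_snps), n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome), theta = theta,
                 gamma_sd = gamma_sd, pleiotropy = pleiotropy,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 mediation = mediation, invalid_frac = invalid_frac,
                 gamma_positive = isTRUE(gamma_positive),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Pleiotropy regimes
#'
#' `pleiotropy_none()` sets every direct effect to zero;
#' `pleiotropy_balanced(sd)` draws `alpha_j ~ N(0, sd^2)` (InSIDE holds:
#' alpha independent of gamma); `pleiotropy_directional(mean, sd)` draws
#' `alpha_j ~ N(mean, sd^2)`, biasing naive estimators while leaving the
#' MR-Egger slope consistent.
#'
#' @param sd standard deviation of direct effects.
#' @param mean mean direct effect (directional regime).
#' @return A pleiotropy-regime list.
#' @export
pleiotropy_none <- function() list(kind = "none", mean = 0, sd = 0)

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(sd) list(kind = "balanced", mean = 0, sd = sd)

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mean, sd = 0) {
  list(kind = "directional", mean = mean, sd = sd)
}

# se of a per-allele effect on a standardized trait
.se_std <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

.sim_positions <- function(n_snps, block_id) {
  # independent loci 20 Mb apart (beyond any clumping window), cycling
  # through chromosomes; block members packed 10 kb apart at their locus
  n_loci <- max(block_id)
  chrom <- character(n_snps)
  pos <- integer(n_snps)
  within <- stats::ave(seq_len(n_snps), block_id, FUN = seq_along)
  locus_chrom <- as.character(((seq_len(n_loci) - 1) %% 22) + 1)
  locus_pos <- 1e6 + ((seq_len(n_loci) - 1) %/% 22) * 2e7
  chrom <- locus_chrom[block_id]
  pos <- as.integer(locus_pos[block_id] + (within - 1) * 1e4)
  list(chrom = chrom, pos = pos)
}

.sim_table <- function(snp_id, chrom, pos, eaf, beta_true, se, n, trait_id,
                       trait_type) {
  beta_obs <- beta_true + stats::rnorm(length(se), 0, se)
  p <- pmax(2 * stats::pnorm(-abs(beta_obs / se)), 1e-300)
  trait_table(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         effect_allele = "A", other_allele = "G",
                         eaf = eaf, beta = beta_obs, se = se,
                         pvalue = p, n = n, stringsAsFactors = FALSE),
              trait_id = trait_id, trait_type = trait_type)
}

#' Simulate a paired exposure/outcome summary-statistics set
#'
#' Generates one exposure and one outcome trait table over the same SNPs,
#' with the generating model of [sim_config()], plus pairwise LD for the
#' configured blocks and the full generating truth. Alleles are fixed at
#' A/G so harmonization is exercised but never drops simulated SNPs.
#'
#' @param config a [sim_config()].
#' @return List with `exposure`, `outcome` ([trait_table()]s), `ld`
#'   ([ld_info()]) and `truth` (per-SNP `gamma`, `alpha`, config echo).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n <- config$n_snps
    sizes <- vapply(config$ld_blocks, function(b) as.integer(b[1]), integer(1))
    if (sum(sizes) > n) stop("ld_blocks exceed n_snps", call. = FALSE)
    # block id per SNP; singleton blocks for unassigned SNPs
    block_id <- integer(0)
    block_r2 <- numeric(0)
    for (i in seq_along(sizes)) {
      block_id <- c(block_id, rep(i, sizes[i]))
      block_r2 <- c(block_r2, config$ld_blocks[[i]][2])
    }
    n_extra <- n - length(block_id)
    if (n_extra > 0)
      block_id <- c(block_id, length(sizes) + seq_len(n_extra))
    snp_id <- sprintf("rs%06d", seq_len(n))
    loc <- .sim_positions(n, block_id)
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    # one causal signal per block, shared by its members (perfect proxies
    # up to noise); LD file reports the configured within-block r2
    gamma_locus <- stats::rnorm(max(block_id), 0, config$gamma_sd)
    if (config$gamma_positive) gamma_locus <- abs(gamma_locus)
    gamma <- gamma_locus[block_id]
    alpha <- numeric(n)
    pl <- config$pleiotropy
    if (pl$kind != "none") {
      invalid <- stats::runif(n) < config$invalid_frac
      alpha[invalid] <- stats::rnorm(sum(invalid), pl$mean, pl$sd)
    }
    se_x <- .se_std(maf, config$n_exposure)
    se_y <- .se_std(maf, config$n_outcome)
    exposure <- .sim_table(snp_id, loc$chrom, loc$pos, maf, gamma, se_x,
                           config$n_exposure, "sim_exposure", "exposure")
    outcome <- .sim_table(snp_id, loc$chrom, loc$pos, maf,
                          config$theta * gamma + alpha, se_y,
                          config$n_outcome, "sim_outcome", "outcome")
    pairs <- do.call(rbind, lapply(which(tabulate(block_id) > 1), function(b) {
      members <- snp_id[block_id == b]
      idx <- utils::combn(length(members), 2)
      data.frame(snp_a = members[idx[1, ]], snp_b = members[idx[2, ]],
                 r2 = block_r2[b], stringsAsFactors = FALSE)
    }))
    if (is.null(pairs))
      pairs <- data.frame(snp_a = character(), snp_b = character(),
                          r2 = numeric())
    list(exposure = exposure, outcome = outcome, ld = ld_info(pairs),
         truth = list(config = config, snp_id = snp_id, gamma = gamma,
                      alpha = alpha, maf = maf, block_id = block_id))
  })
}

#' Simulate an exposure/mediator/outcome mediation triple
#'
#' Generates the X -> M -> Y chain: exposure instruments (effects
#' `gamma_j`) act on the mediator with slope `beta1` and on the outcome
#' with total slope `direct_theta + beta1 * beta2`; an independent set of
#' mediator-specific instruments (effects `delta_j`, same `gamma_sd` scale)
#' acts on the outcome with slope `beta2`, giving the M -> Y leg its own
#' valid instruments. Every table covers all SNPs, so each MR leg selects
#' its own instruments from the shared panel.
#'
#' @param config a [sim_config()] whose `mediation` field is
#'   `list(beta1 = ..., beta2 = ..., direct_theta = ...,
#'   n_mediator_snps = ..., n_mediator = ...)` (the last two optional;
#'   defaults `config$n_snps` and `config$n_exposure`).
#' @return List with `exposure`, `mediator`, `outcome` tables, `ld` and
#'   `truth` (including the implied total effect and proportion mediated).
#' @export
simulate_mediation_triple <- function(config) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$mediation))
  med <- config$mediation
  stopifnot(!is.null(med$beta1), !is.null(med$beta2), !is.null(med$direct_theta))
  n_msnps <- med$n_mediator_snps %||% config$n_snps
  n_med <- med$n_mediator %||% config$n_exposure
  withr_seed(config$seed, {
    nx <- config$n_snps
    n <- nx + n_msnps
    snp_id <- sprintf("rs%06d", seq_len(n))
    block_id <- seq_len(n)
    loc <- .sim_positions(n, block_id)
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    gamma <- c(stats::rnorm(nx, 0, config$gamma_sd), numeric(n_msnps))
    delta <- c(numeric(nx), stats::rnorm(n_msnps, 0, config$gamma_sd))
    theta_total <- med$direct_theta + med$beta1 * med$beta2
    beta_x <- gamma
    beta_m <- med$beta1 * gamma + delta
    beta_y <- theta_total * gamma + med$beta2 * delta
    se_x <- .se_std(maf, config$n_exposure)
    se_m <- .se_std(maf, n_med)
    se_y <- .se_std(maf, config$n_outcome)
    list(exposure = .sim_table(snp_id, loc$chrom, loc$pos, maf, beta_x, se_x,
                               config$n_exposure, "sim_exposure", "exposure"),
         mediator = .sim_table(snp_id, loc$chrom, loc$pos, maf, beta_m, se_m,
                               n_med, "sim_mediator", "mediator"),
         outcome = .sim_table(snp_id, loc$chrom, loc$pos, maf, beta_y, se_y,
                              config$n_outcome, "sim_outcome", "outcome"),
         ld = ld_info(),
         truth = list(config = config, snp_id = snp_id, gamma = gamma,
                      delta = delta, theta_total = theta_total,
                      proportion_pct = if (theta_total != 0)
                        100 * med$beta1 * med$beta2 / theta_total else NA_real_))
  })
}
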