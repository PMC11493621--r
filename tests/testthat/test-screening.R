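cfg_fast <- run_config(n_boot = 30)

test_that("tier assignment uses strict thresholds on the primary p-value", {
  tier <- mrmediate:::.tier
  expect_equal(tier(0.005, cfg_fast), "significant")
  expect_equal(tier(0.01, cfg_fast), "suggestive")    # boundary is strict
  expect_equal(tier(0.03, cfg_fast), "suggestive")
  expect_equal(tier(0.05, cfg_fast), "rejected")      # boundary is strict
  expect_equal(tier(0.5, cfg_fast), "rejected")
  expect_equal(tier(NA_real_, cfg_fast), "rejected")
})

test_that("the forward screen records per-exposure failures without aborting", {
  s <- simulate_pair(sim_config(n_snps = 30, theta = 0.3, gamma_sd = 0.15,
                                n_exposure = 1e5, seed = 81))
  weak <- trait_table(transform(as.data.frame(s$exposure), pvalue = 0.5),
                      "no_iv_trait", "exposure")
  batch <- forward_screen(list(s$exposure, weak), s$outcome, s$ld, cfg_fast)
  expect_length(batch, 2L)
  expect_equal(batch[[2]]$failure_reason, "no_instruments")
  expect_equal(batch[[2]]$tier, "rejected")
  expect_equal(batch[[1]]$tier, "significant")
  expect_false(is.na(batch[[1]]$ivw_beta))
  expect_error(forward_screen(list(), s$outcome, s$ld, cfg_fast), "no exposures")

  smry <- screen_summary(batch)
  expect_equal(nrow(smry), 2L)
  expect_equal(smry$failure_reason[2], "no_instruments")
  expect_true("ivw_p_bh" %in% names(smry))
})

test_that("a null batch yields about the nominal suggestive fraction", {
  exposures <- list()
  outcome <- NULL
  for (i in 1:50) {
    s <- simulate_pair(sim_config(n_snps = 20, theta = 0, gamma_sd = 0.15,
                                  n_exposure = 1e5, seed = 900 + i))
    ex <- s$exposure
    attr(ex, "trait_id") <- sprintf("null%02d", i)
    exposures[[i]] <- ex
    if (i == 1) outcome <- s$outcome
  }
  batch <- forward_screen(exposures, outcome, ld_info(), cfg_fast)
  n_hits <- sum(vapply(batch, function(r) r$tier != "rejected", logical(1)))
  # Binomial(50, ~0.05): 8 is beyond the 99.9th percentile
  expect_lte(n_hits, 8L)

  # monotonicity: a stricter suggestive threshold never adds members
  tight <- run_config(tier_suggestive = 0.01, tier_significant = 0.001,
                      n_boot = 30)
  batch_tight <- forward_screen(exposures, outcome, ld_info(), tight)
  n_tight <- sum(vapply(batch_tight, function(r) r$tier != "rejected",
                        logical(1)))
  expect_lte(n_tight, n_hits)
})

test_that("the reverse screen clears simulated forward-only causal pairs", {
  clear <- logical(40)
  for (i in seq_along(clear)) {
    s <- simulate_pair(sim_config(n_snps = 30, theta = 0.2, n_outcome = 15000,
                                  seed = 6000 + i))
    batch <- forward_screen(list(s$exposure), s$outcome, s$ld, cfg_fast)
    batch[[1]]$tier <- "suggestive"   # exercise the reverse leg on every seed
    batch <- reverse_screen(batch, s$outcome, list(s$exposure), s$ld, cfg_fast)
    clear[i] <- isTRUE(batch[[1]]$reverse_clear)
  }
  expect_gte(mean(clear), 0.9)
})

test_that("reverse clearance thresholds are respected on explicit records", {
  s <- simulate_pair(sim_config(n_snps = 30, theta = 0.2, n_outcome = 15000,
                                seed = 6101))
  batch <- forward_screen(list(s$exposure), s$outcome, s$ld, cfg_fast)
  batch[[1]]$tier <- "suggestive"
  batch <- reverse_screen(batch, s$outcome, list(s$exposure), s$ld, cfg_fast)
  r <- batch[[1]]
  if (!is.na(r$reverse_p)) {
    expect_equal(r$reverse_clear, r$reverse_p > cfg_fast$reverse_clear_p)
  } else {
    expect_true(r$reverse_clear)   # no usable reverse instruments
  }
})

test_that("Bayesian validation demotes at the strict threshold", {
  fake_record <- function(p) {
    est <- as.data.frame(mr_estimate("bwmr", beta = 1, se = 1, nsnp = 5))
    est$pvalue <- p
    structure(list(exposure_id = "x", outcome_id = "y", direction = "forward",
                   estimates = est, tier = "significant",
                   failure_reason = NA_character_,
                   bayes_confirmed = NA, bayes_p = NA_real_),
              class = "screen_record")
  }
  cfg <- run_config()
  recs <- bayes_validate(list(fake_record(0.004), fake_record(0.052),
                              fake_record(0.05)), cfg)
  expect_true(recs[[1]]$bayes_confirmed)
  expect_equal(recs[[1]]$tier, "significant")
  expect_false(recs[[2]]$bayes_confirmed)
  expect_equal(recs[[2]]$tier, "suggestive")
  expect_equal(recs[[2]]$failure_reason, "bayes_unconfirmed")
  expect_false(recs[[3]]$bayes_confirmed)   # p == threshold is demoted
})

test_that("configuration validation rejects out-of-range thresholds and unknown keys", {
  expect_error(run_config(p_instrument = 0), "p_instrument")
  expect_error(run_config(tier_suggestive = 1), "tier_suggestive")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("p_instrument: 1.0e-4", "f_min: 12"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$p_instrument, 1e-4)
  expect_equal(cfg$f_min, 12)
  expect_equal(cfg$clump_kb, 10000)   # defaulting
  writeLines("not_a_key: 1", path)
  expect_error(read_run_config(path), "not_a_key")
})
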