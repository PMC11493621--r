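.Z95 <- 1.959963985  # fixed 97.5% normal quantile for bit-stable CIs

# Normal two-sided p with underflow protection (p stored in (0, 1]).
.norm_p <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, 1e-300)
}

#' Construct an MR estimate
#'
#' All estimators return this shape: the causal effect on the log-odds (or
#' linear) scale, its standard error, a two-sided normal p-value, and the
#' odds-ratio-scale point estimate and 95% confidence interval
#' (`exp(beta +/- 1.959963985 * se)`).
#'
#' @param method estimator label.
#' @param beta,se causal effect and standard error.
#' @param nsnp number of instruments used.
#' @param exposure,outcome trait labels.
#' @param extra named list of method-specific quantities (Egger intercept,
#'   heterogeneity scale, ...).
#' @return An `mr_estimate` (a one-row data frame with an `extra` attribute).
#' @export
mr_estimate <- function(method, beta, se, nsnp, exposure = NA_character_,
                        outcome = NA_character_, extra = list()) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  out <- data.frame(method = method, exposure = exposure, outcome = outcome,
                    nsnp = as.integer(nsnp), beta = beta, se = se,
                    or_ = exp(beta),
                    ci_low = exp(beta - .Z95 * se),
                    ci_high = exp(beta + .Z95 * se),
                    pvalue = .norm_p(beta, se),
                    stringsAsFactors = FALSE)
  structure(out, extra = extra, class = c("mr_estimate", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hs <- function(h) {
  stopifnot(inherits(h, "harmonized_set"), nrow(h) >= 1)
  list(bx = h$bx, se_x = h$se_x, by = h$by, se_y = h$se_y, k = nrow(h),
       exposure = attr(h, "exposure_id") %||% NA_character_,
       outcome = attr(h, "outcome_id") %||% NA_character_)
}

#' Wald ratio estimator (single instrument)
#'
#' `beta = by / bx` with first-order delta-method standard error
#' `|se_y / bx|`.
#'
#' @param h a one-SNP `harmonized_set`.
#' @return An [mr_estimate()].
#' @export
mr_wald_ratio <- function(h) {
  d <- .hs(h)
  if (d$k != 1L) stop("wald ratio requires exactly 1 SNP", call. = FALSE)
  if (d$bx == 0) stop("degenerate instrument: bx = 0", call. = FALSE)
  mr_estimate("wald_ratio", d$by / d$bx, abs(d$se_y / d$bx), 1L,
              d$exposure, d$outcome)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted zero-intercept regression of outcome on exposure effects with
#' weights `1/se_y^2`; in closed form
#' `beta = sum(bx * by / se_y^2) / sum(bx^2 / se_y^2)`. The fixed-effect
#' standard error is `sqrt(1 / sum(bx^2 / se_y^2))`; the default
#' multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q / (k - 1)))` with `Q` Cochran's heterogeneity statistic at
#' the IVW estimate, never deflating below the fixed-effect value.
#'
#' @param h a `harmonized_set` with `k >= 2` (a single SNP delegates to
#'   [mr_wald_ratio()]).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An [mr_estimate()]; `extra` carries `q`, `q_df` and the
#'   se-inflation factor `phi`.
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  d <- .hs(h)
  if (d$k == 1L) return(mr_wald_ratio(h))
  w <- 1 / d$se_y^2
  denom <- sum(w * d$bx^2)
  if (denom == 0) stop("degenerate instruments: all bx = 0", call. = FALSE)
  beta <- sum(w * d$bx * d$by) / denom
  se_fixed <- sqrt(1 / denom)
  q <- sum(w * (d$by - beta * d$bx)^2)
  phi <- if (d$k > 1) max(1, sqrt(q / (d$k - 1))) else 1
  se <- if (model == "fixed") se_fixed else se_fixed * phi
  mr_estimate(paste0("ivw", if (model == "fixed") "_fixed" else ""),
              beta, se, d$k, d$exposure, d$outcome,
              extra = list(q = q, q_df = d$k - 1L, phi = phi, model = model))
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with a free intercept and weights
#' `1/se_y^2`. Instruments are first oriented so every `bx >= 0` (flipping
#' `(bx, by)` jointly), the conventional orientation that makes the
#' intercept interpretable as directional pleiotropy. The slope is the
#' pleiotropy-corrected causal effect; the intercept, its standard error
#' and two-sided p-value form the horizontal-pleiotropy test. Standard
#' errors use the multiplicative random-effects inflation
#' `max(1, residual sd)`.
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @return An [mr_estimate()]; `extra` carries `intercept`, `intercept_se`,
#'   `intercept_p`, `q_egger` and `q_egger_df`.
#' @export
mr_egger <- function(h) {
  d <- .hs(h)
  if (d$k < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- 1 / d$se_y^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * by)))
  vcov_raw <- solve(xtwx)                # fixed-effect coefficient covariance
  resid <- by - drop(X %*% coefs)
  q_egger <- sum(w * resid^2)
  # multiplicative random effects: inflate, never deflate
  infl <- max(1, sqrt(q_egger / (d$k - 2)))
  beta <- unname(coefs[2])
  se <- sqrt(vcov_raw[2, 2]) * infl
  a <- unname(coefs[1])
  a_se <- sqrt(vcov_raw[1, 1]) * infl
  mr_estimate("egger", beta, se, d$k, d$exposure, d$outcome,
              extra = list(intercept = a, intercept_se = a_se,
                           intercept_p = .norm_p(a, a_se),
                           q_egger = q_egger, q_egger_df = d$k - 2L))
}

# Weighted 50% percentile of ratio estimates with the centered
# cumulative-weight interpolation rule: s_j = (cum_j - w_j/2) / sum(w).
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The weighted median of per-SNP Wald ratios `by/bx` with inverse-variance
#' weights `(bx/se_y)^2`; consistent when instruments carrying at least half
#' the weight are valid. Standard error by seeded parametric bootstrap:
#' `by` and `bx` are resampled from `N(by, se_y^2)` and `N(bx, se_x^2)` and
#' the weighted median recomputed; the p-value uses the normal
#' approximation `beta / se_boot`.
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory for reproducibility).
#' @return An [mr_estimate()].
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  d <- .hs(h)
  if (d$k < 3L) stop("weighted median requires at least 3 instruments",
                     call. = FALSE)
  ratio <- d$by / d$bx
  w <- (d$bx / d$se_y)^2
  beta <- .weighted_median(ratio, w)
  se <- .boot_se(d, n_boot, seed, function(bx, by) {
    .weighted_median(by / bx, (bx / d$se_y)^2)
  })
  mr_estimate("weighted_median", beta, se, d$k, d$exposure, d$outcome,
              extra = list(n_boot = n_boot, seed = seed))
}

.boot_se <- function(d, n_boot, seed, statistic) {
  est <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(d$k, d$bx, d$se_x)
      by <- stats::rnorm(d$k, d$by, d$se_y)
      statistic(bx, by)
    }, numeric(1))
  })
  stats::sd(est)
}

# evaluate `code` under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# Mode of the weighted normal-kernel density of the ratio estimates,
# located on a fine grid.
.weighted_mode <- function(b, w, bandwidth_factor = 1) {
  s <- stats::mad(b)
  if (s == 0) return(stats::median(b))
  # modified Silverman rule on the ratio estimates (mad-based)
  h <- bandwidth_factor * 0.9 * s / length(b)^0.2
  dens <- stats::density(b, weights = w / sum(w), bw = h, n = 512)
  dens$x[which.max(dens$y)]
}

#' Weighted mode estimator
#'
#' The mode of the inverse-variance-weighted kernel-smoothed density of the
#' per-SNP Wald ratios; consistent when the largest group of instruments
#' sharing one causal estimate is valid (plurality validity). Bandwidth is
#' `bandwidth_factor` times a modified (MAD-based) Silverman rule. Standard
#' error by seeded parametric bootstrap as in [mr_weighted_median()].
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @param bandwidth_factor multiplier on the default bandwidth (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  d <- .hs(h)
  if (d$k < 3L) stop("weighted mode requires at least 3 instruments",
                     call. = FALSE)
  ratio <- d$by / d$bx
  w <- (d$bx / d$se_y)^2
  beta <- .weighted_mode(ratio, w, bandwidth_factor)
  se <- .boot_se(d, n_boot, seed, function(bx, by) {
    .weighted_mode(by / bx, (bx / d$se_y)^2, bandwidth_factor)
  })
  mr_estimate("weighted_mode", beta, se, d$k, d$exposure, d$outcome,
              extra = list(bandwidth_factor = bandwidth_factor,
                           n_boot = n_boot, seed = seed))
}

#' Bayesian weighted MR with outlier down-weighting
#'
#' Fits the measurement-error model
#' `by_j ~ N(theta * gamma_j, se_y_j^2 + tau^2)`,
#' `bx_j ~ N(gamma_j, se_x_j^2)`, `theta ~ N(0, prior_sd_theta^2)` by
#' blockwise conditional updates: true instrument effects `gamma_j` are
#' replaced by their conditional posterior means, `theta` by its Gaussian
#' posterior mean given them, the overdispersion `tau^2` by a weighted
#' moment estimate, and each SNP receives a responsibility weight
#' `P(inlier)` under a two-component (inlier / heavy-tailed contaminant)
#' model of the standardized residuals, down-weighting gross outliers.
#' Iteration stops when `theta` moves less than `tol`.
#'
#' @param h a `harmonized_set` with `k >= 3`.
#' @param prior_sd_theta prior standard deviation of the causal effect
#'   (default 10, effectively weakly informative).
#' @param max_iter maximum iterations (default 500).
#' @param tol convergence tolerance on `theta` (default 1e-6).
#' @param outlier_sd standard-deviation ratio of the contaminant component
#'   (default 8).
#' @param outlier_prob prior contaminant probability (default 0.02; kept small so that in clean data the fit stays numerically indistinguishable from fixed-effect IVW while gross outliers, whose inlier likelihood collapses, are still removed).
#' @return An [mr_estimate()]; `extra` carries `tau2`, the per-SNP inlier
#'   weights and the iteration count.
#' @export
mr_bwmr <- function(h, prior_sd_theta = 10, max_iter = 500, tol = 1e-6,
                    outlier_sd = 8, outlier_prob = 0.02) {
  d <- .hs(h)
  if (d$k < 3L) stop("Bayesian weighted MR requires at least 3 instruments",
                     call. = FALSE)
  theta <- mr_ivw(h, model = "fixed")$beta
  tau2 <- 0
  wgt <- rep(1, d$k)
  gamma <- d$bx
  iter <- 0L
  repeat {
    iter <- iter + 1L
    vy <- d$se_y^2 + tau2
    # conditional posterior mean of the true instrument effects
    gamma <- (d$bx / d$se_x^2 + theta * d$by / vy) /
      (1 / d$se_x^2 + theta^2 / vy)
    # Gaussian posterior for theta given gamma, with outlier weights
    prec <- sum(wgt * gamma^2 / vy) + 1 / prior_sd_theta^2
    theta_new <- sum(wgt * gamma * d$by / vy) / prec
    resid <- d$by - theta_new * gamma
    # weighted moment update of the overdispersion
    tau2 <- max(0, sum(wgt * (resid^2 - d$se_y^2)) / sum(wgt))
    z <- resid / sqrt(d$se_y^2 + tau2)
    f_in <- stats::dnorm(z)
    f_out <- stats::dnorm(z, sd = outlier_sd)
    wgt <- (1 - outlier_prob) * f_in /
      ((1 - outlier_prob) * f_in + outlier_prob * f_out)
    done <- abs(theta_new - theta) < tol
    theta <- theta_new
    if (done) break
    if (iter >= max_iter)
      stop(sprintf("bwmr failed to converge in %d iterations (last theta=%.6g)",
                   max_iter, theta), call. = FALSE)
  }
  se <- sqrt(1 / (sum(wgt * gamma^2 / (d$se_y^2 + tau2)) + 1 / prior_sd_theta^2))
  mr_estimate("bwmr", theta, se, d$k, d$exposure, d$outcome,
              extra = list(tau2 = tau2, weights = wgt, iterations = iter,
                           prior_sd_theta = prior_sd_theta))
}

#' Run the full panel of estimators
#'
#' Applies every estimator the instrument count supports: one SNP gives the
#' Wald ratio, two give IVW only, three or more give IVW, MR-Egger,
#' weighted median, weighted mode and Bayesian weighted MR. A failing
#' method is recorded as a failure row (`method`, `error`), never aborting
#' the batch.
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap replicates for median/mode (default 1000).
#' @param seed RNG seed for stochastic methods.
#' @param ivw_model passed to [mr_ivw()].
#' @return A data frame of estimates (class `mr_estimates`); failures, if
#'   any, are kept in the `"failures"` attribute.
#' @export
mr_run_all <- function(h, n_boot = 1000, seed = 1L,
                       ivw_model = "multiplicative_random") {
  k <- nrow(h)
  runs <- if (k == 1L) {
    list(wald_ratio = function() mr_wald_ratio(h))
  } else if (k == 2L) {
    list(ivw = function() mr_ivw(h, model = ivw_model))
  } else {
    list(ivw = function() mr_ivw(h, model = ivw_model),
         egger = function() mr_egger(h),
         weighted_median = function() mr_weighted_median(h, n_boot, seed),
         weighted_mode = function() mr_weighted_mode(h, n_boot = n_boot,
                                                     seed = seed),
         bwmr = function() mr_bwmr(h))
  }
  out <- list()
  failures <- list()
  for (nm in names(runs)) {
    res <- tryCatch(runs[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
    } else {
      out[[nm]] <- as.data.frame(res)
    }
  }
  est <- if (length(out)) do.call(rbind, unname(out)) else
    as.data.frame(mr_estimate("none", 0, 1, 0L))[0, ]
  rownames(est) <- NULL
  structure(est, failures = failures, class = c("mr_estimates", "data.frame"))
}
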