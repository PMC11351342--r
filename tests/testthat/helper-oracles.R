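# Shared fixture builders and independent oracles. The oracles deliberately
# go through different code paths (lm / explicit enumeration) than the
# implementation they check.

# Random harmonized set with configurable effects.
make_hset <- function(n, beta = 0.3, se_out = 0.05, se_exp = 0.02,
                      bx_mean = 0.1, bx_sd = 0.03,
                      n_exp = 1e5, n_out = 1e5, seed = NULL) {
  build <- function() {
    bx <- stats::rnorm(n, bx_mean, bx_sd)
    bx[abs(bx) < 1e-4] <- 1e-4
    by <- beta * bx + stats::rnorm(n, 0, se_out)
    data.frame(snp = sprintf("rs%04d", seq_len(n)),
               beta_exp = bx, se_exp = se_exp, pval_exp = 1e-10, n_exp = n_exp,
               beta_out = by, se_out = se_out, pval_out = 0.5, n_out = n_out,
               eaf = 0.3, flipped = FALSE, palindromic = FALSE,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# Brute-force IVW via weighted lm through the origin.
oracle_ivw <- function(h, effects_model = "fixed") {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
  sm <- summary(fit)
  se_fixed <- sm$coefficients[1, 2] / sm$sigma
  se <- if (effects_model == "random") se_fixed * max(1, sm$sigma) else se_fixed
  list(beta = unname(stats::coef(fit)[1]), se = se)
}

# Brute-force Egger via weighted lm with intercept, exposure-oriented.
oracle_egger <- function(h) {
  s <- ifelse(h$beta_exp < 0, -1, 1)
  d <- data.frame(bx = h$beta_exp * s, by = h$beta_out * s)
  fit <- stats::lm(by ~ bx, data = d, weights = 1 / h$se_out^2)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sm$coefficients[2, 2] / sm$sigma * scale,
       intercept = unname(stats::coef(fit)[1]),
       intercept_se = sm$coefficients[1, 2] / sm$sigma * scale)
}

# Independent clumping oracle: accept-in-p-order rule evaluated through a
# precomputed conflict matrix rather than the implementation's loop.
oracle_clump <- function(candidates, ld, r2_threshold, window_kb) {
  n <- nrow(candidates)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same_chr <- candidates$chrom[i] == candidates$chrom[j]
      close <- abs(candidates$pos[i] - candidates$pos[j]) <= window_kb * 1000
      high_ld <- ld[candidates$snp[i], candidates$snp[j]] >= r2_threshold
      conflict[i, j] <- same_chr && close && high_ld
    }
  }
  ord <- order(candidates$pval, candidates$pos, candidates$snp)
  accepted <- logical(n)
  for (i in ord) {
    accepted[i] <- !any(conflict[i, ] & accepted)
  }
  sort(candidates$snp[accepted])
}

# Small canonical summary-stat data frame.
make_ss_df <- function(n, seed = 1, beta = NULL, se = NULL, pval = NULL,
                       nn = 10000) {
  withr::with_seed(seed, {
    pair <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    k <- pair[sample.int(4, n, replace = TRUE), , drop = FALSE]
    beta <- beta %||% round(stats::rnorm(n, 0, 0.05), 6)
    se <- se %||% round(stats::runif(n, 0.005, 0.05), 6)
    data.frame(snp = sprintf("rs%04d", seq_len(n)),
               chrom = as.character(rep(1:22, length.out = n)),
               pos = seq(1e6, by = 2e7, length.out = n),
               effect_allele = k[, 1], other_allele = k[, 2],
               eaf = round(stats::runif(n, 0.05, 0.95), 4),
               beta = beta,
               se = se,
               pval = pval %||% (2 * stats::pnorm(-abs(beta / se))),
               n = nn,
               stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Summary-statistic tables for one simulated scenario; the workhorse of the
# property and acceptance tests.
scenario_tables <- function(name, seed, overrides = list(),
                            roles = c("exposure", "mediator", "outcome")) {
  cfg <- build_scenario(name, c(overrides, list(seed = seed)))
  sim <- simulate_cohort(cfg, roles = roles)
  out <- list(sim = sim, exposure_panel = sim$exposure_panel,
              mediator_panel = sim$mediator_panel)
  if ("exposure" %in% roles) {
    out$exposure <- quiet(summary_stats_from_cohort(
      sim$cohorts$exposure$G, sim$cohorts$exposure$X, "continuous",
      sim$snp_info, "exposure"))
  }
  if ("mediator" %in% roles) {
    out$mediator <- quiet(summary_stats_from_cohort(
      sim$cohorts$mediator$G, sim$cohorts$mediator$M, "continuous",
      sim$snp_info, "mediator"))
  }
  if ("outcome" %in% roles) {
    out$outcome <- quiet(summary_stats_from_cohort(
      sim$cohorts$outcome$G, sim$cohorts$outcome$Y, "binary",
      sim$snp_info, "outcome"))
  }
  out
}
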