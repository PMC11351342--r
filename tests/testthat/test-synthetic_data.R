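# Synthetic cohort generator, summary-statistic scan, 2SLS, presets.

test_that("scenario presets encode the intended causal structures", {
  expect_error(build_scenario("nonsense"), "valid names")
  null <- build_scenario("null")
  expect_equal(null$theta1 + null$theta2 + null$delta + null$theta_rev, 0)
  med <- build_scenario("mediated")
  expect_equal(med$theta1 * med$theta2, 0.2)
  rev <- build_scenario("reverse")
  expect_gt(rev$theta_rev, 0)
  ple <- build_scenario("pleiotropic")
  expect_identical(ple$pleiotropy$type, "directional")
  over <- build_scenario("mediated", list(n_per_cohort = 500L))
  expect_equal(over$n_per_cohort, 500L)
  expect_error(build_scenario("mediated", list(outcome_prevalence = 2)))
})

test_that("cohort simulation is seed-deterministic and hits target h2", {
  cfg <- build_scenario("mediated", list(n_per_cohort = 2000L, seed = 42L))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohorts$exposure$G, s2$cohorts$exposure$G)
  expect_identical(s1$cohorts$outcome$Y, s2$cohorts$outcome$Y)
  expect_identical(s1$truth, s2$truth)

  # realized instrument R2 tracks exposure_h2 (spec'd window at h2 = 0.05)
  r2 <- vapply(1:30, function(r) {
    cfg <- build_scenario("null", list(exposure_h2 = 0.05, seed = 7000 + r,
                                       n_snps_mediator = 0L))
    sim <- simulate_cohort(cfg, roles = "exposure")
    co <- sim$cohorts$exposure
    stats::cor(drop(co$G %*% sim$truth$a), co$X)^2
  }, numeric(1))
  expect_equal(mean(r2), 0.05, tolerance = 0.1)
  expect_true(all(r2 > 0.035 & r2 < 0.065))

  # null scenario: exposure and outcome uncorrelated
  tabs <- build_scenario("null", list(seed = 77L, n_per_cohort = 5000L))
  sim <- simulate_cohort(tabs, roles = "outcome")
  co <- sim$cohorts$outcome
  expect_lt(abs(stats::cor(co$X, co$Y)), 3 / sqrt(5000))

  # infeasible variance budget is rejected with an explanation
  bad <- build_scenario("mediated", list(theta1 = 0.9, mediator_h2 = 0.3))
  expect_error(simulate_cohort(bad), "residual variance")

  # outcome prevalence is respected
  expect_equal(mean(co$Y), 0.25, tolerance = 0.03)
})

test_that("per-SNP summary statistics match closed-form OLS and flag monomorphic SNPs", {
  cfg <- build_scenario("null", list(n_per_cohort = 1500L, seed = 3L,
                                     n_snps = 20L, n_snps_mediator = 0L))
  sim <- simulate_cohort(cfg, roles = "exposure")
  G <- sim$cohorts$exposure$G
  y <- sim$cohorts$exposure$X
  tab <- quiet(summary_stats_from_cohort(G, y, "continuous", sim$snp_info, "t"))
  # closed form cov/var oracle per SNP
  for (j in c(1, 7, 20)) {
    expect_equal(tab$beta[j], stats::cov(G[, j], y) / stats::var(G[, j]),
                 tolerance = 1e-10)
    fit <- stats::lm(y ~ G[, j])
    expect_equal(tab$se[j], summary(fit)$coefficients[2, 2], tolerance = 1e-10)
  }

  # constructed signal: phenotype = 2 * dosage of SNP 1, no noise
  y2 <- 2 * G[, 1]
  tab2 <- quiet(summary_stats_from_cohort(G, y2, "continuous", sim$snp_info, "t"))
  expect_equal(tab2$beta[1], 2, tolerance = 1e-10)

  # monomorphic SNP flagged with eaf 0/1
  G2 <- cbind(G, 0L)
  info2 <- rbind(sim$snp_info,
                 data.frame(snp = "rs_mono", chrom = "22", pos = 9e6,
                            effect_allele = "A", other_allele = "G"))
  expect_message(tab3 <- summary_stats_from_cohort(G2, y, "continuous", info2, "t"),
                 "monomorphic")
  expect_identical(attr(tab3, "monomorphic"), "rs_mono")
  expect_equal(tab3$eaf[21], 0)

  # binary scan: z^2 is chi-square(1) under the null (KS, 2000 SNPs)
  nb <- 3000
  withr::with_seed(11, {
    Gb <- matrix(stats::rbinom(nb * 2000, 2L, 0.3), nb, 2000)
    yb <- stats::rbinom(nb, 1L, 0.25)
  })
  infob <- data.frame(snp = sprintf("s%d", 1:2000), chrom = "1",
                      pos = seq_len(2000) * 1e4,
                      effect_allele = "A", other_allele = "G")
  tabb <- quiet(summary_stats_from_cohort(Gb, yb, "binary", infob, "b"))
  z2 <- (tabb$beta / tabb$se)^2
  expect_gt(stats::ks.test(z2, stats::pchisq, df = 1)$p.value, 0.01)

  # score approximation agrees with the full logistic fit at GWAS effect sizes
  tabg <- quiet(summary_stats_from_cohort(Gb[, 1:5], yb, "binary", infob[1:5, ],
                                          "b", method = "glm"))
  expect_equal(tabb$beta[1:5], tabg$beta[1:5], tolerance = 0.02)

  expect_error(summary_stats_from_cohort(G, y[-1], "continuous", sim$snp_info),
               "match")
})

test_that("2SLS matches the Wald ratio identity and is calibrated under the null", {
  # single strong instrument: 2SLS equals the summary-stat Wald ratio
  withr::with_seed(21, {
    n <- 4000
    g <- stats::rbinom(n, 2L, 0.4)
    x <- 0.5 * g + stats::rnorm(n)
    y <- 0.3 * x + stats::rnorm(n)
  })
  ts <- quiet(two_stage_least_squares(matrix(g, ncol = 1), x, y))
  bx <- stats::cov(g, x) / stats::var(g)
  by <- stats::cov(g, y) / stats::var(g)
  expect_equal(ts$beta, by / bx, tolerance = 1e-6)
  expect_gt(ts$multiple_r2, 0)

  # exposure regressed on itself: beta exactly 1
  expect_equal(quiet(two_stage_least_squares(matrix(g, ncol = 1), x, x))$beta, 1,
               tolerance = 1e-12)

  # response independent of exposure: p-values uniform (KS over 400 replicates)
  ps <- vapply(1:400, function(r) {
    withr::with_seed(500 + r, {
      G <- matrix(stats::rbinom(400 * 5, 2L, 0.3), 400, 5)
      x <- drop(G %*% rep(0.2, 5)) + stats::rnorm(400)
      y <- stats::rnorm(400)
      quiet(two_stage_least_squares(G, x, y))$pval
    })
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # rank-deficient stage 1 is fatal
  expect_error(quiet(two_stage_least_squares(cbind(g, g), x, y)), "rank")
})

test_that("LD blocks reach the target within-block r2 and are clumpable", {
  cfg <- build_scenario("null", list(
    n_per_cohort = 4000L, n_snps = 12L, n_snps_mediator = 0L, seed = 13L,
    maf_range = c(0.3, 0.3001), ld_blocks = list(size = 4, r2 = 0.3)))
  sim <- simulate_cohort(cfg, roles = "exposure")
  G <- sim$cohorts$exposure$G
  within <- c()
  for (b in 0:2) {
    idx <- b * 4 + 1:4
    cc <- stats::cor(G[, idx])^2
    within <- c(within, cc[upper.tri(cc)])
  }
  expect_equal(mean(within), 0.3, tolerance = 0.05 / 0.3)
  # across blocks: essentially independent
  expect_lt(mean(stats::cor(G[, 1:4], G[, 5:8])^2), 0.01)
})

test_that("scenario presets run end-to-end through the pipeline quickly", {
  for (name in c("null", "mediated", "reverse")) {
    tabs <- scenario_tables(name, seed = 321,
                            overrides = list(n_per_cohort = 4000L),
                            roles = c("exposure", "outcome"))
    cfg <- run_config(p_threshold = 1e-4, f_min = 10, n_boot = 50, seed = 1)
    run <- quiet(run_mr(tabs$exposure, tabs$outcome, cfg))
    expect_true(run$status %in% c("ok", "not estimable"))
    if (run$status == "ok") {
      expect_true(all(c("IVW", "MR-Egger") %in% run$estimates$method) ||
                  nrow(run$harmonized) < 3)
    }
  }
})
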