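# MR estimator suite: worked examples, oracle equivalence, invariances.

one_record <- function(bx, sx, by, sy) {
  data.frame(snp = "rs1", beta_exp = bx, se_exp = sx, pval_exp = 1e-10,
             n_exp = 1e5, beta_out = by, se_out = sy, pval_out = 0.5,
             n_out = 1e5, eaf = 0.3, flipped = FALSE, palindromic = FALSE)
}

test_that("Wald ratio arithmetic, null case and second-order SE", {
  est <- mr_wald_ratio(one_record(0.5, 0.05, 0.25, 0.10))
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  est0 <- mr_wald_ratio(one_record(0.5, 0.05, 0, 0.10))
  expect_equal(est0$beta, 0)
  expect_equal(est0$pval, 1)
  expect_error(mr_wald_ratio(one_record(0, 0.05, 0.1, 0.1)), "zero")

  # second-order delta SE vs Monte-Carlo SE of the ratio at |bx/sx| = 10
  h <- one_record(0.5, 0.05, 0.25, 0.10)
  mc <- withr::with_seed(42, {
    stats::sd(stats::rnorm(1e6, h$beta_out, h$se_out) /
              stats::rnorm(1e6, h$beta_exp, h$se_exp))
  })
  est2 <- mr_wald_ratio(h, second_order = TRUE)
  expect_equal(est2$se, mc, tolerance = 0.05)
})

test_that("IVW matches the symmetric-pair example, delegation and the WLS oracle", {
  h <- rbind(one_record(1, 0.1, 0.4, 1), one_record(1, 0.1, 0.6, 1))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 1 / sqrt(2))

  # single record delegates to the Wald ratio
  expect_equal(mr_ivw(h[1, ])$beta, mr_wald_ratio(h[1, ])$beta)
  expect_identical(mr_ivw(h[1, ])$method, "Wald ratio")

  # 50 random records: equality with a WLS-through-origin oracle to 1e-10
  for (seed in 1:5) {
    hr <- make_hset(50, seed = seed)
    for (model in c("fixed", "random")) {
      got <- mr_ivw(hr, model)
      want <- oracle_ivw(hr, model)
      expect_equal(got$beta, want$beta, tolerance = 1e-10)
      expect_equal(got$se, want$se, tolerance = 1e-10)
    }
  }

  # equal weights on bx = 1 reduce to the arithmetic mean of outcome betas
  hm <- make_hset(9, seed = 9)
  hm$beta_exp <- 1; hm$se_out <- 0.05
  expect_equal(mr_ivw(hm, "fixed")$beta, mean(hm$beta_out), tolerance = 1e-12)
})

test_that("Egger fits the collinear example exactly and matches the WLS oracle", {
  h <- rbind(one_record(1, .01, 0.6, 1), one_record(2, .01, 1.1, 1),
             one_record(3, .01, 1.6, 1))
  fit <- mr_egger(h)
  expect_equal(fit$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$residual_scale, 0, tolerance = 1e-7)

  expect_error(mr_egger(h[1:2, ]), "at least 3")

  for (seed in 1:5) {
    hr <- make_hset(40, seed = seed + 10, bx_mean = 0.05, bx_sd = 0.05)
    got <- mr_egger(hr)
    want <- oracle_egger(hr)
    expect_equal(got$slope$beta, want$slope, tolerance = 1e-10)
    expect_equal(got$slope$se, want$slope_se, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$intercept_se, want$intercept_se, tolerance = 1e-10)
  }

  # directional pleiotropy of known size is recovered by the intercept
  hp <- make_hset(80, seed = 3, beta = 0.3, se_out = 0.02,
                  bx_mean = 0.1, bx_sd = 0.04)
  hp$beta_out <- hp$beta_out + 0.2
  expect_equal(mr_egger(hp)$intercept, 0.2, tolerance = 0.1)
})

test_that("weighted median interpolates correctly and its bootstrap SE converges", {
  h <- rbind(one_record(1, .01, 0.2, 1), one_record(1, .01, 0.5, 1),
             one_record(1, .01, 0.8, 1))
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta, 0.5)

  # dominant weight pulls the estimate to that SNP's ratio
  hw <- h
  hw$se_out <- c(1, 1, 1 / sqrt(49))  # weight 0.98 on ratio 0.8
  expect_equal(mr_weighted_median(hw, n_boot = 10, seed = 1)$beta, 0.8,
               tolerance = 0.05)

  # equal weights and odd nsnp: ordinary median
  hm <- make_hset(11, seed = 4)
  hm$beta_exp <- 1; hm$se_out <- 0.05
  expect_equal(mr_weighted_median(hm, n_boot = 10, seed = 1)$beta,
               stats::median(hm$beta_out))

  # bootstrap SE at 1000 vs 100000 replicates agrees within 15% relative
  hb <- make_hset(10, seed = 5)
  se1 <- mr_weighted_median(hb, n_boot = 1000, seed = 2)$se
  se2 <- mr_weighted_median(hb, n_boot = 100000, seed = 3)$se
  expect_lt(abs(se1 - se2) / se2, 0.15)
})

test_that("mode estimators find the dominant ratio cluster", {
  # point mass: all ratios equal
  h <- rbind(one_record(1, .01, 0.3, .1), one_record(2, .01, 0.6, .1),
             one_record(4, .01, 1.2, .1))
  expect_equal(mr_mode(h, "simple", n_boot = 10, seed = 1)$beta, 0.3,
               tolerance = 1e-6)

  # 7 ratios near 0.5, 3 near 2.0 with comparable SEs: simple mode near 0.5
  hmix <- withr::with_seed(6, {
    r <- c(stats::rnorm(7, 0.5, 0.02), stats::rnorm(3, 2, 0.02))
    data.frame(snp = sprintf("rs%d", 1:10), beta_exp = 1, se_exp = 0.01,
               pval_exp = 1e-10, n_exp = 1e5, beta_out = r, se_out = 0.1,
               pval_out = .5, n_out = 1e5, eaf = .3, flipped = FALSE,
               palindromic = FALSE)
  })
  expect_equal(mr_mode(hmix, "simple", n_boot = 10, seed = 1)$beta, 0.5,
               tolerance = 0.1)

  # weighted variant with nearly all weight on the 2.0 cluster
  hmix$se_out <- c(rep(1, 7), rep(0.01, 3))
  expect_equal(mr_mode(hmix, "weighted", n_boot = 10, seed = 1)$beta, 2,
               tolerance = 0.1)
  expect_error(mr_mode(hmix[1:2, ], "simple"), "at least 3")
})

test_that("every causal estimator is scale-equivariant in the exposure", {
  h <- make_hset(15, seed = 7)
  h2 <- h
  cc <- -2.5
  h2$beta_exp <- h$beta_exp * cc
  h2$se_exp <- h$se_exp * abs(cc)
  for (fn in list(function(x) mr_ivw(x, "fixed"),
                  function(x) mr_egger(x)$slope,
                  function(x) mr_weighted_median(x, n_boot = 50, seed = 1),
                  function(x) mr_mode(x, "weighted", n_boot = 50, seed = 1))) {
    expect_equal(fn(h2)$beta, fn(h)$beta / cc, tolerance = 1e-6)
  }
})

test_that("mr_all_methods assembles the method grid and odds-ratio columns", {
  h1 <- one_record(0.5, 0.05, 0.25, 0.1)
  out1 <- quiet(mr_all_methods(h1))
  expect_identical(out1$method, "Wald ratio")

  h <- make_hset(20, seed = 8)
  out <- mr_all_methods(h, or_scale = TRUE, n_boot = 50, seed = 1)
  expect_setequal(out$method,
                  c("MR-Egger", "Weighted median", "IVW", "Simple mode",
                    "Weighted mode"))
  expect_equal(out$or, exp(out$beta))
  expect_true(all(out$or_ci_low <= out$or & out$or <= out$or_ci_high))

  # null input: all ORs near 1
  h0 <- make_hset(20, seed = 9, beta = 0)
  out0 <- mr_all_methods(h0, or_scale = TRUE, n_boot = 50, seed = 1)
  expect_true(all(abs(out0$or - 1) < 0.25))

  # two records: only IVW is applicable
  out2 <- quiet(mr_all_methods(h[1:2, ]))
  expect_true(all(out2$method %in% c("IVW", "IVW (random)")))
})
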