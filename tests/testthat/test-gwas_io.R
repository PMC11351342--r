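# Summary-statistic I/O and allele harmonization.

test_that("read/write round-trips a table, including alternative headers", {
  df <- make_ss_df(100, seed = 7)
  tab <- summary_stat_table(df, "traitA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path, trait_id = "traitA")
  expect_identical(back$snp, tab$snp)
  expect_identical(back$effect_allele, tab$effect_allele)
  for (col in c("eaf", "beta", "se", "pval", "n", "pos")) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-10)
  }

  # header-only file for an empty table
  empty <- summary_stat_table(df[0, ], "empty")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(empty, p2)
  expect_length(readLines(p2), 1L)
  expect_length(readLines(path), 101L)

  # same content under foreign headers + column_map reads identically
  foreign <- df
  names(foreign)[names(foreign) == "snp"] <- "rsid"
  names(foreign)[names(foreign) == "beta"] <- "Effect"
  names(foreign)[names(foreign) == "se"] <- "StdErr"
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(foreign, p3, sep = ",", row.names = FALSE, quote = FALSE)
  mapped <- read_summary_stats(p3, column_map = c(snp = "rsid", beta = "Effect",
                                                  se = "StdErr"),
                               trait_id = "traitA")
  expect_equal(as.data.frame(mapped), as.data.frame(tab), tolerance = 1e-10)
})

test_that("hard invariant violations are dropped and counted; errors are fatal", {
  df <- make_ss_df(3, seed = 1)
  df$se[2] <- 0
  expect_message(tab <- summary_stat_table(df, "t"), "dropped 1 invalid")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "n_dropped"), 1L)

  expect_error(read_summary_stats(tempfile()), "cannot read")
  df_missing <- make_ss_df(3)[, -7]  # drop beta
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df_missing, p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_summary_stats(p), "beta")
})

test_that("pval/z inconsistency warns but keeps the record", {
  df <- make_ss_df(2, seed = 2, beta = c(0.5, 0.01), se = c(0.01, 0.01))
  df$pval <- c(0.9, 0.5)  # first is wildly inconsistent with z = 50
  expect_warning(tab <- summary_stat_table(df, "t"), "inconsistent")
  expect_equal(nrow(tab), 2L)
})

make_pair <- function(exp_alleles, out_alleles, beta_out = -0.2,
                      eaf_exp = 0.3, eaf_out = 0.3) {
  base <- make_ss_df(1, seed = 3, beta = 0.1, se = 0.01)
  ex <- base
  ex$effect_allele <- exp_alleles[1]; ex$other_allele <- exp_alleles[2]
  ex$eaf <- eaf_exp
  ou <- base
  ou$effect_allele <- out_alleles[1]; ou$other_allele <- out_alleles[2]
  ou$beta <- beta_out; ou$eaf <- eaf_out
  ou$pval <- 2 * stats::pnorm(-abs(ou$beta / ou$se))
  list(exposure = summary_stat_table(ex, "e"),
       outcome = summary_stat_table(ou, "o", "binary"))
}

test_that("allele swap, strand complement and irreconcilable pairs behave as specified", {
  # exposure A/G beta 0.10; outcome G/A beta -0.20 -> flipped, beta_out +0.20
  p <- make_pair(c("A", "G"), c("G", "A"))
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_true(h$flipped)
  expect_equal(h$beta_out, 0.2)

  # outcome C/T vs exposure G/A, concordant eaf -> strand complement, sign kept
  p <- make_pair(c("G", "A"), c("C", "T"))
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_false(h$flipped)
  expect_equal(h$beta_out, -0.2)

  # A/G vs A/C cannot be reconciled -> dropped with empty result
  p <- make_pair(c("A", "G"), c("A", "C"))
  expect_message(h <- harmonize_pair(p$exposure, p$outcome), "irreconcilable")
  expect_equal(nrow(h), 0L)

  # no shared SNPs is fatal
  e2 <- p$exposure; e2$snp <- "rs9999"
  expect_error(harmonize_pair(e2, p$outcome), "no shared SNPs")
})

test_that("palindromic SNPs follow the policy and the eaf ambiguity window", {
  # eaf 0.50 under infer_by_eaf, window 0.08 -> dropped
  p <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = 0.5, eaf_out = 0.5)
  expect_message(
    h <- harmonize_pair(p$exposure, p$outcome, "infer_by_eaf", eaf_window = 0.08),
    "palindromic")
  expect_equal(nrow(h), 0L)

  # clear frequencies on opposite sides of 0.5 -> orientation flip
  p <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = 0.2, eaf_out = 0.8)
  h <- harmonize_pair(p$exposure, p$outcome, "infer_by_eaf")
  expect_true(h$flipped)
  expect_equal(h$beta_out, 0.2)

  # concordant clear frequencies -> kept unflipped
  p <- make_pair(c("C", "G"), c("C", "G"), eaf_exp = 0.2, eaf_out = 0.25)
  h <- harmonize_pair(p$exposure, p$outcome, "infer_by_eaf")
  expect_false(h$flipped)

  # drop policy never emits palindromic records; missing eaf always drops
  p <- make_pair(c("A", "T"), c("A", "T"), eaf_exp = 0.2, eaf_out = 0.2)
  h <- quiet(harmonize_pair(p$exposure, p$outcome, "drop"))
  expect_equal(nrow(h), 0L)
  p$outcome$eaf <- NA_real_
  h <- quiet(harmonize_pair(p$exposure, p$outcome, "infer_by_eaf"))
  expect_equal(nrow(h), 0L)
})

test_that("harmonization is involution-safe and invariant to outcome re-coding", {
  df_e <- make_ss_df(40, seed = 10)
  df_o <- make_ss_df(40, seed = 11)
  df_o[c("snp", "chrom", "pos", "effect_allele", "other_allele")] <-
    df_e[c("snp", "chrom", "pos", "effect_allele", "other_allele")]
  # re-code a third of the outcome rows with swapped alleles
  idx <- seq(1, 40, by = 3)
  df_o[idx, c("effect_allele", "other_allele")] <-
    df_o[idx, c("other_allele", "effect_allele")]
  df_o$beta[idx] <- -df_o$beta[idx]
  df_o$eaf[idx] <- 1 - df_o$eaf[idx]
  ex <- summary_stat_table(df_e, "e")
  ou <- summary_stat_table(df_o, "o")

  h1 <- harmonize_pair(ex, ou)
  expect_true(all(h1$flipped[match(df_e$snp[idx], h1$snp)]))

  # rebuild the outcome table from the harmonized records: re-harmonizing
  # must change nothing
  df_o2 <- df_o
  df_o2$beta <- h1$beta_out[match(df_o2$snp, h1$snp)]
  df_o2[c("effect_allele", "other_allele")] <- df_e[c("effect_allele", "other_allele")]
  df_o2$eaf <- df_e$eaf
  h2 <- harmonize_pair(ex, summary_stat_table(df_o2, "o"))
  expect_false(any(h2$flipped))
  expect_equal(h2$beta_out, h1$beta_out)

  # negating every outcome beta and swapping its alleles is a no-op
  df_o3 <- df_o
  df_o3[c("effect_allele", "other_allele")] <- df_o[c("other_allele", "effect_allele")]
  df_o3$beta <- -df_o$beta
  df_o3$eaf <- 1 - df_o$eaf
  h3 <- harmonize_pair(ex, summary_stat_table(df_o3, "o"))
  expect_equal(h3$beta_out, h1$beta_out)
  expect_equal(h3$snp, h1$snp)
})
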