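# Orchestration: single MR runs with full instrument selection and
# sensitivity, bidirectional runs, and the two-step mediation scan.

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline with the conventional
#' defaults: genome-wide instrument significance `p_threshold = 5e-8`,
#' clumping at `r2 < 0.001` within a 10,000 kb window, weak-instrument cutoff
#' `f_min = 10`, screening level `alpha = 0.05`, palindromic variants dropped,
#' and IVW reported under the multiplicative random-effects model when the
#' Cochran Q p-value falls below `alpha` (`effects_model = "auto_by_q"`).
#'
#' @param p_threshold Instrument significance threshold.
#' @param clump_r2,clump_kb LD clumping parameters.
#' @param f_min Minimum per-instrument F statistic.
#' @param alpha Significance level used throughout the cascade.
#' @param palindromic_policy,eaf_window Passed to [harmonize_pair()].
#' @param effects_model `"auto_by_q"`, `"fixed"` or `"random"`.
#' @param n_boot Bootstrap resamples for median/mode SEs.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                       f_min = 10, alpha = 0.05,
                       palindromic_policy = "drop", eaf_window = 0.08,
                       effects_model = "auto_by_q", n_boot = 1000, seed = 1) {
  stopifnot(p_threshold > 0, clump_r2 > 0, clump_kb > 0, f_min >= 0,
            alpha > 0, alpha < 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min, alpha = alpha,
                 palindromic_policy = palindromic_policy,
                 eaf_window = eaf_window, effects_model = effects_model,
                 n_boot = n_boot, seed = seed),
            class = "run_config")
}

count_stage <- function(counts, stage, n_in, n_kept) {
  rbind(counts, data.frame(stage = stage, n_in = n_in, n_kept = n_kept,
                           n_dropped = n_in - n_kept, stringsAsFactors = FALSE))
}

#' Run one complete two-sample MR analysis
#'
#' The full per-pair pipeline: genome-wide instrument selection, optional LD
#' clumping and confounder exclusion, outcome-association exclusion,
#' F-statistic filtering, harmonization, the complete estimator suite and the
#' sensitivity report. Per-stage instrument counts are tracked so that
#' `n_in = n_kept + n_dropped` holds at every filter. If no instruments
#' survive, a fragment with `status = "not estimable"` is returned rather
#' than an error.
#'
#' @param exposure,outcome `summary_stats` tables (distinct traits).
#' @param config A [run_config()].
#' @param ld Optional LD r-squared matrix for clumping.
#' @param confounder_lookup Optional data frame `snp, trait`.
#' @param confounder_traits Traits to exclude through the lookup.
#' @return List of class `"mr_run"`: `exposure_id`, `outcome_id`, `status`,
#'   `estimates`, `sensitivity`, `harmonized`, `instruments`, `counts`,
#'   `config`.
#' @export
run_mr <- function(exposure, outcome, config = run_config(), ld = NULL,
                   confounder_lookup = NULL, confounder_traits = character(0)) {
  if (identical(trait_id(exposure), trait_id(outcome)) ||
      isTRUE(all.equal(as.data.frame(exposure), as.data.frame(outcome),
                       check.attributes = FALSE))) {
    stop("run_mr: exposure and outcome are the same trait (self-MR guard)")
  }
  counts <- data.frame(stage = character(0), n_in = integer(0),
                       n_kept = integer(0), n_dropped = integer(0))

  iv <- select_genomewide(exposure, config$p_threshold)
  counts <- count_stage(counts, "genomewide", nrow(exposure), nrow(iv))

  n_in <- nrow(iv)
  iv <- ld_clump(iv, ld = ld, r2_threshold = config$clump_r2,
                 window_kb = config$clump_kb)
  counts <- count_stage(counts, "ld_clump", n_in, nrow(iv))

  n_in <- nrow(iv)
  iv <- exclude_outcome_associated(iv, outcome, config$p_threshold)
  counts <- count_stage(counts, "outcome_exclusion", n_in, nrow(iv))

  n_in <- nrow(iv)
  iv <- exclude_listed_confounders(iv, confounder_lookup, confounder_traits)
  counts <- count_stage(counts, "confounder_exclusion", n_in, nrow(iv))

  if (nrow(iv) > 0) {
    iv <- compute_f_statistics(iv)
    n_in <- nrow(iv)
    iv <- filter_weak_instruments(iv, config$f_min)
    counts <- count_stage(counts, "f_filter", n_in, nrow(iv))
  }

  base <- list(exposure_id = trait_id(exposure), outcome_id = trait_id(outcome),
               counts = counts, config = config, instruments = iv)
  if (nrow(iv) == 0L) {
    return(structure(c(base, list(status = "not estimable", estimates = NULL,
                                  sensitivity = NULL, harmonized = NULL)),
                     class = "mr_run"))
  }

  iv_table <- summary_stat_table(iv[CANONICAL_COLS],
                                 trait_id = trait_id(exposure),
                                 trait_type = trait_type(exposure),
                                 validate = FALSE)
  h <- harmonize_pair(iv_table, outcome,
                      palindromic_policy = config$palindromic_policy,
                      eaf_window = config$eaf_window)
  counts <- count_stage(counts, "harmonization", nrow(iv), nrow(h))
  base$counts <- counts
  if (nrow(h) == 0L) {
    return(structure(c(base, list(status = "not estimable", estimates = NULL,
                                  sensitivity = NULL, harmonized = h)),
                     class = "mr_run"))
  }

  binary_out <- identical(trait_type(outcome), "binary")
  estimates <- mr_all_methods(h, effects_model = config$effects_model,
                              q_alpha = config$alpha, or_scale = binary_out,
                              n_boot = config$n_boot, seed = config$seed)
  sens <- sensitivity_report(h, estimates, binary_outcome = binary_out,
                             alpha = config$alpha)
  structure(c(base, list(status = "ok", estimates = estimates,
                         sensitivity = sens, harmonized = h)),
            class = "mr_run")
}

# Reported causal-effect row: Wald ratio when a single instrument survived,
# otherwise the IVW row (whichever effects model was reported).
primary_estimate <- function(run) {
  est <- run$estimates
  if (is.null(est)) return(NULL)
  row <- est[est$method %in% c("IVW", "IVW (random)", "Wald ratio"), , drop = FALSE]
  row[1, , drop = FALSE]
}

#' Bidirectional MR between an exposure and an outcome
#'
#' Runs the full pipeline exposure-to-outcome and, with roles swapped, the
#' reverse direction under the same thresholds (the reverse run instruments
#' on the outcome GWAS's significant variants).
#'
#' @inheritParams run_mr
#' @return List of class `"bidirectional_mr"` with `forward` and `reverse`
#'   `mr_run` fragments.
#' @export
run_bidirectional <- function(exposure, outcome, config = run_config(),
                              ld = NULL, confounder_lookup = NULL,
                              confounder_traits = character(0)) {
  forward <- run_mr(exposure, outcome, config, ld, confounder_lookup,
                    confounder_traits)
  reverse <- run_mr(outcome, exposure, config, ld, confounder_lookup,
                    confounder_traits)
  structure(list(forward = forward, reverse = reverse),
            class = "bidirectional_mr")
}

#' Two-step mediation scan across candidate mediator GWAS
#'
#' Orchestrates the full study design: the total exposure-to-outcome effect;
#' per mediator, a step-1 run (exposure to mediator, screened on the dual
#' IVW + 2SLS significance rule and the Egger-intercept pleiotropy rule) and
#' a step-2 run (mediator to outcome with the mediator's own instruments,
#' screened on effect significance, heterogeneity and the Steiger
#' direction); and the Sobel product-of-coefficients test for every mediator,
#' assembled into the final mediation table. Per-mediator failures are
#' isolated: a mediator whose runs error is marked failed and the scan
#' continues.
#'
#' @param exposure `summary_stats` table for the exposure.
#' @param mediators Named list of `summary_stats` tables.
#' @param outcome `summary_stats` table for the outcome.
#' @param config A [run_config()].
#' @param tsls Optional data frame `mediator_id, tsls_pval` holding
#'   two-stage least squares results from individual-level data; when absent
#'   the step-1 screen is applied with `require_tsls = FALSE`.
#' @param mediator_meta Optional data frame `mediator_id, region, phenotype`
#'   used to label the final table.
#' @param ld,confounder_lookup,confounder_traits Passed to [run_mr()].
#' @return List of class `"study_report"`: `total` (forward `mr_run`),
#'   `step1`, `step2` (per-mediator summaries), `verdicts`,
#'   `mediation` (final table with attribute `region_summary`), `runs`
#'   (per-mediator `mr_run` pairs), `failed`, `config`.
#' @export
run_two_step <- function(exposure, mediators, outcome, config = run_config(),
                         tsls = NULL, mediator_meta = NULL, ld = NULL,
                         confounder_lookup = NULL,
                         confounder_traits = character(0)) {
  stopifnot(length(mediators) >= 1, !is.null(names(mediators)))
  total_run <- run_mr(exposure, outcome, config, ld, confounder_lookup,
                      confounder_traits)
  total_row <- primary_estimate(total_run)
  total_effect <- if (is.null(total_row)) NA_real_ else total_row$beta

  step1 <- step2 <- med_rows <- list()
  runs <- list()
  failed <- character(0)

  for (id in names(mediators)) {
    res <- tryCatch({
      med <- mediators[[id]]
      r1 <- run_mr(exposure, med, config, ld, confounder_lookup,
                   confounder_traits)
      r2 <- run_mr(med, outcome, config, ld, confounder_lookup,
                   confounder_traits)
      if (!identical(r1$status, "ok") || !identical(r2$status, "ok")) {
        stop("mediator not estimable")
      }
      e1 <- primary_estimate(r1)
      e2 <- primary_estimate(r2)
      tsls_p <- if (!is.null(tsls) && id %in% tsls$mediator_id) {
        tsls$tsls_pval[match(id, tsls$mediator_id)]
      } else {
        NA_real_
      }
      s1 <- data.frame(mediator_id = id, ivw_pval = e1$pval, tsls_pval = tsls_p,
                       pleiotropy_pval = r1$sensitivity$egger_intercept$pval %||% NA_real_,
                       nsnp = e1$nsnp, b1 = e1$beta, s1 = e1$se,
                       stringsAsFactors = FALSE)
      s2 <- data.frame(mediator_id = id, effect_pval = e2$pval,
                       het_pval = if (is.null(r2$sensitivity$q)) NA_real_ else r2$sensitivity$q$q_pval,
                       steiger = r2$sensitivity$steiger$direction,
                       steiger_pval = r2$sensitivity$steiger$steiger_pval,
                       nsnp = e2$nsnp, b2 = e2$beta, s2 = e2$se,
                       stringsAsFactors = FALSE)
      med_row <- cbind(mediator_id = id,
                       sobel_mediation(e1$beta, e1$se, e2$beta, e2$se,
                                       total_effect = total_effect))
      list(s1 = s1, s2 = s2, med = med_row, runs = list(step1 = r1, step2 = r2))
    }, error = function(e) {
      log_msg("run_two_step: mediator '%s' failed: %s", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failed <- c(failed, id)
      step1[[id]] <- data.frame(mediator_id = id, ivw_pval = NA_real_,
                                tsls_pval = NA_real_, pleiotropy_pval = NA_real_,
                                nsnp = NA_integer_, b1 = NA_real_, s1 = NA_real_,
                                stringsAsFactors = FALSE)
      step2[[id]] <- data.frame(mediator_id = id, effect_pval = NA_real_,
                                het_pval = NA_real_, steiger = NA_character_,
                                steiger_pval = NA_real_, nsnp = NA_integer_,
                                b2 = NA_real_, s2 = NA_real_,
                                stringsAsFactors = FALSE)
    } else {
      step1[[id]] <- res$s1
      step2[[id]] <- res$s2
      med_rows[[id]] <- res$med
      runs[[id]] <- res$runs
    }
  }

  step1 <- do.call(rbind, step1)
  step2 <- do.call(rbind, step2)
  rownames(step1) <- rownames(step2) <- NULL
  v1 <- screen_step1(step1, alpha = config$alpha, require_tsls = !is.null(tsls))
  v2 <- screen_step2(step2, alpha = config$alpha)
  verdicts <- merge(v1, v2, by = "mediator_id")

  mediation_results <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame(mediator_id = character(0))
  if (!is.null(mediator_meta) && nrow(mediation_results)) {
    mediation_results <- merge(mediation_results, mediator_meta,
                               by = "mediator_id", all.x = TRUE)
  }
  mediation <- assemble_mediation_table(verdicts, mediation_results,
                                        alpha = config$alpha)

  provenance <- list(
    package_version = as.character(utils::packageVersion("mrmediate")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    n_mediators = length(mediators),
    n_failed = length(failed),
    total_counts = total_run$counts
  )

  structure(list(total = total_run, step1 = step1, step2 = step2,
                 verdicts = verdicts, mediation = mediation, runs = runs,
                 failed = failed, config = config, provenance = provenance),
            class = "study_report")
}

#' Write a study report as a directory of tab-delimited tables
#'
#' Serializes the tables of a [run_two_step()] report (total-effect
#' estimates, per-mediator step-1/step-2 summaries, screening verdicts, the
#' mediation table and its per-region summary, per-stage instrument counts)
#' plus a `provenance.txt` echoing the configuration, seed and versions.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
    }
  }
  wr(report$total$estimates, "total_estimates.tsv")
  wr(report$total$counts, "total_counts.tsv")
  wr(report$step1, "step1.tsv")
  wr(report$step2, "step2.tsv")
  wr(report$verdicts, "verdicts.tsv")
  wr(as.data.frame(report$mediation), "mediation.tsv")
  wr(attr(report$mediation, "region_summary"), "region_summary.tsv")
  pv <- report$provenance
  lines <- c(
    paste0("mrmediate ", pv$package_version),
    pv$r_version,
    paste0("seed: ", pv$seed),
    paste0("mediators: ", pv$n_mediators, " (failed: ", pv$n_failed, ")"),
    "config:",
    paste0("  ", names(pv$config), " = ",
           vapply(pv$config, function(x) paste(format(x), collapse = ","),
                  character(1)))
  )
  writeLines(lines, file.path(dir, "provenance.txt"))
  invisible(dir)
}
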