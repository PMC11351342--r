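# Deterministic 10-mediator screening fixture, constructed at the
# summary-statistic level with designed verdicts. Synthetic by construction:
# every number below is designed, none comes from real GWAS data.

#' Build the 10-mediator screening fixture
#'
#' Generates a complete synthetic input set for [run_two_step()] with known
#' screening truth: one exposure GWAS (30 genome-wide-significant
#' instruments), ten mediator GWAS (each carrying the exposure instruments
#' plus 20 strong instruments of its own) and one binary-outcome GWAS
#' covering every SNP. The ten mediators are designed so that, under the
#' standard cascade (dual step-1 significance, pleiotropy exclusion, step-2
#' effect + heterogeneity + directionality screens, Sobel p < 0.05):
#' \itemize{
#'   \item 3 mediators are true (pass everything; `b1 = 0.4`, `b2 = 0.3`),
#'   \item 2 carry directional pleiotropy in step 1 (fail the Egger
#'     intercept screen),
#'   \item 2 are heterogeneous in step 2 (fail Cochran's Q),
#'   \item 3 are null (fail the step-1 effect criterion).
#' }
#' Deviations from the designed effects are small, alternating-sign
#' perturbations (fractions of the standard errors) so each verdict is
#' deterministic rather than borderline. Per-mediator two-stage least squares
#' p-values are supplied alongside, as a two-step run would obtain them from
#' individual-level data.
#'
#' @param seed Seed controlling allele assignment and frequencies.
#' @return List with `exposure`, `mediators` (named list of tables),
#'   `outcome`, `tsls` (data frame `mediator_id, tsls_pval, multiple_r2`),
#'   `meta` (mediator regions/phenotypes) and `truth` (designed survivor ids
#'   and class labels).
#' @export
build_mediation_fixture <- function(seed = 1) {
  with_seed(seed, {
    n_exp_snp <- 30L
    n_med_snp <- 20L
    n_exp <- 400000
    n_med <- 30000
    n_out <- 70000

    classes <- c(true = 3L, pleiotropic = 2L, heterogeneous = 2L, null = 3L)
    meta <- data.frame(
      mediator_id = c("FA_internal_capsule_L", "MD_posterior_corona_radiata_R",
                      "L1_superior_longitudinal_fasciculus_L",
                      "FA_forceps_minor_L", "ICVF_posterior_thalamic_radiation_L",
                      "L2_internal_capsule_L", "MD_anterior_corona_radiata_R",
                      "FA_cingulum_cingulate_gyrus_L", "L3_internal_capsule_L",
                      "ICVF_inferior_longitudinal_fasciculus_L"),
      region = c("internal capsule (L)", "posterior corona radiata (R)",
                 "superior longitudinal fasciculus (L)", "forceps minor (L)",
                 "posterior thalamic radiation (L)", "internal capsule (L)",
                 "anterior corona radiata (R)", "cingulum cingulate gyrus (L)",
                 "internal capsule (L)", "inferior longitudinal fasciculus (L)"),
      phenotype = c("FA", "MD", "L1", "FA", "ICVF", "L2", "MD", "FA", "L3", "ICVF"),
      class = rep(names(classes), classes),
      stringsAsFactors = FALSE
    )

    m_total <- n_exp_snp + n_med_snp * nrow(meta)
    info <- make_snp_info(m_total)
    eaf <- round(stats::runif(m_total, 0.15, 0.85), 3)
    exp_idx <- seq_len(n_exp_snp)
    med_idx <- lapply(seq_len(nrow(meta)), function(k) {
      n_exp_snp + (k - 1L) * n_med_snp + seq_len(n_med_snp)
    })

    alt <- function(k, scale) scale * rep_len(c(1, -1), k)

    # Exposure GWAS: instruments with z between 8 and 15.
    se_exp <- 0.003
    z_exp <- seq(8, 15, length.out = n_exp_snp)
    beta_exp <- z_exp * se_exp
    exposure <- summary_stat_table(
      data.frame(info[exp_idx, ], eaf = eaf[exp_idx],
                 beta = beta_exp, se = se_exp,
                 pval = pval_norm(z_exp), n = n_exp),
      trait_id = "exposure_TL_synthetic", trait_type = "continuous")

    theta1 <- 0.4
    theta2 <- 0.3
    se_med <- 0.01
    se_med_own <- 0.008
    se_out <- 0.015
    z_own <- seq(9, 12, length.out = n_med_snp)
    beta_own <- z_own * se_med_own

    mediators <- list()
    out_beta <- numeric(m_total)
    # Exposure SNPs in the outcome: a modest protective total effect.
    out_beta[exp_idx] <- -0.2 * beta_exp + alt(n_exp_snp, 0.3 * se_out)

    for (k in seq_len(nrow(meta))) {
      cls <- meta$class[k]
      # Step 1: mediator values at the exposure instruments.
      b_at_exp <- switch(cls,
        true = ,
        heterogeneous = theta1 * beta_exp + alt(n_exp_snp, 0.3 * se_med),
        pleiotropic = theta1 * beta_exp + 0.03 + alt(n_exp_snp, 0.3 * se_med),
        null = alt(n_exp_snp, 0.3 * se_med))
      idx <- med_idx[[k]]
      rows <- rbind(
        data.frame(info[exp_idx, ], eaf = eaf[exp_idx],
                   beta = b_at_exp, se = se_med,
                   pval = pval_norm(b_at_exp / se_med), n = n_med),
        data.frame(info[idx, ], eaf = eaf[idx],
                   beta = beta_own, se = se_med_own,
                   pval = pval_norm(z_own), n = n_med)
      )
      mediators[[meta$mediator_id[k]]] <- summary_stat_table(
        rows, trait_id = meta$mediator_id[k], trait_type = "continuous")

      # Step 2: outcome values at the mediator's own instruments.
      out_beta[idx] <- switch(cls,
        true = ,
        pleiotropic = theta2 * beta_own + alt(n_med_snp, 0.3 * se_out),
        heterogeneous = theta2 * beta_own + alt(n_med_snp, 3 * se_out),
        null = alt(n_med_snp, 0.3 * se_out))
    }

    outcome <- summary_stat_table(
      data.frame(info, eaf = eaf, beta = out_beta, se = se_out,
                 pval = pval_norm(out_beta / se_out), n = n_out),
      trait_id = "outcome_AN_synthetic", trait_type = "binary")

    tsls <- data.frame(
      mediator_id = meta$mediator_id,
      tsls_pval = ifelse(meta$class == "null", 0.5, 1e-4),
      multiple_r2 = ifelse(meta$class == "null", 0.001, 0.12),
      stringsAsFactors = FALSE
    )

    list(exposure = exposure, mediators = mediators, outcome = outcome,
         tsls = tsls, meta = meta[c("mediator_id", "region", "phenotype")],
         truth = list(survivors = meta$mediator_id[meta$class == "true"],
                      classes = stats::setNames(meta$class, meta$mediator_id)))
  })
}
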