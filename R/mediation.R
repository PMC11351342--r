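# Product-of-coefficients mediation with the Sobel test, and the two-stage
# screening cascade that selects which mediators the statistic is applied to.

#' Sobel test for a product-of-coefficients indirect effect
#'
#' Given `b1` (the MR effect of the exposure on the mediator) and `b2` (the
#' MR effect of the mediator on the outcome) with standard errors `s1`, `s2`,
#' the indirect (mediated) effect is `b1 * b2`, its Sobel standard error
#' \deqn{S = \sqrt{b_1^2 s_2^2 + b_2^2 s_1^2},}
#' the test statistic `Z = b1 b2 / S` (two-sided normal p-value), and the 95%
#' confidence interval `b1 b2 +/- 1.96 S`. When the total effect of the
#' exposure on the outcome is supplied, the direct effect
#' (`total - indirect`) and the proportion mediated (`indirect / total`) are
#' reported as well; the proportion is deliberately unconstrained and may be
#' negative or exceed 1 when effect signs oppose. `se_form = "linear"`
#' replaces S with the first-order sum `b1 s2 + b2 s1`, a compatibility form
#' that is not a valid standard error (it is not scale-equivariant) and is
#' never the default.
#'
#' @param b1,s1 Exposure-to-mediator effect and SE (`s1 > 0`).
#' @param b2,s2 Mediator-to-outcome effect and SE (`s2 > 0`).
#' @param total_effect Optional exposure-to-outcome total effect.
#' @param se_form `"sobel"` (default) or `"linear"`.
#' @return One-row data frame `b1, s1, b2, s2, indirect, sobel_se, z_stat,
#'   pval, ci_low, ci_high, total_effect, direct_effect, proportion_mediated`.
#' @export
sobel_mediation <- function(b1, s1, b2, s2, total_effect = NULL,
                            se_form = c("sobel", "linear")) {
  se_form <- match.arg(se_form)
  if (s1 <= 0 || s2 <= 0) stop("sobel_mediation: standard errors must be positive")
  indirect <- b1 * b2
  S <- if (se_form == "sobel") {
    sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  } else {
    b1 * s2 + b2 * s1
  }
  if (S <= 0) {
    # Only reachable when b1 = b2 = 0 (Sobel form): define a null result.
    z <- 0
    p <- 1
    S <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    z <- indirect / S
    p <- pval_norm(z)
    ci <- indirect + c(-1, 1) * stats::qnorm(0.975) * S
  }
  data.frame(
    b1 = b1, s1 = s1, b2 = b2, s2 = s2,
    indirect = indirect, sobel_se = S, z_stat = z, pval = p,
    ci_low = ci[1], ci_high = ci[2],
    total_effect = total_effect %||% NA_real_,
    direct_effect = if (is.null(total_effect)) NA_real_ else total_effect - indirect,
    proportion_mediated = if (is.null(total_effect)) NA_real_ else indirect / total_effect
  )
}

#' Step-1 screening: exposure-to-mediator runs
#'
#' A mediator passes step 1 when its IVW p-value and its two-stage least
#' squares p-value are both below `alpha` (the dual significance criterion)
#' and its Egger-intercept pleiotropy p-value is at least `alpha` (pleiotropic
#' mediators are excluded before the next step). The reason string records
#' the first failing rule; a mediator with any required p-value missing fails
#' with reason `"incomplete"`. When no individual-level data exist for 2SLS,
#' set `require_tsls = FALSE` to screen on IVW and pleiotropy alone.
#'
#' @param step1 Data frame with columns `mediator_id`, `ivw_pval`,
#'   `tsls_pval`, `pleiotropy_pval`.
#' @param alpha Significance level (default 0.05).
#' @param require_tsls Enforce the 2SLS half of the dual criterion.
#' @return Data frame `mediator_id, step1_pass, step1_reason`.
#' @export
screen_step1 <- function(step1, alpha = 0.05, require_tsls = TRUE) {
  need <- c("ivw_pval", "pleiotropy_pval")
  if (require_tsls) need <- c("ivw_pval", "tsls_pval", "pleiotropy_pval")
  rows <- lapply(seq_len(nrow(step1)), function(i) {
    r <- step1[i, ]
    vals <- unlist(r[intersect(need, names(r))])
    if (length(vals) < length(need) || any(is.na(vals))) {
      return(data.frame(mediator_id = r$mediator_id, step1_pass = FALSE,
                        step1_reason = "incomplete", stringsAsFactors = FALSE))
    }
    reason <- ""
    pass <- TRUE
    if (r$ivw_pval >= alpha) {
      pass <- FALSE; reason <- "ivw"
    } else if (require_tsls && r$tsls_pval >= alpha) {
      pass <- FALSE; reason <- "tsls"
    } else if (r$pleiotropy_pval < alpha) {
      pass <- FALSE; reason <- "pleiotropy"
    }
    data.frame(mediator_id = r$mediator_id, step1_pass = pass,
               step1_reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Step-2 screening: mediator-to-outcome runs
#'
#' A mediator passes step 2 when its causal-effect p-value (Wald ratio for a
#' single instrument, IVW otherwise) is below `alpha`, its heterogeneity
#' p-value is at least `alpha`, and the Steiger direction verdict is
#' `"true"`. Reasons: `"effect"`, `"heterogeneity"`, `"direction"`,
#' `"incomplete"`.
#'
#' @param step2 Data frame with columns `mediator_id`, `effect_pval`,
#'   `het_pval`, `steiger` (verdict string).
#' @param alpha Significance level.
#' @return Data frame `mediator_id, step2_pass, step2_reason`.
#' @export
screen_step2 <- function(step2, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(step2)), function(i) {
    r <- step2[i, ]
    if (is.na(r$effect_pval) || is.na(r$het_pval) || is.na(r$steiger)) {
      return(data.frame(mediator_id = r$mediator_id, step2_pass = FALSE,
                        step2_reason = "incomplete", stringsAsFactors = FALSE))
    }
    reason <- ""
    pass <- TRUE
    if (r$effect_pval >= alpha) {
      pass <- FALSE; reason <- "effect"
    } else if (r$het_pval < alpha) {
      pass <- FALSE; reason <- "heterogeneity"
    } else if (r$steiger != "true") {
      pass <- FALSE; reason <- "direction"
    }
    data.frame(mediator_id = r$mediator_id, step2_pass = pass,
               step2_reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the final mediation table
#'
#' Joins the screening verdicts with the per-mediator Sobel results. A
#' mediator's `final_pass` is true when it passed both screening steps and
#' its mediation p-value is below `alpha`. The table is sorted by region then
#' phenotype (when those columns are present in `mediation_results`), and a
#' per-region summary of mean indirect effects over the passing mediators is
#' attached as attribute `region_summary`.
#'
#' @param verdicts Data frame with `mediator_id`, `step1_pass`,
#'   `step1_reason`, `step2_pass`, `step2_reason`.
#' @param mediation_results Data frame of [sobel_mediation()] rows plus a
#'   `mediator_id` column (optionally `region`, `phenotype`).
#' @param alpha Significance level for the mediated effect.
#' @return Data frame with screening columns, mediation columns,
#'   `final_pass` and `reason`.
#' @export
assemble_mediation_table <- function(verdicts, mediation_results, alpha = 0.05) {
  tab <- merge(verdicts, mediation_results, by = "mediator_id", all.x = TRUE)
  tab$final_pass <- tab$step1_pass & tab$step2_pass &
    !is.na(tab$pval) & tab$pval < alpha
  tab$reason <- ifelse(!tab$step1_pass, paste0("step1:", tab$step1_reason),
                ifelse(!tab$step2_pass, paste0("step2:", tab$step2_reason),
                ifelse(!tab$final_pass, "mediation", "")))
  if (!"region" %in% names(tab)) tab$region <- NA_character_
  if (!"phenotype" %in% names(tab)) tab$phenotype <- NA_character_
  tab <- tab[order(tab$region, tab$phenotype, tab$mediator_id), ]
  rownames(tab) <- NULL
  passing <- tab[tab$final_pass & !is.na(tab$region), , drop = FALSE]
  region_summary <- if (nrow(passing)) {
    agg <- aggregate(cbind(indirect, pval) ~ region, data = passing, FUN = mean)
    names(agg) <- c("region", "mean_indirect", "mean_pval")
    agg$n_phenotypes <- as.integer(table(passing$region)[agg$region])
    agg
  } else {
    data.frame(region = character(0), mean_indirect = numeric(0),
               mean_pval = numeric(0), n_phenotypes = integer(0))
  }
  structure(tab, region_summary = region_summary)
}
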