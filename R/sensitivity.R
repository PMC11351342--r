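# Heterogeneity, pleiotropy, directionality and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' \deqn{Q = \sum_j (\beta_{Yj} - \hat\beta\,\beta_{Xj})^2 / \sigma_{Yj}^2}
#' referred to a chi-square distribution with `nsnp - 1` degrees of freedom.
#' Per the standard definition, Q is always computed around the fixed-effect
#' IVW estimate (supplied via `beta_ivw` or recomputed).
#'
#' @param h Harmonized data frame with at least 2 rows.
#' @param beta_ivw Optional fixed-effect IVW estimate to use as the centre.
#' @return List `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h, beta_ivw = NULL) {
  check_hset(h, 2, "cochran_q")
  if (is.null(beta_ivw)) beta_ivw <- mr_ivw(h, "fixed")$beta
  w <- 1 / h$se_out^2
  q <- sum(w * (h$beta_out - beta_ivw * h$beta_exp)^2)
  df <- nrow(h) - 1L
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept term from the MR-Egger weighted fit and tests it
#' against zero with a two-sided t-test on `nsnp - 2` degrees of freedom. A
#' non-zero intercept indicates that the average pleiotropic effect of the
#' instruments differs from zero.
#'
#' @param h Harmonized data frame with at least 3 rows.
#' @return List `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate with each instrument excluded in turn and
#' flags instruments whose exclusion changes the significance verdict at
#' `alpha`. With only two instruments each leave-one-out estimate is the
#' remaining SNP's Wald ratio (permitted with a warning).
#'
#' @param h Harmonized data frame with at least 2 rows.
#' @param effects_model IVW effects model used for each refit.
#' @param alpha Significance level for the verdict-change flag.
#' @return Data frame `snp, beta, se, pval, verdict_change`, with the
#'   full-set estimate attached as attribute `full`.
#' @export
leave_one_out <- function(h, effects_model = c("fixed", "random"), alpha = 0.05) {
  effects_model <- match.arg(effects_model)
  check_hset(h, 2, "leave_one_out")
  if (nrow(h) == 2L) {
    warning("leave_one_out with 2 instruments: estimates are single-SNP Wald ratios",
            call. = FALSE)
  }
  full <- mr_ivw(h, effects_model)
  rows <- lapply(seq_len(nrow(h)), function(j) {
    est <- mr_ivw(h[-j, , drop = FALSE], effects_model)
    data.frame(snp = h$snp[j], beta = est$beta, se = est$se, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$verdict_change <- (out$pval < alpha) != (full$pval < alpha)
  rownames(out) <- NULL
  structure(out, full = full)
}

# Per-SNP variance explained from the t statistic: r2 = t^2 / (t^2 + n - 2).
r2_from_t <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against the
#' variance they explain in the outcome. Per-SNP r-squared values are
#' obtained from the t-statistic approximation on each side and summed;
#' the correlations `r = sqrt(r2)` are Fisher z-transformed and compared with
#' \deqn{Z = \frac{\mathrm{atanh}(r_{exp}) - \mathrm{atanh}(r_{out})}
#'   {\sqrt{1/(n_{exp}-3) + 1/(n_{out}-3)}}.}
#' The inferred direction is `"true"` (exposure to outcome) when the
#' instruments explain significantly more variance in the exposure,
#' `"false"` when reversed, and `"uncertain"` when p >= 0.05. For binary
#' traits the r-squared is an observed-scale approximation; this is recorded
#' in the `r2_scale` field so liability-scale values can be substituted.
#'
#' @param h Harmonized data frame.
#' @param binary_outcome Flag recorded in the output metadata.
#' @return List `direction`, `steiger_pval`, `r2_exposure`, `r2_outcome`,
#'   `r2_scale`.
#' @export
steiger_direction <- function(h, binary_outcome = FALSE) {
  check_hset(h, 1, "steiger_direction")
  n_exp <- stats::median(h$n_exp)
  n_out <- stats::median(h$n_out)
  if (n_exp <= 3 || n_out <= 3) {
    stop("steiger_direction: sample size must exceed 3 on both sides")
  }
  r2_exp <- min(sum(r2_from_t(h$beta_exp, h$se_exp, h$n_exp)), 1 - 1e-12)
  r2_out <- min(sum(r2_from_t(h$beta_out, h$se_out, h$n_out)), 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p <- pval_norm(z)
  direction <- if (p >= 0.05) {
    "uncertain"
  } else if (r2_exp > r2_out) {
    "true"
  } else {
    "false"
  }
  list(direction = direction, steiger_pval = p,
       r2_exposure = r2_exp, r2_outcome = r2_out,
       r2_scale = if (binary_outcome) "observed-scale approximation" else "observed")
}

#' Plot-ready funnel and scatter tables
#'
#' Emits the coordinates behind the standard MR diagnostic plots without
#' rendering anything: `funnel` pairs each per-SNP ratio estimate with its
#' precision `1/se`, and `scatter` gives the `(beta_exp, beta_out)` points
#' plus one fitted line per supplied method estimate (slope = the method's
#' causal estimate; intercept 0 except for MR-Egger, whose intercept must be
#' supplied through `egger_intercept`).
#'
#' @param h Harmonized data frame.
#' @param estimates Data frame of `MREstimate` rows (e.g. from
#'   [mr_all_methods()]).
#' @param egger_intercept Intercept for the MR-Egger line, if present.
#' @return List of data frames `funnel`, `scatter_points`, `scatter_lines`.
#' @export
funnel_scatter_data <- function(h, estimates, egger_intercept = 0) {
  check_hset(h, 1, "funnel_scatter_data")
  rs <- ratio_set(h)
  funnel <- data.frame(snp = h$snp, ratio = rs$ratio, precision = 1 / rs$se,
                       stringsAsFactors = FALSE)
  pts <- data.frame(snp = h$snp, beta_exp = h$beta_exp, se_exp = h$se_exp,
                    beta_out = h$beta_out, se_out = h$se_out,
                    stringsAsFactors = FALSE)
  lines <- data.frame(method = estimates$method, slope = estimates$beta,
                      intercept = ifelse(estimates$method == "MR-Egger",
                                         egger_intercept, 0),
                      stringsAsFactors = FALSE)
  list(funnel = funnel, scatter_points = pts, scatter_lines = lines)
}

#' Full sensitivity report for one MR run
#'
#' Bundles every diagnostic attached to an estimator run: Cochran's Q,
#' MR-Egger intercept, Steiger directionality, leave-one-out influence, and
#' the funnel/scatter coordinate tables. Diagnostics requiring more
#' instruments than are available are returned as `NULL` with a log note.
#'
#' @param h Harmonized data frame.
#' @param estimates Optional estimate table for the scatter lines.
#' @param binary_outcome Passed to [steiger_direction()].
#' @param alpha Level used by [leave_one_out()].
#' @return List of class `"sensitivity_report"` with elements `q`,
#'   `egger_intercept`, `steiger`, `loo`, `plots`.
#' @export
sensitivity_report <- function(h, estimates = NULL, binary_outcome = FALSE,
                               alpha = 0.05) {
  n <- nrow(h)
  q <- if (n >= 2) cochran_q(h) else NULL
  egger <- if (n >= 3) {
    fit <- mr_egger(h)
    list(intercept = fit$intercept, se = fit$intercept_se,
         pval = fit$intercept_pval)
  } else {
    log_msg("sensitivity_report: %d instrument(s); Egger intercept skipped", n)
    NULL
  }
  loo <- if (n >= 2) leave_one_out(h, alpha = alpha) else NULL
  steiger <- steiger_direction(h, binary_outcome = binary_outcome)
  plots <- if (!is.null(estimates)) {
    funnel_scatter_data(h, estimates,
                        egger_intercept = if (is.null(egger)) 0 else egger$intercept)
  } else {
    NULL
  }
  structure(list(q = q, egger_intercept = egger, steiger = steiger,
                 loo = loo, plots = plots),
            class = "sensitivity_report")
}
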