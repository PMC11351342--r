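# Summary-statistic MR estimators: Wald ratio, IVW, MR-Egger, weighted
# median, simple/weighted mode.

mr_estimate <- function(method, nsnp, beta, se, pval, ci_mult = stats::qnorm(0.975)) {
  data.frame(method = method, nsnp = nsnp, beta = beta, se = se, pval = pval,
             ci_low = beta - ci_mult * se, ci_high = beta + ci_mult * se,
             stringsAsFactors = FALSE)
}

check_hset <- function(h, min_n, what) {
  if (nrow(h) < min_n) {
    stop(sprintf("%s requires at least %d harmonized record(s), got %d",
                 what, min_n, nrow(h)))
  }
  if (any(h$se_exp <= 0) || any(h$se_out <= 0)) {
    stop(what, ": standard errors must be positive")
  }
  invisible(h)
}

# Per-SNP ratio estimates and first-order SEs; the raw material of the
# median- and mode-based estimators.
ratio_set <- function(h) {
  if (any(h$beta_exp == 0)) stop("ratio estimates undefined: beta_exp = 0")
  b <- h$beta_out / h$beta_exp
  s <- h$se_out / abs(h$beta_exp)
  list(ratio = b, se = s, w = 1 / s^2)
}

#' Wald ratio estimate from a single instrument
#'
#' The single-instrument causal estimate `beta_out / beta_exp`, with the
#' first-order delta-method standard error `se_out / |beta_exp|` (default) or
#' the second-order form
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)`.
#'
#' @param h One-row harmonized data frame.
#' @param second_order Use the second-order delta-method SE.
#' @return One-row `MREstimate` data frame
#'   (`method, nsnp, beta, se, pval, ci_low, ci_high`).
#' @export
mr_wald_ratio <- function(h, second_order = FALSE) {
  check_hset(h, 1, "mr_wald_ratio")
  h <- h[1, , drop = FALSE]
  if (h$beta_exp == 0) stop("mr_wald_ratio: beta_exp is zero")
  beta <- h$beta_out / h$beta_exp
  se <- if (second_order) {
    sqrt(h$se_out^2 / h$beta_exp^2 + h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  } else {
    h$se_out / abs(h$beta_exp)
  }
  mr_estimate("Wald ratio", 1L, beta, se, pval_norm(beta / se))
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`:
#' \deqn{\hat\beta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/\sigma_{Yj}^2}
#'   {\sum_j \beta_{Xj}^2/\sigma_{Yj}^2}.}
#' The fixed-effect SE is `(sum beta_exp^2/se_out^2)^(-1/2)`; the
#' multiplicative random-effects SE scales it by `max(1, sqrt(Q/(nsnp-1)))`
#' where Q is Cochran's heterogeneity statistic. A single record delegates to
#' [mr_wald_ratio()]. P-values use the normal approximation.
#'
#' @param h Harmonized data frame (>= 2 rows; 1 row falls back to the Wald
#'   ratio).
#' @param effects_model `"fixed"` or `"random"`.
#' @return One-row `MREstimate` data frame.
#' @export
mr_ivw <- function(h, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  check_hset(h, 1, "mr_ivw")
  if (nrow(h) == 1L) return(mr_wald_ratio(h))
  if (all(h$beta_exp == 0)) stop("mr_ivw: all exposure betas are zero")
  w <- 1 / h$se_out^2
  denom <- sum(w * h$beta_exp^2)
  beta <- sum(w * h$beta_exp * h$beta_out) / denom
  se <- sqrt(1 / denom)
  if (effects_model == "random") {
    q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
    se <- se * max(1, sqrt(q / (nrow(h) - 1)))
  }
  est <- mr_estimate("IVW", nrow(h), beta, se, pval_norm(beta / se))
  est$method <- if (effects_model == "random") "IVW (random)" else "IVW"
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting records so every
#' exposure beta is non-negative. The slope is the pleiotropy-adjusted causal
#' estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy. Standard errors carry the multiplicative residual scaling
#' `max(1, sqrt(RSS/(nsnp - 2)))`; inference uses the t distribution with
#' `nsnp - 2` degrees of freedom.
#'
#' @param h Harmonized data frame with at least 3 rows.
#' @return List with `slope` (one-row `MREstimate`), `intercept`,
#'   `intercept_se`, `intercept_pval`, `residual_scale`.
#' @export
mr_egger <- function(h) {
  check_hset(h, 3, "mr_egger")
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  W <- sum(w); Sx <- sum(w * bx); Sy <- sum(w * by)
  Sxx <- sum(w * bx^2); Sxy <- sum(w * bx * by)
  denom <- W * Sxx - Sx^2
  if (abs(denom) < .Machine$double.eps * Sxx * W) {
    stop("mr_egger: exposure betas are collinear; slope not identified")
  }
  slope <- (W * Sxy - Sx * Sy) / denom
  intercept <- (Sy - slope * Sx) / W
  resid <- by - intercept - slope * bx
  df <- nrow(h) - 2L
  sigma <- sqrt(sum(w * resid^2) / df)
  scale <- max(1, sigma)
  se_slope <- sqrt(W / denom) * scale
  se_int <- sqrt(Sxx / denom) * scale
  est <- mr_estimate("MR-Egger", nrow(h), slope, se_slope,
                     pval_t(slope / se_slope, df),
                     ci_mult = stats::qt(0.975, df))
  list(slope = est,
       intercept = intercept,
       intercept_se = se_int,
       intercept_pval = pval_t(intercept / se_int, df),
       residual_scale = sigma)
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  ww <- w[ord] / sum(w)
  s <- cumsum(ww) - ww / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median of the per-SNP ratio estimates: ratios are ordered,
#' inverse-variance weights normalised, and the estimate is the linear
#' interpolation of the ordered ratios at standardised cumulative weight 0.5
#' (with `S_j = (sum_{i<=j} w_i - w_j/2) / sum_i w_i`). Consistent when
#' instruments carrying at least half of the total weight are valid. The SE
#' is a seeded parametric bootstrap: exposure and outcome betas are resampled
#' from their normal sampling distributions and the weighted median
#' recomputed.
#'
#' @param h Harmonized data frame with at least 3 rows.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return One-row `MREstimate` data frame.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  check_hset(h, 3, "mr_weighted_median")
  rs <- ratio_set(h)
  beta <- weighted_median_point(rs$ratio, rs$w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      s <- h$se_out / abs(bx)
      weighted_median_point(r, 1 / s^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("Weighted median", nrow(h), beta, se, pval_norm(beta / se))
}

mode_point <- function(ratio, weights, bw) {
  weights <- weights / sum(weights)
  d <- stats::density(ratio, weights = weights, bw = bw, n = 2048)
  d$x[which.max(d$y)]
}

mode_bandwidth <- function(ratio, bandwidth_factor) {
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) / length(ratio)^(1 / 5)
  if (!is.finite(s) || s <= 0) s <- max(stats::sd(ratio), .Machine$double.eps)
  max(1e-8, bandwidth_factor * s)
}

#' Mode-based estimate
#'
#' The mode of the kernel-smoothed density of the per-SNP ratio estimates
#' ("simple" variant: equal kernel weights; "weighted": kernels weighted by
#' the inverse-variance weights). Bandwidth is `bandwidth_factor` times a
#' modified Silverman rule, `0.9 min(sd, mad) n^(-1/5)`, applied to the
#' ratios. Consistent when the largest group of instruments sharing a causal
#' estimate is valid. SE via seeded parametric bootstrap.
#'
#' @param h Harmonized data frame with at least 3 rows.
#' @param variant `"simple"` or `"weighted"`.
#' @param bandwidth_factor Multiplier on the Silverman bandwidth (default 1).
#' @param n_boot,seed Bootstrap controls.
#' @return One-row `MREstimate` data frame.
#' @export
mr_mode <- function(h, variant = c("simple", "weighted"), bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  variant <- match.arg(variant)
  check_hset(h, 3, "mr_mode")
  rs <- ratio_set(h)
  wts <- if (variant == "weighted") rs$w else rep(1, nrow(h))
  beta <- mode_point(rs$ratio, wts, mode_bandwidth(rs$ratio, bandwidth_factor))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      s <- h$se_out / abs(bx)
      wb <- if (variant == "weighted") 1 / s^2 else rep(1, length(r))
      mode_point(r, wb, mode_bandwidth(r, bandwidth_factor))
    }, numeric(1))
  })
  se <- stats::sd(boots)
  label <- if (variant == "weighted") "Weighted mode" else "Simple mode"
  mr_estimate(label, nrow(h), beta, se, pval_norm(beta / se))
}

#' Run every applicable MR method
#'
#' Applies the full estimator suite to a harmonized set: Wald ratio for a
#' single instrument; IVW from two instruments; MR-Egger, weighted median and
#' both mode estimators from three. Methods needing more instruments than are
#' available are skipped with a log note. With `effects_model = "auto_by_q"`
#' the IVW row is reported under the multiplicative random-effects model when
#' the Cochran Q p-value falls below `q_alpha`, and under the fixed-effect
#' model otherwise. For binary outcomes set `or_scale = TRUE` to append
#' odds-ratio columns (`or`, `or_ci_low`, `or_ci_high` = exponentiated beta
#' and interval).
#'
#' @param h Harmonized data frame.
#' @param effects_model `"auto_by_q"`, `"fixed"` or `"random"` for the IVW row.
#' @param q_alpha Heterogeneity level for the automatic choice.
#' @param or_scale Append odds-ratio columns.
#' @param n_boot,seed Bootstrap controls for median/mode SEs.
#' @return Data frame with one `MREstimate` row per method.
#' @export
mr_all_methods <- function(h, effects_model = c("auto_by_q", "fixed", "random"),
                           q_alpha = 0.05, or_scale = FALSE,
                           n_boot = 1000, seed = 1) {
  effects_model <- match.arg(effects_model)
  check_hset(h, 1, "mr_all_methods")
  n <- nrow(h)
  rows <- list()
  if (n == 1L) {
    rows$wald <- mr_wald_ratio(h)
  } else {
    model <- effects_model
    if (model == "auto_by_q") {
      q <- cochran_q(h)
      model <- if (q$q_pval < q_alpha) "random" else "fixed"
    }
    rows$ivw <- mr_ivw(h, effects_model = model)
    if (n >= 3L) {
      rows$egger <- mr_egger(h)$slope
      rows$wmedian <- mr_weighted_median(h, n_boot = n_boot,
                                         seed = child_seed(seed, 1))
      rows$smode <- mr_mode(h, "simple", n_boot = n_boot,
                            seed = child_seed(seed, 2))
      rows$wmode <- mr_mode(h, "weighted", n_boot = n_boot,
                            seed = child_seed(seed, 3))
    } else {
      log_msg("mr_all_methods: %d instrument(s); Egger/median/mode skipped", n)
    }
  }
  out <- do.call(rbind, unname(rows))
  out <- out[order(match(out$method,
                         c("MR-Egger", "Weighted median", "IVW", "IVW (random)",
                           "Simple mode", "Weighted mode", "Wald ratio"))), ]
  rownames(out) <- NULL
  if (or_scale) {
    out$or <- exp(out$beta)
    out$or_ci_low <- exp(out$ci_low)
    out$or_ci_high <- exp(out$ci_high)
  }
  out
}
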