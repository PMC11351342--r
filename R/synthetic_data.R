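# Synthetic GWAS cohorts with known causal structure, per-SNP summary
# statistics, a two-stage least squares estimator, and named scenario presets
# mirroring the failure modes the screening cascade tests for.

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T")
)

make_snp_info <- function(m, prefix = "rs") {
  pair <- NON_PALINDROMIC_PAIRS[sample.int(nrow(NON_PALINDROMIC_PAIRS), m, replace = TRUE), ,
                                drop = FALSE]
  chrom <- as.character(rep(1:22, length.out = m))
  pos <- numeric(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 1e6 + (seq_along(idx) - 1) * 25e6
  }
  data.frame(snp = sprintf("%s%05d", prefix, seq_len(m)),
             chrom = chrom, pos = pos,
             effect_allele = pair[, 1], other_allele = pair[, 2],
             stringsAsFactors = FALSE)
}

#' Build a named simulation scenario
#'
#' Returns a fully specified, seeded configuration for [simulate_cohort()].
#' Presets (all share `n_per_cohort = 20000`, an exposure instrument panel of
#' `n_snps = 50` SNPs, a mediator-specific panel of `n_snps_mediator = 50`
#' SNPs -- each mediator trait has its own GWAS hits, which are what a step-2
#' MR instruments -- `maf_range = c(0.1, 0.5)`, `exposure_h2 = 0.15`,
#' `mediator_h2 = 0.15`, `outcome_prevalence = 0.25`):
#' \describe{
#'   \item{null}{no causal effects anywhere (`theta1 = theta2 = delta = 0`).}
#'   \item{mediated}{`theta1 = 0.4` (exposure to mediator), `theta2 = 0.5`
#'     (mediator to outcome, log-odds), `delta = 0`; true indirect effect
#'     `0.2`.}
#'   \item{direct_only}{`delta = -0.161` (log-odds), no mediated path.}
#'   \item{pleiotropic}{no causal effects, but every instrument carries a
#'     directional direct effect on the mediator, drawn U(0, 0.04)
#'     (mean 0.02).}
#'   \item{heterogeneous}{balanced per-SNP direct effects on the mediator,
#'     N(0, 0.05), inflating Cochran's Q without directional bias.}
#'   \item{reverse}{causality routed outcome-to-exposure: the instruments act
#'     on the outcome's liability and the exposure is downstream of it
#'     (`theta_rev = 0.25`).}
#' }
#' The exposure heritability gives per-instrument F statistics around 60 at
#' the default sizes, comfortably inside the range reported for real
#' telomere-length instruments; the prevalence matches the case fraction of
#' large psychiatric case-control GWAS.
#'
#' @param name Preset name.
#' @param overrides Named list of fields to override.
#' @return List of class `"scenario_config"`.
#' @export
build_scenario <- function(name = c("null", "mediated", "direct_only",
                                    "pleiotropic", "heterogeneous", "reverse"),
                           overrides = list()) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown scenario '", name[1], "'; valid names: null, mediated, ",
         "direct_only, pleiotropic, heterogeneous, reverse")
  })
  config <- list(
    name = name,
    n_per_cohort = 20000L,
    n_snps = 50L,
    n_snps_mediator = 50L,
    maf_range = c(0.1, 0.5),
    exposure_h2 = 0.15,
    mediator_h2 = 0.15,
    theta1 = 0, theta2 = 0, delta = 0, theta_rev = 0,
    pleiotropy = list(type = "none", magnitude = 0, prop_invalid = 0),
    ld_blocks = NULL,
    outcome_prevalence = 0.25,
    overlap_frac = 0,
    seed = 1L
  )
  preset <- switch(name,
    null = list(),
    mediated = list(theta1 = 0.4, theta2 = 0.5),
    direct_only = list(delta = -0.161),
    pleiotropic = list(pleiotropy = list(type = "directional", magnitude = 0.02,
                                         prop_invalid = 1)),
    heterogeneous = list(pleiotropy = list(type = "balanced", magnitude = 0.05,
                                           prop_invalid = 1)),
    reverse = list(theta_rev = 0.25)
  )
  config[names(preset)] <- preset
  config[names(overrides)] <- overrides
  stopifnot(config$maf_range[1] > 0, config$maf_range[2] <= 0.5,
            config$exposure_h2 >= 0, config$exposure_h2 < 1,
            config$outcome_prevalence > 0, config$outcome_prevalence < 1)
  structure(config, class = "scenario_config")
}

# Latent-Gaussian correlation giving a target allele-indicator correlation at
# frequency `maf` (tetrachoric calibration for the LD copula).
calibrate_copula_rho <- function(target_cor, maf) {
  if (target_cor <= 0) return(0)
  q <- stats::qnorm(maf)
  p11 <- function(rho) {
    stats::integrate(function(z) {
      stats::pnorm((q - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
    }, -Inf, q)$value
  }
  cor_at <- function(rho) (p11(rho) - maf^2) / (maf * (1 - maf))
  stats::uniroot(function(r) cor_at(r) - target_cor,
                 lower = 1e-6, upper = 0.9999, tol = 1e-6)$root
}

# Genotype matrix: independent binomial dosages, or block-correlated dosages
# through a one-factor Gaussian copula on the haplotype alleles.
simulate_genotypes <- function(n, maf, ld_blocks = NULL) {
  m <- length(maf)
  if (is.null(ld_blocks)) {
    return(matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m))
  }
  size <- ld_blocks$size
  target_r <- sqrt(ld_blocks$r2)
  G <- matrix(0L, n, m)
  start <- 1L
  while (start <= m) {
    idx <- start:min(start + size - 1L, m)
    block_maf <- maf[idx[1]]
    rho <- calibrate_copula_rho(target_r, block_maf)
    q <- stats::qnorm(block_maf)
    for (hap in 1:2) {
      w <- stats::rnorm(n)
      z <- sqrt(rho) * matrix(w, n, length(idx)) +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(idx)), n, length(idx))
      G[, idx] <- G[, idx] + (z < q)
    }
    start <- start + size
  }
  G
}

#' Simulate linked cohorts with known causal structure
#'
#' Generates disjoint sub-cohorts for the exposure, mediator and outcome GWAS
#' roles from one scenario configuration. The generative model is
#' \deqn{X = \sum_j a_j G_j + \varepsilon_x, \quad
#'       M = \theta_1 X + \sum_j (\gamma_j + b_j) G_j + \varepsilon_m, \quad
#'       \mathrm{logit}\,P(Y=1) = \alpha + \theta_2 M + \delta X,}
#' with genotypes `G_j ~ Binomial(2, maf_j)` (optionally block-correlated via
#' a Gaussian copula). Exposure-instrument effects `a_j` (first `n_snps`
#' SNPs) are drawn as |N(0, s)| and scaled so the panel explains
#' `exposure_h2` of the exposure variance; mediator-specific effects `b_j`
#' live on the remaining `n_snps_mediator` SNPs and explain `mediator_h2` of
#' the mediator variance (these are the instruments a mediator-to-outcome MR
#' selects); pleiotropic effects `gamma_j` contaminate the exposure panel
#' only. The intercept `alpha` is solved so cases occur at
#' `outcome_prevalence`. The binary
#' outcome is generated through a logistic link, i.e. a liability threshold
#' with logistic errors, so `theta2` and `delta` are log-odds effects on the
#' same scale the per-SNP logistic summary statistics estimate. In reverse
#' mode (`theta_rev != 0`) the instruments act on a core liability trait `L`
#' with the outcome downstream of `L` and the exposure
#' `X = theta_rev L + noise`, so the analyst's instrument panel for X in fact
#' proxies the outcome.
#'
#' @param config A `scenario_config` from [build_scenario()].
#' @param roles Which cohorts to generate (subset of
#'   `c("exposure", "mediator", "outcome")`); skipping unused cohorts speeds
#'   up large replicate studies.
#' @return List with `config`, `snp_info`, `maf`, per-role `cohorts` (each a
#'   list holding the genotype matrix `G` and the phenotypes defined for that
#'   role) and `truth` (realized `a`, `gamma`, `theta1`, `theta2`, `delta`,
#'   `theta_rev`, `indirect`).
#' @export
simulate_cohort <- function(config, roles = c("exposure", "mediator", "outcome")) {
  stopifnot(inherits(config, "scenario_config"))
  roles <- match.arg(roles, several.ok = TRUE)
  with_seed(config$seed, {
    m_exp <- config$n_snps
    m_med <- config$n_snps_mediator %||% 0L
    m <- m_exp + m_med
    n <- config$n_per_cohort
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    snp_info <- make_snp_info(m)
    var_g <- 2 * maf * (1 - maf)
    exposure_panel <- seq_len(m_exp)
    mediator_panel <- if (m_med > 0) m_exp + seq_len(m_med) else integer(0)

    # Exposure instruments: effect alleles coded trait-increasing, magnitudes
    # |N(0, s)| scaled so the panel explains exposure_h2 of var(X).
    a <- rep(0, m)
    if (config$exposure_h2 > 0) {
      raw <- abs(stats::rnorm(m_exp))
      a[exposure_panel] <- raw *
        sqrt(config$exposure_h2 / sum(raw^2 * var_g[exposure_panel]))
    }
    # Mediator-specific instruments (the mediator's own GWAS hits), scaled to
    # mediator_h2 of var(M).
    b <- rep(0, m)
    if (m_med > 0 && config$mediator_h2 > 0) {
      raw <- abs(stats::rnorm(m_med))
      b[mediator_panel] <- raw *
        sqrt(config$mediator_h2 / sum(raw^2 * var_g[mediator_panel]))
    }

    gamma <- rep(0, m)
    plei <- config$pleiotropy
    if (plei$type != "none" && plei$prop_invalid > 0 && plei$magnitude > 0) {
      k <- max(1L, round(plei$prop_invalid * m_exp))
      invalid <- sample(exposure_panel, k)
      gamma[invalid] <- switch(plei$type,
        directional = stats::runif(k, 0, 2 * plei$magnitude),
        balanced = stats::rnorm(k, 0, plei$magnitude),
        stop("unknown pleiotropy type: ", plei$type))
    }

    var_gg <- sum(gamma^2 * var_g)
    med_h2 <- sum(b^2 * var_g)
    resid_x <- 1 - config$exposure_h2
    resid_m <- 1 - config$theta1^2 - var_gg - med_h2
    if (resid_m <= 0) {
      stop("infeasible configuration: theta1, pleiotropy and mediator_h2 leave",
           " no residual variance for the mediator")
    }

    make_pheno <- function(nn) {
      G <- simulate_genotypes(nn, maf, config$ld_blocks)
      if (config$theta_rev != 0) {
        # Reverse causation: genetics -> liability core L -> (outcome, exposure).
        L <- drop(G %*% a) + stats::rnorm(nn, 0, sqrt(resid_x))
        X <- config$theta_rev * L + stats::rnorm(nn, 0, sqrt(1 - config$theta_rev^2))
        M <- stats::rnorm(nn)
        eta <- L
      } else {
        X <- drop(G %*% a) + stats::rnorm(nn, 0, sqrt(resid_x))
        M <- config$theta1 * X + drop(G %*% (gamma + b)) +
          stats::rnorm(nn, 0, sqrt(resid_m))
        eta <- config$theta2 * M + config$delta * X
      }
      alpha <- stats::uniroot(function(al) {
        mean(stats::plogis(al + eta)) - config$outcome_prevalence
      }, lower = -30, upper = 30)$root
      Y <- stats::rbinom(nn, 1L, stats::plogis(alpha + eta))
      list(G = G, X = X, M = M, Y = Y)
    }

    cohorts <- list()
    for (role in c("exposure", "mediator", "outcome")) {
      if (role %in% roles) cohorts[[role]] <- make_pheno(n)
    }

    list(config = config, snp_info = snp_info, maf = maf, cohorts = cohorts,
         exposure_panel = exposure_panel, mediator_panel = mediator_panel,
         truth = list(a = a, b = b, gamma = gamma,
                      theta1 = config$theta1, theta2 = config$theta2,
                      delta = config$delta, theta_rev = config$theta_rev,
                      indirect = config$theta1 * config$theta2))
  })
}

#' Per-SNP GWAS summary statistics from a cohort
#'
#' Runs the marginal per-SNP association scan that produces a GWAS
#' summary-statistic table. Continuous phenotypes use ordinary least squares
#' (closed form, vectorised across SNPs). Binary phenotypes use, by default,
#' the one-iteration score approximation to the per-SNP logistic fit
#' (`beta = U/V`, `se = V^{-1/2}` with score `U` and information `V` from the
#' null model) -- exactly calibrated under the null and accurate at the small
#' per-SNP effects typical of GWAS -- or the full IRLS logistic fit with
#' `method = "glm"`. Monomorphic SNPs are emitted with `eaf` 0/1, an `NA`
#' standard error and are listed in the `monomorphic` attribute.
#'
#' @param G Genotype dosage matrix (individuals x SNPs).
#' @param phenotype Numeric phenotype vector (0/1 for binary).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param snp_info Data frame `snp, chrom, pos, effect_allele, other_allele`
#'   (e.g. from [simulate_cohort()]).
#' @param trait_id Trait identifier for the resulting table.
#' @param method Binary-trait fitting method, `"score"` or `"glm"`.
#' @return A `summary_stats` table.
#' @export
summary_stats_from_cohort <- function(G, phenotype,
                                      trait_type = c("continuous", "binary"),
                                      snp_info, trait_id = "trait",
                                      method = c("score", "glm")) {
  trait_type <- match.arg(trait_type)
  method <- match.arg(method)
  if (nrow(G) != length(phenotype)) {
    stop("phenotype length must match genotype rows")
  }
  n <- nrow(G)
  m <- ncol(G)
  gbar <- colMeans(G)
  eaf <- gbar / 2
  Sxx <- colSums(G^2) - n * gbar^2
  mono <- Sxx <= 0

  if (trait_type == "continuous") {
    yc <- phenotype - mean(phenotype)
    Syy <- sum(yc^2)
    Sxy <- drop(crossprod(G, yc))
    beta <- Sxy / Sxx
    sigma2 <- pmax(Syy - beta * Sxy, 0) / (n - 2)
    se <- sqrt(sigma2 / Sxx)
    pval <- pmax(pval_t(beta / se, n - 2), .Machine$double.xmin)
  } else if (method == "score") {
    p0 <- mean(phenotype)
    U <- drop(crossprod(G, phenotype - p0))
    V <- p0 * (1 - p0) * Sxx
    beta <- U / V
    se <- 1 / sqrt(V)
    pval <- pval_norm(beta / se)
  } else {
    beta <- se <- pval <- numeric(m)
    for (j in seq_len(m)) {
      if (mono[j]) next
      fit <- stats::glm(phenotype ~ G[, j], family = stats::binomial())
      cf <- summary(fit)$coefficients
      beta[j] <- cf[2, 1]
      se[j] <- cf[2, 2]
      pval[j] <- max(cf[2, 4], .Machine$double.xmin)
    }
  }
  beta[mono] <- 0
  se[mono] <- NA_real_
  pval[mono] <- 1
  if (any(mono)) {
    log_msg("summary_stats_from_cohort [%s]: %d monomorphic SNP(s) flagged",
            trait_id, sum(mono))
  }
  df <- data.frame(snp_info,
                   eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                   stringsAsFactors = FALSE)
  out <- summary_stat_table(df, trait_id = trait_id, trait_type = trait_type,
                            validate = FALSE)
  attr(out, "monomorphic") <- snp_info$snp[mono]
  out
}

#' Two-stage least squares on individual-level data
#'
#' Stage 1 regresses the exposure on the instrument genotypes; stage 2
#' regresses the response on the fitted exposure. The coefficient standard
#' error uses the proper instrumental-variable variance (residuals formed
#' with the observed, not fitted, exposure). Also returns the stage-1
#' multiple R-squared. A binary response is fitted as a linear probability
#' model in stage 2, with a log note.
#'
#' @param G Genotype matrix restricted to the instruments.
#' @param exposure Numeric exposure vector.
#' @param response Numeric response vector (continuous, or 0/1).
#' @return List `beta`, `se`, `pval`, `multiple_r2`, `n`.
#' @export
two_stage_least_squares <- function(G, exposure, response) {
  n <- length(exposure)
  stopifnot(nrow(G) == n, length(response) == n)
  if (all(response %in% c(0, 1))) {
    log_msg("two_stage_least_squares: binary response fitted as linear probability model")
  }
  Z <- cbind(1, G)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    stop("two_stage_least_squares: rank-deficient first stage")
  }
  fit1 <- qr.fitted(qrz, exposure)
  tss <- sum((exposure - mean(exposure))^2)
  rss1 <- sum((exposure - fit1)^2)
  multiple_r2 <- 1 - rss1 / tss
  xh <- fit1 - mean(fit1)
  Sxx <- sum(xh^2)
  beta <- sum(xh * (response - mean(response))) / Sxx
  # IV variance: residuals against the observed exposure.
  resid <- (response - mean(response)) - beta * (exposure - mean(exposure))
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / Sxx)
  list(beta = beta, se = se, pval = pval_t(beta / se, n - 2),
       multiple_r2 = multiple_r2, n = n)
}
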