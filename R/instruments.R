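# Instrumental-variable selection: genome-wide significance, LD clumping,
# outcome-association and confounder exclusion, per-SNP F statistics.

#' Retain genome-wide significant variants
#'
#' Keeps records with `pval` strictly below `p_threshold` (default the
#' conventional genome-wide significance level 5e-8). The returned data frame
#' is the instrument-candidate table consumed by the rest of this module.
#'
#' @param exposure A `summary_stats` table.
#' @param p_threshold Significance threshold; strict `<` comparison.
#' @return Subset of `exposure` (attributes preserved).
#' @export
select_genomewide <- function(exposure, p_threshold = 5e-8) {
  keep <- which(exposure$pval < p_threshold)
  out <- exposure[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("select_genomewide: no variants reach p < ", p_threshold, call. = FALSE)
  }
  out
}

#' Read a square LD matrix file
#'
#' Expects a delimited file whose header row lists SNP ids and whose body is
#' the symmetric matrix of pairwise r-squared values with unit diagonal.
#'
#' @param path File path.
#' @return Numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  validate_ld_matrix(m)
  m
}

validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) stop("LD matrix must be square")
  if (is.null(colnames(ld))) stop("LD matrix must carry SNP ids as dimnames")
  if (any(ld < 0 | ld > 1, na.rm = TRUE)) stop("LD r-squared values must lie in [0, 1]")
  if (any(abs(diag(ld) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(abs(ld - t(ld)) > 1e-8)) stop("LD matrix must be symmetric")
  invisible(ld)
}

#' Greedy LD clumping
#'
#' Prunes candidate instruments so retained variants are approximately
#' independent: candidates are visited in ascending p-value order (ties broken
#' by position, then SNP id) and accepted only if their pairwise r-squared
#' with every already-accepted variant on the same chromosome within
#' `window_kb` is below `r2_threshold`. Variants on different chromosomes, or
#' farther apart than the window, are never compared. Candidates absent from
#' the LD matrix are dropped with a warning. The result is ordered by
#' chromosome and position.
#'
#' @param candidates Instrument-candidate table with columns `snp`, `chrom`,
#'   `pos`, `pval` (as produced by [select_genomewide()]).
#' @param ld Symmetric r-squared matrix with SNP-id dimnames, or `NULL` to
#'   skip r-squared checks (variants treated as unlinked; a note is logged).
#' @param r2_threshold Maximum tolerated pairwise r-squared (default 0.001).
#' @param window_kb Window in kilobases within which pairs are compared
#'   (default 10000, i.e. 10 Mb).
#' @return Subset of `candidates`.
#' @export
ld_clump <- function(candidates, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  if (nrow(candidates) == 0L) return(candidates)
  if (is.null(ld)) {
    log_msg("ld_clump: no LD matrix supplied; variants assumed unlinked")
  } else {
    validate_ld_matrix(ld)
    present <- candidates$snp %in% colnames(ld)
    if (any(!present)) {
      warning("ld_clump: dropped ", sum(!present),
              " candidate(s) absent from the LD matrix", call. = FALSE)
      candidates <- candidates[present, , drop = FALSE]
    }
  }
  ord <- order(candidates$pval, candidates$pos, candidates$snp)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      if (candidates$chrom[i] != candidates$chrom[j]) next
      if (abs(candidates$pos[i] - candidates$pos[j]) > window_kb * 1000) next
      if (is.null(ld)) next
      if (ld[candidates$snp[i], candidates$snp[j]] >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  out <- candidates[accepted, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude instruments associated with the outcome
#'
#' Drops instruments whose outcome-GWAS p-value is below `p_threshold`
#' (default genome-wide significance), removing variants whose primary signal
#' plausibly acts on the outcome directly. Instruments missing from the
#' outcome table are retained with a log note (no evidence against them).
#'
#' @param instruments Instrument table.
#' @param outcome A `summary_stats` table for the outcome.
#' @param p_threshold Exclusion threshold (strict `<`).
#' @return Subset of `instruments`.
#' @export
exclude_outcome_associated <- function(instruments, outcome, p_threshold = 5e-8) {
  idx <- match(instruments$snp, outcome$snp)
  p_out <- outcome$pval[idx]
  missing <- is.na(idx)
  if (any(missing)) {
    log_msg("exclude_outcome_associated: %d instrument(s) absent from outcome table; retained",
            sum(missing))
  }
  drop <- !missing & p_out < p_threshold
  if (any(drop)) {
    log_msg("exclude_outcome_associated: dropped %d outcome-associated instrument(s)",
            sum(drop))
  }
  out <- instruments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude instruments linked to listed confounder traits
#'
#' Offline stand-in for interactive variant-trait catalogue queries: given a
#' lookup table of known SNP-trait associations, drops any instrument whose
#' SNP maps to a trait matching one of `confounder_traits`
#' (case-insensitive substring match).
#'
#' @param instruments Instrument table.
#' @param lookup Data frame with columns `snp` and `trait` (may be empty).
#' @param confounder_traits Character vector of trait names to screen out.
#' @return Subset of `instruments`.
#' @export
exclude_listed_confounders <- function(instruments, lookup, confounder_traits) {
  if (length(confounder_traits) == 0L || is.null(lookup) || nrow(lookup) == 0L) {
    return(instruments)
  }
  hit_trait <- Reduce(`|`, lapply(confounder_traits, function(tr) {
    grepl(tolower(tr), tolower(lookup$trait), fixed = TRUE)
  }))
  bad_snps <- unique(lookup$snp[hit_trait])
  drop <- instruments$snp %in% bad_snps
  if (any(drop)) {
    log_msg("exclude_listed_confounders: dropped %d confounder-linked instrument(s)",
            sum(drop))
  }
  out <- instruments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-instrument F statistics
#'
#' Computes, for each instrument, the variance in the exposure it explains and
#' the corresponding F statistic
#' \deqn{F = \frac{R^2 (N - K - 1)}{K (1 - R^2)}, \quad K = 1,}
#' the standard per-SNP instrument-strength measure. When `r2_snp` is not
#' already present it is estimated from the summary statistics via the
#' t-statistic approximation \eqn{R^2 = t^2 / (t^2 + n - 2)} with
#' \eqn{t = \beta/\mathrm{se}}; users with individual-level estimates can
#' supply an `r2_snp` column instead.
#'
#' @param instruments Instrument table with `beta`, `se`, `n` columns.
#' @param n_override Optional sample size used for every record in place of
#'   the per-record `n`.
#' @return `instruments` with `r2_snp` and `f_stat` columns filled.
#' @export
compute_f_statistics <- function(instruments, n_override = NULL) {
  n <- if (is.null(n_override)) instruments$n else rep(n_override, nrow(instruments))
  if (any(n <= 2)) {
    stop("compute_f_statistics: sample size must exceed K + 1 = 2 for every record")
  }
  if (is.null(instruments$r2_snp) || all(is.na(instruments$r2_snp))) {
    t2 <- (instruments$beta / instruments$se)^2
    instruments$r2_snp <- t2 / (t2 + n - 2)
  }
  r2 <- instruments$r2_snp
  instruments$f_stat <- r2 * (n - 2) / (1 - r2)
  instruments
}

#' Drop weak instruments
#'
#' Retains instruments with `f_stat` strictly greater than `f_min` (default
#' 10, the conventional weak-instrument cutoff).
#'
#' @param instruments Instrument table with `f_stat` filled.
#' @param f_min Minimum F statistic.
#' @return Subset of `instruments`.
#' @export
filter_weak_instruments <- function(instruments, f_min = 10) {
  if (is.null(instruments$f_stat)) {
    stop("filter_weak_instruments: call compute_f_statistics() first")
  }
  out <- instruments[instruments$f_stat > f_min, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("filter_weak_instruments: no instruments with F > ", f_min, call. = FALSE)
  }
  out
}
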