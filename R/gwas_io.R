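# Reading, validating, writing GWAS summary statistics, and harmonizing an
# exposure/outcome pair onto a common effect allele.

CANONICAL_COLS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")

#' Construct a validated summary-statistic table
#'
#' The central container of the package: one row per SNP with the canonical
#' columns `snp, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval,
#' n`. Rows violating hard invariants (alleles outside A/C/G/T or equal,
#' non-positive `se`, `pval` outside (0, 1], non-positive `n`, `eaf` outside
#' [0, 1], non-finite `beta`) are dropped with a message; missing `eaf` is
#' preserved as `NA`. A soft check compares the reported p-value against the
#' normal approximation `2 * pnorm(-|beta/se|)` and warns (never rejects) when
#' they disagree by more than two-fold, since rounding in public GWAS breaks
#' exact agreement.
#'
#' @param df Data frame holding at least the canonical columns.
#' @param trait_id Identifier of the trait the statistics describe.
#' @param trait_type `"continuous"` or `"binary"` (betas on the log-odds
#'   scale for binary traits).
#' @param validate Set `FALSE` to skip invariant checks (internal use).
#' @return A `data.frame` of class `"summary_stats"` with attributes
#'   `trait_id`, `trait_type` and `n_dropped`.
#' @export
summary_stat_table <- function(df, trait_id, trait_type = c("continuous", "binary"),
                               validate = TRUE) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(CANONICAL_COLS, names(df))
  if (length(missing_cols)) {
    stop("summary statistics are missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[CANONICAL_COLS]
  df$snp <- as.character(df$snp)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  n_dropped <- 0L
  if (validate) {
    ok <- df$effect_allele %in% c("A", "C", "G", "T") &
      df$other_allele %in% c("A", "C", "G", "T") &
      df$effect_allele != df$other_allele &
      is.finite(df$beta) &
      is.finite(df$se) & df$se > 0 &
      is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
      is.finite(df$n) & df$n > 0 &
      (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
    ok[is.na(ok)] <- FALSE
    n_dropped <- sum(!ok)
    if (n_dropped > 0) {
      log_msg("summary_stat_table [%s]: dropped %d invalid record(s)",
              trait_id, n_dropped)
      df <- df[ok, , drop = FALSE]
    }
    if (anyDuplicated(df$snp)) {
      dup <- duplicated(df$snp)
      log_msg("summary_stat_table [%s]: dropped %d duplicate snp id(s)",
              trait_id, sum(dup))
      n_dropped <- n_dropped + sum(dup)
      df <- df[!dup, , drop = FALSE]
    }
    # Soft consistency: reported p vs normal approximation, two-fold window.
    p_z <- pval_norm(df$beta / df$se)
    bad <- df$pval > 2 * p_z | df$pval < p_z / 2
    if (any(bad, na.rm = TRUE)) {
      warning(sprintf(
        "summary_stat_table [%s]: %d record(s) have pval inconsistent with |beta/se| beyond two-fold (kept)",
        trait_id, sum(bad, na.rm = TRUE)), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df,
            trait_id = trait_id,
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("summary_stats", "data.frame"))
}

#' @export
trait_id <- function(x) attr(x, "trait_id", exact = TRUE)

#' @export
trait_type <- function(x) attr(x, "trait_type", exact = TRUE)

#' Read a GWAS summary-statistic file
#'
#' Reads a tab- or comma-delimited file with a header row into a validated
#' [summary_stat_table()]. Non-canonical headers are renamed through
#' `column_map`, a named character vector mapping standard field names to the
#' column names used in the file, e.g.
#' `c(snp = "rsid", beta = "Effect", se = "StdErr")`.
#'
#' @param path File path.
#' @param column_map Named character vector (standard field -> source column);
#'   `NULL` if the file already uses the canonical header.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_id Trait identifier; defaults to the file name sans extension.
#' @return A `summary_stats` table.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("continuous", "binary"),
                               trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("cannot read summary statistics: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "", "."))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df)) {
        stop("column_map field '", std, "' refers to absent column '", src, "'")
      }
      names(df)[names(df) == src] <- std
    }
  }
  missing_cols <- setdiff(CANONICAL_COLS, names(df))
  if (length(missing_cols)) {
    stop("required field(s) not resolvable from file header: ",
         paste(missing_cols, collapse = ", "))
  }
  summary_stat_table(df, trait_id = trait_id %||% sub("\\.[^.]*$", "", basename(path)),
                     trait_type = trait_type)
}

#' Write a summary-statistic table
#'
#' Writes the canonical tab-delimited format (header
#' `snp chrom pos effect_allele other_allele eaf beta se pval n`). Numeric
#' fields are written with enough precision that
#' `read_summary_stats(write_summary_stats(x))` is the identity.
#'
#' @param table A `summary_stats` table.
#' @param path Output path.
#' @export
write_summary_stats <- function(table, path) {
  out <- as.data.frame(table)[CANONICAL_COLS]
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    out[[col]][out[[col]] %in% c("NA", " NA")] <- NA
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write summary statistics to: ", path)
  invisible(path)
}

ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_alleles <- function(x) unname(ALLELE_COMPLEMENT[x])

is_palindromic <- function(ea, oa) ea == complement_alleles(oa)

#' Harmonize an exposure/outcome pair onto the exposure's effect allele
#'
#' Joins two summary-statistic tables on SNP id and aligns the outcome records
#' to the exposure's effect allele. Matching alleles are kept as-is; swapped
#' alleles flip the outcome beta sign and effect-allele frequency; alleles
#' reported on the opposite strand are complemented first. Palindromic (A/T or
#' C/G) variants cannot be resolved from alleles alone and are handled per
#' `palindromic_policy`: `"drop"` removes them; `"infer_by_eaf"` orients them
#' from the allele frequency when both sides lie outside the ambiguity window
#' `[0.5 - eaf_window, 0.5 + eaf_window]`, and drops them otherwise (also when
#' either frequency is missing). Irreconcilable allele pairs are dropped with
#' a log entry.
#'
#' @param exposure,outcome `summary_stats` tables.
#' @param palindromic_policy `"drop"` (default) or `"infer_by_eaf"`.
#' @param eaf_window Half-width of the frequency ambiguity window (default
#'   0.08, i.e. eaf in `[0.42, 0.58]` is treated as uninformative).
#' @return A `data.frame` of class `"harmonized"` with columns `snp`,
#'   exposure-side `beta_exp, se_exp, pval_exp, n_exp`, outcome-side
#'   `beta_out, se_out, pval_out, n_out`, aligned `eaf`, and logical
#'   `flipped`, `palindromic`. Drop/flip counts are attached as attributes.
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindromic_policy = c("drop", "infer_by_eaf"),
                           eaf_window = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) {
    stop("harmonize_pair: no shared SNPs between exposure and outcome tables")
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp), ]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  c_ea <- complement_alleles(ou$effect_allele)
  c_oa <- complement_alleles(ou$other_allele)
  strand_same <- c_ea == ex$effect_allele & c_oa == ex$other_allele
  strand_swapped <- c_ea == ex$other_allele & c_oa == ex$effect_allele

  keep <- rep(TRUE, length(shared))
  flip <- rep(FALSE, length(shared))
  n_pal_dropped <- 0L

  # Non-palindromic: allele sets identify orientation (strand flip harmless).
  npal <- !pal
  flip[npal & (swapped | strand_swapped)] <- TRUE
  keep[npal & !(same | swapped | strand_same | strand_swapped)] <- FALSE
  n_incompat <- sum(!keep)

  # Palindromic: same/swapped coincide with their strand complements, so
  # orientation must come from allele frequency (or the SNP is dropped).
  if (any(pal)) {
    compatible <- same | swapped | strand_same | strand_swapped
    keep[pal & !compatible] <- FALSE
    n_incompat <- n_incompat + sum(pal & !compatible)
    idx <- which(pal & compatible)
    if (palindromic_policy == "drop") {
      keep[idx] <- FALSE
      n_pal_dropped <- length(idx)
    } else {
      for (i in idx) {
        fe <- ex$eaf[i]
        fo <- ou$eaf[i]
        informative <- !is.na(fe) && !is.na(fo) &&
          abs(fe - 0.5) > eaf_window && abs(fo - 0.5) > eaf_window
        if (!informative) {
          keep[i] <- FALSE
          n_pal_dropped <- n_pal_dropped + 1L
        } else if ((fe < 0.5) != (fo < 0.5)) {
          flip[i] <- TRUE
        }
      }
    }
  }

  beta_out <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  h <- data.frame(
    snp = ex$snp,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval, n_exp = ex$n,
    beta_out = beta_out, se_out = ou$se, pval_out = ou$pval, n_out = ou$n,
    eaf = ifelse(is.na(ex$eaf), eaf_out, ex$eaf),
    flipped = flip, palindromic = pal,
    stringsAsFactors = FALSE
  )
  h <- h[keep, , drop = FALSE]
  rownames(h) <- NULL
  if (n_incompat > 0) {
    log_msg("harmonize_pair: dropped %d SNP(s) with irreconcilable alleles", n_incompat)
  }
  if (n_pal_dropped > 0) {
    log_msg("harmonize_pair: dropped %d unresolvable palindromic SNP(s)", n_pal_dropped)
  }
  structure(h,
            n_shared = length(shared),
            n_flipped = sum(h$flipped),
            n_dropped_incompatible = n_incompat,
            n_dropped_palindromic = n_pal_dropped,
            class = c("harmonized", "data.frame"))
}
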