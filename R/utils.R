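# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All user-facing randomness goes through this so a
# single integer seed reproduces a whole analysis.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% .Machine$integer.max)
}

# Two-sided normal p-value, floored away from exact zero so p stays in (0, 1].
pval_norm <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

pval_t <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df)
  pmax(p, .Machine$double.xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message(sprintf(...))
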