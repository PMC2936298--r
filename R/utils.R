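# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic stream of child seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647L) + 1L
}

logit <- function(p) stats::qlogis(p)

inv_logit <- function(x) stats::plogis(x)

# log(sum(exp(m[i, ]))) row-wise, numerically stable
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
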