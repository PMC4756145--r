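#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm runif var coef approx setNames
#' @importFrom utils write.table read.table head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a base seed; keeps the result a valid
# 32-bit integer for set.seed().
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 12289L * as.numeric(k)) %%
               .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    x == round(x)
}

# Standardize columns of a matrix to zero mean, unit (sample) variance.
# Columns with zero variance are centered only.
zscore_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), `-`)
  s <- apply(x, 2L, sd)
  s[s <= 0] <- 1
  sweep(x, 2L, s, `/`)
}

# Standardize rows (used for spatial maps stored component x voxel).
zscore_rows <- function(x) t(zscore_cols(t(x)))
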