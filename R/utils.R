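#' Derive reproducible child seeds from one master seed
#'
#' All stochastic stages of the pipeline draw their randomness from child
#' seeds derived deterministically from a single master seed, so that any
#' stage can be re-run in isolation and the whole pipeline is reproducible
#' from one integer.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of `n` distinct seeds, each below `2^31`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Column-wise z-scoring; columns with zero variance map to zero.
zscore <- function(x) {
  if (is.matrix(x)) {
    s <- apply(x, 2, sd)
    s[s == 0] <- 1
    scale(x, center = TRUE, scale = s)[, , drop = FALSE]
  } else {
    s <- sd(x)
    if (is.na(s) || s == 0) s <- 1
    as.numeric(scale(x, center = TRUE, scale = s))
  }
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
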