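#' @useDynLib condylometry, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd median anova lm coef kruskal.test shapiro.test
#'   chisq.test pchisq setNames runif
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.  All stochastic operations in the package go
# through this so that identical seeds give identical results regardless of
# the surrounding RNG state.
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

# Per-stage seeds are derived from the master seed by a fixed affine scheme
# modulo the Mersenne prime 2^31 - 1 (exact in double arithmetic), so that a
# single experiment seed reproduces every stage while stages stay decorrelated.
derive_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.numeric(seed) %% 2147483647) * 69621 +
    stage_code * 1013 + as.numeric(index)
  as.integer(val %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_condylometry <- function(msg, class = "condylometry_error") {
  stop(errorCondition(msg, class = class, call = sys.call(-1)))
}
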