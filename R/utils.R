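#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov coef complete.cases cor glm lm lm.fit median
#'   p.adjust pchisq phyper pnorm pt qchisq qnorm quantile rbinom rexp rnorm
#'   runif sd setNames t.test var binomial rbeta
#' @importFrom utils head write.table read.delim
NULL

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state.  Kept below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0L) return(integer(0))
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Evaluate `expr` under a fixed seed, restoring the previous RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Column-centering that tolerates zero-variance columns.
center_cols <- function(X) {
  sweep(X, 2L, colMeans(X), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pf <- function(...) stop(sprintf(...), call. = FALSE)
warn_pf <- function(...) warning(sprintf(...), call. = FALSE)
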