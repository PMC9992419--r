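#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rbinom runif aov anova shapiro.test t.test
#'   wilcox.test cor.test prcomp hclust as.dist cor TukeyHSD sd qnorm
#'   complete.cases setNames median quantile var as.formula dist
#' @importFrom utils read.csv write.csv modifyList head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic operations in the package take explicit integer seeds and
#' run under a locally-seeded RNG, so generation never disturbs (nor depends
#' on) the caller's global random state.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
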