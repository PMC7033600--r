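#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats median rnorm runif rbinom rpois rgamma rlnorm rmultinom
#'   rnbinom model.matrix glm.fit pnorm p.adjust cor quantile setNames
#' @importFrom utils read.table write.table read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All generators route randomness through this so
# that every simulation is a pure function of (config, seed).
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar validators used by constructors; `name` feeds the error message so
# validation failures name the offending field
assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("field '%s' must be a single non-missing number", name),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("field '%s' must be an integer", name), call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(sprintf("field '%s' must be in %s%s, %s]", name,
                 if (strict_lower) "(" else "[", format(lower), format(upper)),
         call. = FALSE)
  invisible(x)
}

geomMean <- function(x) exp(mean(log(x)))

# lognormal multiplicative jitter with unit mean and coefficient of variation cv
jitterLognormal <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Draw integer counts summing exactly to `depth` whose marginals are
# approximately negative binomial with relative extra-Poisson variance
# `alpha`: gamma-perturbed weights followed by a multinomial draw.
dirichletMultinomial <- function(depth, weights, alpha) {
  stopifnot(depth >= 0, all(weights >= 0))
  if (depth == 0) return(integer(length(weights)))
  w <- weights
  pos <- w > 0
  if (alpha > 0) {
    shape <- 1 / alpha
    w[pos] <- rgamma(sum(pos), shape = shape, rate = shape / w[pos])
  }
  if (sum(w) == 0) w[] <- 1
  as.integer(rmultinom(1, size = depth, prob = w / sum(w)))
}
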