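#' @importFrom stats as.formula coef complete.cases cor.test dist lm logLik
#'   p.adjust plogis pnorm qlogis quantile rbeta rbinom rgamma rnbinom rnorm
#'   runif sd setNames step terms vcov
#' @importFrom utils head read.csv write.csv
NULL

# Deterministic polynomial rolling hash of a string (mod 2^31 - 1); used to
# derive named RNG substreams from one global seed so stages do not perturb
# each other.
.strHash <- function(x) {
  h <- 7
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Derive a named RNG substream seed from a global seed
#'
#' One global seed is fanned out to per-stage substreams by hashing the stage
#' name, so changing the draws of one stage never perturbs another.
#'
#' @param seed integer global seed.
#' @param name character substream name.
#' @return an integer seed below 2^31.
#' @export
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  as.integer((abs(seed) %% 65011 * 33013 + .strHash(name)) %% 2147483647)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state,
# so seeded helpers are pure functions of their arguments.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Lightweight logging to stderr; level in c("debug", "info", "warn").
.pwLog <- function(..., level = "info") {
  message(sprintf("[pawebs:%s] %s", level, paste0(...)))
}

# Stable hash of an arbitrary config object (deparsed), for run manifests.
.configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  sprintf("%08x", .strHash(s))
}

# Shannon diversity of a vector of class labels (natural log).
.shannon <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_real_)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

.zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}
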