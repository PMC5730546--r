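`%||%` <- function(a, b) if (is.null(a)) b else a

## scalar validation helpers: every simulator/analysis constructor funnels
## through these so errors always name the offending field
check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric of length %d", field, len),
         call. = FALSE)
  }
  lo_ok <- if (strict_min) all(x > min) else all(x >= min)
  if (!lo_ok || any(x > max)) {
    stop(sprintf("'%s' out of range [%s, %s]%s: %s", field,
                 format(min), format(max),
                 if (strict_min) " (lower bound exclusive)" else "",
                 paste(format(x), collapse = ", ")),
         call. = FALSE)
  }
  x
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", field), call. = FALSE)
  }
  x
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed)) {
    stop("'seed' must be an explicit integer", call. = FALSE)
  }
  as.integer(seed %% .Machine$integer.max)
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  seed <- check_seed(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## deterministic stream of sub-seeds derived from one master seed,
## kept strictly below 2^31 - 1
derive_seed <- function(seed, i) {
  seed <- as.numeric(check_seed(seed))
  as.integer((seed %% 1000003) * 2011 + 7 * as.numeric(i) + 1) %% 2147483647L
}

## mean of N(mean, sd^2) truncated at zero; exact hop-length expectation
truncnorm_mean <- function(mean, sd) {
  if (sd <= 0) return(mean)
  a <- -mean / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
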