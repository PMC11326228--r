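# Internal numerical helpers.

#' @importFrom stats qnorm pnorm approx rnorm runif sd t.test qt
NULL

# complementary error function and its inverse via the normal CDF
erfc_ <- function(x) 2 * pnorm(-sqrt(2) * x)

erfcinv_ <- function(y) {
  stopifnot(all(y > 0 & y < 2))
  qnorm(y / 2, lower.tail = FALSE) / sqrt(2)
}

# cumulative trapezoidal integral of y over x, starting at 0
cumtrapz_ <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
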