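#' @import data.table
#' @importFrom stats dnbinom dgamma pgamma qgamma dnorm pnorm qnorm pchisq
#'   pt rnorm runif rbinom rpois rgamma rmultinom lm median sd mad coef
#'   setNames integrate optim quantile
#' @importFrom utils head tail
NULL

# numerically stable log(sum(exp(x))) along rows of a two-column matrix
logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  # both -Inf: result -Inf, avoid NaN
  out <- m + log(exp(x - m) + exp(y - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Round half away from zero
#'
#' Fixed-precision rounding where .5 always rounds up in magnitude
#' (`round_half_up(0.125, 2) == 0.13`), the convention used by most
#' clinical tables, unlike [round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# format a number at fixed precision with half-up rounding ("0.79")
fmt_num <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# "est (lo, hi)" at fixed precision, e.g. "0.79 (0.72, 0.88)"
fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf("%s (%s, %s)", fmt_num(est, digits), fmt_num(lo, digits),
          fmt_num(hi, digits))
}

# derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) + 7919L * as.integer(stream)) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
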