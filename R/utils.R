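#' @useDynLib blanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd aov uniroot var median approx pnorm
#' @importFrom utils read.csv write.csv
NULL

# x/(exp(x/y) - 1) with the removable singularity at x = 0 resolved by its
# Taylor limit (value y - x/2 as x -> 0).  The workhorse for all "trap"-form
# opening/closing rates.
vtrap <- function(x, y) {
  out <- numeric(length(x))
  small <- abs(x / y) < 1e-6
  out[small] <- y * (1 - x[small] / (2 * y))
  xs <- x[!small]
  out[!small] <- xs / (exp(xs / y) - 1)
  out
}

# Deterministic sub-seed for a named random substream.  Every source of
# randomness (placement, wiring, weights, afferent trains, OU noise) draws from
# its own substream so that, e.g., an ablated network re-uses the identical
# structure and noise of its parent run.
sub_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
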