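# internal helpers shared across pipeline stages

Z75 <- stats::qnorm(0.75)

#' Derive a deterministic 32-bit seed from a master seed and labels
#'
#' Stable string hash used to split one pipeline seed into independent
#' per-stage / per-specimen / per-projection substreams, so that stages do
#' not share RNG state and any single phantom can be regenerated in
#' isolation.
#'
#' @param seed master integer seed.
#' @param ... labels (stage name, specimen id, projection index, ...).
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, ...) {
  s <- paste(as.integer(seed), paste(..., sep = "/"), sep = "/")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483563
  as.integer(h)
}

#' Quantile function of a two-piece (split) log-normal
#'
#' ln X is split-normal: scale `(ln m - ln q1)/z75` below the median and
#' `(ln q3 - ln m)/z75` above it, so the quartiles of X are exactly
#' (q1, m, q3). Degenerate triples (q1 = m = q3) give a point mass at m.
#'
#' @param p probabilities in (0, 1).
#' @param q1,med,q3 target quartiles, positive, non-decreasing.
#' @return quantiles of the split log-normal.
#' @keywords internal
qsplitlnorm <- function(p, q1, med, q3) {
  z <- stats::qnorm(p)
  s_lo <- (log(med) - log(q1)) / Z75
  s_hi <- (log(q3) - log(med)) / Z75
  exp(log(med) + ifelse(z < 0, s_lo, s_hi) * z)
}

#' Smooth spatially correlated standard-normal field
#'
#' Draws an iid N(0,1) field and convolves it (circularly, via FFT) with a
#' Gaussian kernel of width `sigma` pixels, dividing by the kernel l2-norm
#' so every pixel is exactly N(0,1) marginally. Uses the current RNG state.
#'
#' @param h,w field dimensions in pixels.
#' @param sigma Gaussian correlation length in pixels; 0 disables smoothing.
#' @return an h x w numeric matrix.
#' @keywords internal
gaussian_field <- function(h, w, sigma = 3) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma <= 0) return(z)
  dy <- pmin(0:(h - 1), h - (0:(h - 1)))
  dx <- pmin(0:(w - 1), w - (0:(w - 1)))
  k <- outer(exp(-dy^2 / (2 * sigma^2)), exp(-dx^2 / (2 * sigma^2)))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (h * w)
  sm / sqrt(sum(k^2))
}

#' Quartiles (q1, median, q3) with linear interpolation
#' @param x numeric vector.
#' @return length-3 named numeric vector.
#' @keywords internal
quartiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  names(q) <- c("q1", "median", "q3")
  q
}

#' Wrap angles to (-pi, pi]
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
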