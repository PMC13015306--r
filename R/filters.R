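## Narrowband IIR filtering primitives.
##
## A 3rd-order Butterworth bandpass at 0.1-0.5 Hz on a 1 kHz signal has
## normalized corner frequencies of 2e-4 and 1e-3: the single transfer-function
## (b, a) form of that filter is numerically singular in double precision, so
## all design and application here works on cascaded second-order sections.

## Analog Butterworth lowpass prototype poles for given order.
butter_prototype_poles <- function(order) {
  k <- seq_len(order)
  complex(modulus = 1, argument = pi * (2 * k + order - 1) / (2 * order))
}

## Bilinear transform of one analog conjugate pole pair (zeros supplied in z).
bilinear_pole <- function(p, fs) (1 + p / (2 * fs)) / (1 - p / (2 * fs))

sos_response <- function(sos, f, fs) {
  z <- exp(2i * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (s in sos) {
    H <- H * (s$b[1] + s$b[2] / z + s$b[3] / z^2) /
      (s$a[1] + s$a[2] / z + s$a[3] / z^2)
  }
  H
}

#' Design a Butterworth bandpass as second-order sections
#'
#' Analog prototype -> lowpass-to-bandpass transform -> bilinear transform with
#' frequency prewarping, returned as a cascade of biquads with unit gain at the
#' geometric center frequency. The cascade form stays numerically sound for
#' very narrow normalized bands (e.g. 0.1-0.5 Hz at 1 kHz), where the expanded
#' polynomial form breaks down.
#'
#' @param order analog prototype order (the bandpass has `2 * order` poles).
#' @param band_low,band_high passband edges in Hz.
#' @param fs sampling rate in Hz.
#' @return object of class `sos_filter`: a list of sections, each with
#'   3-vectors `b` and `a`.
#' @export
butter_bandpass_sos <- function(order, band_low, band_high, fs) {
  stopifnot(is_count(order), is_num1(band_low), is_num1(band_high), is_num1(fs))
  if (!(band_low > 0 && band_low < band_high && band_high < fs / 2))
    stopf("need 0 < band_low < band_high < fs/2 (got %g, %g at fs=%g)",
          band_low, band_high, fs)
  wl <- 2 * fs * tan(pi * band_low / fs)   # prewarped rad/s
  wh <- 2 * fs * tan(pi * band_high / fs)
  B <- wh - wl
  w0 <- sqrt(wl * wh)
  a <- butter_prototype_poles(order) * B / 2
  poles <- c(a + sqrt(a^2 - w0^2), a - sqrt(a^2 - w0^2))
  zp <- bilinear_pole(poles, fs)
  pos <- zp[Im(zp) > 0]
  sos <- lapply(pos, function(p) {
    list(b = c(1, 0, -1),                   # zeros at z = +1 and z = -1
         a = c(1, -2 * Re(p), Mod(p)^2))
  })
  g <- Mod(sos_response(sos, sqrt(band_low * band_high), fs))
  sos[[1]]$b <- sos[[1]]$b / g
  structure(sos, class = "sos_filter", fs = fs,
            band = c(band_low, band_high), order = order)
}

#' Design a notch biquad
#'
#' Standard second-order IIR notch with -3 dB bandwidth `freq / q`.
#'
#' @param freq notch center frequency in Hz (must be below Nyquist).
#' @param q quality factor.
#' @param fs sampling rate in Hz.
#' @return object of class `sos_filter` with a single section.
#' @export
notch_sos <- function(freq, q, fs) {
  stopifnot(is_num1(freq), is_num1(q), is_num1(fs))
  if (freq >= fs / 2)
    stopf("notch frequency %g Hz is at or above Nyquist (%g Hz)", freq, fs / 2)
  w0 <- 2 * pi * freq / fs
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  sos <- list(list(b = gain * c(1, -2 * cos(w0), 1),
                   a = c(1, -2 * gain * cos(w0), 2 * gain - 1)))
  structure(sos, class = "sos_filter", fs = fs, notch = freq, q = q)
}

apply_sos_once <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

#' Zero-phase application of a second-order-section cascade
#'
#' Forward-backward filtering with odd-reflection padding at both ends, so
#' that detected extremum times carry no group delay and startup transients
#' decay inside the padding rather than the data. The effective magnitude
#' response is the squared single-pass response.
#'
#' @param x numeric signal.
#' @param sos an `sos_filter`.
#' @param pad_n padding length in samples on each side (capped at
#'   `length(x) - 1`).
#' @return filtered numeric vector, same length as `x`.
#' @export
sos_filtfilt <- function(x, sos, pad_n) {
  n <- length(x)
  stopifnot(inherits(sos, "sos_filter"), n > 2L, is_num1(pad_n))
  pad_n <- min(as.integer(pad_n), n - 1L)
  pre <- 2 * x[1] - x[(pad_n + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad_n)]
  y <- c(pre, x, post)
  y <- apply_sos_once(sos, y)
  y <- rev(apply_sos_once(sos, rev(y)))
  y[(pad_n + 1L):(pad_n + n)]
}

## Analytic signal by the FFT half-spectrum method. The input is continued by
## odd reflection to an FFT-friendly length (mixed-radix FFTs of awkward prime
## lengths are quadratic in R).
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 8L)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  if (m > n) {
    k <- m - n
    ext <- 2 * x[n] - x[(n - 1L):(n - k)]
    xx <- c(x, ext)
  } else xx <- x
  X <- fft(xx)
  h <- numeric(m)
  if (m %% 2L == 0L) {
    h[1L] <- 1; h[m / 2L + 1L] <- 1
    h[2L:(m / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((m + 1L) / 2L)] <- 2
  }
  a <- fft(X * h, inverse = TRUE) / m
  a[seq_len(n)]
}
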