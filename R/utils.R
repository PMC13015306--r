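`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

is_num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Deterministic child seed
#'
#' Derives a per-unit seed from a pipeline-level seed so that unit `i`
#' regenerated alone equals unit `i` from a batch. Kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param index positive integer unit index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is_num1(seed), is_count(index))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + index * 16807) %% m)
}

## wrap angles (degrees) to (-180, 180]
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180] <- y[y <= -180] + 360  # defensive; %% already yields [0, 360)
  y
}

trapz_int <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}
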