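#' Scalar sample series
#'
#' Light container for a stream of scalar samples (reaction-coordinate
#' values, restraint-energy differences) with its provenance: the sample
#' index or time column, the RNG seed that produced it, and free-form
#' metadata such as the Metropolis acceptance fraction.
#'
#' @param value numeric samples
#' @param time sample index or time; defaults to 0-based index
#' @param seed RNG seed that generated the series, or `NA`
#' @param meta named list of extra metadata
#' @return object of class `sample_series`
#' @export
sample_series <- function(value, time = NULL, seed = NA_integer_, meta = list()) {
  stopifnot(is.numeric(value))
  if (is.null(time)) time <- seq_along(value) - 1
  stopifnot(length(time) == length(value))
  structure(list(value = as.numeric(value), time = as.numeric(time),
                 seed = seed, meta = meta),
            class = "sample_series")
}

#' @export
length.sample_series <- function(x) length(x$value)

#' @export
as.numeric.sample_series <- function(x, ...) x$value

#' @export
mean.sample_series <- function(x, ...) mean(x$value, ...)

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series> n = %d, mean = %.4g, sd = %.4g",
              length(x$value), mean(x$value), stats::sd(x$value)))
  if (!is.na(x$seed)) cat(sprintf(", seed = %d", x$seed))
  if (!is.null(x$meta$acceptance))
    cat(sprintf(", acceptance = %.2f", x$meta$acceptance))
  cat("\n")
  invisible(x)
}

#' Statistical inefficiency of a correlated series
#'
#' g = 1 + 2 * tau, where tau is the integrated autocorrelation time
#' (summed until the estimated autocorrelation first drops below zero).
#' Effective sample size is n / g. Used to de-bias histogram count errors
#' from Markov-chain samplers.
#'
#' @param x numeric vector or [sample_series()]
#' @param max_lag cap on summed lags (default `min(n/2, 2000)`; the
#'   integrated time of any usably mixing chain is far shorter)
#' @return statistical inefficiency g >= 1
#' @export
statistical_inefficiency <- function(x, max_lag = NULL) {
  if (inherits(x, "sample_series")) x <- x$value
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(1)
  if (is.null(max_lag)) max_lag <- min(n %/% 2, 2000L)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  neg <- which(ac <= 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  g <- 1 + 2 * sum(ac * (1 - seq_along(ac) / n))
  max(1, g)
}
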