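#' Unit-peak hemodynamic response kernel
#'
#' Single-gamma kernel parameterized directly by its timing landmarks: it is
#' zero at the event, rises to a unit peak at `peak_time`, and has decayed to
#' 5% of the peak at `return_time`, monotonically decreasing thereafter.
#'
#' The functional form is `h(t) = (t/p)^(p/b) * exp((p - t)/b)` with peak
#' `p = peak_time` and decay scale `b` solved in closed form so that
#' `h(return_time) = 0.05`.
#'
#' @param params An [hrf_params()] object.
#' @param sample_rate Sampling rate in Hz (default 50).
#' @param duration Kernel support in seconds (default `return_time + 25`,
#'   beyond which the kernel is numerically negligible).
#'
#' @return An `hrf_kernel` object: list with `time` (seconds, starting at 0),
#'   `value` (unit peak) and the parameters.
#' @export
hrf_kernel <- function(params = hrf_params(), sample_rate = 50,
                       duration = params$return_time + 25) {
  stopifnot(inherits(params, "hrf_params"))
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be positive.", call. = FALSE)
  }
  p <- params$peak_time
  r <- params$return_time
  if (p >= r) stop("`peak_time` must be less than `return_time`.", call. = FALSE)
  # h(r) = 0.05  =>  b = (p*log(r/p) + p - r) / log(0.05)
  b <- (p * log(r / p) + p - r) / log(0.05)
  a <- p / b
  t <- seq(0, duration, by = 1 / sample_rate)
  value <- ifelse(t <= 0, 0, (t / p)^a * exp((p - t) / b))
  structure(
    list(time = t, value = value, peak_time = p, return_time = r,
         shape = a, scale = b, sample_rate = sample_rate),
    class = "hrf_kernel"
  )
}

#' Median of the HRF kernel over the HDR statistic window
#'
#' The expected value of the median-window HDR statistic for a noise-free
#' unit-amplitude response: the median of the unit kernel over the post-onset
#' statistic window (default 5-20 s). Multiplying by a condition amplitude
#' gives that condition's expected median HDR.
#'
#' @param params An [hrf_params()] object.
#' @param window Statistic window in seconds after onset (default `c(5, 20)`).
#' @param sample_rate Sampling rate in Hz (default 50).
#'
#' @return A single number in (0, 1].
#' @export
hrf_window_median <- function(params = hrf_params(), window = c(5, 20),
                              sample_rate = 50) {
  k <- hrf_kernel(params, sample_rate = sample_rate,
                  duration = max(window) + 1)
  keep <- k$time >= window[1] & k$time <= window[2]
  stats::median(k$value[keep])
}
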