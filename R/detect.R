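# Swallow-onset detection: rectified accelerometer -> Bartlett-smoothed
# envelope -> derivative -> first positive zero-crossing inside a respiratory
# apnea.

# Centered running mean with edge replication; O(n) via cumulative sums.
running_mean <- function(x, width) {
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(width):length(xp)] - c(0, cs[seq_len(length(xp) - width)])) / width
}

#' Smoothed rectified accelerometer envelope
#'
#' Rectifies the signal and smooths it with a centered triangular (Bartlett)
#' window of `window` taps with unit weight sum, so a constant input maps to
#' its absolute value and the filter introduces no lag. The triangular window
#' is realized as two passes of a `(window + 1)/2`-point moving average
#' (a boxcar self-convolution), giving center tap weight `2/(window + 1)`.
#'
#' @param x Numeric accelerometer signal.
#' @param window Window length in samples; must be odd (default 201).
#'
#' @return Numeric envelope, same length as `x`.
#' @export
accel_envelope <- function(x, window = 201) {
  if (window %% 2 == 0) {
    stop("`window` must be odd.", call. = FALSE)
  }
  if (window < 3) return(abs(x))
  m <- (window + 1L) %/% 2L
  if (m %% 2 == 1) {
    # boxcar self-convolution: two centered m-point moving averages
    return(running_mean(running_mean(abs(x), m), m))
  }
  # general odd window: direct convolution with triangular weights
  w <- (m - abs(seq(-(m - 1L), m - 1L))) / m^2
  half <- m - 1L
  ax <- abs(x)
  xp <- c(rep(ax[1], half), ax, rep(ax[length(ax)], half))
  out <- stats::filter(xp, w, sides = 2)
  as.numeric(out[(half + 1L):(half + length(ax))])
}

#' Central-difference derivative
#'
#' First derivative estimate: central differences scaled by the sample rate
#' in the interior, one-sided differences at the endpoints.
#'
#' @param x Numeric series (at least 2 samples).
#' @param sample_rate Sampling rate in Hz.
#'
#' @return Numeric derivative, same length as `x`, in units of `x` per second.
#' @export
signal_derivative <- function(x, sample_rate) {
  n <- length(x)
  if (n < 2) stop("Need at least 2 samples.", call. = FALSE)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * sample_rate
  d[n] <- (x[n] - x[n - 1]) * sample_rate
  if (n > 2) {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * sample_rate / 2
  }
  d
}

#' Detect respiratory apnea intervals
#'
#' Finds maximal intervals where the magnitude of the smoothed respiration
#' derivative stays below a fraction of its record-wide median for at least
#' `min_duration` seconds -- the flattening of the respiratory trace that
#' accompanies a pharyngeal swallow.
#'
#' @param resp Numeric respiration signal.
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param deriv_threshold_fraction Threshold as a fraction of the median
#'   absolute derivative (default 0.1).
#' @param min_duration Minimum apnea duration in seconds (default 0.75).
#' @param smooth_s Pre-derivative moving-average smoothing span in seconds
#'   (default 0.15).
#'
#' @return Tibble of non-overlapping, sorted `start`/`end` times (seconds).
#'   An all-constant record (no respiratory modulation at all) is flagged as
#'   a single full-record interval with a warning.
#' @export
detect_apnea <- function(resp, sample_rate = 1000,
                         deriv_threshold_fraction = 0.1,
                         min_duration = 0.75, smooth_s = 0.15) {
  if (any(!is.finite(resp))) stop("Respiration signal must be finite.",
                                  call. = FALSE)
  n <- length(resp)
  if (n < min_duration * sample_rate) {
    stop("Record shorter than `min_duration`.", call. = FALSE)
  }
  w <- max(3L, round(smooth_s * sample_rate))
  if (w %% 2 == 0) w <- w + 1L
  d <- signal_derivative(running_mean(resp, w), sample_rate)
  absd <- abs(d)
  med <- stats::median(absd)
  if (med <= .Machine$double.eps * max(absd, 1)) {
    warning("Respiration record has no modulation; flagging entire record ",
            "as one apnea.", call. = FALSE)
    return(tibble::tibble(start = 0, end = (n - 1) / sample_rate))
  }
  thr <- deriv_threshold_fraction * med
  below <- absd < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration * sample_rate
  tibble::tibble(
    start = (starts[keep] - 1L) / sample_rate,
    end = (ends[keep] - 1L) / sample_rate
  )
}

#' Detect swallow onsets from the envelope derivative
#'
#' Within each apnea interval, the onset candidate is the first sample where
#' the derivative transitions from non-positive to positive and remains
#' positive for `persistence` consecutive samples (suppressing noise-induced
#' zero-crossing chatter). At most one onset is returned per apnea; onsets
#' closer together than `refractory` seconds are deduplicated keeping the
#' earlier one.
#'
#' @param deriv Numeric derivative series (from [signal_derivative()] of the
#'   envelope).
#' @param sample_rate Sampling rate of `deriv` in Hz.
#' @param apneas Tibble of apnea `start`/`end` times (seconds), on the same
#'   time base as `deriv`.
#' @param refractory Minimum separation between onsets in seconds (default 2).
#' @param persistence Samples the derivative must stay positive after the
#'   crossing (default 25).
#'
#' @return Numeric vector of onset times in seconds (possibly empty).
#' @export
detect_onsets <- function(deriv, sample_rate, apneas,
                          refractory = 2, persistence = 25) {
  if (is.null(apneas) || nrow(apneas) == 0) return(numeric(0))
  n <- length(deriv)
  pos <- deriv > 0
  # remaining length of the positive run starting at/continuing through i
  r <- rle(pos)
  grp_end <- rep.int(cumsum(r$lengths), r$lengths)
  fwd <- grp_end - seq_len(n) + 1L
  crossing <- pos & !c(TRUE, pos[-n]) & fwd >= persistence
  cand_idx <- which(crossing)
  if (length(cand_idx) == 0) return(numeric(0))
  cand_t <- (cand_idx - 1) / sample_rate
  onsets <- numeric(0)
  for (k in seq_len(nrow(apneas))) {
    inside <- cand_t[cand_t >= apneas$start[k] & cand_t <= apneas$end[k]]
    if (length(inside) > 0) onsets <- c(onsets, inside[1])
  }
  onsets <- sort(onsets)
  kept <- numeric(0)
  for (o in onsets) {
    if (length(kept) == 0 || o - kept[length(kept)] >= refractory) {
      kept <- c(kept, o)
    }
  }
  kept
}

#' Label detected onsets with protocol conditions
#'
#' Assigns each onset the block, head position and within-segment ordinal of
#' the schedule segment containing it (half-open segments `[start, end)`).
#' Onsets falling in inter-block rest periods (or the session tail) are kept
#' but flagged `verified = FALSE` and carry no condition labels; onsets
#' outside the session entirely raise an integrity error.
#'
#' @param onsets Numeric vector of onset times (seconds).
#' @param schedule A [make_schedule()] result.
#'
#' @return Tibble of swallow events: `onset`, `block`, `position`,
#'   `ordinal`, `verified`, sorted by onset. Labeling is idempotent: applying
#'   it to already-labeled onset times reproduces the same labels.
#' @export
assign_conditions <- function(onsets, schedule) {
  stopifnot(inherits(schedule, "swallow_schedule"))
  if (length(onsets) == 0) {
    return(tibble::tibble(onset = numeric(), block = integer(),
                          position = character(), ordinal = integer(),
                          verified = logical()))
  }
  if (min(onsets) < 0 || max(onsets) > schedule$duration) {
    stop(sprintf("Onset at %.2f s lies outside the session [0, %.2f].",
                 onsets[which.max(abs(onsets - schedule$duration / 2))],
                 schedule$duration), call. = FALSE)
  }
  onsets <- sort(onsets)
  seg <- schedule$segments
  block <- rep(NA_integer_, length(onsets))
  position <- rep(NA_character_, length(onsets))
  seg_id <- rep(NA_integer_, length(onsets))
  for (i in seq_along(onsets)) {
    hit <- which(seg$start <= onsets[i] & onsets[i] < seg$end)
    if (length(hit) == 1) {
      block[i] <- as.integer(seg$block[hit])
      position[i] <- seg$position[hit]
      seg_id[i] <- hit
    }
  }
  out <- tibble::tibble(onset = onsets, block = block, position = position,
                        seg_id = seg_id)
  out <- out |>
    dplyr::group_by(.data$seg_id) |>
    dplyr::mutate(ordinal = ifelse(is.na(.data$seg_id), NA_integer_,
                                   dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(verified = !is.na(.data$position)) |>
    dplyr::select("onset", "block", "position", "ordinal", "verified")
  out
}

#' Detect and label swallow events in a session
#'
#' Runs the full onset-detection chain on a session recording: rectified
#' Bartlett-smoothed accelerometer envelope, central-difference derivative,
#' respiration-derived apnea gating, first-positive-zero-crossing onset
#' detection, and schedule-based condition labeling. Each event is annotated
#' with the apnea interval that gated it.
#'
#' @param session A `session_recording` (see [simulate_session()] /
#'   [read_session()]).
#' @param envelope_window Bartlett window length in samples (default 201).
#' @param apnea_params List of overrides for [detect_apnea()]
#'   (`deriv_threshold_fraction`, `min_duration`, `smooth_s`).
#' @param refractory,persistence Passed to [detect_onsets()].
#'
#' @return Tibble of swallow events: `onset`, `block`, `position`, `ordinal`,
#'   `apnea_start`, `apnea_end`, `verified`.
#' @export
detect_swallows <- function(session, envelope_window = 201,
                            apnea_params = list(), refractory = 2,
                            persistence = 25) {
  stopifnot(inherits(session, "session_recording"))
  env <- accel_envelope(session$accel, window = envelope_window)
  d <- signal_derivative(env, session$sample_rates$accel)
  apneas <- do.call(detect_apnea,
                    c(list(resp = session$resp,
                           sample_rate = session$sample_rates$resp),
                      apnea_params))
  onsets <- detect_onsets(d, session$sample_rates$accel, apneas,
                          refractory = refractory, persistence = persistence)
  events <- assign_conditions(onsets, session$schedule)
  if (nrow(events) > 0 && nrow(apneas) > 0) {
    ai <- vapply(events$onset, function(o) {
      hit <- which(apneas$start <= o & o <= apneas$end)
      if (length(hit) >= 1) hit[1] else NA_integer_
    }, integer(1))
    events$apnea_start <- apneas$start[ai]
    events$apnea_end <- apneas$end[ai]
  } else {
    events$apnea_start <- numeric(nrow(events))
    events$apnea_end <- numeric(nrow(events))
  }
  dplyr::relocate(events, "verified", .after = "apnea_end")
}
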