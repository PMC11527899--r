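#' Experimental protocol specification
#'
#' Describes the blocked water-swallowing protocol: repeated blocks in which
#' the participant holds each of three head positions (chin-down, chin-neutral,
#' chin-up) in randomized order while receiving water boluses at a fixed
#' cadence, swallowing once per bolus.
#'
#' @param n_blocks Number of recording blocks (default 4).
#' @param positions Ordered head-position labels; the factor levels used
#'   throughout the pipeline. Default `c("down", "neutral", "up")`.
#' @param swallows_per_position_per_block Consecutive swallows completed in
#'   each head position within a block (default 8).
#' @param inter_swallow_interval Seconds between successive swallow onsets
#'   within a position segment (default 38).
#' @param bolus_volume Bolus volume in ml (default 5).
#' @param bolus_duration Seconds over which each bolus is delivered (default 3;
#'   delivery begins this long before the expected swallow).
#' @param pump_rate Pump flow rate in ml/min (default 100).
#' @param inter_block_rest Seconds of rest between blocks (default 210).
#' @param first_onset_offset Seconds from the start of a position segment to
#'   the first planned swallow onset (default 15; leaves room for the 10 s
#'   pre-onset epoch window).
#' @param position_order_seed Optional integer seed controlling the
#'   per-block randomization of head-position order in [make_schedule()].
#'
#' @return A `protocol_spec` object (a validated list).
#' @seealso [make_schedule()]
#' @export
protocol_spec <- function(n_blocks = 4,
                          positions = c("down", "neutral", "up"),
                          swallows_per_position_per_block = 8,
                          inter_swallow_interval = 38,
                          bolus_volume = 5,
                          bolus_duration = 3,
                          pump_rate = 100,
                          inter_block_rest = 210,
                          first_onset_offset = 15,
                          position_order_seed = NULL) {
  if (!is.numeric(n_blocks) || n_blocks < 1 || n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a positive integer.", call. = FALSE)
  }
  if (length(positions) < 1 || anyDuplicated(positions)) {
    stop("`positions` must be distinct labels.", call. = FALSE)
  }
  spp <- swallows_per_position_per_block
  if (!is.numeric(spp) || spp < 1 || spp != round(spp)) {
    stop("`swallows_per_position_per_block` must be a positive integer.",
         call. = FALSE)
  }
  for (nm in c("inter_swallow_interval", "bolus_volume", "bolus_duration",
               "pump_rate", "first_onset_offset")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number.", nm), call. = FALSE)
    }
  }
  if (inter_block_rest < 0) {
    stop("`inter_block_rest` must be non-negative.", call. = FALSE)
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      positions = as.character(positions),
      swallows_per_position_per_block = as.integer(spp),
      inter_swallow_interval = inter_swallow_interval,
      bolus_volume = bolus_volume,
      bolus_duration = bolus_duration,
      pump_rate = pump_rate,
      inter_block_rest = inter_block_rest,
      first_onset_offset = first_onset_offset,
      position_order_seed = position_order_seed
    ),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>\n")
  cat(sprintf("  %d block(s) x %d position(s) x %d swallow(s)/segment (%d total)\n",
              x$n_blocks, length(x$positions),
              x$swallows_per_position_per_block,
              x$n_blocks * length(x$positions) *
                x$swallows_per_position_per_block))
  cat(sprintf("  onset spacing %g s, bolus %g ml over %g s at %g ml/min\n",
              x$inter_swallow_interval, x$bolus_volume, x$bolus_duration,
              x$pump_rate))
  cat(sprintf("  inter-block rest %g s\n", x$inter_block_rest))
  invisible(x)
}

#' Default fNIRS montage
#'
#' Ten long emitter-detector pairs at 3 cm separation, five per hemisphere,
#' covering premotor cortex (pairing 1), precentral gyrus (pairings 2-3) and
#' postcentral gyrus (pairings 4-5). Optionally one short-separation channel
#' per hemisphere (0.8 cm) sampling only superficial scalp hemodynamics, for
#' use as a nuisance regressor.
#'
#' @param short_channels Include one short-separation channel per hemisphere
#'   (default `TRUE`).
#' @param separation Long-channel source-detector separation in cm (default 3).
#' @param short_separation Short-channel separation in cm (default 0.8).
#' @param wavelengths The two laser wavelengths in nm (default 790 and 830).
#'
#' @return A `channel_set` tibble with columns `channel`, `emitter`,
#'   `detector`, `hemisphere` ("L"/"R"), `roi`, `separation` (cm) and
#'   `type` ("long"/"short").
#' @export
default_montage <- function(short_channels = TRUE,
                            separation = 3,
                            short_separation = 0.8,
                            wavelengths = c(790, 830)) {
  roi <- c("premotor", "precentral", "precentral", "postcentral", "postcentral")
  long <- tibble::tibble(
    channel = c(paste0("L", 1:5), paste0("R", 1:5)),
    emitter = c(paste0("E-L", 1:5), paste0("E-R", 1:5)),
    detector = c(paste0("D-L", 1:5), paste0("D-R", 1:5)),
    hemisphere = rep(c("L", "R"), each = 5),
    roi = rep(roi, 2),
    separation = separation,
    type = "long"
  )
  out <- long
  if (isTRUE(short_channels)) {
    short <- tibble::tibble(
      channel = c("SS-L", "SS-R"),
      emitter = c("E-L1", "E-R1"),
      detector = c("Dss-L", "Dss-R"),
      hemisphere = c("L", "R"),
      roi = "superficial",
      separation = short_separation,
      type = "short"
    )
    out <- dplyr::bind_rows(long, short)
  }
  attr(out, "wavelengths") <- wavelengths
  class(out) <- c("channel_set", class(out))
  out
}

#' Hemodynamic response parameters
#'
#' Timing landmarks and condition amplitudes of the swallow-locked
#' hemodynamic response used by the forward generator. The response peaks
#' 4-6 s after the event and has returned close to baseline by 20-30 s; the
#' generator parameterizes a single-gamma kernel directly by those landmarks.
#'
#' @param peak_time Seconds from event onset to the kernel peak (default 5).
#' @param return_time Seconds at which the kernel has decayed to 5% of its
#'   peak (default 25).
#' @param amplitude_by_position Named numeric: peak oxyhemoglobin response
#'   amplitude (uM) per head position. Defaults down 0.6, neutral 0.9,
#'   up 1.4, matching the order of magnitude of reported group means.
#' @param hbr_ratio Scaling of the deoxyhemoglobin response relative to the
#'   oxyhemoglobin response (default -1/3, the usual inverted, smaller HbR
#'   response).
#'
#' @return An `hrf_params` object.
#' @seealso [hrf_kernel()]
#' @export
hrf_params <- function(peak_time = 5,
                       return_time = 25,
                       amplitude_by_position = c(down = 0.6, neutral = 0.9,
                                                 up = 1.4),
                       hbr_ratio = -1 / 3) {
  if (!is.numeric(peak_time) || peak_time <= 0) {
    stop("`peak_time` must be positive.", call. = FALSE)
  }
  if (!is.numeric(return_time) || return_time <= peak_time) {
    stop("`return_time` must exceed `peak_time`.", call. = FALSE)
  }
  if (is.null(names(amplitude_by_position)) ||
      any(!nzchar(names(amplitude_by_position)))) {
    stop("`amplitude_by_position` must be a named numeric vector.",
         call. = FALSE)
  }
  structure(
    list(
      peak_time = peak_time,
      return_time = return_time,
      amplitude_by_position = amplitude_by_position,
      hbr_ratio = hbr_ratio
    ),
    class = "hrf_params"
  )
}

#' Physiological and instrumental noise parameters
#'
#' Amplitudes (uM) and frequencies (Hz) of the structured physiological
#' noise superimposed on the simulated concentration series: cardiac
#' pulsation, respiration, Mayer waves, a low-frequency random-walk drift,
#' white sensor noise, and sparse motion artifacts (single-sample spikes and
#' step shifts that persist to the end of the block).
#'
#' @param cardiac `c(freq, amp)` of the cardiac oscillation (default 1.1 Hz,
#'   0.30 uM).
#' @param respiratory `c(freq, amp)` of the respiratory oscillation (default
#'   0.25 Hz, 0.20 uM).
#' @param mayer `c(freq, amp)` of Mayer waves (default 0.1 Hz, 0.15 uM).
#' @param drift_sd Per-sample standard deviation of the random-walk drift
#'   increment (uM; default 0.002).
#' @param white_sd Standard deviation of white sensor noise (uM; default 0.1).
#' @param motion_spike_rate Expected motion spikes per minute (default 0.5).
#' @param motion_shift_rate Expected baseline shifts per minute (default 0.1).
#' @param spike_scale Laplacian scale of spike amplitudes (uM; default 1).
#' @param shift_scale Standard deviation of shift amplitudes (uM; default 0.3).
#'
#' @return A `noise_params` object.
#' @export
noise_params <- function(cardiac = c(1.1, 0.30),
                         respiratory = c(0.25, 0.20),
                         mayer = c(0.1, 0.15),
                         drift_sd = 0.002,
                         white_sd = 0.1,
                         motion_spike_rate = 0.5,
                         motion_shift_rate = 0.1,
                         spike_scale = 1,
                         shift_scale = 0.3) {
  for (nm in c("cardiac", "respiratory", "mayer")) {
    v <- get(nm)
    if (length(v) != 2 || any(!is.finite(v)) || v[2] < 0) {
      stop(sprintf("`%s` must be c(freq, amp) with amp >= 0.", nm),
           call. = FALSE)
    }
    if (v[1] <= 0 || v[1] >= 25) {
      stop(sprintf("`%s` frequency must lie in (0, 25) Hz (Nyquist at 50 Hz).",
                   nm), call. = FALSE)
    }
  }
  for (nm in c("drift_sd", "white_sd", "motion_spike_rate",
               "motion_shift_rate", "spike_scale", "shift_scale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number.", nm),
           call. = FALSE)
    }
  }
  structure(
    list(cardiac = cardiac, respiratory = respiratory, mayer = mayer,
         drift_sd = drift_sd, white_sd = white_sd,
         motion_spike_rate = motion_spike_rate,
         motion_shift_rate = motion_shift_rate,
         spike_scale = spike_scale, shift_scale = shift_scale),
    class = "noise_params"
  )
}

#' Noise parameters with every component switched off
#'
#' Convenience constructor for noise-free forward simulations, used by the
#' round-trip and amplitude-recovery checks.
#'
#' @return A `noise_params` object with all amplitudes and rates zero.
#' @export
noise_off <- function() {
  noise_params(cardiac = c(1.1, 0), respiratory = c(0.25, 0),
               mayer = c(0.1, 0), drift_sd = 0, white_sd = 0,
               motion_spike_rate = 0, motion_shift_rate = 0,
               spike_scale = 0, shift_scale = 0)
}

#' Build the block/position/swallow schedule
#'
#' Lays out the session timeline: per block, the three head positions in a
#' seeded random order, each position held for one contiguous segment
#' containing `swallows_per_position_per_block` planned swallow onsets spaced
#' `inter_swallow_interval` seconds apart, with rest periods between blocks.
#'
#' @param protocol A [protocol_spec()].
#' @param seed Optional integer seed for the per-block position permutations;
#'   defaults to `protocol$position_order_seed`. `NULL` draws from the current
#'   RNG state.
#'
#' @return A `swallow_schedule` object with elements `segments` (tibble:
#'   `block`, `position`, `start`, `end`; half-open intervals in seconds),
#'   `onsets` (tibble: `block`, `position`, `ordinal`, `time`), `rests`
#'   (tibble: `start`, `end`), `duration` (seconds) and the protocol.
#' @export
make_schedule <- function(protocol = protocol_spec(),
                          seed = protocol$position_order_seed) {
  stopifnot(inherits(protocol, "protocol_spec"))
  draw <- function() {
    spp <- protocol$swallows_per_position_per_block
    seg_dur <- spp * protocol$inter_swallow_interval
    n_pos <- length(protocol$positions)
    segments <- vector("list", protocol$n_blocks)
    t0 <- 0
    rests <- list()
    for (b in seq_len(protocol$n_blocks)) {
      order_b <- sample(protocol$positions)
      segments[[b]] <- tibble::tibble(
        block = b,
        position = order_b,
        start = t0 + (seq_len(n_pos) - 1) * seg_dur,
        end = t0 + seq_len(n_pos) * seg_dur
      )
      t0 <- t0 + n_pos * seg_dur
      if (b < protocol$n_blocks && protocol$inter_block_rest > 0) {
        rests[[length(rests) + 1]] <-
          tibble::tibble(start = t0, end = t0 + protocol$inter_block_rest)
        t0 <- t0 + protocol$inter_block_rest
      }
    }
    segments <- dplyr::bind_rows(segments)
    onsets <- segments |>
      dplyr::rowwise() |>
      dplyr::reframe(
        block = .data$block,
        position = .data$position,
        ordinal = seq_len(spp),
        time = .data$start + protocol$first_onset_offset +
          (seq_len(spp) - 1) * protocol$inter_swallow_interval
      )
    # 30 s tail so the final epoch window and response decay stay in-record
    duration <- t0 + 30
    structure(
      list(segments = segments, onsets = onsets,
           rests = if (length(rests)) dplyr::bind_rows(rests) else
             tibble::tibble(start = numeric(), end = numeric()),
           duration = duration, protocol = protocol),
      class = "swallow_schedule"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.swallow_schedule <- function(x, ...) {
  cat("<swallow_schedule>\n")
  cat(sprintf("  %d planned onsets over %.0f s (%d block(s))\n",
              nrow(x$onsets), x$duration, x$protocol$n_blocks))
  print(dplyr::count(x$onsets, .data$position))
  invisible(x)
}
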