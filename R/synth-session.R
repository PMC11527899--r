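# Forward model of a recording session: everything the analysis later inverts.

laplace_rnd <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# Structured superficial (scalp) hemodynamic noise shared within a hemisphere.
superficial_noise <- function(t, noise) {
  osc <- function(fa) {
    if (fa[2] == 0) return(0)
    fa[2] * sin(2 * pi * fa[1] * t + stats::runif(1, 0, 2 * pi))
  }
  drift <- if (noise$drift_sd > 0) cumsum(stats::rnorm(length(t), 0, noise$drift_sd))
           else 0
  osc(noise$cardiac) + osc(noise$respiratory) + osc(noise$mayer) + drift
}

#' Simulate hemoglobin concentration series with ground-truth events
#'
#' Forward model of the concentration dynamics the processing chain assumes:
#' each long channel carries the sum of swallow-locked hemodynamic responses
#' (position-dependent amplitude times the unit HRF kernel), a
#' hemisphere-shared superficial physiological component (cardiac,
#' respiratory, Mayer waves, drift) scaled by a per-channel coupling, white
#' sensor noise, and sparse motion artifacts. Deoxyhemoglobin carries
#' `hbr_ratio` times the event component plus its own (smaller) noise.
#' Short-separation channels contain only the superficial component plus
#' white noise -- no event response.
#'
#' @param schedule A [make_schedule()] result.
#' @param channels A [default_montage()] channel set.
#' @param hrf An [hrf_params()] object.
#' @param noise A [noise_params()] object (use [noise_off()] for noise-free).
#' @param sample_rate fNIRS sampling rate in Hz (default 50).
#' @param seed Optional integer seed; `NULL` draws from the current RNG state.
#'
#' @return List with `conc` (a `conc_series` over all channels) and `events`
#'   (the ground-truth onset tibble from the schedule).
#' @export
simulate_concentrations <- function(schedule, channels = default_montage(),
                                    hrf = hrf_params(),
                                    noise = noise_params(),
                                    sample_rate = 50, seed = NULL) {
  stopifnot(inherits(schedule, "swallow_schedule"))
  run <- function() {
    t <- seq(0, schedule$duration, by = 1 / sample_rate)
    n <- length(t)
    nch <- nrow(channels)
    amp <- hrf$amplitude_by_position
    missing_pos <- setdiff(unique(schedule$onsets$position), names(amp))
    if (length(missing_pos) > 0) {
      stop(sprintf("No HRF amplitude for position(s): %s.",
                   paste(missing_pos, collapse = ", ")), call. = FALSE)
    }
    kern <- hrf_kernel(hrf, sample_rate = sample_rate)
    nk <- length(kern$value)

    # event regressor, unit amplitude per uM of response amplitude
    event_sig <- numeric(n)
    for (i in seq_len(nrow(schedule$onsets))) {
      i0 <- round(schedule$onsets$time[i] * sample_rate) + 1L
      idx <- i0:min(n, i0 + nk - 1L)
      event_sig[idx] <- event_sig[idx] +
        amp[[schedule$onsets$position[i]]] * kern$value[seq_along(idx)]
    }

    sup_hbo <- lapply(unique(channels$hemisphere),
                      function(h) superficial_noise(t, noise))
    names(sup_hbo) <- unique(channels$hemisphere)
    sup_hbr <- lapply(sup_hbo, function(s) {
      hrf$hbr_ratio * s + superficial_noise(t, noise) * 0.2
    })

    blocks <- schedule$segments |>
      dplyr::group_by(.data$block) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end))

    motion <- function() {
      m <- numeric(n)
      mins <- schedule$duration / 60
      nsp <- stats::rpois(1, noise$motion_spike_rate * mins)
      if (nsp > 0) {
        at <- sample.int(n, nsp)
        m[at] <- m[at] + laplace_rnd(nsp, noise$spike_scale)
      }
      nsh <- stats::rpois(1, noise$motion_shift_rate * mins)
      if (nsh > 0) {
        at <- stats::runif(nsh, 0, schedule$duration)
        for (tt in at) {
          b <- blocks[blocks$start <= tt & blocks$end > tt, ]
          end_t <- if (nrow(b) == 1) b$end else schedule$duration
          i1 <- round(tt * sample_rate) + 1L
          i2 <- min(n, round(end_t * sample_rate) + 1L)
          m[i1:i2] <- m[i1:i2] + stats::rnorm(1, 0, noise$shift_scale)
        }
      }
      m
    }

    hbo <- hbr <- matrix(0, n, nch,
                         dimnames = list(NULL, channels$channel))
    for (j in seq_len(nch)) {
      h <- channels$hemisphere[j]
      if (channels$type[j] == "long") {
        coupling <- stats::runif(1, 0.5, 1)
        mo <- motion()
        hbo[, j] <- event_sig + coupling * sup_hbo[[h]] +
          stats::rnorm(n, 0, noise$white_sd) + mo
        hbr[, j] <- hrf$hbr_ratio * event_sig + coupling * sup_hbr[[h]] +
          stats::rnorm(n, 0, noise$white_sd / 3) + mo
      } else {
        hbo[, j] <- sup_hbo[[h]] + stats::rnorm(n, 0, noise$white_sd / 2)
        hbr[, j] <- sup_hbr[[h]] + stats::rnorm(n, 0, noise$white_sd / 6)
      }
    }
    conc <- structure(
      list(time = t, hbo = hbo, hbr = hbr,
           channels = tibble::as_tibble(channels), sample_rate = sample_rate),
      class = "conc_series"
    )
    list(conc = conc, events = schedule$onsets)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Forward model: concentrations to raw two-wavelength intensity
#'
#' Applies the forward modified Beer-Lambert law and the exponential
#' attenuation model `I(lambda, t) = I0 * exp(-dOD(lambda, t))` to produce
#' the raw intensity the instrument would record.
#'
#' @param conc A `conc_series` object.
#' @param optics An [optics_table()].
#' @param i0 Emitted/baseline detected intensity (arbitrary units, default 1;
#'   must be positive).
#'
#' @return A `raw_intensity` object: list with `time`, `intensity` (named
#'   list of time-by-channel matrices per wavelength), `channels`, `i0`,
#'   `sample_rate`.
#' @export
concentrations_to_intensity <- function(conc, optics = default_optics(),
                                        i0 = 1) {
  if (!is.numeric(i0) || any(i0 <= 0)) {
    stop("`i0` must be positive.", call. = FALSE)
  }
  od <- conc_to_od(conc, optics)
  intensity <- lapply(od$od, function(m) i0 * exp(-m))
  structure(
    list(time = conc$time, intensity = intensity, channels = conc$channels,
         i0 = i0, sample_rate = conc$sample_rate),
    class = "raw_intensity"
  )
}

# Piecewise-linear amplitude profile of a laryngeal movement burst: a dip
# beginning before the swallow reaches its trough exactly at onset, then a
# steep rise and decay back to baseline within about a second.
burst_profile <- function(t, onset, dip_start = 0.6, dip_level = 0.3,
                          rise_dur = 0.35, peak = 5, end = 1.0) {
  a <- rep(NA_real_, length(t))
  tau <- t - onset
  seg <- tau >= -dip_start & tau < 0
  a[seg] <- 1 + (dip_level - 1) * (tau[seg] + dip_start) / dip_start
  seg <- tau >= 0 & tau < rise_dur
  a[seg] <- dip_level + (peak - dip_level) * tau[seg] / rise_dur
  seg <- tau >= rise_dur & tau < end
  a[seg] <- peak + (1 - peak) * (tau[seg] - rise_dur) / (end - rise_dur)
  a
}

#' Simulate the laryngeal accelerometer signal
#'
#' High-rate accelerometry of hyolaryngeal movement: a continuous oscillatory
#' carrier whose amplitude is modulated by per-swallow movement bursts, plus
#' white sensor noise. Each burst's smoothed-rectified envelope has a local
#' minimum (trough) exactly at the ground-truth onset followed by a steep
#' rise, so the envelope-derivative zero-crossing detector recovers the onset.
#'
#' @param events Numeric vector of ground-truth onset times (seconds).
#' @param duration Recording duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 4000).
#' @param carrier_freq Carrier frequency in Hz (default 80).
#' @param scale Overall signal scale (arbitrary units, default 0.5).
#' @param noise_sd White-noise standard deviation relative to `scale`
#'   (default 0.04).
#' @param seed Optional integer seed; `NULL` draws from the current RNG state.
#'
#' @return Numeric signal vector of length `duration * sample_rate + 1`.
#' @export
simulate_accelerometer <- function(events, duration, sample_rate = 4000,
                                   carrier_freq = 80, scale = 0.5,
                                   noise_sd = 0.04, seed = NULL) {
  if (length(events) > 0 && (min(events) < 0 || max(events) > duration)) {
    stop("Event times must lie within [0, duration].", call. = FALSE)
  }
  run <- function() {
    t <- seq(0, duration, by = 1 / sample_rate)
    amp <- rep(1, length(t))
    for (ev in events) {
      i1 <- max(1L, floor((ev - 0.6) * sample_rate) + 1L)
      i2 <- min(length(t), ceiling((ev + 1.0) * sample_rate) + 1L)
      idx <- i1:i2
      prof <- burst_profile(t[idx], ev)
      amp[idx] <- ifelse(is.na(prof), amp[idx], prof)
    }
    phi <- stats::runif(1, 0, 2 * pi)
    scale * amp * sin(2 * pi * carrier_freq * t + phi) +
      stats::rnorm(length(t), 0, scale * noise_sd)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the respiratory plethysmography signal
#'
#' Quasi-sinusoidal breathing at ~0.25 Hz with a flattened (apneic) segment
#' spanning each swallow onset: respiration is held at its pre-apnea value
#' over the apnea window, with short cross-fades outside the window so the
#' flat core retains its full nominal length.
#'
#' @param events Numeric vector of ground-truth onset times (seconds).
#' @param duration Recording duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 1000).
#' @param breath_freq Breathing frequency in Hz (default 0.25).
#' @param amplitude Breathing amplitude (arbitrary units, default 1). Zero
#'   yields a degenerate flat record, which [detect_apnea()] flags as one
#'   full-length apnea.
#' @param apnea_pre Seconds of apnea before each onset (default 0.5).
#' @param apnea_post Seconds of apnea after each onset (default 1.0).
#' @param noise_sd White-noise standard deviation (default 0.003).
#' @param seed Optional integer seed; `NULL` draws from the current RNG state.
#'
#' @return List with `signal` (numeric vector) and `apneas`
#'   (tibble of ground-truth `start`/`end` in seconds).
#' @export
simulate_respiration <- function(events, duration, sample_rate = 1000,
                                 breath_freq = 0.25, amplitude = 1,
                                 apnea_pre = 0.5, apnea_post = 1.0,
                                 noise_sd = 0.003, seed = NULL) {
  if (length(events) > 0 && (min(events) < 0 || max(events) > duration)) {
    stop("Event times must lie within [0, duration].", call. = FALSE)
  }
  run <- function() {
    t <- seq(0, duration, by = 1 / sample_rate)
    phi <- stats::runif(1, 0, 2 * pi)
    breath <- amplitude * sin(2 * pi * breath_freq * t + phi)
    sig <- breath
    fade <- 0.2
    for (ev in events) {
      hold_val <- amplitude * sin(2 * pi * breath_freq * (ev - apnea_pre) + phi)
      w_start <- ev - apnea_pre - fade
      w_end <- ev + apnea_post + fade
      i1 <- max(1L, floor(w_start * sample_rate) + 1L)
      i2 <- min(length(t), ceiling(w_end * sample_rate) + 1L)
      idx <- i1:i2
      tau <- t[idx]
      w <- rep(1, length(idx))
      pre <- tau < ev - apnea_pre
      w[pre] <- (tau[pre] - w_start) / fade
      post <- tau > ev + apnea_post
      w[post] <- (w_end - tau[post]) / fade
      w <- pmin(pmax(w, 0), 1)
      sig[idx] <- (1 - w) * sig[idx] + w * hold_val
    }
    sig <- sig + stats::rnorm(length(t), 0, noise_sd)
    apneas <- if (length(events) > 0) {
      tibble::tibble(start = events - apnea_pre, end = events + apnea_post)
    } else {
      tibble::tibble(start = numeric(), end = numeric())
    }
    list(signal = sig, apneas = apneas)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete recording session
#'
#' Generates one participant's session under the blocked protocol: the
#' schedule, hemoglobin concentration ground truth, raw two-wavelength fNIRS
#' intensity, 4 kHz laryngeal accelerometry and 1 kHz respiratory
#' plethysmography, all sharing `t = 0` at session start, plus the
#' ground-truth events the detector and epoching stages should recover.
#'
#' @param protocol A [protocol_spec()].
#' @param channels A [default_montage()] channel set.
#' @param hrf An [hrf_params()] object.
#' @param noise A [noise_params()] object.
#' @param optics An [optics_table()].
#' @param participant Participant identifier (default `"P01"`).
#' @param seed Integer seed driving the whole generation (schedule
#'   randomization and every noise source). `NULL` draws from the current
#'   RNG state.
#' @param accel_rate,resp_rate,fnirs_rate Sampling rates in Hz.
#' @param i0 Baseline detected intensity passed to
#'   [concentrations_to_intensity()].
#'
#' @return A `session_recording` object: raw signals, montage, schedule,
#'   sample rates, and a `truth` element (events, apnea intervals, and the
#'   concentration series actually generated, for validation).
#' @export
simulate_session <- function(protocol = protocol_spec(),
                             channels = default_montage(),
                             hrf = hrf_params(),
                             noise = noise_params(),
                             optics = default_optics(),
                             participant = "P01",
                             seed = NULL,
                             accel_rate = 4000, resp_rate = 1000,
                             fnirs_rate = 50, i0 = 1) {
  run <- function() {
    schedule <- make_schedule(protocol, seed = NULL)
    sim <- simulate_concentrations(schedule, channels, hrf, noise,
                                   sample_rate = fnirs_rate, seed = NULL)
    intensity <- concentrations_to_intensity(sim$conc, optics, i0 = i0)
    accel <- simulate_accelerometer(sim$events$time, schedule$duration,
                                    sample_rate = accel_rate, seed = NULL)
    resp <- simulate_respiration(sim$events$time, schedule$duration,
                                 sample_rate = resp_rate, seed = NULL)
    structure(
      list(
        participant = participant,
        sample_rates = list(fnirs = fnirs_rate, accel = accel_rate,
                            resp = resp_rate),
        montage = tibble::as_tibble(channels),
        schedule = schedule,
        intensity = intensity,
        accel = accel,
        resp = resp$signal,
        truth = list(events = sim$events, apneas = resp$apneas,
                     conc = sim$conc),
        i0 = i0,
        seed = seed,
        provenance = list()
      ),
      class = "session_recording"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording>", x$participant, "\n")
  cat(sprintf("  duration %.0f s; fNIRS %g Hz x %d ch; accel %g Hz; resp %g Hz\n",
              x$schedule$duration, x$sample_rates$fnirs, nrow(x$montage),
              x$sample_rates$accel, x$sample_rates$resp))
  cat(sprintf("  %d ground-truth swallow(s)\n", nrow(x$truth$events)))
  invisible(x)
}
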