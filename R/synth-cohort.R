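#' Simulate event-level median-HDR values for a cohort
#'
#' Fast cohort-level arm of the synthetic-data generator: instead of
#' synthesizing raw multi-rate signals for every participant, it draws the
#' event-level median-HDR scalars that the signal pipeline would deliver,
#' from the same forward model. Each value is
#' `amplitude[position] * m + b_participant + (optional timing/hemisphere
#' shifts) + noise`, where `m` is the median of the unit HRF kernel over the
#' statistic window ([hrf_window_median()]), `b_participant` is a Gaussian
#' participant intercept, and the event noise reflects the residual left
#' after median/mean summarization of a noisy session.
#'
#' @param n_participants Cohort size (default 26).
#' @param protocol A [protocol_spec()] (defines blocks and swallows per
#'   segment).
#' @param hrf An [hrf_params()] object; its `amplitude_by_position` sets the
#'   condition means.
#' @param sigma_participant SD of the participant random intercept (uM,
#'   default 0.7).
#' @param sigma_event SD of event-level noise (uM, default 2.0; summarized
#'   cell SDs across participants are then on the order of 1 uM).
#' @param hemisphere_effect Additive shift (uM) for the right hemisphere
#'   (default 0).
#' @param timing_effect Additive shift (uM) for the last two swallows of each
#'   segment (default 0).
#' @param window Statistic window passed to [hrf_window_median()].
#' @param seed Optional integer seed.
#'
#' @return Tibble: `participant`, `position`, `block`, `ordinal`,
#'   `hemisphere`, `oxyhb` (uM); ready for [aggregate_hdr()].
#' @export
simulate_hdr_events <- function(n_participants = 26,
                                protocol = protocol_spec(),
                                hrf = hrf_params(),
                                sigma_participant = 0.7,
                                sigma_event = 2.0,
                                hemisphere_effect = 0,
                                timing_effect = 0,
                                window = c(5, 20),
                                seed = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(hrf, "hrf_params"))
  run <- function() {
    m <- hrf_window_median(hrf, window = window)
    spp <- protocol$swallows_per_position_per_block
    grid <- tidyr::expand_grid(
      participant = sprintf("P%02d", seq_len(n_participants)),
      position = protocol$positions,
      block = seq_len(protocol$n_blocks),
      ordinal = seq_len(spp),
      hemisphere = c("L", "R")
    )
    b <- stats::rnorm(n_participants, 0, sigma_participant)
    names(b) <- sprintf("P%02d", seq_len(n_participants))
    mu <- hrf$amplitude_by_position[grid$position] * m
    grid$oxyhb <- mu + b[grid$participant] +
      hemisphere_effect * (grid$hemisphere == "R") +
      timing_effect * (grid$ordinal > spp - 2) +
      stats::rnorm(nrow(grid), 0, sigma_event)
    grid
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a cohort HDR summary table
#'
#' Convenience wrapper: [simulate_hdr_events()] followed by
#' [aggregate_hdr()].
#'
#' @inheritParams simulate_hdr_events
#' @param ... Passed to [simulate_hdr_events()].
#' @return The aggregated HDR summary tibble.
#' @export
simulate_hdr_cohort <- function(n_participants = 26,
                                protocol = protocol_spec(), ...) {
  ev <- simulate_hdr_events(n_participants = n_participants,
                            protocol = protocol, ...)
  aggregate_hdr(ev, swallows_per_segment =
                  protocol$swallows_per_position_per_block)
}
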