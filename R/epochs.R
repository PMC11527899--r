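# Event-related epoching and the median-window HDR statistic.

#' Extract event-related epochs
#'
#' Cuts a window around each swallow onset from the concentration series.
#' Events whose window would extend beyond the record are dropped with a
#' warning (and their count reported).
#'
#' @param conc A `conc_series` (typically from [process_session()]).
#' @param events Tibble of swallow events with at least `onset`; condition
#'   columns (`position`, `block`, `ordinal`, `participant`) are carried
#'   through. Events flagged `verified = FALSE` are excluded.
#' @param pre Seconds before onset (default 10).
#' @param post Seconds after onset (default 20; use 30 for grand-average
#'   plotting).
#' @param chromophore Which series to epoch, `"hbo"` (default) or `"hbr"`.
#'
#' @return An `epoch_set`: list with `data` (array time x channel x event),
#'   `tau` (seconds relative to onset, `-pre` to `post`), `events`,
#'   `channels`, `sample_rate`, `baseline_applied = FALSE`.
#' @export
extract_epochs <- function(conc, events, pre = 10, post = 20,
                           chromophore = c("hbo", "hbr")) {
  stopifnot(inherits(conc, "conc_series"))
  chromophore <- match.arg(chromophore)
  events <- tibble::as_tibble(events)
  if ("verified" %in% names(events)) {
    events <- dplyr::filter(events, .data$verified)
  }
  events <- dplyr::arrange(events, .data$onset)
  fs <- conc$sample_rate
  n <- length(conc$time)
  npre <- round(pre * fs)
  npost <- round(post * fs)
  tau <- seq(-npre, npost) / fs
  sig <- conc[[chromophore]]
  keep <- logical(nrow(events))
  idx0 <- round(events$onset * fs) + 1L
  keep <- idx0 - npre >= 1L & idx0 + npost <= n
  if (any(!keep)) {
    warning(sprintf("%d event(s) dropped: epoch window outside the record.",
                    sum(!keep)), call. = FALSE)
  }
  events <- events[keep, ]
  idx0 <- idx0[keep]
  data <- array(NA_real_,
                dim = c(length(tau), ncol(sig), nrow(events)),
                dimnames = list(NULL, colnames(sig), NULL))
  for (e in seq_len(nrow(events))) {
    data[, , e] <- sig[(idx0[e] - npre):(idx0[e] + npost), , drop = FALSE]
  }
  structure(
    list(data = data, tau = tau, events = events, channels = conc$channels,
         sample_rate = fs, baseline_applied = FALSE),
    class = "epoch_set"
  )
}

#' Baseline-normalize epochs
#'
#' Subtracts, per epoch and per channel, the mean over the pre-onset baseline
#' window (`tau` in `[-pre, 0)`; the onset sample itself belongs to neither
#' the baseline nor the statistic window). The removed baseline means are
#' stored in the result for the baseline-consistency check. Applying the
#' normalization twice is an error.
#'
#' @param epochs An `epoch_set`.
#'
#' @return The normalized `epoch_set` with `baseline_applied = TRUE` and a
#'   `baseline_means` matrix (channel x event).
#' @export
baseline_normalize <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (isTRUE(epochs$baseline_applied)) {
    stop("Baseline normalization has already been applied.", call. = FALSE)
  }
  bl_idx <- which(epochs$tau < 0)
  nch <- dim(epochs$data)[2]
  nev <- dim(epochs$data)[3]
  bl <- matrix(NA_real_, nch, nev,
               dimnames = list(dimnames(epochs$data)[[2]], NULL))
  for (e in seq_len(nev)) {
    m <- colMeans(epochs$data[bl_idx, , e, drop = FALSE])
    bl[, e] <- m
    epochs$data[, , e] <- sweep(epochs$data[, , e, drop = FALSE], 2, m)
  }
  epochs$baseline_means <- bl
  epochs$baseline_applied <- TRUE
  epochs
}

#' Median-window HDR statistic
#'
#' Per event and channel, the median of the baseline-normalized epoch over
#' the post-onset statistic window (default 5-20 s, the window over which
#' the swallowing hemodynamic response is near its peak).
#'
#' @param epochs A baseline-normalized `epoch_set`.
#' @param window Statistic window in seconds after onset (default `c(5, 20)`,
#'   closed); must lie inside the epoch window.
#'
#' @return Tidy tibble: one row per event x channel with the event metadata,
#'   `channel`, `hemisphere` and `oxyhb` (uM).
#' @export
median_hdr <- function(epochs, window = c(5, 20)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!isTRUE(epochs$baseline_applied)) {
    stop("Apply `baseline_normalize()` before computing the HDR statistic.",
         call. = FALSE)
  }
  if (window[1] < min(epochs$tau) || window[2] > max(epochs$tau)) {
    stop("Statistic window lies outside the epoch window.", call. = FALSE)
  }
  widx <- which(epochs$tau >= window[1] & epochs$tau <= window[2])
  nev <- dim(epochs$data)[3]
  per_event <- lapply(seq_len(nev), function(e) {
    vals <- apply(epochs$data[widx, , e, drop = FALSE], 2, stats::median)
    dplyr::bind_cols(
      epochs$events[rep(e, length(vals)), , drop = FALSE],
      tibble::tibble(channel = names(vals), oxyhb = unname(vals))
    )
  })
  out <- dplyr::bind_rows(per_event)
  out |>
    dplyr::left_join(
      dplyr::select(epochs$channels, "channel", "hemisphere"),
      by = "channel"
    )
}

#' Aggregate HDR statistics by position, hemisphere and timing
#'
#' Builds the summary table feeding the mixed model: per participant, head
#' position and hemisphere, the mean of the per-channel (or per-event)
#' median-HDR values, split by within-block timing: `first` (ordinals 1-2 of
#' each position segment), `last` (the final two ordinals) and `all`.
#' Channel-level input is first averaged across each hemisphere's channels
#' per event; values already collapsed to hemisphere level are used as-is.
#'
#' @param scalars Tibble with columns `participant`, `position`, `block`,
#'   `ordinal`, `hemisphere`, `oxyhb` and optionally `channel`.
#' @param swallows_per_segment Planned swallows per position segment
#'   (default 8); defines the `last` timing group.
#'
#' @return Tibble: `participant`, `position`, `hemisphere`,
#'   `timing` (`first`/`last`/`all`), `oxyhb` (uM).
#' @export
aggregate_hdr <- function(scalars, swallows_per_segment = 8) {
  scalars <- tibble::as_tibble(scalars)
  needed <- c("participant", "position", "block", "ordinal", "hemisphere",
              "oxyhb")
  missing <- setdiff(needed, names(scalars))
  if (length(missing) > 0) {
    stop(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(scalars$hemisphere)) {
    stop("Every value needs a hemisphere label.", call. = FALSE)
  }
  if ("channel" %in% names(scalars)) {
    scalars <- scalars |>
      dplyr::group_by(.data$participant, .data$position, .data$block,
                      .data$ordinal, .data$hemisphere) |>
      dplyr::summarise(oxyhb = mean(.data$oxyhb), .groups = "drop")
  }
  spp <- swallows_per_segment
  timing_groups <- list(
    first = c(1, 2),
    last = c(spp - 1, spp),
    all = seq_len(spp)
  )
  out <- lapply(names(timing_groups), function(tg) {
    scalars |>
      dplyr::filter(.data$ordinal %in% timing_groups[[tg]]) |>
      dplyr::group_by(.data$participant, .data$position, .data$hemisphere) |>
      dplyr::summarise(oxyhb = mean(.data$oxyhb), .groups = "drop") |>
      dplyr::mutate(timing = tg)
  })
  dplyr::bind_rows(out) |>
    dplyr::select("participant", "position", "hemisphere", "timing", "oxyhb") |>
    dplyr::arrange(.data$participant, .data$position, .data$hemisphere,
                   .data$timing)
}

#' Grand-average event-related time course
#'
#' Pointwise mean of the epochs (averaged across channels within each epoch,
#' then across epochs) per grouping level, with the across-epoch standard
#' error as the dispersion band.
#'
#' @param epochs An `epoch_set` (extend `post` to 30 s at extraction for the
#'   conventional display window).
#' @param by Grouping column in the event metadata (default `"position"`).
#'
#' @return Tibble: grouping level, `tau`, `mean`, `se`, `n_epochs`.
#' @export
grand_average <- function(epochs, by = "position") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!by %in% names(epochs$events)) {
    stop(sprintf("No `%s` column in the event metadata.", by), call. = FALSE)
  }
  groups <- unique(epochs$events[[by]])
  out <- lapply(groups, function(g) {
    sel <- which(epochs$events[[by]] == g)
    # channel-mean trace per epoch, then mean/se across epochs
    traces <- sapply(sel, function(e) rowMeans(epochs$data[, , e, drop = FALSE]))
    traces <- matrix(traces, nrow = length(epochs$tau))
    tibble::tibble(
      !!by := g,
      tau = epochs$tau,
      mean = rowMeans(traces),
      se = if (length(sel) > 1) apply(traces, 1, stats::sd) / sqrt(length(sel))
           else NA_real_,
      n_epochs = length(sel)
    )
  })
  dplyr::bind_rows(out)
}

#' Plot grand-average HDR time courses
#'
#' Mean event-related oxyhemoglobin trace per head position with a
#' +/- 1 standard-error band. Requires ggplot2.
#'
#' @param ga A [grand_average()] tibble.
#' @param by Grouping column used when the averages were computed
#'   (default `"position"`).
#'
#' @return A ggplot object.
#' @export
plot_grand_average <- function(ga, by = "position") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting.", call. = FALSE)
  }
  ggplot2::ggplot(ga, ggplot2::aes(x = .data$tau, y = .data$mean,
                                   colour = .data[[by]],
                                   fill = .data[[by]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from swallow onset (s)",
                  y = expression(Delta * "HbO (" * mu * "M)")) +
    ggplot2::theme_minimal()
}

#' Baseline-consistency check across within-block timing
#'
#' Verifies that pre-swallow baseline levels do not drift over a block: for
#' each head position, the participant-level mean baseline of the first two
#' swallows is compared with that of the last two by a paired two-sided
#' t-test. The check passes when every position's p-value exceeds `alpha`.
#' A degenerate comparison (zero-variance differences, e.g. identical
#' baselines) is reported as a pass with `p = NA` and a note.
#'
#' @param baselines Tibble with columns `participant`, `position`, `timing`
#'   (`"first"`/`"last"`) and `baseline` (uM): per-participant mean baseline
#'   values, e.g. from the `baseline_means` stored by [baseline_normalize()].
#' @param alpha Significance level (default 0.05).
#'
#' @return Tibble: `position`, `mean_first`, `mean_last`, `p_value`, `pass`,
#'   `note`; with attribute `all_pass`.
#' @export
baseline_consistency_check <- function(baselines, alpha = 0.05) {
  baselines <- tibble::as_tibble(baselines)
  needed <- c("participant", "position", "timing", "baseline")
  missing <- setdiff(needed, names(baselines))
  if (length(missing) > 0) {
    stop(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(unique(baselines$participant)) < 2) {
    stop("Need at least 2 participants for the paired comparison.",
         call. = FALSE)
  }
  wide <- baselines |>
    dplyr::group_by(.data$participant, .data$position, .data$timing) |>
    dplyr::summarise(baseline = mean(.data$baseline), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timing", values_from = "baseline")
  out <- wide |>
    dplyr::group_by(.data$position) |>
    dplyr::group_modify(function(d, key) {
      diffs <- d$last - d$first
      if (stats::sd(diffs) <= .Machine$double.eps * max(abs(diffs), 1)) {
        return(tibble::tibble(
          mean_first = mean(d$first), mean_last = mean(d$last),
          p_value = NA_real_, pass = TRUE,
          note = "zero-variance differences; test undefined, treated as pass"
        ))
      }
      tt <- stats::t.test(d$last, d$first, paired = TRUE)
      tibble::tibble(mean_first = mean(d$first), mean_last = mean(d$last),
                     p_value = tt$p.value, pass = tt$p.value > alpha,
                     note = NA_character_)
    }) |>
    dplyr::ungroup()
  attr(out, "all_pass") <- all(out$pass)
  out
}
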