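# Epoch extraction, baseline normalization, median HDR, aggregation.

const_conc <- function(value = 7, n = 4000, nch = 2) {
  channels <- tibble::tibble(
    channel = paste0(c("L", "R"), 1)[seq_len(nch)],
    hemisphere = c("L", "R")[seq_len(nch)],
    roi = "premotor", separation = 3, type = "long"
  )
  structure(
    list(time = seq(0, by = 0.02, length.out = n),
         hbo = matrix(value, n, nch,
                      dimnames = list(NULL, channels$channel)),
         hbr = matrix(-value / 3, n, nch,
                      dimnames = list(NULL, channels$channel)),
         channels = channels, sample_rate = 50),
    class = "conc_series"
  )
}

simple_events <- function(onsets) {
  tibble::tibble(onset = onsets, block = 1L,
                 position = rep_len(c("down", "neutral", "up"),
                                    length(onsets)),
                 ordinal = seq_along(onsets), participant = "P01")
}

test_that("epochs are cut exactly and bounds violations are dropped", {
  conc <- const_conc()
  expect_warning(
    ep <- extract_epochs(conc, simple_events(c(5, 20))),
    "1 event\\(s\\) dropped"
  )
  expect_equal(dim(ep$data)[3], 1L)
  expect_equal(length(ep$tau), 30 * 50 + 1)
  expect_true(all(ep$data == 7))
  # empty event list is fine
  ep0 <- extract_epochs(conc, simple_events(numeric(0)))
  expect_equal(dim(ep0$data)[3], 0L)
})

test_that("noise-free epoch equals amplitude times the kernel", {
  s <- noisefree_session()
  conc <- process_session(s, band = NULL, short_regression = FALSE,
                          apply_cbsi = FALSE, i0 = s$i0)
  ev <- dplyr::mutate(s$truth$events, onset = time, participant = "P01")
  ep <- baseline_normalize(extract_epochs(conc, ev))
  kern <- hrf_kernel(hrf_params(), sample_rate = 50)
  amps <- hrf_params()$amplitude_by_position
  post <- which(ep$tau >= 0)
  for (e in seq_len(dim(ep$data)[3])) {
    expected <- amps[[ep$events$position[e]]] * kern$value[seq_along(post)]
    expect_equal(ep$data[post, 1, e], expected, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("baseline normalization is exact, slope-preserving, single-use", {
  conc <- const_conc()
  ep <- extract_epochs(conc, simple_events(c(15, 45)))
  ep <- baseline_normalize(ep)
  expect_true(all(ep$data == 0))
  expect_error(baseline_normalize(ep), "already")
  # random epochs: baseline mean is zero to machine precision
  s <- noisy_tiny_session()
  concs <- process_session(s)
  ev <- dplyr::mutate(detect_swallows(s), participant = "P01")
  eps <- baseline_normalize(extract_epochs(concs, ev))
  bl_idx <- which(eps$tau < 0)
  for (e in seq_len(dim(eps$data)[3])) {
    expect_lt(max(abs(colMeans(eps$data[bl_idx, , e]))), 1e-12)
  }
  # linear ramp keeps its slope, shifted so the baseline mean is zero
  ramp <- const_conc()
  ramp$hbo[, 1] <- seq_len(nrow(ramp$hbo)) * 0.01
  epr <- baseline_normalize(extract_epochs(ramp, simple_events(15)))
  v <- epr$data[, 1, 1]
  slopes <- diff(v)
  expect_equal(max(slopes), min(slopes), tolerance = 1e-10)
  expect_equal(mean(v[epr$tau < 0]), 0, tolerance = 1e-12)
})

test_that("median HDR is the window median and is spike-robust", {
  conc <- const_conc(value = 0)
  ep <- extract_epochs(conc, simple_events(15))
  ep <- baseline_normalize(ep)
  widx <- which(ep$tau >= 5 & ep$tau <= 20)
  # constant window value c
  ep$data[widx, , 1] <- 2.5
  hdr <- median_hdr(ep)
  expect_true(all(hdr$oxyhb == 2.5))
  # perturbing fewer than half the window samples cannot move the median
  ep2 <- ep
  n_spike <- floor(length(widx) / 2) - 1
  ep2$data[widx[seq_len(n_spike)], 1, 1] <- 1e9
  expect_equal(median_hdr(ep2)$oxyhb[1], 2.5)
  expect_error(median_hdr(ep, window = c(5, 50)), "outside")
  ep_raw <- extract_epochs(conc, simple_events(15))
  expect_error(median_hdr(ep_raw), "baseline_normalize")
})

test_that("aggregation averages hemispheres and timing groups correctly", {
  grid <- tidyr::expand_grid(
    participant = "P01", position = c("down", "neutral", "up"),
    block = 1:4, ordinal = 1:8, hemisphere = c("L", "R"),
    channel = paste0("c", 1:2)
  )
  # all equal: every cell equals that constant
  summ <- aggregate_hdr(dplyr::mutate(grid, oxyhb = 3))
  expect_equal(nrow(summ), 3 * 2 * 3)
  expect_true(all(summ$oxyhb == 3))
  # left/right distinct
  summ2 <- aggregate_hdr(
    dplyr::mutate(grid, oxyhb = ifelse(hemisphere == "L", 1, 2)))
  expect_true(all(summ2$oxyhb[summ2$hemisphere == "L"] == 1))
  expect_true(all(summ2$oxyhb[summ2$hemisphere == "R"] == 2))
  # "all" cell equals the brute-force mean of its event-level components
  withr::with_seed(21, {
    noisy <- dplyr::mutate(grid, oxyhb = rnorm(nrow(grid)))
    summ3 <- aggregate_hdr(noisy)
    cell <- summ3[summ3$position == "up" & summ3$hemisphere == "L" &
                    summ3$timing == "all", ]
    brute <- noisy |>
      dplyr::filter(position == "up", hemisphere == "L") |>
      dplyr::group_by(block, ordinal) |>
      dplyr::summarise(v = mean(oxyhb), .groups = "drop")
    expect_equal(cell$oxyhb, mean(brute$v), tolerance = 1e-12)
    # first/last pick ordinals 1-2 and 7-8
    first_cell <- summ3[summ3$position == "up" & summ3$hemisphere == "L" &
                          summ3$timing == "first", ]
    brute_first <- brute  # per-event values already channel-averaged
    expect_equal(first_cell$oxyhb,
                 mean(noisy$oxyhb[noisy$position == "up" &
                                    noisy$hemisphere == "L" &
                                    noisy$ordinal %in% 1:2]),
                 tolerance = 1e-12)
  })
  expect_error(aggregate_hdr(dplyr::select(grid, -hemisphere)), "Missing")
})

test_that("default synthetic cohort summary orders up above down", {
  summ <- simulate_hdr_cohort(seed = 77)
  cells <- summ |>
    dplyr::filter(timing == "all") |>
    dplyr::group_by(position, hemisphere) |>
    dplyr::summarise(m = mean(oxyhb), .groups = "drop") |>
    tidyr::pivot_wider(names_from = position, values_from = m)
  expect_true(all(cells$up > cells$down))
})

test_that("HDR summary scales linearly with the concentration scale", {
  s <- noisy_tiny_session()
  conc <- process_session(s)
  ev <- dplyr::mutate(detect_swallows(s), participant = "P01")
  summarize <- function(cc) {
    ep <- baseline_normalize(extract_epochs(cc, ev))
    aggregate_hdr(median_hdr(ep), swallows_per_segment = 2)
  }
  base <- summarize(conc)
  conc2 <- conc
  conc2$hbo <- 2 * conc$hbo
  scaled <- summarize(conc2)
  expect_equal(scaled$oxyhb, 2 * base$oxyhb, tolerance = 1e-9)
})

test_that("grand averages reduce correctly and order by amplitude", {
  conc <- const_conc(value = 0)
  ev <- simple_events(c(15, 45))
  ep <- extract_epochs(conc, ev)
  ep$data[, , 1] <- 1.5
  ep$data[, , 2] <- -1.5
  # single-epoch group: grand average is that epoch
  ga <- grand_average(ep, by = "position")
  one <- ga[ga$position == ep$events$position[1], ]
  expect_true(all(one$mean == 1.5))
  # x and -x average to zero
  ep$events$position <- c("down", "down")
  ga2 <- grand_average(ep, by = "position")
  expect_true(all(ga2$mean == 0))
  # noise-free session: curves order up > neutral > down at the peak
  s <- noisefree_session()
  concs <- process_session(s, band = NULL, short_regression = FALSE,
                           apply_cbsi = FALSE, i0 = s$i0)
  evs <- dplyr::mutate(s$truth$events, onset = time, participant = "P01")
  eps <- baseline_normalize(extract_epochs(concs, evs))
  ga3 <- grand_average(eps)
  peaks <- ga3 |>
    dplyr::group_by(position) |>
    dplyr::summarise(peak = max(mean), .groups = "drop")
  expect_true(peaks$peak[peaks$position == "up"] >
                peaks$peak[peaks$position == "neutral"])
  expect_true(peaks$peak[peaks$position == "neutral"] >
                peaks$peak[peaks$position == "down"])
})

test_that("baseline-consistency check flags drift and passes clean cohorts", {
  mk <- function(drift = 0, seed = 1, n = 26) {
    withr::with_seed(seed, {
      tidyr::expand_grid(participant = sprintf("P%02d", 1:n),
                         position = c("down", "neutral", "up"),
                         timing = c("first", "last")) |>
        dplyr::mutate(baseline = rnorm(dplyr::n(), 0, 1) +
                        drift * (timing == "last"))
    })
  }
  # identical first/last baselines: degenerate, reported as pass
  same <- mk()
  wide <- same[same$timing == "first", ]
  both <- dplyr::bind_rows(wide, dplyr::mutate(wide, timing = "last"))
  res0 <- baseline_consistency_check(both)
  expect_true(all(res0$pass))
  expect_true(all(is.na(res0$p_value)))
  # a 5 uM drift in the last swallows is detected at n = 26
  res1 <- baseline_consistency_check(mk(drift = 5, seed = 2))
  expect_true(all(res1$p_value < 0.05))
  expect_false(any(res1$pass))
  # clean cohorts pass in >= 90% of seeded runs (per-position alpha 0.05)
  passes <- vapply(1:30, function(i) {
    res <- baseline_consistency_check(mk(seed = 100 + i))
    mean(res$pass)
  }, numeric(1))
  expect_gte(mean(passes), 0.9)
  expect_error(baseline_consistency_check(mk(n = 1)), "2 participants")
})
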