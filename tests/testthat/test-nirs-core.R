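# Intensity -> OD -> filtering -> MBLL -> short-separation -> CBSI.

make_raw <- function(m790, m830, channels = NULL, i0 = 1) {
  n <- nrow(m790)
  if (is.null(channels)) {
    channels <- tibble::tibble(
      channel = colnames(m790), hemisphere = "L", roi = "premotor",
      separation = 3, type = "long"
    )
  }
  structure(
    list(time = seq(0, by = 0.02, length.out = n),
         intensity = list("790" = m790, "830" = m830),
         channels = channels, i0 = i0, sample_rate = 50),
    class = "raw_intensity"
  )
}

test_that("optical density conversion follows -log(I / reference)", {
  m <- matrix(2, 100, 1, dimnames = list(NULL, "L1"))
  raw <- make_raw(m, m)
  od <- intensity_to_od(raw)
  expect_equal(od$od[["790"]][, 1], rep(0, 100), tolerance = 1e-12)
  # one attenuated sample: dOD = 0.1 there (up to the mean-reference shift)
  m2 <- m
  m2[50, 1] <- 2 * exp(-0.1)
  od2 <- intensity_to_od(make_raw(m2, m), i0 = 2)
  expect_equal(unname(od2$od[["790"]][50, 1]), 0.1, tolerance = 1e-12)
  # scale invariance with the mean reference
  od3 <- intensity_to_od(make_raw(m2, m))
  od4 <- intensity_to_od(make_raw(2 * m2, 2 * m))
  expect_equal(od3$od[["790"]], od4$od[["790"]], tolerance = 1e-12)
  m_bad <- m
  m_bad[7, 1] <- 0
  expect_error(intensity_to_od(make_raw(m_bad, m)), "L1.*sample 7")
})

test_that("band-pass matches the analytic Butterworth response", {
  fs <- 50
  t <- seq(0, 600, by = 1 / fs)
  trim <- function(x, s = 200) x[(s * fs):(length(x) - s * fs)]
  # cardiac-band tone: >= 30 dB down, consistent with the analytic gain
  x_card <- sin(2 * pi * 1.1 * t)
  amp_card <- max(abs(trim(bandpass(x_card, fs))))
  expect_lt(amp_card, 10^(-30 / 20))
  expect_lt(amp_card, 1.5 * butter_bandpass_gain(1.1))
  # passband tone within 12%
  x_pass <- sin(2 * pi * 0.1 * t)
  amp_pass <- max(abs(trim(bandpass(x_pass, fs))))
  expect_equal(amp_pass, butter_bandpass_gain(0.1), tolerance = 0.12)
  expect_gt(amp_pass, 0.88)
  expect_lt(amp_pass, 1.12)
  # DC rejected
  dc <- max(abs(trim(bandpass(rep(5, length(t)), fs))))
  expect_lt(dc, 1e-3 * 5)
  expect_error(bandpass(x_pass, fs, high = 25), "Nyquist")
})

test_that("band-pass is idempotent in the passband", {
  fs <- 50
  t <- seq(0, 600, by = 1 / fs)
  x <- sin(2 * pi * 0.1 * t)
  once <- bandpass(x, fs)
  twice <- bandpass(once, fs)
  i <- (200 * fs):(length(t) - 200 * fs)
  expect_equal(max(abs(twice[i])), max(abs(once[i])), tolerance = 0.02)
})

test_that("MBLL inversion solves the 2x2 system exactly", {
  n <- 200
  channels <- tibble::tibble(channel = "L1", hemisphere = "L",
                             roi = "premotor", separation = 3, type = "long")
  conc <- structure(
    list(time = seq(0, by = 0.02, length.out = n),
         hbo = matrix(1, n, 1, dimnames = list(NULL, "L1")),
         hbr = matrix(-0.3, n, 1, dimnames = list(NULL, "L1")),
         channels = channels, sample_rate = 50),
    class = "conc_series"
  )
  opt <- default_optics()
  od <- conc_to_od(conc, opt)
  # independent oracle: direct 2x2 solve at one sample
  A <- 3 * diag(opt$dpf) %*% opt$extinction
  oracle <- solve(A, c(od$od[["790"]][1, 1], od$od[["830"]][1, 1])) * 1e3
  expect_equal(unname(oracle), c(1, -0.3), tolerance = 1e-9)
  rec <- od_to_conc(od, opt)
  expect_lt(max(abs(rec$hbo - 1)), 1e-9)
  expect_lt(max(abs(rec$hbr + 0.3)), 1e-9)
  # zero OD maps to zero concentrations
  od0 <- od
  od0$od <- lapply(od0$od, function(m) m * 0)
  rec0 <- od_to_conc(od0, opt)
  expect_true(all(rec0$hbo == 0) && all(rec0$hbr == 0))
  expect_error(
    optics_table(extinction = matrix(c(1, 2, 2, 4), 2, byrow = TRUE)),
    "condition number"
  )
})

test_that("short-separation regression projects out the superficial signal", {
  n <- 480   # integer number of 40-sample periods: sin and cos orthogonal
  t <- seq_len(n)
  channels <- tibble::tibble(
    channel = c("L1", "SS-L"), hemisphere = "L",
    roi = c("premotor", "superficial"), separation = c(3, 0.8),
    type = c("long", "short")
  )
  mk <- function(long, short) {
    structure(
      list(time = t / 50,
           hbo = cbind(L1 = long, `SS-L` = short),
           hbr = cbind(L1 = long / 2, `SS-L` = short / 2),
           channels = channels, sample_rate = 50),
      class = "conc_series"
    )
  }
  s <- sin(2 * pi * t / 40)
  # long channel exactly proportional to the short one vanishes
  out <- short_sep_regress(mk(2 * s, s))
  expect_lt(max(abs(out$hbo[, 1])), 1e-10)
  # orthogonal long channel is unchanged (up to its mean)
  orth <- cos(2 * pi * t / 40)
  out2 <- short_sep_regress(mk(orth, s))
  expect_equal(out2$hbo[, 1], orth - mean(orth), tolerance = 1e-9)
  # mixed signal: residual decorrelated from the regressor
  withr::with_seed(5, {
    sig <- rnorm(n)
    out3 <- short_sep_regress(mk(sig + 0.8 * s, s))
    expect_lt(abs(sum(out3$hbo[, 1] * s)), 1e-8)
    expect_lt(abs(stats::cor(out3$hbo[, 1], s)), 1e-10)
  })
  # zero-variance short channel: skipped with a warning per chromophore
  expect_warning(
    expect_warning(out4 <- short_sep_regress(mk(s, rep(1, n))),
                   "zero variance"),
    "zero variance"
  )
  expect_equal(out4$hbo[, 1], s, tolerance = 1e-12)
  # no short channels at all: unchanged with a warning
  no_short <- mk(s, s)
  no_short$channels$type <- "long"
  expect_warning(out5 <- short_sep_regress(no_short), "No short-separation")
  expect_equal(ncol(out5$hbo), 2L)
})

test_that("CBSI output is exactly anti-correlated and kills common mode", {
  withr::with_seed(6, {
    for (rep in 1:5) {
      hbo <- rnorm(300)
      hbr <- rnorm(300)
      cc <- cbsi(hbo, hbr)
      expect_equal(stats::cor(cc$hbo, cc$hbr), -1, tolerance = 1e-10)
    }
  })
  # already anti-correlated pair is a fixed point
  hbo <- sin(seq(0, 10, length.out = 200))
  cc <- cbsi(hbo, -hbo / 2)
  expect_equal(cc$hbo, hbo, tolerance = 1e-12)
  # pure common-mode artifact maps to zero
  cc2 <- cbsi(hbo, hbo)
  expect_lt(max(abs(cc2$hbo)), 1e-12)
  expect_error(cbsi(hbo, rep(1, 200)), "variance")
})

test_that("processing chain is scale-equivariant past the OD stage", {
  s <- noisy_tiny_session()
  od <- intensity_to_od(s$intensity)
  conc1 <- od_to_conc(od, default_optics())
  od2 <- od
  od2$od <- lapply(od$od, function(m) 2.5 * m)
  conc2 <- od_to_conc(od2, default_optics())
  expect_equal(conc2$hbo, 2.5 * conc1$hbo, tolerance = 1e-9)
  r1 <- short_sep_regress(conc1)
  r2 <- short_sep_regress(conc2)
  expect_equal(r2$hbo, 2.5 * r1$hbo, tolerance = 1e-8)
  c1 <- cbsi(r1$hbo[, 1], r1$hbr[, 1])
  c2 <- cbsi(2.5 * r1$hbo[, 1], 2.5 * r1$hbr[, 1])
  expect_equal(c2$hbo, 2.5 * c1$hbo, tolerance = 1e-9)
})

test_that("noise-free forward model is recovered through the inverse chain", {
  s <- noisefree_session()
  conc <- process_session(s, band = NULL, short_regression = FALSE,
                          apply_cbsi = FALSE, i0 = s$i0)
  truth <- s$truth$conc
  keep <- truth$channels$type == "long"
  expect_lt(max(abs(conc$hbo - truth$hbo[, keep])), 1e-6)
  expect_lt(max(abs(conc$hbr - truth$hbr[, keep])), 1e-6)
  # with the band-pass on, event-locked amplitude is within 15%
  conc_bp <- process_session(s, short_regression = FALSE,
                             apply_cbsi = FALSE, i0 = s$i0)
  ev <- dplyr::mutate(s$truth$events, onset = time, participant = "P01")
  ep <- baseline_normalize(extract_epochs(conc_bp, ev))
  peak_rec <- max(ep$data[ep$tau > 0, 1, 1])
  amp <- hrf_params()$amplitude_by_position[[ep$events$position[1]]]
  expect_equal(peak_rec, amp, tolerance = 0.15)
})
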