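#' Optical constants for the modified Beer-Lambert law
#'
#' Bundles the chromophore extinction coefficients at the two laser
#' wavelengths, the differential pathlength factors (DPF), and the default
#' source-detector separation. The modified Beer-Lambert law relates optical
#' density changes to concentration changes as
#' `dOD(lambda) = d * DPF(lambda) * [eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR]`
#' with `d` the separation in cm and concentrations in mM.
#'
#' The default extinction values are approximate molar extinction coefficients
#' from the standard hemoglobin compilations used across the field; they are
#' configuration, not fixed constants, and every inverse/forward guarantee in
#' the package holds for any non-singular table.
#'
#' @param extinction 2x2 matrix of extinction coefficients in cm^-1 mM^-1;
#'   rows = wavelengths, columns = chromophores (`HbO`, `HbR`).
#' @param wavelengths Wavelengths in nm matching the extinction rows.
#' @param dpf Differential pathlength factor per wavelength (default 6.0 at
#'   both, a common adult default).
#' @param separation Default source-detector separation in cm (default 3);
#'   overridden by per-channel separations when a montage supplies them.
#'
#' @return An `optics_table` object.
#' @export
optics_table <- function(extinction = matrix(c(0.735, 0.896,
                                               0.974, 0.693),
                                             nrow = 2, byrow = TRUE,
                                             dimnames = list(c("790", "830"),
                                                             c("HbO", "HbR"))),
                         wavelengths = c(790, 830),
                         dpf = c(6, 6),
                         separation = 3) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)) || any(!is.finite(extinction))) {
    stop("`extinction` must be a finite 2x2 matrix.", call. = FALSE)
  }
  kappa <- kappa(extinction, exact = TRUE)
  if (kappa >= 1e6) {
    stop(sprintf("Extinction matrix is ill-conditioned (condition number %.3g).",
                 kappa), call. = FALSE)
  }
  if (length(dpf) != 2 || any(dpf <= 0)) {
    stop("`dpf` must be two positive values.", call. = FALSE)
  }
  if (separation <= 0) stop("`separation` must be positive.", call. = FALSE)
  structure(
    list(extinction = extinction, wavelengths = wavelengths, dpf = dpf,
         separation = separation),
    class = "optics_table"
  )
}

#' @rdname optics_table
#' @export
default_optics <- optics_table

# Per-channel MBLL coefficient matrices: list of 2x2 (wavelength x chromophore)
mbll_matrix <- function(optics, separations) {
  lapply(separations, function(d) {
    d * diag(optics$dpf) %*% optics$extinction
  })
}

channel_separations <- function(channels, optics) {
  if (!is.null(channels$separation)) channels$separation
  else rep(optics$separation, nrow(channels))
}

#' Forward modified Beer-Lambert law: concentrations to optical density
#'
#' Computes per-channel optical density changes at both wavelengths from
#' oxy-/deoxyhemoglobin concentration changes. This is the exact algebraic
#' inverse of [od_to_conc()].
#'
#' @param conc A `conc_series` object (see [simulate_concentrations()]).
#' @param optics An [optics_table()].
#'
#' @return An `od_series` object: list with `time`, `od` (named list of
#'   time-by-channel matrices, one per wavelength), `channels`, `sample_rate`.
#' @export
conc_to_od <- function(conc, optics = default_optics()) {
  stopifnot(inherits(conc, "conc_series"), inherits(optics, "optics_table"))
  seps <- channel_separations(conc$channels, optics)
  mats <- mbll_matrix(optics, seps)
  n <- length(conc$time)
  wl <- as.character(optics$wavelengths)
  od <- stats::setNames(
    lapply(wl, function(w) matrix(0, n, nrow(conc$channels),
                                  dimnames = list(NULL, conc$channels$channel))),
    wl
  )
  for (j in seq_len(nrow(conc$channels))) {
    # concentrations carried in uM; MBLL coefficients expect mM
    c_mM <- cbind(conc$hbo[, j], conc$hbr[, j]) * 1e-3
    od_j <- c_mM %*% t(mats[[j]])
    od[[wl[1]]][, j] <- od_j[, 1]
    od[[wl[2]]][, j] <- od_j[, 2]
  }
  structure(
    list(time = conc$time, od = od, channels = conc$channels,
         sample_rate = conc$sample_rate),
    class = "od_series"
  )
}

#' Convert raw intensity to optical density changes
#'
#' `dOD(t) = -ln(I(t) / I_ref)` per channel and wavelength. By default the
#' reference is the channel's mean intensity over the record, so the optical
#' density series is approximately zero-mean; when the true emitted intensity
#' is known (as in forward simulations) it can be supplied for an exact
#' inversion.
#'
#' @param raw A `raw_intensity` object (see [concentrations_to_intensity()]).
#' @param i0 Optional known reference intensity (scalar, or vector per
#'   channel); `NULL` (default) uses each channel's record mean.
#'
#' @return An `od_series` object.
#' @export
intensity_to_od <- function(raw, i0 = NULL) {
  stopifnot(inherits(raw, "raw_intensity"))
  od <- lapply(names(raw$intensity), function(w) {
    m <- raw$intensity[[w]]
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "Non-positive intensity at %s nm, channel %s, sample %d.",
        w, colnames(m)[bad[1, 2]], bad[1, 1]), call. = FALSE)
    }
    ref <- if (is.null(i0)) colMeans(m) else rep_len(i0, ncol(m))
    -log(sweep(m, 2, ref, "/"))
  })
  names(od) <- names(raw$intensity)
  structure(
    list(time = raw$time, od = od, channels = raw$channels,
         sample_rate = raw$sample_rate),
    class = "od_series"
  )
}

#' Invert the modified Beer-Lambert law
#'
#' Solves, per channel and sample, the 2x2 linear system relating optical
#' density changes at the two wavelengths to oxy-/deoxyhemoglobin
#' concentration changes.
#'
#' @param od An `od_series` object.
#' @param optics An [optics_table()].
#'
#' @return A `conc_series` object with `hbo` and `hbr` matrices in uM.
#' @export
od_to_conc <- function(od, optics = default_optics()) {
  stopifnot(inherits(od, "od_series"), inherits(optics, "optics_table"))
  seps <- channel_separations(od$channels, optics)
  mats <- mbll_matrix(optics, seps)
  wl <- names(od$od)
  n <- length(od$time)
  nch <- nrow(od$channels)
  hbo <- hbr <- matrix(0, n, nch,
                       dimnames = list(NULL, od$channels$channel))
  for (j in seq_len(nch)) {
    A <- mats[[j]]
    kap <- kappa(A, exact = TRUE)
    if (!is.finite(kap) || kap >= 1e6) {
      stop(sprintf(
        "MBLL matrix for channel %s is ill-conditioned (condition number %.3g).",
        od$channels$channel[j], kap), call. = FALSE)
    }
    od_j <- cbind(od$od[[wl[1]]][, j], od$od[[wl[2]]][, j])
    c_mM <- od_j %*% t(solve(A))
    hbo[, j] <- c_mM[, 1] * 1e3
    hbr[, j] <- c_mM[, 2] * 1e3
  }
  structure(
    list(time = od$time, hbo = hbo, hbr = hbr, channels = od$channels,
         sample_rate = od$sample_rate),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  cat("<conc_series>\n")
  cat(sprintf("  %d samples at %g Hz (%.1f s), %d channel(s)\n",
              length(x$time), x$sample_rate,
              length(x$time) / x$sample_rate, ncol(x$hbo)))
  invisible(x)
}
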