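# Motion/superficial-signal correction: short-separation regression and
# correlation-based signal improvement (CBSI).

#' Short-separation channel regression
#'
#' Removes superficial (scalp) hemodynamics from each long channel by
#' regressing it on its nearest short-separation channel (the short channel
#' on the same hemisphere, by default) and keeping the residual. The
#' regression coefficient is estimated by ordinary least squares over the
#' full record, separately per chromophore; the output is orthogonal to its
#' regressor.
#'
#' @param conc A `conc_series` containing long and short channels (channel
#'   metadata column `type`).
#' @param mapping Optional named character vector mapping long channel ids to
#'   short channel ids; defaults to the same-hemisphere short channel.
#'
#' @return A `conc_series` containing the corrected long channels only. If
#'   the series has no short channels the input long channels are returned
#'   unchanged with a warning; a zero-variance short channel is skipped with
#'   a warning.
#' @export
short_sep_regress <- function(conc, mapping = NULL) {
  stopifnot(inherits(conc, "conc_series"))
  ch <- conc$channels
  long_idx <- which(ch$type == "long")
  short_idx <- which(ch$type == "short")
  keep_long <- function() {
    structure(
      list(time = conc$time,
           hbo = conc$hbo[, long_idx, drop = FALSE],
           hbr = conc$hbr[, long_idx, drop = FALSE],
           channels = ch[long_idx, ], sample_rate = conc$sample_rate),
      class = "conc_series"
    )
  }
  if (length(short_idx) == 0) {
    warning("No short-separation channels; returning long channels unchanged.",
            call. = FALSE)
    return(keep_long())
  }
  if (is.null(mapping)) {
    mapping <- vapply(long_idx, function(j) {
      same <- short_idx[ch$hemisphere[short_idx] == ch$hemisphere[j]]
      ch$channel[if (length(same) > 0) same[1] else short_idx[1]]
    }, character(1))
    names(mapping) <- ch$channel[long_idx]
  }
  out <- keep_long()
  for (chrom in c("hbo", "hbr")) {
    full <- conc[[chrom]]
    for (k in seq_along(long_idx)) {
      long_name <- ch$channel[long_idx[k]]
      s <- full[, mapping[[long_name]]]
      if (stats::var(s) <= .Machine$double.eps) {
        warning(sprintf("Short channel %s has zero variance; skipping %s/%s.",
                        mapping[[long_name]], long_name, chrom),
                call. = FALSE)
        next
      }
      y <- full[, long_idx[k]]
      fit <- stats::lm.fit(cbind(1, s), y)
      out[[chrom]][, k] <- fit$residuals
    }
  }
  out
}

#' Correlation-based signal improvement (CBSI)
#'
#' Motion correction exploiting the physiological anti-correlation of oxy-
#' and deoxyhemoglobin: with `alpha = sd(hbo)/sd(hbr)`, the corrected pair is
#' `hbo* = (hbo - alpha * hbr) / 2` and `hbr* = -hbo* / alpha`. Common-mode
#' artifacts (identical in both chromophores up to the `alpha` scaling, as
#' motion is) cancel exactly, and the output pair is exactly anti-correlated.
#'
#' @param hbo,hbr Numeric vectors or time-by-channel matrices of equal shape;
#'   every series must have non-zero variance.
#'
#' @return List with corrected `hbo` and `hbr` of the same shape.
#' @export
cbsi <- function(hbo, hbr) {
  if (is.matrix(hbo)) {
    stopifnot(is.matrix(hbr), all(dim(hbo) == dim(hbr)))
    out_o <- hbo
    out_r <- hbr
    for (j in seq_len(ncol(hbo))) {
      cc <- cbsi(hbo[, j], hbr[, j])
      out_o[, j] <- cc$hbo
      out_r[, j] <- cc$hbr
    }
    return(list(hbo = out_o, hbr = out_r))
  }
  stopifnot(length(hbo) == length(hbr))
  sd_r <- stats::sd(hbr)
  if (!is.finite(sd_r) || sd_r == 0) {
    stop("`hbr` has zero variance; CBSI is undefined.", call. = FALSE)
  }
  sd_o <- stats::sd(hbo)
  if (!is.finite(sd_o) || sd_o == 0) {
    stop("`hbo` has zero variance; CBSI is undefined.", call. = FALSE)
  }
  alpha <- sd_o / sd_r
  hbo_c <- (hbo - alpha * hbr) / 2
  list(hbo = hbo_c, hbr = -hbo_c / alpha)
}
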