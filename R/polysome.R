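## Polysome-profile quantification: Savitzky-Golay smoothing, 40S/60S/80S
## peak localization, 80S reference scaling and subunit ratios.

#' Smooth a polysome profile with a Savitzky-Golay filter
#'
#' Local least-squares cubic fit per window; output length equals input
#' length with polynomial handling of the edge windows, so a trace that is
#' itself a polynomial of degree <= `polyorder` passes through unchanged.
#' Unevenly sampled traces are first resampled to a uniform grid of the same
#' length by linear interpolation (the filter assumes uniform spacing).
#'
#' @param profile a [PolysomeProfile-class].
#' @param window odd filter window length, conventionally in [51, 61]
#'   (default 57, the midpoint); must exceed `polyorder`.
#' @param polyorder polynomial order (default 3).
#' @return A smoothed [PolysomeProfile-class] (`smoothed = TRUE`, smoothing
#'   parameters recorded).
#' @export
smoothProfile <- function(profile, window = 57, polyorder = 3) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed the polynomial order")
  x <- profile@position; y <- profile@absorbance
  if (length(y) < window)
    stop("trace shorter than the smoothing window")
  d <- diff(x)
  if (max(d) - min(d) > 1e-8 * mean(d)) {
    xu <- seq(x[1], x[length(x)], length.out = length(x))
    y <- approx(x, y, xout = xu)$y
    x <- xu
  }
  ys <- signal::sgolayfilt(y, p = polyorder, n = window)
  new("PolysomeProfile", position = x, absorbance = ys,
      label = profile@label, smoothed = TRUE, window = window,
      polyorder = polyorder, metadata = profile@metadata)
}

#' Locate 40S/60S/80S peaks in a profile
#'
#' Each species' peak is the global maximum of the (ideally smoothed) trace
#' within its search window; a species whose window maximum does not rise
#' above `baseline + epsilon` is flagged not detected. Windows must be
#' ordered 40S < 60S < 80S along the gradient and non-overlapping.
#'
#' @param profile a [PolysomeProfile-class].
#' @param windows named list `list("40S" = c(lo, hi), "60S" = ..., "80S" =
#'   ...)` of position windows.
#' @param baseline baseline level; defaults to the trace minimum.
#' @param epsilon detection margin above baseline; defaults to 1% of the
#'   trace dynamic range.
#' @return A [PeakSet-class].
#' @export
locateSubunitPeaks <- function(profile, windows, baseline = NULL,
                               epsilon = NULL) {
  x <- profile@position; y <- profile@absorbance
  species <- names(windows)
  if (is.null(species) || !all(c("40S", "60S", "80S") %in% species))
    stop("windows must be named and include 40S, 60S and 80S")
  wm <- do.call(rbind, windows)
  colnames(wm) <- c("lo", "hi")
  if (any(wm[, "lo"] < min(x)) || any(wm[, "hi"] > max(x)))
    stop("search windows must lie within the trace range")
  if (is.null(baseline)) baseline <- min(y)
  if (is.null(epsilon)) epsilon <- 0.01 * diff(range(y))
  pos <- hei <- rep(NA_real_, length(species))
  det <- logical(length(species))
  for (i in seq_along(species)) {
    idx <- which(x >= wm[i, "lo"] & x <= wm[i, "hi"])
    if (length(idx) == 0) next
    j <- idx[which.max(y[idx])]
    if (y[j] > baseline + epsilon) {
      det[i] <- TRUE; pos[i] <- x[j]; hei[i] <- y[j]
    }
  }
  new("PeakSet", species = species, position = pos, height = hei,
      detected = det, windows = wm, baseline = baseline)
}

#' Scale a profile so its 80S peak matches a reference profile
#'
#' Profiles are adjusted to the 80S monosome peak: every absorbance value of
#' `profile` is multiplied by `reference 80S height / sample 80S height`, so
#' the scaled profile's 80S peak equals the reference's. Subunit ratios are
#' unaffected (they are scale invariant). Set `invert = TRUE` for the
#' opposite multiplier.
#'
#' @param profile,reference [PolysomeProfile-class] objects (smoothed).
#' @param windows search windows as in [locateSubunitPeaks()].
#' @param invert use sample/reference instead of reference/sample.
#' @return The scaled [PolysomeProfile-class]; the factor used is stored in
#'   `metadata$scale_factor`.
#' @export
scaleToReference <- function(profile, reference, windows, invert = FALSE) {
  p80 <- locateSubunitPeaks(profile, windows)
  r80 <- locateSubunitPeaks(reference, windows)
  hs <- peakHeights(p80)["80S"]; hr <- peakHeights(r80)["80S"]
  if (!p80@detected[p80@species == "80S"] ||
      !r80@detected[r80@species == "80S"])
    stop("80S peak not detected in sample and/or reference")
  f <- if (invert) unname(hs / hr) else unname(hr / hs)
  md <- profile@metadata
  md$scale_factor <- f
  new("PolysomeProfile", position = profile@position,
      absorbance = profile@absorbance * f, label = profile@label,
      smoothed = profile@smoothed, window = profile@window,
      polyorder = profile@polyorder, metadata = md)
}

#' Ribosomal subunit peak-height ratios
#'
#' Ratios of maximum peak intensities between species; with
#' `subtractBaseline = TRUE` the PeakSet's baseline is removed from each
#' height first.
#'
#' @param peaks a [PeakSet-class] with all of 40S, 60S, 80S detected.
#' @param subtractBaseline subtract the baseline before forming ratios
#'   (off by default).
#' @return Named numeric `c("60S/40S", "80S/40S", "80S/60S")`.
#' @export
subunitRatios <- function(peaks, subtractBaseline = FALSE) {
  h <- peakHeights(peaks)
  need <- c("40S", "60S", "80S")
  det <- setNames(peaks@detected, peaks@species)[need]
  if (!all(det))
    stop("species not detected: ", paste(need[!det], collapse = ", "))
  if (subtractBaseline) h <- h - peaks@baseline
  c("60S/40S" = unname(h["60S"] / h["40S"]),
    "80S/40S" = unname(h["80S"] / h["40S"]),
    "80S/60S" = unname(h["80S"] / h["60S"]))
}
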