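# Ion-image rendering: ppm-window extraction, TIC normalisation, quantile
# hotspot clipping, global mass-axis recalibration, mean spectra.
#
# The extraction window is two-sided and relative to the target m/z
# (half-width = target * tol * 1e-6), with inclusive bounds — the community
# convention for "a 10 ppm tolerance".

#' Extract an ion image for one target m/z
#'
#' Per pixel, sums the intensities of every peak whose m/z lies within
#' `tolerance_ppm` of `target_mz` (|mz - target| / target <= tol * 1e-6,
#' bounds inclusive). Pixels with empty spectra yield 0. The result is
#' neither normalised nor clipped; see [tic_normalize()] and
#' [quantile_hotspot_clip()].
#'
#' @param img a [spectral_image()].
#' @param target_mz target m/z in Da; must lie within `img$mz_range`.
#' @param tolerance_ppm mass window half-width in parts per million
#'   (default 10).
#' @return object of class `ion_image`: list with `target_mz`,
#'   `tolerance_ppm`, `raster` (height x width matrix), `normalized`,
#'   `clipped_at`.
#' @export
extract_ion_image <- function(img, target_mz, tolerance_ppm = 10) {
  stopifnot(inherits(img, "spectral_image"), tolerance_ppm > 0)
  if (target_mz < img$mz_range[1] || target_mz > img$mz_range[2])
    stop("target m/z ", target_mz, " outside the acquired range [",
         img$mz_range[1], ", ", img$mz_range[2], "]")
  half <- target_mz * tolerance_ppm * 1e-6
  lo <- target_mz - half; hi <- target_mz + half
  v <- vapply(img$peaks, function(p) {
    if (!length(p$mz)) return(0)
    # mz sorted: bracket the window instead of scanning every peak
    i1 <- findInterval(lo, p$mz, left.open = TRUE) + 1L
    i2 <- findInterval(hi, p$mz)
    if (i1 > i2) 0 else sum(p$intensity[i1:i2])
  }, numeric(1))
  structure(list(target_mz = target_mz, tolerance_ppm = tolerance_ppm,
                 raster = matrix(v, nrow = img$height, ncol = img$width,
                                 byrow = TRUE),
                 normalized = FALSE, clipped_at = NULL),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf(
    "<ion_image> m/z %.4f +/- %g ppm, %d x %d px%s%s\n",
    x$target_mz, x$tolerance_ppm, ncol(x$raster), nrow(x$raster),
    if (x$normalized) ", TIC-normalised" else "",
    if (!is.null(x$clipped_at)) sprintf(", clipped at %g", x$clipped_at)
    else ""))
  invisible(x)
}

#' Total-ion-current normalisation of an ion image
#'
#' Divides each pixel by that pixel's total ion current (the sum of all
#' peak intensities across the full mass range), cancelling per-pixel
#' acquisition variability. Pixels with zero TIC map to 0. Values are pure
#' ratios — no rescaling by the mean TIC is applied, which is immaterial
#' for the scale-invariant Pearson correlation downstream.
#'
#' @param ionimg an [extract_ion_image()] result from `img`.
#' @param img the [spectral_image()] the ion image was extracted from.
#' @return the normalised `ion_image` (`normalized` flag set).
#' @export
tic_normalize <- function(ionimg, img) {
  stopifnot(inherits(ionimg, "ion_image"), inherits(img, "spectral_image"))
  tic <- tic_image(img)
  check_same_shape(ionimg$raster, tic, "ion image and source image")
  out <- ionimg$raster / tic
  out[tic == 0] <- 0
  ionimg$raster <- out
  ionimg$normalized <- TRUE
  ionimg
}

#' Quantile hotspot clipping
#'
#' Computes the `q` quantile (linear interpolation between order
#' statistics) of the nonzero pixel values and caps every value above it at
#' that threshold, so a handful of extreme pixels cannot dominate the
#' display scale. Zeros are off-tissue background and are excluded from the
#' quantile by default (`nonzero_only = FALSE` computes it over all
#' pixels). An all-zero image is returned unchanged with `clipped_at = 0`.
#'
#' Clipping is saturation: an image whose `clipped_at` is already set is
#' returned unchanged, which makes the operation idempotent (re-estimating
#' the quantile on clipped data would otherwise creep the threshold
#' downwards). To clip at a different level, start from the un-clipped
#' image.
#'
#' @param ionimg an `ion_image`.
#' @param q quantile in (0, 1); default 0.99.
#' @param nonzero_only compute the quantile over nonzero pixels only
#'   (default TRUE).
#' @return the clipped `ion_image` with `clipped_at` recorded.
#' @export
quantile_hotspot_clip <- function(ionimg, q = 0.99, nonzero_only = TRUE) {
  stopifnot(inherits(ionimg, "ion_image"), q > 0, q < 1)
  if (!is.null(ionimg$clipped_at)) return(ionimg) # already saturated
  v <- ionimg$raster
  pool <- v[is.finite(v)]
  if (nonzero_only) pool <- pool[pool != 0]
  if (!length(pool)) {
    ionimg$clipped_at <- 0
    return(ionimg)
  }
  thr <- as.numeric(stats::quantile(pool, q, type = 7, names = FALSE))
  v[v > thr] <- thr
  ionimg$raster <- v
  ionimg$clipped_at <- thr
  ionimg
}

#' Fit a global mass-axis recalibration
#'
#' Estimates a single multiplicative m/z correction factor from known
#' reference masses (endogenous lipid signals of known composition). For
#' each reference, all observed peaks within `search_ppm` are pooled across
#' pixels and their intensity-weighted mean m/z is taken as the observed
#' position; the correction factor is the intensity-weighted mean of
#' theoretical/observed ratios over the matched references. References with
#' no peak in the window are skipped and reported.
#'
#' @param img a [spectral_image()].
#' @param references numeric vector of theoretical m/z values.
#' @param search_ppm peak-matching window half-width in ppm (default 30).
#' @return object of class `recal_model`: `factor` (multiplicative),
#'   `shift_ppm`, `pairs` (data.frame observed/theoretical/weight),
#'   `unmatched` (theoretical m/z without a peak in the window).
#' @export
fit_recalibration <- function(img, references, search_ppm = 30) {
  stopifnot(inherits(img, "spectral_image"), length(references) >= 1,
            search_ppm > 0)
  all_mz <- unlist(lapply(img$peaks, `[[`, "mz"), use.names = FALSE)
  all_int <- unlist(lapply(img$peaks, `[[`, "intensity"), use.names = FALSE)
  obs <- thr <- wt <- numeric(0)
  unmatched <- numeric(0)
  for (ref in references) {
    half <- ref * search_ppm * 1e-6
    sel <- all_mz >= ref - half & all_mz <= ref + half & all_int > 0
    if (!any(sel)) { unmatched <- c(unmatched, ref); next }
    w <- all_int[sel]
    obs <- c(obs, sum(all_mz[sel] * w) / sum(w))
    thr <- c(thr, ref)
    wt <- c(wt, sum(w))
  }
  if (!length(obs))
    stop("no reference matched any observed peak within ", search_ppm,
         " ppm; cannot calibrate")
  f <- sum(thr / obs * wt) / sum(wt)
  if (abs(f - 1) > 100e-6)
    warning("fitted correction exceeds 100 ppm (",
            format((f - 1) * 1e6, digits = 3),
            " ppm); check the reference list")
  structure(list(factor = f, shift_ppm = (f - 1) * 1e6,
                 pairs = data.frame(observed = obs, theoretical = thr,
                                    weight = wt),
                 unmatched = unmatched),
            class = "recal_model")
}

#' @export
print.recal_model <- function(x, ...) {
  cat(sprintf("<recal_model> correction %+.3f ppm from %d reference(s)%s\n",
              x$shift_ppm, nrow(x$pairs),
              if (length(x$unmatched))
                sprintf(" (%d unmatched)", length(x$unmatched)) else ""))
  invisible(x)
}

#' Apply a mass-axis recalibration
#'
#' Multiplies every stored m/z by the fitted correction factor; intensities
#' are untouched. The mass range is rescaled accordingly.
#'
#' @param img a [spectral_image()].
#' @param model a [fit_recalibration()] result (or a bare numeric factor).
#' @return the recalibrated [spectral_image()].
#' @export
apply_recalibration <- function(img, model) {
  stopifnot(inherits(img, "spectral_image"))
  f <- if (inherits(model, "recal_model")) model$factor else as.numeric(model)
  stopifnot(is.finite(f), f > 0)
  img$peaks <- lapply(img$peaks, function(p)
    list(mz = p$mz * f, intensity = p$intensity))
  img$mz_range <- img$mz_range * f
  img
}

#' Mean spectrum over all pixels
#'
#' Pools every peak of every pixel into ppm-constant (geometrically spaced)
#' m/z bins and reports the per-bin mean intensity per pixel — pixels
#' without a peak in a bin contribute 0 — so images of different tissue
#' coverage remain comparable.
#'
#' @param img a [spectral_image()].
#' @param bin_width_ppm bin width in ppm (default 5).
#' @return data.frame with `mz` (geometric bin centre) and
#'   `mean_intensity`, nonempty bins only, ascending m/z.
#' @export
mean_spectrum <- function(img, bin_width_ppm = 5) {
  stopifnot(inherits(img, "spectral_image"), bin_width_ppm > 0)
  all_mz <- unlist(lapply(img$peaks, `[[`, "mz"), use.names = FALSE)
  all_int <- unlist(lapply(img$peaks, `[[`, "intensity"), use.names = FALSE)
  if (!length(all_mz))
    return(data.frame(mz = numeric(0), mean_intensity = numeric(0)))
  w <- bin_width_ppm * 1e-6
  m0 <- if (is.finite(img$mz_range[1]) && img$mz_range[1] > 0)
    img$mz_range[1] else min(all_mz)
  idx <- floor(log(all_mz / m0) / log1p(w))
  tot <- tapply(all_int, idx, sum)
  k <- as.numeric(names(tot))
  centers <- m0 * (1 + w)^(k + 0.5) # geometric bin centre
  n_px <- length(img$peaks)
  data.frame(mz = centers, mean_intensity = as.numeric(tot) / n_px)[
    order(centers), , drop = FALSE]
}
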