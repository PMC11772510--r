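# Core containers for the two imaging modalities.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based, col = x, row = y, origin top-left,
#     pixel centers at integer coordinates;
#   * rasters are base-R matrices of dim c(height, width), so
#     raster[row + 1, col + 1] is the pixel at (row, col);
#   * per-pixel spectra are stored in row-major order, index
#     row * width + col + 1;
#   * missing elemental values are NA_real_ (0 is a legitimate count).

#' Construct a centroided spectral image
#'
#' A pixel grid where every pixel holds a centroided mass spectrum, the
#' in-memory form of a MALDI-type imaging run. The grid is always complete:
#' off-tissue or unacquired pixels hold an empty spectrum, never an absent
#' entry.
#'
#' @param peaks list of length `width * height`, in row-major order (pixel
#'   `(row, col)` at index `row * width + col + 1`); each element a list with
#'   numeric vectors `mz` (Da, strictly increasing) and `intensity` (>= 0).
#' @param width,height pixel counts.
#' @param pixel_size isotropic pixel edge in micrometres.
#' @param mz_range length-2 numeric, acquisition mass range in Da; defaults
#'   to the range of the stored peaks (or c(0, Inf) for an all-empty image).
#' @param metadata free-form named list (polarity, source description, ...).
#' @return object of class `spectral_image`.
#' @export
spectral_image <- function(peaks, width, height, pixel_size = 30,
                           mz_range = NULL, metadata = list()) {
  stopifnot(width >= 1, height >= 1, pixel_size > 0)
  if (length(peaks) != width * height)
    stop("`peaks` must have exactly width * height = ", width * height,
         " entries (got ", length(peaks), "); represent missing pixels as ",
         "empty spectra")
  peaks <- lapply(peaks, function(p) {
    if (is.null(p)) p <- list(mz = numeric(0), intensity = numeric(0))
    mz <- as.numeric(p$mz); int <- as.numeric(p$intensity)
    if (length(mz) != length(int))
      stop("mz and intensity lengths differ within one pixel")
    if (any(int < 0)) stop("negative peak intensity")
    if (is.unsorted(mz, strictly = TRUE)) {
      o <- order(mz)
      mz <- mz[o]; int <- int[o]
      if (anyDuplicated(mz)) {
        # merge exact duplicates so the strictly-increasing invariant holds
        int <- as.numeric(tapply(int, mz, sum))
        mz <- sort(unique(mz))
      }
    }
    list(mz = mz, intensity = int)
  })
  all_mz <- unlist(lapply(peaks, `[[`, "mz"), use.names = FALSE)
  if (is.null(mz_range)) {
    mz_range <- if (length(all_mz)) range(all_mz) else c(0, Inf)
  }
  mz_range <- as.numeric(mz_range)
  stopifnot(length(mz_range) == 2, mz_range[1] <= mz_range[2])
  if (length(all_mz) && (min(all_mz) < mz_range[1] || max(all_mz) > mz_range[2]))
    stop("stored m/z values fall outside mz_range [", mz_range[1], ", ",
         mz_range[2], "]")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size = pixel_size, peaks = peaks, mz_range = mz_range,
         metadata = metadata),
    class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  n_peaks <- sum(lengths(lapply(x$peaks, `[[`, "mz")))
  cat(sprintf(
    "<spectral_image> %d x %d pixels @ %g um, m/z %g-%g, %d peaks total\n",
    x$width, x$height, x$pixel_size, x$mz_range[1], x$mz_range[2], n_peaks))
  invisible(x)
}

#' Retrieve one pixel's spectrum
#' @param img a [spectral_image()].
#' @param row,col 0-based pixel coordinates.
#' @return list with `mz` and `intensity`.
#' @export
pixel_spectrum <- function(img, row, col) {
  stopifnot(inherits(img, "spectral_image"),
            row >= 0, row < img$height, col >= 0, col < img$width)
  img$peaks[[row * img$width + col + 1]]
}

#' Per-pixel total ion current
#'
#' Sum of all peak intensities in each pixel's spectrum across the full
#' acquired mass range; the denominator of TIC normalisation and the basis
#' of the tissue mask.
#'
#' @param img a [spectral_image()].
#' @return height x width matrix of TIC values (0 for empty spectra).
#' @export
tic_image <- function(img) {
  stopifnot(inherits(img, "spectral_image"))
  v <- vapply(img$peaks, function(p) sum(p$intensity), numeric(1))
  matrix(v, nrow = img$height, ncol = img$width, byrow = TRUE)
}

#' Construct an elemental image stack
#'
#' A named set of co-gridded per-element rasters, each carrying its own
#' unit. Quantified (mg/kg) and unquantified (counts/s) channels may
#' coexist, as when only a subset of isotopes has external calibration
#' standards.
#'
#' @param channels named list of height x width numeric matrices
#'   (NA = missing, distinct from a 0 count).
#' @param pixel_size pixel edge in micrometres.
#' @param units character vector, one of `"counts_per_second"` or
#'   `"mg_per_kg"` per channel; recycled if length 1.
#' @param metadata free-form named list.
#' @return object of class `elemental_stack`.
#' @export
elemental_stack <- function(channels, pixel_size = 30,
                            units = "counts_per_second", metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1, pixel_size > 0)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named by its element label (e.g. \"66Zn\")")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("channels must be matrices")
  d0 <- dims[[1]]
  ok <- vapply(dims, function(d) identical(d, d0), logical(1))
  if (!all(ok))
    stop("channel rasters disagree in shape: ",
         paste(names(channels)[!ok], collapse = ", "))
  units <- rep_len(units, length(channels))
  bad <- setdiff(unique(units), c("counts_per_second", "mg_per_kg"))
  if (length(bad)) stop("unknown unit(s): ", paste(bad, collapse = ", "))
  names(units) <- names(channels)
  structure(
    list(width = as.integer(d0[2]), height = as.integer(d0[1]),
         pixel_size = pixel_size,
         channels = lapply(channels, function(m) {
           storage.mode(m) <- "double"; m
         }),
         units = units, metadata = metadata),
    class = "elemental_stack")
}

#' @export
print.elemental_stack <- function(x, ...) {
  cat(sprintf("<elemental_stack> %d x %d pixels @ %g um\n",
              x$width, x$height, x$pixel_size))
  for (el in names(x$channels))
    cat(sprintf("  %-6s [%s]  missing: %d px\n", el, x$units[[el]],
                sum(is.na(x$channels[[el]]))))
  invisible(x)
}

#' Landmark correspondences between two modality grids
#'
#' Paired pixel coordinates identifying the same anatomical points in the
#' fixed and moving images, the serialised equivalent of interactively
#' clicked multi-image landmark pairs.
#'
#' @param fixed,moving two-column numeric matrices (x, y) in each modality's
#'   own 0-based pixel coordinates; equal row counts.
#' @param labels optional character vector of point names.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(fixed, moving, labels = NULL) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  storage.mode(fixed) <- storage.mode(moving) <- "double"
  if (nrow(fixed) < 1) stop("no landmarks")
  if (!identical(dim(fixed), dim(moving)) || ncol(fixed) != 2)
    stop("fixed and moving must be n x 2 matrices of equal size")
  if (!all(is.finite(fixed)) || !all(is.finite(moving)))
    stop("landmark coordinates must be finite")
  colnames(fixed) <- colnames(moving) <- c("x", "y")
  if (!is.null(labels) && length(labels) != nrow(fixed))
    stop("labels length must match the number of pairs")
  structure(list(fixed = fixed, moving = moving, labels = labels),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d pairs\n", nrow(x$fixed)))
  invisible(x)
}

#' One LA-ICP-MS laser ablation line
#'
#' A single time-resolved line scan: counts-per-second readings per element
#' at strictly increasing timestamps, plus the scan geometry needed to map
#' time onto along-line position (position = time x scan speed).
#'
#' @param time_s numeric, seconds since line start, strictly increasing.
#' @param counts data.frame (or named list) of equal-length numeric
#'   counts-per-second vectors, one column per element.
#' @param y_offset line start offset across lines, micrometres.
#' @param scan_speed stage speed in micrometres per second.
#' @param beam_diameter laser spot size in micrometres.
#' @param line_index optional integer identifier.
#' @return object of class `laser_line`.
#' @export
laser_line <- function(time_s, counts, y_offset, scan_speed = 750,
                       beam_diameter = 30, line_index = NA_integer_) {
  time_s <- as.numeric(time_s)
  if (length(time_s) < 1) stop("empty line")
  if (is.unsorted(time_s, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  counts <- as.data.frame(counts)
  if (nrow(counts) != length(time_s))
    stop("element series length must equal the number of timestamps")
  stopifnot(scan_speed > 0, beam_diameter > 0)
  structure(list(time_s = time_s, counts = counts,
                 y_offset = as.numeric(y_offset), scan_speed = scan_speed,
                 beam_diameter = beam_diameter,
                 line_index = as.integer(line_index)),
            class = "laser_line")
}

# shared internal: shape check for two rasters
check_same_shape <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b)))
    stop(what, " differ in shape: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
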