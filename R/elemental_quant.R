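# LA-ICP-MS quantification: line-scan rasterization and external
# calibration against spiked gelatine standards.

#' Rasterize time-resolved laser line scans
#'
#' Maps each reading to an along-line position (timestamp x scan speed) and
#' averages the readings falling in `[k * pixel_size, (k + 1) * pixel_size)`
#' into pixel `k` of that line's row — half-open intervals, so every reading
#' contributes to exactly one pixel. Rows are ordered by `y_offset`; lines
#' shorter than the longest are padded with missing values.
#'
#' @param lines list of [laser_line()] objects sharing scan speed and
#'   element set.
#' @param pixel_size output pixel edge in micrometres; defaults to the
#'   laser beam diameter of the first line (a 30 um beam at 750 um/s gives
#'   a 0.04 s pixel dwell).
#' @param fun aggregator within a pixel: `"mean"` (default) or `"median"`.
#' @return an [elemental_stack()] in counts per second.
#' @export
rasterize_lines <- function(lines, pixel_size = NULL,
                            fun = c("mean", "median")) {
  fun <- match.arg(fun)
  agg <- if (fun == "mean") mean else stats::median
  if (!length(lines)) stop("empty line list")
  stopifnot(all(vapply(lines, inherits, logical(1), "laser_line")))
  speeds <- vapply(lines, `[[`, numeric(1), "scan_speed")
  if (length(unique(speeds)) != 1)
    stop("all lines must share one scan speed")
  elements <- names(lines[[1]]$counts)
  same <- vapply(lines, function(l)
    identical(names(l$counts), elements), logical(1))
  if (!all(same)) stop("lines disagree in their element set")
  if (is.null(pixel_size)) pixel_size <- lines[[1]]$beam_diameter
  stopifnot(pixel_size > 0)

  offs <- vapply(lines, `[[`, numeric(1), "y_offset")
  if (anyDuplicated(offs)) stop("overlapping line y_offsets")
  lines <- lines[order(offs)]

  per_line <- lapply(lines, function(l) {
    pix <- floor(l$time_s * l$scan_speed / pixel_size)
    lapply(l$counts, function(v)
      tapply(v, pix, agg))
  })
  width <- max(vapply(per_line, function(pl)
    max(as.numeric(names(pl[[1]]))) + 1, numeric(1)))
  height <- length(lines)
  channels <- lapply(elements, function(el) {
    m <- matrix(NA_real_, nrow = height, ncol = width)
    for (r in seq_len(height)) {
      vals <- per_line[[r]][[el]]
      m[r, as.numeric(names(vals)) + 1] <- as.numeric(vals)
    }
    m
  })
  names(channels) <- elements
  elemental_stack(channels, pixel_size = pixel_size,
                  units = "counts_per_second",
                  metadata = list(scan_speed = speeds[1],
                                  beam_diameter = lines[[1]]$beam_diameter,
                                  aggregator = fun))
}

#' Describe one spiked gelatine calibration standard
#'
#' @param element element label (e.g. `"66Zn"`).
#' @param nominal_concentration spiked concentration in mg/kg (>= 0; the
#'   0 mg/kg blank carries the gelatine background).
#' @param observed numeric vector of counts-per-second readings ablated
#'   from the standard (>= 1 reading).
#' @return object of class `calibration_standard`.
#' @export
calibration_standard <- function(element, nominal_concentration, observed) {
  stopifnot(nominal_concentration >= 0, length(observed) >= 1,
            all(is.finite(observed)))
  structure(list(element = element,
                 nominal_concentration = nominal_concentration,
                 observed = as.numeric(observed)),
            class = "calibration_standard")
}

#' Fit an external calibration curve
#'
#' Ordinary least squares of per-standard summarised counts (mean by
#' default) against nominal concentration, intercept fitted — the gelatine
#' matrix has a nonzero blank, so the line is not forced through zero.
#'
#' @param standards list of [calibration_standard()] objects for one
#'   element; >= 2 distinct nominal concentrations required.
#' @param fun per-standard summary of readings: `"mean"` (default) or
#'   `"median"`.
#' @return object of class `calibration_curve`: `element`, `slope`
#'   (counts/s per mg/kg), `intercept` (counts/s), `r_squared`,
#'   `n_standards`, `negative_slope` flag.
#' @export
fit_calibration <- function(standards, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  summ <- if (fun == "mean") mean else stats::median
  stopifnot(length(standards) >= 2,
            all(vapply(standards, inherits, logical(1),
                       "calibration_standard")))
  el <- unique(vapply(standards, `[[`, character(1), "element"))
  if (length(el) != 1)
    stop("standards mix elements: ", paste(el, collapse = ", "))
  conc <- vapply(standards, `[[`, numeric(1), "nominal_concentration")
  if (length(unique(conc)) < 2)
    stop("need >= 2 distinct nominal concentrations to fit a line")
  y <- vapply(standards, function(s) summ(s$observed), numeric(1))
  fit <- stats::lm(y ~ conc)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2) # direct r^2: no perfect-fit warnings
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  curve <- structure(
    list(element = el, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_standards = length(standards),
         negative_slope = slope <= 0),
    class = "calibration_curve")
  if (curve$negative_slope)
    warning("non-positive calibration slope for ", el,
            "; curve flagged unusable")
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: slope %.4g cps per mg/kg, intercept %.4g cps, r^2 %.4f (n = %d)%s\n",
    x$element, x$slope, x$intercept, x$r_squared, x$n_standards,
    if (x$negative_slope) " [NEGATIVE SLOPE]" else ""))
  invisible(x)
}

#' Quantify elemental channels against calibration curves
#'
#' Transforms each requested channel as
#' `concentration = (counts - intercept) / slope`, relabelling its unit to
#' mg/kg. Channels not requested pass through untouched in counts per
#' second — mirroring runs where only a subset of isotopes has usable
#' standards (high endogenous background in gelatine precludes the rest).
#' Negative concentrations are reported, not clamped (clamping would bias
#' region means and correlations); affected pixel counts are recorded in
#' the stack metadata as a QC flag.
#'
#' @param stack an [elemental_stack()].
#' @param curves named list of [fit_calibration()] curves, keyed by
#'   element label.
#' @param elements channels to quantify; default: every channel with a
#'   curve.
#' @return the stack with requested channels in mg/kg.
#' @export
apply_calibration <- function(stack, curves,
                              elements = intersect(names(stack$channels),
                                                   names(curves))) {
  stopifnot(inherits(stack, "elemental_stack"))
  missing_curve <- setdiff(elements, names(curves))
  if (length(missing_curve))
    stop("no calibration curve for: ", paste(missing_curve, collapse = ", "))
  missing_chan <- setdiff(elements, names(stack$channels))
  if (length(missing_chan))
    stop("no such channel: ", paste(missing_chan, collapse = ", "))
  neg <- integer(0)
  for (el in elements) {
    cv <- curves[[el]]
    stopifnot(inherits(cv, "calibration_curve"))
    if (cv$negative_slope)
      stop("calibration curve for ", el, " has a non-positive slope")
    q <- (stack$channels[[el]] - cv$intercept) / cv$slope
    neg[el] <- sum(q < 0, na.rm = TRUE)
    stack$channels[[el]] <- q
    stack$units[[el]] <- "mg_per_kg"
  }
  stack$metadata$negative_concentration_pixels <- as.list(neg)
  stack
}

#' Write a calibration report as CSV
#' @param curves named list of [fit_calibration()] curves.
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
write_calibration_report <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(element = cv$element, slope = cv$slope,
               intercept = cv$intercept, r_squared = cv$r_squared,
               n_standards = cv$n_standards)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read LA-ICP-MS line scans from CSV plus a run sheet
#'
#' Each line is one CSV with a `time_s` column followed by one column per
#' element; the YAML run sheet holds `scan_speed`, `beam_diameter` and a
#' `lines:` list of `{file, y_offset}` entries.
#'
#' @param run_sheet path to the YAML run sheet; line CSV paths are resolved
#'   relative to it.
#' @return list of [laser_line()] objects ready for [rasterize_lines()].
#' @export
read_line_scans <- function(run_sheet) {
  rs <- yaml::read_yaml(run_sheet)
  base <- dirname(run_sheet)
  if (is.null(rs$lines) || !length(rs$lines))
    stop("run sheet lists no lines: ", run_sheet)
  lapply(seq_along(rs$lines), function(i) {
    entry <- rs$lines[[i]]
    df <- utils::read.csv(file.path(base, entry$file))
    if (!"time_s" %in% names(df))
      stop("line CSV lacks a time_s column: ", entry$file)
    laser_line(time_s = df$time_s,
               counts = df[setdiff(names(df), "time_s")],
               y_offset = entry$y_offset,
               scan_speed = rs$scan_speed %||% 750,
               beam_diameter = rs$beam_diameter %||% 30,
               line_index = i)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
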