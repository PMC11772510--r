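# Paired two-modality phantoms with analytic ground truth.
#
# The phantom emulates a region-structured brain-like section imaged by
# both modalities: nested ellipses stand in for cortex, white matter and a
# hippocampus-like ring, each region carrying its own mean per channel.
# The elemental modality is acquired on a grid misaligned by a known
# similarity transform; lipid pixels carry a random per-pixel TIC factor
# (the quantity TIC normalisation must cancel) and truncated-Gaussian
# multiplicative noise, elemental pixels Poisson counting noise. Ground
# truth (region map, transform, population correlations) stays analytic.

#' Phantom configuration
#'
#' Defaults describe the study conditions the rest of the package is
#' validated under: a 400 x 300 px section (a ~1.2 cm specimen at 30 um
#' pixels), three tissue regions of comparable area, five lipid and five
#' element channels with region means >= 50 counts, 15% multiplicative
#' lipid noise, per-pixel TIC factors in [0.5, 2], Poisson elemental
#' counts, a 5 degree / (4.5, -3.2) px similarity misalignment and 0.5 px
#' landmark jitter.
#'
#' @param width,height grid size in pixels.
#' @param pixel_size pixel edge, micrometres.
#' @param n_regions number of tissue regions R (>= 2).
#' @param geometry `"brain"` (nested ellipses + ring) or `"bands"`
#'   (exact vertical bands, for tests needing exact region splits).
#' @param margin off-tissue fraction: for `"bands"`, the exact fraction of
#'   columns left as background; for `"brain"`, the gap between the tissue
#'   ellipse and the grid edge.
#' @param lipids data.frame with `name` and `mz` of the lipid channels.
#' @param elements character vector of element labels.
#' @param channel_means (n_lipids + n_elements) x R matrix of region mean
#'   intensities, rows named by channel; NULL for the built-in defaults.
#' @param lipid_cv multiplicative lipid noise coefficient of variation.
#' @param tic_range range of the uniform per-pixel TIC factor.
#' @param poisson Poisson-sample elemental counts?
#' @param mass_shift_ppm global m/z shift injected into rendered spectra
#'   (for recalibration recovery tests).
#' @param mz_jitter_ppm per-peak Gaussian m/z jitter, ppm.
#' @param landmark_sigma landmark coordinate jitter, px.
#' @param rotation_deg,translation,scale similarity misalignment applied
#'   to the elemental modality (moving -> fixed, about the grid centre).
#' @param seed integer; fully determines all rendered outputs.
#' @return named list of class `phantom_config`.
#' @export
phantom_config <- function(width = 400, height = 300, pixel_size = 30,
                           n_regions = 3, geometry = c("brain", "bands"),
                           margin = 0.1,
                           lipids = NULL, elements = NULL,
                           channel_means = NULL,
                           lipid_cv = 0.15, tic_range = c(0.5, 2),
                           poisson = TRUE,
                           mass_shift_ppm = 0, mz_jitter_ppm = 0,
                           landmark_sigma = 0.5,
                           rotation_deg = 5, translation = c(4.5, -3.2),
                           scale = 1, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_regions >= 2, width >= 8, height >= 8,
            lipid_cv >= 0, landmark_sigma >= 0)
  if (is.null(lipids))
    lipids <- data.frame(
      name = c("PE 34:1", "PE 36:1", "PE 38:4", "PE 40:6", "HexCer 42:2;2"),
      mz = c(718.53814, 746.56944, 768.55379, 792.55379, 810.68170))
  if (is.null(elements))
    elements <- c("23Na", "24Mg", "31P", "56Fe", "66Zn")
  if (is.null(channel_means)) {
    channel_means <- default_channel_means(lipids$name, elements, n_regions)
  } else {
    channel_means <- as.matrix(channel_means)
    if (nrow(channel_means) != nrow(lipids) + length(elements) ||
        ncol(channel_means) != n_regions)
      stop("channel_means must be (n_lipids + n_elements) x n_regions")
    if (is.null(rownames(channel_means)))
      rownames(channel_means) <- c(lipids$name, elements)
  }
  if (any(channel_means < 0)) stop("channel means must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, n_regions = as.integer(n_regions),
                 geometry = geometry, margin = margin,
                 lipids = lipids, elements = elements,
                 channel_means = channel_means,
                 lipid_cv = lipid_cv, tic_range = tic_range,
                 poisson = poisson, mass_shift_ppm = mass_shift_ppm,
                 mz_jitter_ppm = mz_jitter_ppm,
                 landmark_sigma = landmark_sigma,
                 rotation_deg = rotation_deg, translation = translation,
                 scale = scale, seed = as.integer(seed)),
            class = "phantom_config")
}

# Region means with strong between-region contrast (>= 3x between low and
# high regions for every channel), emulating well-contrasted anatomy:
# region 1 ~ cortex/gray matter, 2 ~ white matter, 3 ~ hippocampus-like
# ring. Strong contrast keeps region structure, not pixel noise, the
# dominant variance component — this is what makes the analytic population
# correlation recoverable from noisy renders. All elemental means >= 50 so
# Poisson counting noise stays moderate relative to the signal.
default_channel_means <- function(lipid_names, elements, R) {
  base <- rbind(
    c(500, 40, 60),     # PE 34:1    cortex-weighted
    c(60, 50, 550),     # PE 36:1    ring-enriched
    c(50, 420, 70),     # PE 38:4    white-matter-weighted
    c(550, 60, 90),     # PE 40:6    cortex-high
    c(60, 560, 80),     # HexCer     white-matter/myelin
    c(1800, 360, 780),  # 23Na
    c(1650, 330, 720),  # 24Mg       tracks the cortical PEs
    c(1350, 360, 780),  # 31P
    c(180, 210, 900),   # 56Fe       ring/ventricle-like
    c(270, 180, 1260))  # 66Zn       hippocampus-ring enriched
  need <- length(lipid_names) + length(elements)
  m <- base[rep_len(seq_len(nrow(base)), need), , drop = FALSE]
  # extend or trim region columns deterministically
  if (R <= 3) m <- m[, seq_len(R), drop = FALSE]
  else m <- cbind(m, m[, rep_len(1:3, R - 3), drop = FALSE] * 0.8)
  rownames(m) <- c(lipid_names, elements)
  colnames(m) <- paste0("region", seq_len(R))
  m
}

#' Generate a phantom
#'
#' Builds the region map and the ground-truth misalignment transform.
#' Deterministic given the config (the seed governs the later renders).
#'
#' @param config a [phantom_config()].
#' @param seed optional override of `config$seed`.
#' @return object of class `phantom`: the config fields plus `region_map`
#'   (height x width integer matrix, 0 = off-tissue) and `true_transform`
#'   (an [affine2d()], moving -> fixed).
#' @export
generate_phantom <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  w <- config$width; h <- config$height; R <- config$n_regions

  if (config$geometry == "bands") {
    n_bg <- floor(config$margin * w)
    n_tissue <- w - n_bg
    per <- n_tissue %/% R
    if (per < 1) stop("infeasible geometry: fewer tissue columns than regions")
    cols <- integer(w)
    # leftover columns go to the last region so splits stay exact elsewhere
    breaks <- n_bg + per * seq_len(R - 1)
    cols[seq_len(w) > n_bg] <- 1L
    for (r in 2:R) cols[seq_len(w) > breaks[r - 1]] <- as.integer(r)
    region_map <- matrix(rep(cols, each = h), nrow = h, ncol = w)
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    a <- (1 - config$margin) * w / 2; b <- (1 - config$margin) * h / 2
    if (a < 2 || b < 2) stop("infeasible geometry: margin leaves no tissue")
    X <- matrix(rep(0:(w - 1), each = h), nrow = h)
    Y <- matrix(rep(0:(h - 1), times = w), nrow = h)
    rad <- function(ax, by, x0 = cx, y0 = cy)
      ((X - x0) / ax)^2 + ((Y - y0) / by)^2
    region_map <- matrix(0L, h, w)
    region_map[rad(a, b) <= 1] <- 1L # tissue / cortex
    if (R >= 3) { # hippocampus-like elliptical ring
      rr <- rad(0.86 * a, 0.835 * b)
      region_map[region_map > 0 & rr <= 1 & rr > 0.45] <- 3L
    }
    if (R >= 2) # inner white-matter ellipse
      region_map[rad(0.50 * a, 0.50 * b, cx, cy + 0.05 * h) <= 1] <- 2L
    if (R > 3) { # additional small blobs for R > 3
      for (r in 4:R) {
        ang <- 2 * pi * (r - 3) / (R - 2)
        region_map[rad(0.12 * a, 0.12 * b,
                       cx + 0.55 * a * cos(ang),
                       cy + 0.55 * b * sin(ang)) <= 1 & region_map > 0] <-
          as.integer(r)
      }
    }
  }
  n_tis <- sum(region_map > 0)
  areas <- tabulate(region_map[region_map > 0], nbins = R)
  if (any(areas < 0.01 * n_tis))
    stop("infeasible geometry: region(s) ",
         paste(which(areas < 0.01 * n_tis), collapse = ", "),
         " cover < 1% of tissue")

  th <- config$rotation_deg * pi / 180
  A <- config$scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)),
                             2, 2, byrow = TRUE)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  b_vec <- ctr - as.numeric(A %*% ctr) + config$translation
  true_transform <- affine2d(A, b_vec, family = "similarity")

  out <- c(unclass(config),
           list(region_map = region_map, true_transform = true_transform,
                region_areas = areas))
  class(out) <- "phantom"
  out
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d x %d px, %d regions (%s tissue px), %d lipid + %d element channels, seed %d\n",
    x$width, x$height, x$n_regions, sum(x$region_map > 0),
    nrow(x$lipids), length(x$elements), x$seed))
  invisible(x)
}

#' Render the spectral (lipid) modality of a phantom
#'
#' Per tissue pixel, one peak per lipid m/z with base intensity
#' `max(0, Normal(mean, cv * mean))`, all peaks multiplied by a per-pixel
#' TIC factor drawn uniformly from `tic_range` — the explicit mechanism
#' that makes TIC normalisation consequential. Off-tissue pixels hold
#' empty spectra. A configured global mass shift and per-peak m/z jitter
#' are applied multiplicatively. Deterministic given the phantom seed.
#'
#' @param phantom a [generate_phantom()] result.
#' @return a [spectral_image()] with `mz_range = c(200, 1000)`.
#' @export
render_spectral <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  set.seed(phantom$seed)
  w <- phantom$width; h <- phantom$height
  nl <- nrow(phantom$lipids)
  mz0 <- phantom$lipids$mz * (1 + phantom$mass_shift_ppm * 1e-6)
  means <- phantom$channel_means[phantom$lipids$name, , drop = FALSE]
  reg <- as.vector(t(phantom$region_map)) # row-major to match peak order
  peaks <- vector("list", w * h)
  tissue <- which(reg > 0)
  n_t <- length(tissue)
  base <- matrix(0, n_t, nl)
  for (j in seq_len(nl)) {
    mu <- means[j, reg[tissue]]
    base[, j] <- pmax(0, stats::rnorm(n_t, mu, phantom$lipid_cv * mu))
  }
  ticf <- stats::runif(n_t, phantom$tic_range[1], phantom$tic_range[2])
  jit <- if (phantom$mz_jitter_ppm > 0)
    matrix(1 + stats::rnorm(n_t * nl, 0, phantom$mz_jitter_ppm * 1e-6),
           n_t, nl) else matrix(1, n_t, nl)
  empty <- list(mz = numeric(0), intensity = numeric(0))
  for (i in seq_len(w * h)) peaks[[i]] <- empty
  for (k in seq_len(n_t)) {
    mz <- mz0 * jit[k, ]
    o <- order(mz)
    peaks[[tissue[k]]] <- list(mz = mz[o],
                               intensity = base[k, o] * ticf[k])
  }
  spectral_image(peaks, width = w, height = h,
                 pixel_size = phantom$pixel_size, mz_range = c(200, 1000),
                 metadata = list(polarity = "positive", source = "phantom"))
}

#' Render the elemental modality of a phantom
#'
#' Samples the elemental rasters on a grid displaced by the ground-truth
#' transform (each moving pixel takes the region under its mapped fixed
#' position), with Poisson counting noise when configured. Also emits six
#' fiducial landmark pairs mapped through the true transform with Gaussian
#' jitter, and optionally per-line time series consistent with the scan
#' geometry (pixel dwell = pixel size / scan speed) for exercising
#' [rasterize_lines()]. Deterministic given the phantom seed.
#'
#' @param phantom a [generate_phantom()] result.
#' @param emit_lines also build the per-line time-series representation?
#' @param scan_speed stage speed for the emitted lines, um/s.
#' @param readings_per_pixel ICP readings emitted per pixel dwell.
#' @return list with `stack` (moving-frame [elemental_stack()]),
#'   `landmarks` (a [landmark_set()], fixed = spectral frame) and `lines`
#'   (list of [laser_line()] or NULL).
#' @export
render_elemental <- function(phantom, emit_lines = FALSE, scan_speed = 750,
                             readings_per_pixel = 4) {
  stopifnot(inherits(phantom, "phantom"))
  set.seed(phantom$seed + 1L)
  w <- phantom$width; h <- phantom$height
  els <- phantom$elements
  means <- phantom$channel_means[els, , drop = FALSE]

  # region under each moving pixel center, via the true moving->fixed map
  grid <- cbind(x = rep(0:(w - 1), times = h), y = rep(0:(h - 1), each = w))
  fpos <- transform_points(phantom$true_transform, grid)
  fx <- round(fpos[, 1]); fy <- round(fpos[, 2])
  inside <- fx >= 0 & fx < w & fy >= 0 & fy < h
  reg <- integer(w * h)
  reg[inside] <- phantom$region_map[cbind(fy[inside] + 1, fx[inside] + 1)]

  channels <- lapply(els, function(el) {
    mu <- numeric(w * h)
    mu[reg > 0] <- means[el, reg[reg > 0]]
    v <- if (phantom$poisson) stats::rpois(w * h, mu) else mu
    matrix(v, nrow = h, ncol = w, byrow = TRUE)
  })
  names(channels) <- els
  stack <- elemental_stack(channels, pixel_size = phantom$pixel_size,
                           units = "counts_per_second",
                           metadata = list(source = "phantom"))

  # fiducials at the section periphery: a wide design minimises affine
  # extrapolation error over the tissue
  fixed_pts <- cbind(
    x = (w - 1) * c(0.05, 0.95, 0.05, 0.95, 0.50, 0.50),
    y = (h - 1) * c(0.05, 0.05, 0.95, 0.95, 0.05, 0.95))
  moving_pts <- transform_points(invert_transform(phantom$true_transform),
                                 fixed_pts)
  if (phantom$landmark_sigma > 0)
    moving_pts <- moving_pts +
      matrix(stats::rnorm(length(moving_pts), 0, phantom$landmark_sigma),
             ncol = 2)
  landmarks <- landmark_set(fixed_pts, moving_pts,
                            labels = paste0("fid", seq_len(nrow(fixed_pts))))

  lines <- NULL
  if (emit_lines) {
    dwell <- phantom$pixel_size / scan_speed
    dt <- dwell / readings_per_pixel
    lines <- lapply(seq_len(h), function(r) {
      times <- as.vector(vapply(0:(w - 1), function(k)
        k * dwell + (seq_len(readings_per_pixel) - 0.5) * dt,
        numeric(readings_per_pixel)))
      counts <- lapply(els, function(el)
        rep(stack$channels[[el]][r, ], each = readings_per_pixel))
      names(counts) <- els
      laser_line(times, counts, y_offset = (r - 1) * phantom$pixel_size,
                 scan_speed = scan_speed,
                 beam_diameter = phantom$pixel_size, line_index = r)
    })
  }
  list(stack = stack, landmarks = landmarks, lines = lines)
}

#' Analytic population correlation of a phantom channel pair
#'
#' The Pearson coefficient the pipeline should recover: computed in closed
#' form from region areas and channel means over the tissue mask, with the
#' lipid channel taken after noiseless TIC normalisation (its per-region
#' value is the channel mean divided by the summed lipid means of that
#' region, exactly what a noise-free pipeline produces). Constant channels
#' yield NA, the explicit undefined marker.
#'
#' @param phantom a [generate_phantom()] result.
#' @param lipid_channel lipid name (row of `channel_means`).
#' @param element_channel element label.
#' @return population Pearson r, or NA if undefined.
#' @export
expected_correlation <- function(phantom, lipid_channel, element_channel) {
  stopifnot(inherits(phantom, "phantom"))
  if (!lipid_channel %in% phantom$lipids$name)
    stop("unknown lipid channel: ", lipid_channel)
  if (!element_channel %in% phantom$elements)
    stop("unknown element channel: ", element_channel)
  areas <- phantom$region_areas
  lip_means <- phantom$channel_means[phantom$lipids$name, , drop = FALSE]
  x <- lip_means[lipid_channel, ] / colSums(lip_means) # TIC-normalised
  y <- phantom$channel_means[element_channel, ]
  wts <- areas / sum(areas)
  mx <- sum(wts * x); my <- sum(wts * y)
  vx <- sum(wts * (x - mx)^2); vy <- sum(wts * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(wts * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' All-pairs analytic correlation matrix of a phantom
#' @param phantom a [generate_phantom()] result.
#' @return matrix lipids x elements of population Pearson coefficients.
#' @export
expected_correlation_matrix <- function(phantom) {
  ln <- phantom$lipids$name; en <- phantom$elements
  m <- matrix(NA_real_, length(ln), length(en), dimnames = list(ln, en))
  for (i in ln) for (j in en) m[i, j] <- expected_correlation(phantom, i, j)
  m
}

#' Simulate readings ablated from spiked calibration standards
#'
#' Counts follow `slope * concentration + intercept` with optional Poisson
#' counting noise, emulating gelatine standards with a nonzero blank.
#'
#' @param element element label.
#' @param concentrations nominal mg/kg levels (one standard each).
#' @param slope,intercept true response, counts/s per mg/kg and blank
#'   counts/s.
#' @param n_readings readings per standard.
#' @param poisson add Poisson noise?
#' @return list of [calibration_standard()] objects.
#' @export
simulate_standards <- function(element, concentrations = c(0, 10, 20, 40),
                               slope = 50, intercept = 200,
                               n_readings = 200, poisson = TRUE) {
  lapply(concentrations, function(cc) {
    mu <- slope * cc + intercept
    obs <- if (poisson) stats::rpois(n_readings, mu) else rep(mu, n_readings)
    calibration_standard(element, cc, obs)
  })
}

#' End-to-end phantom recovery harness
#'
#' Runs the complete analysis chain in memory on one phantom: render both
#' modalities, extract and TIC-normalise one ion image per lipid target,
#' fit external calibration curves from simulated gelatine standards and
#' quantify the requested elements, estimate the landmark transform,
#' resample the elemental stack onto the spectral grid, build the shared
#' mask and compute the pairwise Pearson matrix — the same stage order the
#' file-based pipeline runs. Used to validate that the pipeline recovers
#' the phantom's analytic population correlations.
#'
#' @param phantom a [generate_phantom()] result.
#' @param quantify_elements element channels to pass through the fit/apply
#'   calibration step (Pearson correlation is invariant to this affine
#'   map; the step is included so the full chain is exercised). NULL or
#'   empty to skip.
#' @param tolerance_ppm ion-image extraction window, ppm.
#' @param family transform family for [estimate_transform()].
#' @param interpolation resampling scheme for [resample_to_fixed()].
#' @return list with `correlation` (the [pearson_matrix()] result),
#'   `expected` (the analytic [expected_correlation_matrix()]),
#'   `transform`, `mask` and `curves`.
#' @export
correlate_phantom <- function(phantom,
                              quantify_elements = c("56Fe", "66Zn"),
                              tolerance_ppm = 10, family = "auto",
                              interpolation = "bilinear") {
  stopifnot(inherits(phantom, "phantom"))
  simg <- render_spectral(phantom)
  el <- render_elemental(phantom)
  stack <- el$stack
  curves <- NULL
  quantify_elements <- intersect(quantify_elements, phantom$elements)
  if (length(quantify_elements)) {
    set.seed(phantom$seed + 2L)
    curves <- lapply(quantify_elements, function(eln)
      fit_calibration(simulate_standards(eln, c(0, 10, 20, 40),
                                         slope = 50, intercept = 200,
                                         n_readings = 200,
                                         poisson = phantom$poisson)))
    names(curves) <- quantify_elements
    stack <- apply_calibration(stack, curves, quantify_elements)
  }
  tr <- estimate_transform(el$landmarks, family = family)
  reg <- resample_to_fixed(stack, tr,
                           fixed_shape = c(phantom$height, phantom$width),
                           interpolation = interpolation)
  mask <- build_mask(tic_image(simg), reg)
  lipids <- lapply(seq_len(nrow(phantom$lipids)), function(i)
    tic_normalize(extract_ion_image(simg, phantom$lipids$mz[i],
                                    tolerance_ppm), simg))
  names(lipids) <- phantom$lipids$name
  list(correlation = pearson_matrix(lipids, reg, mask),
       expected = expected_correlation_matrix(phantom),
       transform = tr, mask = mask, curves = curves)
}
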