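# Masked pixel-to-pixel Pearson correlation between the registered lipid
# and element stacks, heatmap export, and two-colour composites.

#' Build the shared tissue mask
#'
#' TRUE where the spectral modality recorded signal (TIC > 0) and every
#' elemental channel is non-missing; the correlation is computed over this
#' mask so off-tissue and out-of-overlap pixels never enter.
#'
#' @param spectral_tic height x width TIC raster (see [tic_image()]).
#' @param elemental a registered [elemental_stack()] on the same grid.
#' @return logical height x width matrix.
#' @export
build_mask <- function(spectral_tic, elemental) {
  stopifnot(inherits(elemental, "elemental_stack"))
  m <- spectral_tic > 0
  for (ch in elemental$channels) {
    check_same_shape(spectral_tic, ch, "TIC raster and elemental channel")
    m <- m & !is.na(ch)
  }
  m
}

#' Pairwise Pearson correlation between two channel stacks
#'
#' For every (lipid, element) pair, the Pearson coefficient over the mask
#' pixels where both values are present (pairwise-complete deletion per
#' cell, maximising usable pixels for each pair). A cell is undefined (NA)
#' when fewer than 2 complete pixels remain or either channel is constant
#' over them — an explicit marker, never silently 0.
#'
#' @param lipid_stack named list of `ion_image`s (or bare rasters) on the
#'   fixed grid; typically TIC-normalised, un-clipped images.
#' @param element_stack a registered [elemental_stack()].
#' @param mask logical matrix from [build_mask()]; needs >= 2 TRUE pixels.
#' @return object of class `correlation_matrix`: `r` (lipids x elements),
#'   `n_pixels` (complete pixels per cell), `mask_summary`.
#' @export
pearson_matrix <- function(lipid_stack, element_stack, mask) {
  stopifnot(inherits(element_stack, "elemental_stack"))
  rasters <- lapply(lipid_stack, function(x)
    if (inherits(x, "ion_image")) x$raster else x)
  if (is.null(names(rasters)) || any(!nzchar(names(rasters))))
    stop("lipid channels must be named")
  if (sum(mask, na.rm = TRUE) < 2) stop("mask has fewer than 2 pixels")
  for (r in rasters) check_same_shape(mask, r, "mask and lipid raster")
  for (r in element_stack$channels)
    check_same_shape(mask, r, "mask and elemental raster")

  lip_names <- names(rasters)
  el_names <- names(element_stack$channels)
  r_mat <- n_mat <- matrix(NA_real_, length(lip_names), length(el_names),
                           dimnames = list(lip_names, el_names))
  idx <- which(mask)
  for (i in seq_along(lip_names)) {
    x <- rasters[[i]][idx]
    for (j in seq_along(el_names)) {
      y <- element_stack$channels[[j]][idx]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      n_mat[i, j] <- n
      if (n >= 2 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
        r_mat[i, j] <- stats::cor(x[ok], y[ok])
    }
  }
  structure(list(r = r_mat, n_pixels = n_mat,
                 row_labels = lip_names, col_labels = el_names,
                 mask_summary = sum(mask)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d lipid x %d element channels over %d mask pixels\n",
              nrow(x$r), ncol(x$r), x$mask_summary))
  print(round(x$r, 3))
  invisible(x)
}

#' Two-channel false-colour composite
#'
#' Each raster is independently clipped at its own `display_q` quantile
#' (nonzero values), rescaled to `[0, 1]`, assigned to the palette's two
#' colours and additively blended: `red_blue` maps a -> red, b -> blue;
#' `magenta_cyan` maps a -> magenta (R+B), b -> cyan (G+B), so equal-signal
#' pixels tend toward white. Masked-out or missing pixels are black.
#'
#' @param a,b numeric rasters of equal shape (lipid and element channel).
#' @param palette `"red_blue"` or `"magenta_cyan"`.
#' @param mask optional logical matrix; FALSE pixels render black.
#' @param display_q quantile clip applied per channel for display
#'   (default 0.99).
#' @return height x width x 3 RGB array in `[0, 1]`.
#' @export
composite_overlay <- function(a, b, palette = c("red_blue", "magenta_cyan"),
                              mask = NULL, display_q = 0.99) {
  palette <- match.arg(palette)
  check_same_shape(a, b, "composite channels")
  scale01 <- function(v) {
    v[is.na(v)] <- 0
    pool <- v[v != 0]
    if (length(pool)) {
      thr <- as.numeric(stats::quantile(pool, display_q, type = 7))
      if (thr > 0) { v[v > thr] <- thr; v <- v / thr }
    }
    pmin(pmax(v, 0), 1)
  }
  av <- scale01(a); bv <- scale01(b)
  if (!is.null(mask)) {
    check_same_shape(a, mask, "composite channels and mask")
    av[!mask] <- 0; bv[!mask] <- 0
  }
  rgb <- array(0, dim = c(nrow(a), ncol(a), 3))
  if (palette == "red_blue") {
    rgb[, , 1] <- av
    rgb[, , 3] <- bv
  } else {
    rgb[, , 1] <- av          # magenta = R + B
    rgb[, , 2] <- bv          # cyan    = G + B
    rgb[, , 3] <- pmin(av + bv, 1)
  }
  rgb[, , 1] <- pmin(rgb[, , 1], 1)
  rgb[, , 2] <- pmin(rgb[, , 2], 1)
  rgb[, , 3] <- pmin(rgb[, , 3], 1)
  rgb
}

#' Export a correlation matrix as CSV and heatmap PNG
#'
#' The CSV has lipid channels as rows and element channels as columns;
#' undefined cells serialise as `NA`. The PNG renders each cell as a block
#' coloured on a blue-white-red diverging scale centred at r = 0.
#'
#' @param cm a [pearson_matrix()] result.
#' @param path output stem or CSV path; the heatmap lands next to it as
#'   `<stem>.png`.
#' @param cell_px block edge in pixels for the heatmap (default 24).
#' @return invisibly, the files written.
#' @export
export_heatmap <- function(cm, path, cell_px = 24) {
  stopifnot(inherits(cm, "correlation_matrix"))
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  png_path <- sub("\\.csv$", ".png", csv)
  ok <- tryCatch({
    utils::write.csv(as.data.frame(cm$r), csv, row.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write ", csv)

  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  r <- cm$r
  v <- pmin(pmax((as.vector(r) + 1) / 2, 0), 1)
  nav <- is.na(v)
  v[nav] <- 0.5
  cols <- ramp(v) / 255
  cols[nav, ] <- 0.5 # undefined cells in neutral grey
  img <- array(0, dim = c(nrow(r), ncol(r), 3))
  for (k in 1:3) img[, , k] <- matrix(cols[, k], nrow(r), ncol(r))
  big <- array(0, dim = c(nrow(r) * cell_px, ncol(r) * cell_px, 3))
  for (k in 1:3)
    big[, , k] <- img[rep(seq_len(nrow(r)), each = cell_px),
                      rep(seq_len(ncol(r)), each = cell_px), k]
  png::writePNG(big, png_path)
  invisible(c(csv, png_path))
}

#' Read back a heatmap CSV
#' @param path CSV written by [export_heatmap()].
#' @return numeric matrix with row/column labels.
#' @export
read_heatmap_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
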