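# Plain-text I/O for the elemental modality and for landmark files.
# CSV dialect: comma-separated, "." decimal; "NA" or an empty cell marks a
# missing value (0 is a real count and is never treated as missing).

#' Read elemental rasters from CSV
#'
#' Two layouts are accepted. *Grid* (default): one CSV per element, rows =
#' y, columns = x, no header; with a directory, every `*.csv` becomes a
#' channel named by its file stem. *Long*: a single CSV with header columns
#' `element,row,col,value` (0-based pixel coordinates).
#'
#' Units come from a `stack.yaml` sidecar (keys `units:` per element and
#' optional `pixel_size:`) when present, else from the `unit` argument.
#'
#' @param path a CSV file or a directory of per-element CSV grids.
#' @param format `"grid"` or `"long"`.
#' @param unit default unit for channels without sidecar metadata.
#' @param pixel_size pixel edge in micrometres (sidecar wins if present).
#' @return an [elemental_stack()].
#' @export
read_element_csv <- function(path, format = c("grid", "long"),
                             unit = "counts_per_second", pixel_size = 30) {
  format <- match.arg(format)
  sidecar <- NULL
  if (dir.exists(path)) {
    sc_path <- file.path(path, "stack.yaml")
    if (file.exists(sc_path)) sidecar <- yaml::read_yaml(sc_path)
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no CSV files in ", path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    sc_path <- file.path(dirname(path), "stack.yaml")
    if (file.exists(sc_path)) sidecar <- yaml::read_yaml(sc_path)
    files <- path
  }

  if (format == "long") {
    df <- utils::read.csv(files[[1]], na.strings = c("NA", ""))
    need <- c("element", "row", "col", "value")
    if (!all(need %in% names(df)))
      stop("long-format CSV needs columns ", paste(need, collapse = ", "))
    h <- max(df$row) + 1L; w <- max(df$col) + 1L
    channels <- lapply(split(df, factor(df$element,
                                        levels = unique(df$element))),
                       function(d) {
                         m <- matrix(NA_real_, h, w)
                         m[cbind(d$row + 1L, d$col + 1L)] <- d$value
                         m
                       })
  } else {
    channels <- lapply(files, read_grid_csv)
    names(channels) <- sub("\\.csv$", "", basename(files))
    dims <- vapply(channels, dim, integer(2))
    if (length(channels) > 1 && any(dims[1, ] != dims[1, 1] |
                                    dims[2, ] != dims[2, 1])) {
      bad <- names(channels)[dims[1, ] != dims[1, 1] |
                             dims[2, ] != dims[2, 1]]
      stop("element grids disagree in dimensions: ",
           paste(bad, collapse = ", "))
    }
  }

  units <- rep_len(unit, length(channels))
  names(units) <- names(channels)
  if (!is.null(sidecar)) {
    if (!is.null(sidecar$units))
      for (el in intersect(names(channels), names(sidecar$units)))
        units[[el]] <- sidecar$units[[el]]
    if (!is.null(sidecar$pixel_size)) pixel_size <- sidecar$pixel_size
  }
  elemental_stack(channels, pixel_size = pixel_size, units = units)
}

# headerless numeric grid; errors carry the 1-based offending row index
read_grid_csv <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CSV grid: ", file)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol <- length(cells[[1]])
  bad <- which(lengths(cells) != ncol)
  if (length(bad))
    stop("ragged CSV grid in ", file, ": row ", bad[1], " has ",
         length(cells[[bad[1]]]), " cells, expected ", ncol)
  vals <- lapply(cells, function(r) {
    r <- trimws(r)
    r[r %in% c("NA", "")] <- NA
    suppressWarnings(as.numeric(r))
  })
  bad_cell <- which(vapply(seq_along(vals), function(i)
    any(is.na(vals[[i]]) & !(trimws(cells[[i]]) %in% c("NA", ""))),
    logical(1)))
  if (length(bad_cell))
    stop("non-numeric cell in ", file, ", row ", bad_cell[1])
  matrix(unlist(vals), nrow = length(vals), ncol = ncol, byrow = TRUE)
}

#' Write an elemental stack as per-element CSV grids
#'
#' One headerless CSV grid per channel (named `<element>.csv`) plus a
#' `stack.yaml` sidecar recording units and pixel size, in the dialect
#' [read_element_csv()] reads back.
#'
#' @param stack an [elemental_stack()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_element_csv <- function(stack, dir) {
  stopifnot(inherits(stack, "elemental_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (el in names(stack$channels)) {
    m <- stack$channels[[el]]
    txt <- apply(m, 1, function(r) {
      r <- format(r, digits = 17, scientific = FALSE, trim = TRUE)
      r[r == "NA"] <- "NA"
      paste(r, collapse = ",")
    })
    writeLines(txt, file.path(dir, paste0(el, ".csv")))
  }
  yaml::write_yaml(list(units = as.list(stack$units),
                        pixel_size = stack$pixel_size),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' Read landmark correspondences from TSV
#'
#' Expects a header with columns `x_fixed`, `y_fixed`, `x_moving`,
#' `y_moving` (0-based pixel coordinates of each modality's own grid); an
#' optional `label` column is preserved.
#'
#' @param path TSV file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("x_fixed", "y_fixed", "x_moving", "y_moving")
  if (!all(need %in% names(df)))
    stop("landmark TSV needs columns ", paste(need, collapse = ", "))
  if (nrow(df) < 1) stop("no landmarks in ", path)
  num <- df[need]
  if (!all(vapply(num, is.numeric, logical(1))))
    stop("non-numeric landmark coordinates in ", path)
  landmark_set(fixed = cbind(df$x_fixed, df$y_fixed),
               moving = cbind(df$x_moving, df$y_moving),
               labels = if ("label" %in% names(df))
                 as.character(df$label) else NULL)
}

#' Write landmark correspondences to TSV
#' @param lm a [landmark_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(x_fixed = lm$fixed[, 1], y_fixed = lm$fixed[, 2],
                   x_moving = lm$moving[, 1], y_moving = lm$moving[, 2])
  if (!is.null(lm$labels)) df$label <- lm$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a raster as CSV grid and/or greyscale PNG
#'
#' The PNG is 16-bit greyscale after rescaling the finite values to
#' `[0, 1]`; missing pixels render black.
#'
#' @param raster numeric matrix.
#' @param csv,png optional output paths; each written when non-NULL.
#' @return invisibly, a character vector of the files written.
#' @export
write_raster <- function(raster, csv = NULL, png = NULL) {
  written <- character(0)
  if (!is.null(csv)) {
    txt <- apply(raster, 1, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = ","))
    writeLines(txt, csv)
    written <- c(written, csv)
  }
  if (!is.null(png)) {
    v <- raster
    fin <- is.finite(v)
    rng <- if (any(fin)) range(v[fin]) else c(0, 1)
    scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    scaled[!fin] <- 0
    png::writePNG(scaled, png, dpi = NULL)
    written <- c(written, png)
  }
  invisible(written)
}
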