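# Stage orchestration: simulate / extract / quantify / correlate, wired the
# way the two-modality workflow runs in practice (lipid imaging first, then
# elemental imaging, then registration and correlation). Stage outputs are
# files, not in-memory handoffs, so each stage is independently runnable
# and testable; every run writes a provenance record.

#' Load a pipeline run configuration
#'
#' A flat YAML file of paths and parameters. Unset parameters fall back to
#' the workflow defaults: 10 ppm extraction tolerance, TIC normalisation
#' on, 0.99 hotspot quantile, 5 ppm annotation tolerance, affine (auto)
#' transform family, bilinear interpolation.
#'
#' @param path YAML config path, or a named list already in memory.
#' @return named list of class `run_config`; relative paths are resolved
#'   against the config file's directory.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- if (is.character(path)) dirname(normalizePath(path)) else "."
  defaults <- list(
    tolerance_ppm = 10, tic_normalize = TRUE, hotspot_q = 0.99,
    annotation_ppm = 5, transform_family = "auto",
    interpolation = "bilinear", palette = "both",
    clip_before_correlation = FALSE,
    output_dir = file.path(base, "out"), seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("imzml", "elements_dir", "line_sheet", "landmarks",
              "targets", "lipid_db", "calibration", "output_dir"))
    if (!is.null(cfg[[k]]) && !startsWith(cfg[[k]], "/"))
      cfg[[k]] <- file.path(base, cfg[[k]])
  if (is.character(path)) cfg$config_path <- normalizePath(path)
  class(cfg) <- c("run_config", "list")
  cfg
}

write_provenance <- function(cfg, stage, extra = list()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("msimodal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = if (!is.null(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA,
    seed = cfg$seed,
    tolerance_ppm = cfg$tolerance_ppm,
    tic_normalize = cfg$tic_normalize,
    hotspot_q = cfg$hotspot_q,
    annotation_ppm = cfg$annotation_ppm,
    transform_family = cfg$transform_family,
    interpolation = cfg$interpolation), extra)
  yaml::write_yaml(prov, file.path(cfg$output_dir,
                                   paste0("provenance_", stage, ".yaml")))
  invisible(prov)
}

stage_msg <- function(...) message("[msimodal] ", ...)

#' Simulate a phantom dataset on disk
#'
#' Generates a phantom from the config's `phantom:` block (any
#' [phantom_config()] argument may appear there), renders both modalities
#' and writes them through the standard writers — imzML for the lipid
#' modality, per-element CSV grids for the (misaligned) elemental modality,
#' a landmark TSV, a target list CSV — plus a ground-truth sidecar (region
#' map CSV, true transform record, analytic correlation table), so
#' phantoms and real data enter the pipeline identically.
#'
#' @param cfg a [run_config()] (or path to one).
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pargs <- cfg$phantom %||% list()
  pargs$seed <- pargs$seed %||% cfg$seed
  pc <- do.call(phantom_config, pargs)
  ph <- generate_phantom(pc)
  stage_msg("simulate: ", ph$width, "x", ph$height, " phantom, ",
            sum(ph$region_map > 0), " tissue px, seed ", ph$seed)

  simg <- render_spectral(ph)
  write_imzml(simg, file.path(out, "phantom.imzML"))
  elem <- render_elemental(ph)
  write_element_csv(elem$stack, file.path(out, "elements"))
  write_landmarks(elem$landmarks, file.path(out, "landmarks.tsv"))
  utils::write.csv(data.frame(label = ph$lipids$name, mz = ph$lipids$mz),
                   file.path(out, "targets.csv"), row.names = FALSE)

  truth_dir <- file.path(out, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_raster(ph$region_map + 0, csv = file.path(truth_dir, "region_map.csv"))
  write_transform(ph$true_transform, file.path(truth_dir, "true_transform.txt"))
  ecm <- expected_correlation_matrix(ph)
  utils::write.csv(as.data.frame(ecm),
                   file.path(truth_dir, "expected_correlation.csv"),
                   row.names = TRUE)
  write_provenance(cfg, "simulate",
                   list(phantom_seed = ph$seed,
                        tissue_pixels = sum(ph$region_map > 0)))
  invisible(out)
}

safe_label <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Extract, normalise and clip ion images for every target
#'
#' Runs extract -> TIC-normalise -> quantile clip per target lipid and
#' writes, per target, the normalised un-clipped raster (the correlation
#' input, `ion_<label>.csv`) and a clipped display raster
#' (`ion_<label>_display.csv/.png`), plus the TIC raster and an accurate-
#' mass annotation report against the configured lipid database.
#'
#' @param cfg a [run_config()]; needs `imzml` and `targets` paths.
#' @return invisibly, the named list of normalised `ion_image`s.
#' @export
run_extract <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(cfg$imzml)) stop("extract: config lacks an `imzml` path")
  if (is.null(cfg$targets)) stop("extract: config lacks a `targets` path")
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  img <- read_imzml(cfg$imzml)
  targets <- utils::read.csv(cfg$targets)
  if (!all(c("label", "mz") %in% names(targets)))
    stop("extract: target list needs columns label, mz")
  stage_msg("extract: ", length(img$peaks), " pixels, ",
            nrow(targets), " targets, tolerance ", cfg$tolerance_ppm, " ppm")

  write_raster(tic_image(img), csv = file.path(out, "tic.csv"))
  images <- list()
  for (i in seq_len(nrow(targets))) {
    ii <- extract_ion_image(img, targets$mz[i], cfg$tolerance_ppm)
    if (isTRUE(cfg$tic_normalize)) ii <- tic_normalize(ii, img)
    lab <- safe_label(targets$label[i])
    write_raster(ii$raster, csv = file.path(out, paste0("ion_", lab, ".csv")))
    disp <- quantile_hotspot_clip(ii, q = cfg$hotspot_q)
    write_raster(disp$raster,
                 csv = file.path(out, paste0("ion_", lab, "_display.csv")),
                 png = file.path(out, paste0("ion_", lab, "_display.png")))
    stage_msg("  ", targets$label[i], ": ",
              sum(ii$raster > 0), " nonzero px, clip at ",
              format(disp$clipped_at, digits = 4))
    images[[as.character(targets$label[i])]] <- ii
  }

  db_path <- cfg$lipid_db %||%
    system.file("extdata", "lipid_db.csv", package = "msimodal")
  db <- read_lipid_db(db_path)
  ann <- annotate(targets$mz, db, tolerance_ppm = cfg$annotation_ppm)
  write_annotation_report(ann, file.path(out, "annotation_report.csv"))
  write_provenance(cfg, "extract",
                   list(n_targets = nrow(targets),
                        n_pixels = length(img$peaks)))
  invisible(images)
}

#' Rasterize (if needed) and quantify the elemental modality
#'
#' Reads per-element CSV grids (`elements_dir`) or time-resolved line
#' scans (`line_sheet`), fits external calibration curves from the
#' config's calibration sheet and converts the requested channels to
#' mg/kg; unlisted channels pass through in counts per second. Writes the
#' quantified stack and a calibration report.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the quantified [elemental_stack()].
#' @export
run_quantify <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stack <- if (!is.null(cfg$line_sheet)) {
    rasterize_lines(read_line_scans(cfg$line_sheet))
  } else if (!is.null(cfg$elements_dir)) {
    read_element_csv(cfg$elements_dir)
  } else stop("quantify: config needs `elements_dir` or `line_sheet`")
  stage_msg("quantify: ", length(stack$channels), " channels on ",
            stack$width, "x", stack$height, " grid")

  curves <- list()
  if (!is.null(cfg$calibration)) {
    cal <- yaml::read_yaml(cfg$calibration)
    for (el in names(cal)) {
      standards <- lapply(cal[[el]], function(s) {
        obs <- if (!is.null(s$readings_file))
          utils::read.csv(file.path(dirname(cfg$calibration),
                                    s$readings_file))[[1]]
        else unlist(s$readings)
        calibration_standard(el, s$concentration, obs)
      })
      curves[[el]] <- fit_calibration(standards)
      stage_msg("  ", el, ": slope ",
                format(curves[[el]]$slope, digits = 4), ", r^2 ",
                format(curves[[el]]$r_squared, digits = 4))
    }
    write_calibration_report(curves,
                             file.path(out, "calibration_report.csv"))
    quantify <- cfg$quantify_elements %||%
      intersect(names(stack$channels), names(curves))
    stack <- apply_calibration(stack, curves, quantify)
  }
  write_element_csv(stack, file.path(out, "quantified"))
  write_provenance(cfg, "quantify",
                   list(n_channels = length(stack$channels),
                        quantified = names(which(stack$units == "mg_per_kg"))))
  invisible(stack)
}

#' Register the modalities and correlate all channel pairs
#'
#' Fits the landmark transform, resamples the elemental stack onto the
#' spectral grid, builds the shared tissue mask, computes the pairwise
#' Pearson matrix and writes the heatmap (CSV + PNG), the fitted transform
#' and two-colour composites for every (lipid, element) pair in the
#' requested palette(s). Requires the extract and quantify outputs in
#' `output_dir`.
#'
#' @param cfg a [run_config()]; needs `landmarks`.
#' @return invisibly, the [pearson_matrix()] result.
#' @export
run_correlate <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  out <- cfg$output_dir
  tic_path <- file.path(out, "tic.csv")
  if (!file.exists(tic_path))
    stop("correlate: missing extract outputs in ", out,
         " (run the extract stage first)")
  qdir <- file.path(out, "quantified")
  if (!dir.exists(qdir))
    stop("correlate: missing quantify outputs in ", out,
         " (run the quantify stage first)")
  if (is.null(cfg$landmarks)) stop("correlate: config lacks `landmarks`")

  tic <- read_grid_csv(tic_path)
  ion_files <- list.files(out, pattern = "^ion_.*\\.csv$")
  ion_files <- ion_files[!grepl("_display\\.csv$", ion_files)]
  if (!length(ion_files))
    stop("correlate: no ion images in ", out,
         " (run the extract stage first)")
  lipids <- lapply(file.path(out, ion_files), read_grid_csv)
  names(lipids) <- sub("^ion_(.*)\\.csv$", "\\1", ion_files)
  stack <- read_element_csv(qdir)

  lm <- read_landmarks(cfg$landmarks)
  tr <- estimate_transform(lm, family = cfg$transform_family)
  stage_msg("correlate: ", tr$family, " transform from ", nrow(lm$fixed),
            " landmarks, residual rmse ",
            format(tr$residual_rmse, digits = 3), " px")
  write_transform(tr, file.path(out, "transform.txt"))
  reg <- resample_to_fixed(stack, tr, fixed_shape = dim(tic),
                           interpolation = cfg$interpolation)
  mask <- build_mask(tic, reg)
  stage_msg("  mask: ", sum(mask), " / ", length(mask), " pixels")
  if (isTRUE(cfg$clip_before_correlation))
    lipids <- lapply(lipids, function(m) {
      ii <- structure(list(raster = m, normalized = TRUE, clipped_at = NULL,
                           target_mz = NA, tolerance_ppm = NA),
                      class = "ion_image")
      quantile_hotspot_clip(ii, q = cfg$hotspot_q)$raster
    })
  cm <- pearson_matrix(lipids, reg, mask)
  export_heatmap(cm, file.path(out, "correlation_heatmap.csv"))
  utils::write.csv(as.data.frame(cm$n_pixels),
                   file.path(out, "correlation_npixels.csv"))

  palettes <- if (identical(cfg$palette, "both"))
    c("red_blue", "magenta_cyan") else cfg$palette
  pairs <- cfg$composite_pairs
  if (is.null(pairs)) {
    pairs <- expand.grid(lipid = names(lipids),
                         element = names(reg$channels),
                         stringsAsFactors = FALSE)
  } else {
    pairs <- do.call(rbind, lapply(pairs, function(p)
      data.frame(lipid = p[[1]], element = p[[2]])))
  }
  comp_dir <- file.path(out, "composites")
  dir.create(comp_dir, showWarnings = FALSE)
  for (k in seq_len(nrow(pairs))) for (pal in palettes) {
    rgbimg <- composite_overlay(lipids[[pairs$lipid[k]]],
                                reg$channels[[pairs$element[k]]],
                                palette = pal, mask = mask,
                                display_q = cfg$hotspot_q)
    png::writePNG(rgbimg, file.path(
      comp_dir, paste0(safe_label(pairs$lipid[k]), "_vs_",
                       safe_label(pairs$element[k]), "_", pal, ".png")))
  }
  write_provenance(cfg, "correlate",
                   list(fitted_family = tr$family,
                        residual_rmse = tr$residual_rmse,
                        mask_pixels = sum(mask)))
  invisible(cm)
}

#' Run the full workflow
#'
#' simulate (when a `phantom:` block is present and inputs are absent),
#' then extract, quantify and correlate.
#'
#' @param cfg a [run_config()] or path to one.
#' @return invisibly, the [pearson_matrix()] result.
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (!is.null(cfg$phantom) && is.null(cfg$imzml)) {
    out <- run_simulate(cfg)
    cfg$imzml <- file.path(out, "phantom.imzML")
    cfg$elements_dir <- file.path(out, "elements")
    cfg$landmarks <- file.path(out, "landmarks.tsv")
    cfg$targets <- file.path(out, "targets.csv")
  }
  run_extract(cfg)
  run_quantify(cfg)
  run_correlate(cfg)
}
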