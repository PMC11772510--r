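# imzML I/O: the open XML + external-binary (.ibd) format for MS imaging.
# Processed-mode, centroided, uncompressed 64-bit data on write; the reader
# additionally accepts continuous-mode layouts and zlib-compressed arrays.
# imzML positions are 1-based; the package convention is 0-based, shifted at
# this boundary only.

IMZML_CV <- list(
  processed   = "IMS:1000031", continuous = "IMS:1000030",
  pos_x       = "IMS:1000050", pos_y      = "IMS:1000051",
  max_x       = "IMS:1000042", max_y      = "IMS:1000043",
  pixel_x     = "IMS:1000046", pixel_y    = "IMS:1000047",
  ext_offset  = "IMS:1000102", ext_len    = "IMS:1000103",
  ext_enc_len = "IMS:1000104", uuid       = "IMS:1000080",
  mz_array    = "MS:1000514",  int_array  = "MS:1000515",
  centroid    = "MS:1000127",  profile    = "MS:1000128",
  f64 = "MS:1000523", f32 = "MS:1000521",
  i64 = "MS:1000522", i32 = "MS:1000519",
  no_compress = "MS:1000576",  zlib = "MS:1000574")

ibd_path_for <- function(path) {
  sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
}

#' Write a spectral image to imzML
#'
#' Writes a processed-mode, centroided imzML file (64-bit m/z and intensity
#' arrays, no compression) plus its binary `.ibd` companion next to it.
#' `read_imzml(write_imzml(x))` reproduces `x` up to floating-point
#' precision. The binary file's UUID is derived from the peak data, so
#' identical images always serialise to byte-identical files.
#'
#' @param img a [spectral_image()].
#' @param path output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(img, path) {
  stopifnot(inherits(img, "spectral_image"))
  if (!grepl("\\.imzml$", path, ignore.case = TRUE))
    path <- paste0(path, ".imzML")
  ibd <- ibd_path_for(path)

  n <- length(img$peaks)
  lens <- vapply(img$peaks, function(p) length(p$mz), integer(1))
  # data section layout: per spectrum, mz doubles then intensity doubles
  mz_off <- int_off <- numeric(n)
  off <- 16 # after the UUID
  for (i in seq_len(n)) {
    mz_off[i] <- off;  off <- off + 8 * lens[i]
    int_off[i] <- off; off <- off + 8 * lens[i]
  }

  data_tmp <- tempfile(fileext = ".bin")
  con <- file(data_tmp, "wb")
  for (p in img$peaks) {
    writeBin(as.double(p$mz), con, size = 8, endian = "little")
    writeBin(as.double(p$intensity), con, size = 8, endian = "little")
  }
  close(con)
  uuid_hex <- unname(tools::md5sum(data_tmp)) # content-derived, deterministic
  uuid_raw <- as.raw(strtoi(substring(uuid_hex, seq(1, 31, 2),
                                      seq(2, 32, 2)), 16L))
  con <- tryCatch(file(ibd, "wb"),
                  error = function(e) stop("cannot write ", ibd))
  writeBin(uuid_raw, con)
  writeBin(readBin(data_tmp, "raw", n = file.size(data_tmp)), con)
  close(con)
  unlink(data_tmp)
  uuid_str <- paste0("{", substr(uuid_hex, 1, 8), "-", substr(uuid_hex, 9, 12),
                     "-", substr(uuid_hex, 13, 16), "-",
                     substr(uuid_hex, 17, 20), "-", substr(uuid_hex, 21, 32),
                     "}")

  cv <- function(acc, name, value = NULL) {
    ref <- if (startsWith(acc, "IMS")) "IMS" else "MS"
    if (is.null(value))
      sprintf('<cvParam cvRef="%s" accession="%s" name="%s"/>',
              ref, acc, name)
    else
      sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
              ref, acc, name, format(value, digits = 17, scientific = FALSE))
  }
  spectra_xml <- character(n)
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% img$width
    col <- (i - 1L) %%  img$width
    spectra_xml[i] <- paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, lens[i]),
      cv(IMZML_CV$centroid, "centroid spectrum"),
      '<scanList count="1"><scan>',
      cv(IMZML_CV$pos_x, "position x", col + 1L),
      cv(IMZML_CV$pos_y, "position y", row + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv(IMZML_CV$ext_len, "external array length", lens[i]),
      cv(IMZML_CV$ext_enc_len, "external encoded length", 8 * lens[i]),
      cv(IMZML_CV$ext_offset, "external offset", mz_off[i]),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv(IMZML_CV$ext_len, "external array length", lens[i]),
      cv(IMZML_CV$ext_enc_len, "external encoded length", 8 * lens[i]),
      cv(IMZML_CV$ext_offset, "external offset", int_off[i]),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    cv(IMZML_CV$processed, "processed"),
    cv(IMZML_CV$centroid, "centroid spectrum"),
    cv(IMZML_CV$uuid, "universally unique identifier", uuid_str),
    sprintf('<userParam name="mz_range_min" value="%s"/>',
            format(img$mz_range[1], digits = 17)),
    sprintf('<userParam name="mz_range_max" value="%s"/>',
            format(img$mz_range[2], digits = 17)),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv(IMZML_CV$mz_array, "m/z array"),
    cv(IMZML_CV$f64, "64-bit float"),
    cv(IMZML_CV$no_compress, "no compression"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv(IMZML_CV$int_array, "intensity array"),
    cv(IMZML_CV$f64, "64-bit float"),
    cv(IMZML_CV$no_compress, "no compression"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv(IMZML_CV$max_x, "max count of pixels x", img$width),
    cv(IMZML_CV$max_y, "max count of pixels y", img$height),
    cv(IMZML_CV$pixel_x, "pixel size (x)", img$pixel_size),
    cv(IMZML_CV$pixel_y, "pixel size y", img$pixel_size),
    "</scanSettings></scanSettingsList>",
    sprintf('<run id="run1"><spectrumList count="%d" defaultDataProcessingRef="dp1">', n),
    paste0(spectra_xml, collapse = ""),
    "</spectrumList></run></mzML>")
  ok <- tryCatch({ writeLines(xml, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write ", path)
  invisible(path)
}

# collect accession -> value for all cvParams under a node (non-recursive
# into sibling spectra; callers pass a scoped node)
cv_params <- function(node) {
  ps <- xml2::xml_find_all(node, ".//cvParam")
  stats::setNames(xml2::xml_attr(ps, "value"), xml2::xml_attr(ps, "accession"))
}

#' Read a centroided imzML file
#'
#' Supports processed- and continuous-mode layouts with 32/64-bit float or
#' integer arrays, uncompressed or zlib-compressed. Profile-mode data are
#' rejected: this package operates on peak lists only. Pixels absent from
#' the file are filled with empty spectra so the returned grid is always
#' complete; spectra with non-increasing m/z are re-sorted with a warning.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit
#'   next to it.
#' @return a [spectral_image()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd))
    stop("binary companion not found for ", path, " (expected ", ibd, ")")
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed imzML XML in ", path, ": ",
                         conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  fc_cv <- if (!inherits(fc, "xml_missing")) cv_params(fc) else character(0)
  if (IMZML_CV$profile %in% names(fc_cv))
    stop("profile-mode imzML is not supported (", path,
         "); centroid the data first")

  # array type/compression from the referenceable param groups
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_info <- list()
  for (g in groups) {
    acc <- names(cv_params(g))
    group_info[[xml2::xml_attr(g, "id")]] <- acc
    if (IMZML_CV$profile %in% acc)
      stop("profile-mode imzML is not supported (", path,
           "); centroid the data first")
  }

  specs <- xml2::xml_find_all(doc, ".//run//spectrum")
  if (!length(specs)) stop("no spectra found in ", path)

  ss_cv <- cv_params(xml2::xml_find_first(doc, ".//scanSettingsList"))
  num_or <- function(v, default) if (length(v) && !is.na(v))
    as.numeric(v) else default
  pixel_size <- num_or(ss_cv[IMZML_CV$pixel_x], 30)

  ibd_size <- file.size(ibd)
  con <- file(ibd, "rb")
  on.exit(close(con))

  read_array <- function(bda) {
    acc <- cv_params(bda)
    ref <- xml2::xml_attr(
      xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
    all_acc <- c(names(acc),
                 if (!is.na(ref)) group_info[[ref]] else character(0))
    offset <- as.numeric(acc[[IMZML_CV$ext_offset]])
    n_elem <- as.numeric(acc[[IMZML_CV$ext_len]])
    enc_len <- if (IMZML_CV$ext_enc_len %in% names(acc))
      as.numeric(acc[[IMZML_CV$ext_enc_len]]) else NA_real_
    if (is.na(offset) || is.na(n_elem))
      stop("spectrum array missing external offset/length in ", path)
    type <- if (IMZML_CV$f64 %in% all_acc) list(what = "double", size = 8)
      else if (IMZML_CV$f32 %in% all_acc) list(what = "double", size = 4)
      else if (IMZML_CV$i64 %in% all_acc) list(what = "integer", size = 8)
      else if (IMZML_CV$i32 %in% all_acc) list(what = "integer", size = 4)
      else list(what = "double", size = 8)
    zlib <- IMZML_CV$zlib %in% all_acc
    nbytes <- if (zlib) enc_len else n_elem * type$size
    if (is.na(nbytes) || offset + nbytes > ibd_size)
      stop("binary array exceeds .ibd size in ", ibd)
    seek(con, where = offset, origin = "start")
    if (zlib) {
      comp <- readBin(con, "raw", n = nbytes)
      rawv <- tryCatch(memDecompress(comp, type = "gzip"),
                       error = function(e)
                         stop("failed to inflate zlib array in ", ibd))
      readBin(rawv, type$what, n = n_elem, size = type$size,
              endian = "little")
    } else {
      readBin(con, type$what, n = n_elem, size = type$size,
              endian = "little")
    }
  }

  pos <- matrix(NA_integer_, nrow = length(specs), ncol = 2)
  spectra <- vector("list", length(specs))
  n_unsorted <- 0L
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sc <- cv_params(xml2::xml_find_first(sp, ".//scanList"))
    x1 <- as.integer(sc[[IMZML_CV$pos_x]])
    y1 <- as.integer(sc[[IMZML_CV$pos_y]])
    if (is.na(x1) || is.na(y1))
      stop("spectrum ", i, " lacks pixel position in ", path)
    pos[i, ] <- c(x1 - 1L, y1 - 1L) # to 0-based
    mz <- int <- numeric(0)
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      all_acc <- c(names(cv_params(bda)),
                   if (!is.na(ref)) group_info[[ref]] else character(0))
      if (IMZML_CV$mz_array %in% all_acc) mz <- read_array(bda)
      else if (IMZML_CV$int_array %in% all_acc) int <- read_array(bda)
    }
    if (length(mz) != length(int))
      stop("m/z and intensity array lengths differ in spectrum ", i,
           " of ", path)
    if (is.unsorted(mz, strictly = TRUE)) {
      n_unsorted <- n_unsorted + 1L
      o <- order(mz); mz <- mz[o]; int <- int[o]
    }
    spectra[[i]] <- list(mz = mz, intensity = int)
  }
  if (n_unsorted > 0)
    warning(n_unsorted, " spectrum/spectra had non-increasing m/z; ",
            "peaks re-sorted ascending")

  width  <- as.integer(num_or(ss_cv[IMZML_CV$max_x], max(pos[, 1]) + 1L))
  height <- as.integer(num_or(ss_cv[IMZML_CV$max_y], max(pos[, 2]) + 1L))
  peaks <- rep(list(list(mz = numeric(0), intensity = numeric(0))),
               width * height)
  for (i in seq_along(spectra)) {
    idx <- pos[i, 2] * width + pos[i, 1] + 1L
    if (idx < 1 || idx > length(peaks))
      stop("pixel position (", pos[i, 1], ",", pos[i, 2],
           ") outside the declared grid in ", path)
    peaks[[idx]] <- spectra[[i]]
  }

  ups <- xml2::xml_find_all(doc, ".//fileContent/userParam")
  up <- stats::setNames(xml2::xml_attr(ups, "value"),
                        xml2::xml_attr(ups, "name"))
  mz_range <- if (all(c("mz_range_min", "mz_range_max") %in% names(up)))
    as.numeric(up[c("mz_range_min", "mz_range_max")]) else NULL

  spectral_image(peaks, width = width, height = height,
                 pixel_size = pixel_size, mz_range = mz_range,
                 metadata = list(source = path))
}
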