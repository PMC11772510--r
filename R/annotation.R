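# Sum-composition lipid annotation by accurate mass: a peak is assigned
# every database species whose theoretical m/z lies within a ppm tolerance,
# keeping isobaric co-assignments (e.g. a protonated PE and a PC fragment
# sharing one nominal image) as multiple matches.

#' Relative mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`; positive when the
#' observed mass is high.
#'
#' @param observed,theoretical m/z in Da; `theoretical > 0`.
#' @return signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Read a lipid mass list
#'
#' CSV with columns `name` (sum composition, e.g. "PE 34:1"), `adduct`
#' (e.g. "[M+H]+") and `theoretical_mz` (Da); `(name, adduct)` must be
#' unique. The package ships a small synthetic mass list covering common
#' brain PE/PC/ceramide species at
#' `system.file("extdata", "lipid_db.csv", package = "msimodal")`, with
#' masses computed from elemental formulas.
#'
#' @param path CSV path.
#' @return data.frame of class `lipid_db`.
#' @export
read_lipid_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "adduct", "theoretical_mz")
  if (!all(need %in% names(df)))
    stop("lipid database needs columns ", paste(need, collapse = ", "))
  if (any(df$theoretical_mz <= 0)) stop("non-positive theoretical m/z")
  if (anyDuplicated(df[c("name", "adduct")]))
    stop("duplicate (name, adduct) entries in ", path)
  class(df) <- c("lipid_db", class(df))
  df
}

#' Annotate observed peaks against a lipid mass list
#'
#' For each observed m/z, returns every database record within
#' `tolerance_ppm`, sorted by absolute ppm error (ties broken by database
#' order); the first match is the best assignment but all candidates are
#' retained, so isobaric species stay visible as slash-joined alternatives.
#' Peaks with no record in tolerance get an empty match set, not an error.
#'
#' @param peaks numeric vector of observed m/z values.
#' @param db a [read_lipid_db()] data.frame (or any data.frame with the
#'   same columns).
#' @param tolerance_ppm match window half-width in ppm (default 5).
#' @return list of annotations, one per peak: `observed_mz`, `matches`
#'   (data.frame name/adduct/theoretical_mz/ppm_error ordered by
#'   |ppm_error|), `best` (one-row data.frame or NULL).
#' @export
annotate <- function(peaks, db, tolerance_ppm = 5) {
  stopifnot(nrow(db) >= 1, tolerance_ppm > 0)
  lapply(peaks, function(mz) {
    err <- ppm_error(mz, db$theoretical_mz)
    sel <- which(abs(err) <= tolerance_ppm)
    sel <- sel[order(abs(err[sel]))]
    matches <- data.frame(name = db$name[sel], adduct = db$adduct[sel],
                          theoretical_mz = db$theoretical_mz[sel],
                          ppm_error = err[sel])
    list(observed_mz = mz, matches = matches,
         best = if (nrow(matches)) matches[1, ] else NULL)
  })
}

#' Write an annotation report as CSV
#'
#' One row per peak: observed m/z, best assignment and its ppm error, and
#' all candidates slash-joined in `all_matches`.
#'
#' @param annotations result of [annotate()].
#' @param path output CSV path.
#' @return the report data.frame, invisibly.
#' @export
write_annotation_report <- function(annotations, path) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(
      observed_mz = a$observed_mz,
      best_name = if (is.null(a$best)) NA_character_ else a$best$name,
      best_adduct = if (is.null(a$best)) NA_character_ else a$best$adduct,
      best_ppm = if (is.null(a$best)) NA_real_ else a$best$ppm_error,
      all_matches = if (nrow(a$matches))
        paste(paste0(a$matches$name, " ", a$matches$adduct),
              collapse = "/") else "")
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
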