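# Landmark-based 2-D registration: least-squares transform estimation and
# pull (inverse-mapping) resampling of the moving modality onto the fixed
# grid. Pixel centers sit at integer coordinates; landmarks are expressed
# in each grid's own pixel units, so unequal pixel sizes are absorbed into
# the fitted linear part.

#' Construct a 2-D affine transform
#'
#' Maps moving-modality pixel coordinates `(x, y)` into the fixed frame as
#' `A %*% c(x, y) + b`.
#'
#' @param A 2 x 2 linear part, |det| > 1e-8.
#' @param b length-2 translation.
#' @param family one of `"translation"`, `"similarity"`, `"affine"`.
#' @param residual_rmse root-mean-square fixed-frame landmark residual in
#'   pixels (NA when not estimated from landmarks).
#' @return object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), b = c(0, 0), family = "affine",
                     residual_rmse = NA_real_) {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  stopifnot(length(b) == 2, all(is.finite(A)), all(is.finite(b)))
  if (abs(det(A)) <= 1e-8)
    stop("transform linear part is (near-)singular, |det| = ",
         format(abs(det(A))))
  family <- match.arg(family, c("translation", "similarity", "affine"))
  structure(list(A = A, b = b, family = family,
                 residual_rmse = residual_rmse),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> family %s, rmse %s px\n", x$family,
              format(x$residual_rmse, digits = 3)))
  cat(sprintf("  [% .5f % .5f | % .4f]\n  [% .5f % .5f | % .4f]\n",
              x$A[1, 1], x$A[1, 2], x$b[1], x$A[2, 1], x$A[2, 2], x$b[2]))
  invisible(x)
}

#' Apply a transform to point coordinates
#' @param t an [affine2d()].
#' @param xy n x 2 matrix (or length-2 vector) of moving-frame points.
#' @return n x 2 matrix of fixed-frame points.
#' @export
transform_points <- function(t, xy) {
  stopifnot(inherits(t, "affine2d"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  sweep(xy %*% t(t$A), 2, t$b, `+`)
}

#' Invert a transform
#' @param t an [affine2d()].
#' @return the inverse [affine2d()].
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "affine2d"))
  Ai <- solve(t$A)
  affine2d(Ai, -as.numeric(Ai %*% t$b), family = t$family)
}

#' Estimate a transform from landmark correspondences
#'
#' Least-squares fit of the chosen family mapping moving landmarks onto
#' fixed ones. `family = "auto"` picks the richest family the pair count
#' supports: affine with >= 3 non-collinear pairs, similarity (rotation +
#' isotropic scale + translation, no reflection) with 2, translation
#' with 1.
#'
#' @param landmarks a [landmark_set()].
#' @param family `"auto"`, `"translation"`, `"similarity"` or `"affine"`.
#' @return an [affine2d()] with `residual_rmse` set (root mean square of
#'   the per-pair Euclidean residuals in the fixed frame).
#' @export
estimate_transform <- function(landmarks,
                               family = c("auto", "translation",
                                          "similarity", "affine")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  family <- match.arg(family)
  M <- landmarks$moving; F <- landmarks$fixed
  n <- nrow(M)

  collinear <- function() {
    # all points within 1e-8 of one line through the first two distinct ones
    if (n < 3) return(TRUE)
    d <- cbind(M[, 1] - M[1, 1], M[, 2] - M[1, 2])
    qr(d)$rank < 2
  }
  if (family == "auto")
    family <- if (n >= 3 && !collinear()) "affine"
      else if (n >= 2) "similarity" else "translation"

  if (family == "affine") {
    if (n < 3) stop("affine fit needs >= 3 landmark pairs (got ", n, ")")
    if (collinear()) {
      lab <- if (!is.null(landmarks$labels)) landmarks$labels
        else as.character(seq_len(n))
      stop("degenerate landmark configuration for an affine fit: points ",
           paste(lab, collapse = ", "), " are collinear")
    }
    X <- cbind(M, 1)
    beta <- solve(crossprod(X), crossprod(X, F)) # normal equations
    A <- t(beta[1:2, ]); b <- beta[3, ]
  } else if (family == "similarity") {
    if (n < 2) stop("similarity fit needs >= 2 landmark pairs")
    mM <- colMeans(M); mF <- colMeans(F)
    Mc <- sweep(M, 2, mM); Fc <- sweep(F, 2, mF)
    H <- crossprod(Mc, Fc) # 2x2 cross-covariance
    sv <- svd(H)
    S <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% S %*% t(sv$u)
    s <- sum(diag(S) * sv$d) / sum(Mc^2)
    A <- s * R; b <- mF - as.numeric(A %*% mM)
  } else { # translation
    A <- diag(2)
    b <- colMeans(F) - colMeans(M)
  }
  res <- F - sweep(M %*% t(A), 2, b, `+`) # F - (M A^T + b)
  rmse <- sqrt(mean(rowSums(res^2)))
  affine2d(A, b, family = family, residual_rmse = rmse)
}

#' Resample an elemental stack onto the fixed grid
#'
#' Pull resampling: each fixed-grid pixel center is mapped through the
#' inverse transform into the moving image and sampled there. Fixed pixels
#' landing outside the moving grid become missing. Bilinear interpolation
#' ignores missing neighbours by renormalising the remaining weights; a
#' pixel with all four neighbours missing stays missing.
#'
#' @param stack the moving-modality [elemental_stack()].
#' @param t an [affine2d()] mapping moving coordinates into the fixed frame.
#' @param fixed_shape `c(height, width)` of the target grid.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param pixel_size pixel size of the fixed grid for the output stack;
#'   defaults to the moving stack's.
#' @return an [elemental_stack()] on the fixed grid, units preserved.
#' @export
resample_to_fixed <- function(stack, t, fixed_shape,
                              interpolation = c("bilinear", "nearest"),
                              pixel_size = stack$pixel_size) {
  stopifnot(inherits(stack, "elemental_stack"), inherits(t, "affine2d"),
            length(fixed_shape) == 2)
  interpolation <- match.arg(interpolation)
  h <- as.integer(fixed_shape[1]); w <- as.integer(fixed_shape[2])
  ti <- invert_transform(t)
  # fixed pixel centers, row-major
  grid <- cbind(x = rep(0:(w - 1), times = h),
                y = rep(0:(h - 1), each = w))
  src <- transform_points(ti, grid) # positions in moving pixel coords
  sx <- src[, 1]; sy <- src[, 2]
  mh <- stack$height; mw <- stack$width

  sample_channel <- function(m) {
    out <- rep(NA_real_, h * w)
    if (interpolation == "nearest") {
      ix <- round(sx); iy <- round(sy)
      ok <- ix >= 0 & ix <= mw - 1 & iy >= 0 & iy <= mh - 1
      out[ok] <- m[cbind(iy[ok] + 1, ix[ok] + 1)]
    } else {
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      ok <- sx >= 0 & sx <= mw - 1 & sy >= 0 & sy <= mh - 1
      idx <- which(ok)
      if (length(idx)) {
        gx0 <- pmin(pmax(x0[idx], 0), mw - 1)
        gy0 <- pmin(pmax(y0[idx], 0), mh - 1)
        gx1 <- pmin(gx0 + 1, mw - 1)
        gy1 <- pmin(gy0 + 1, mh - 1)
        v00 <- m[cbind(gy0 + 1, gx0 + 1)]
        v01 <- m[cbind(gy0 + 1, gx1 + 1)]
        v10 <- m[cbind(gy1 + 1, gx0 + 1)]
        v11 <- m[cbind(gy1 + 1, gx1 + 1)]
        w00 <- (1 - fx[idx]) * (1 - fy[idx])
        w01 <- fx[idx] * (1 - fy[idx])
        w10 <- (1 - fx[idx]) * fy[idx]
        w11 <- fx[idx] * fy[idx]
        V <- cbind(v00, v01, v10, v11)
        W <- cbind(w00, w01, w10, w11)
        W[is.na(V)] <- 0
        V[is.na(V)] <- 0
        tw <- rowSums(W)
        val <- rowSums(V * W) / tw
        val[tw == 0] <- NA_real_
        out[idx] <- val
      }
    }
    matrix(out, nrow = h, ncol = w, byrow = TRUE)
  }

  channels <- lapply(stack$channels, sample_channel)
  elemental_stack(channels, pixel_size = pixel_size, units = stack$units,
                  metadata = c(stack$metadata,
                               list(registered = TRUE,
                                    interpolation = interpolation)))
}

#' Serialise / read a transform as a 6-number text record
#'
#' Format: one line `family a11 a12 a21 a22 b1 b2`.
#'
#' @param t an [affine2d()].
#' @param path file path.
#' @return `path` invisibly for the writer; an [affine2d()] for the reader.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "affine2d"))
  writeLines(paste(t$family,
                   paste(format(c(t(t$A)), digits = 17),
                         collapse = " "),
                   paste(format(t$b, digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  parts <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  if (length(parts) != 7) stop("malformed transform record in ", path)
  v <- as.numeric(parts[-1])
  affine2d(matrix(v[1:4], 2, 2, byrow = TRUE), v[5:6], family = parts[1])
}
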