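# Brute-force oracles and small fixture builders. Every oracle is written
# as the most literal possible computation, independent of the package's
# code paths, so oracle-equivalence tests are meaningful.

# a spectral image from an explicit list of (row, col, mz, intensity) rows
make_image <- function(df, width, height, pixel_size = 30, mz_range = NULL) {
  peaks <- rep(list(list(mz = numeric(0), intensity = numeric(0))),
               width * height)
  if (nrow(df)) {
    for (k in split(df, df$row * width + df$col)) {
      i <- k$row[1] * width + k$col[1] + 1
      o <- order(k$mz)
      peaks[[i]] <- list(mz = k$mz[o], intensity = k$intensity[o])
    }
  }
  spectral_image(peaks, width, height, pixel_size, mz_range = mz_range)
}

# random small centroided image for property tests
rand_image <- function(seed, width = 4, height = 3, max_peaks = 8,
                       mz_range = c(200, 1000)) {
  set.seed(seed)
  peaks <- lapply(seq_len(width * height), function(i) {
    n <- sample(0:max_peaks, 1)
    if (n == 0) return(list(mz = numeric(0), intensity = numeric(0)))
    mz <- sort(runif(n, mz_range[1], mz_range[2]))
    list(mz = mz, intensity = rexp(n, 1 / 100))
  })
  spectral_image(peaks, width, height, mz_range = mz_range)
}

# literal per-peak loop: sum of intensities within the ppm window
oracle_extract <- function(img, target, tol_ppm) {
  out <- matrix(0, img$height, img$width)
  for (row in 0:(img$height - 1)) for (col in 0:(img$width - 1)) {
    p <- pixel_spectrum(img, row, col)
    s <- 0
    for (j in seq_along(p$mz))
      if (abs(p$mz[j] - target) / target <= tol_ppm * 1e-6)
        s <- s + p$intensity[j]
    out[row + 1, col + 1] <- s
  }
  out
}

# literal pooled ppm binning for the mean spectrum
oracle_mean_spectrum <- function(img, bin_ppm) {
  mz <- unlist(lapply(img$peaks, `[[`, "mz"))
  int <- unlist(lapply(img$peaks, `[[`, "intensity"))
  if (!length(mz)) return(data.frame(mz = numeric(0),
                                     mean_intensity = numeric(0)))
  w <- bin_ppm * 1e-6
  m0 <- img$mz_range[1]
  k_max <- ceiling(log(max(mz) / m0) / log1p(w)) + 1
  edges <- m0 * (1 + w)^(0:(k_max + 1))
  bin <- cut(mz, breaks = edges, right = FALSE, labels = FALSE) - 1
  tot <- tapply(int, bin, sum)
  k <- as.numeric(names(tot))
  df <- data.frame(mz = m0 * (1 + w)^(k + 0.5),
                   mean_intensity = as.numeric(tot) / length(img$peaks))
  df[order(df$mz), , drop = FALSE]
}

# textbook two-pass Pearson coefficient
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# least-squares affine via lm(), an independent solver path
oracle_affine_lm <- function(moving, fixed) {
  fx <- stats::lm(fixed[, 1] ~ moving[, 1] + moving[, 2])
  fy <- stats::lm(fixed[, 2] ~ moving[, 1] + moving[, 2])
  list(A = rbind(stats::coef(fx)[2:3], stats::coef(fy)[2:3]),
       b = c(stats::coef(fx)[1], stats::coef(fy)[1]))
}

# all-pairs annotation filter
oracle_annotate <- function(peaks, db, tol) {
  lapply(peaks, function(mz) {
    hits <- list()
    for (i in seq_len(nrow(db))) {
      e <- (mz - db$theoretical_mz[i]) / db$theoretical_mz[i] * 1e6
      if (abs(e) <= tol)
        hits[[length(hits) + 1]] <- data.frame(name = db$name[i], ppm = e)
    }
    if (!length(hits)) return(character(0))
    hits <- do.call(rbind, hits)
    hits$name[order(abs(hits$ppm))]
  })
}

# literal reading-by-reading line rasterization with mean aggregation
oracle_rasterize <- function(lines, pixel_size) {
  offs <- vapply(lines, `[[`, numeric(1), "y_offset")
  lines <- lines[order(offs)]
  elements <- names(lines[[1]]$counts)
  widths <- vapply(lines, function(l)
    max(floor(l$time_s * l$scan_speed / pixel_size)) + 1, numeric(1))
  w <- max(widths)
  out <- lapply(elements, function(el) {
    m <- matrix(NA_real_, length(lines), w)
    for (r in seq_along(lines)) {
      l <- lines[[r]]
      acc <- vector("list", w)
      for (j in seq_along(l$time_s)) {
        k <- floor(l$time_s[j] * l$scan_speed / pixel_size) + 1
        acc[[k]] <- c(acc[[k]], l$counts[[el]][j])
      }
      for (k in seq_len(w))
        if (length(acc[[k]])) m[r, k] <- mean(acc[[k]])
    }
    m
  })
  names(out) <- elements
  out
}

# similarity transform with given parameters, matching the package's
# moving -> fixed convention
make_similarity <- function(deg, scale, tx, ty, center = c(0, 0)) {
  th <- deg * pi / 180
  A <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                      byrow = TRUE)
  b <- center - as.numeric(A %*% center) + c(tx, ty)
  affine2d(A, b, family = "similarity")
}
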