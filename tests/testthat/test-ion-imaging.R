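# Ion-image rendering rules: ppm-window extraction, TIC normalisation,
# quantile clipping, recalibration, mean spectra.

test_that("extraction window is two-sided, relative and inclusive", {
  target <- 718.5372
  half <- target * 10 * 1e-6 # ~0.00719 Da
  df <- data.frame(
    row = 0, col = 0:3,
    mz = c(target, target + half, target + 0.010, target - half - 1e-6),
    intensity = c(5, 1, 1, 1))
  img <- make_image(df, width = 4, height = 1, mz_range = c(200, 1000))
  ii <- extract_ion_image(img, target, 10)
  expect_equal(ii$raster[1, 1], 5)    # exact hit
  expect_equal(ii$raster[1, 2], 1)    # on the inclusive boundary
  expect_equal(ii$raster[1, 3], 0)    # +0.010 Da is outside 10 ppm
  expect_equal(ii$raster[1, 4], 0)    # just below the lower bound
  expect_false(ii$normalized)
  expect_null(ii$clipped_at)
  expect_error(extract_ion_image(img, 1500, 10), "outside")
})

test_that("extraction matches the brute-force per-peak oracle", {
  for (seed in 1:25) {
    img <- rand_image(seed, width = 5, height = 5, max_peaks = 10)
    target <- runif(1, 300, 900)
    tol <- runif(1, 5, 500)
    ii <- extract_ion_image(img, target, tol)
    expect_equal(ii$raster, oracle_extract(img, target, tol))
  }
})

test_that("TIC normalisation divides by per-pixel TIC and is invariant to
           per-pixel rescaling", {
  df <- data.frame(row = 0, col = c(0, 0, 1), mz = c(500, 600, 500),
                   intensity = c(10, 90, 4))
  img <- make_image(df, width = 2, height = 1, mz_range = c(200, 1000))
  ii <- tic_normalize(extract_ion_image(img, 500, 10), img)
  expect_equal(ii$raster[1, 1], 10 / 100)
  expect_equal(ii$raster[1, 2], 1)
  expect_true(ii$normalized)

  # scaling one pixel's whole spectrum cancels exactly
  img2 <- img
  img2$peaks[[1]]$intensity <- img2$peaks[[1]]$intensity * 7
  ii2 <- tic_normalize(extract_ion_image(img2, 500, 10), img2)
  expect_equal(ii2$raster, ii$raster)

  # empty pixel: 0, no division error
  img3 <- make_image(df[1:2, ], width = 2, height = 1,
                     mz_range = c(200, 1000))
  ii3 <- tic_normalize(extract_ion_image(img3, 500, 10), img3)
  expect_equal(ii3$raster[1, 2], 0)
})

test_that("TIC-normalised images are invariant under arbitrary positive
           per-pixel spectrum scaling", {
  for (seed in 1:10) {
    img <- rand_image(seed, width = 4, height = 4, max_peaks = 6)
    set.seed(seed + 1000)
    factors <- runif(16, 0.01, 50)
    img2 <- img
    for (i in seq_along(img2$peaks))
      img2$peaks[[i]]$intensity <- img2$peaks[[i]]$intensity * factors[i]
    target <- runif(1, 250, 950)
    a <- tic_normalize(extract_ion_image(img, target, 200), img)
    b <- tic_normalize(extract_ion_image(img2, target, 200), img2)
    expect_equal(a$raster, b$raster, tolerance = 1e-12)
  }
})

test_that("quantile clip threshold, idempotence and order preservation", {
  mk <- function(values, w, h) {
    structure(list(target_mz = 700, tolerance_ppm = 10,
                   raster = matrix(values, h, w), normalized = TRUE,
                   clipped_at = NULL),
              class = "ion_image")
  }
  # 100 nonzero pixels 1..100: linear-interpolation 99% quantile = 99.01
  ii <- mk(c(1:100, rep(0, 20)), 12, 10)
  cl <- quantile_hotspot_clip(ii, 0.99)
  expect_equal(cl$clipped_at, 99.01)
  expect_equal(max(cl$raster), 99.01)
  expect_equal(sum(cl$raster != ii$raster), 1) # only the 100 moved
  # idempotent
  cl2 <- quantile_hotspot_clip(cl, 0.99)
  expect_equal(cl2$raster, cl$raster)
  # order preserved below threshold
  expect_true(all(order(cl$raster[ii$raster <= 99.01]) ==
                  order(ii$raster[ii$raster <= 99.01])))
  # constant image unchanged; all-zero image unchanged with clipped_at 0
  cc <- quantile_hotspot_clip(mk(rep(5, 9), 3, 3))
  expect_equal(cc$raster, matrix(5, 3, 3))
  zz <- quantile_hotspot_clip(mk(rep(0, 9), 3, 3))
  expect_equal(zz$clipped_at, 0)
  expect_equal(zz$raster, matrix(0, 3, 3))
  # zeros excluded from the quantile by default, included on request
  v <- c(rep(0, 50), 1:50)
  q_nz <- quantile_hotspot_clip(mk(v, 10, 10), 0.5)
  expect_equal(q_nz$clipped_at,
               as.numeric(quantile(1:50, 0.5, type = 7)))
  q_all <- quantile_hotspot_clip(mk(v, 10, 10), 0.5, nonzero_only = FALSE)
  expect_equal(q_all$clipped_at, as.numeric(quantile(v, 0.5, type = 7)))
})

test_that("recalibration: identity, closed form, inverse round trip", {
  refs <- c(500, 700.7, 900)
  df <- data.frame(row = 0, col = 0, mz = refs, intensity = c(1, 2, 3))
  img <- make_image(df, width = 1, height = 1, mz_range = c(200, 1000))
  m <- fit_recalibration(img, refs, search_ppm = 20)
  expect_equal(m$factor, 1)
  expect_equal(nrow(m$pairs), 3)

  # single reference observed 5 ppm low -> factor 1 + 5e-6 to 1e-12
  obs <- 700 / (1 + 5e-6)
  img2 <- make_image(data.frame(row = 0, col = 0, mz = obs, intensity = 1),
                     width = 1, height = 1, mz_range = c(200, 1000))
  m2 <- fit_recalibration(img2, 700, search_ppm = 20)
  expect_equal(m2$factor, 1 + 5e-6, tolerance = 1e-12)

  # applying the factor moves m/z multiplicatively, intensities untouched
  img3 <- apply_recalibration(img2, m2)
  expect_equal(img3$peaks[[1]]$mz, 700, tolerance = 1e-9)
  expect_equal(img3$peaks[[1]]$intensity, 1)
  expect_equal(apply_recalibration(img2, 1)$peaks, img2$peaks)
  expect_equal(apply_recalibration(img2, 1 + 5e-6)$peaks[[1]]$mz,
               obs * (1 + 5e-6))
  rt <- apply_recalibration(apply_recalibration(img2, 1.00002), 1 / 1.00002)
  expect_equal(rt$peaks[[1]]$mz, img2$peaks[[1]]$mz, tolerance = 1e-9)

  # no reference in window -> explicit failure
  expect_error(fit_recalibration(img2, 400, search_ppm = 5),
               "cannot calibrate")
  # unmatched references are reported, matched ones still used
  m3 <- fit_recalibration(img2, c(700, 400), search_ppm = 20)
  expect_equal(m3$unmatched, 400)
})

test_that("recalibration recovers injected global shifts on phantoms", {
  for (seed in 1:5) {
    set.seed(seed + 77)
    shift <- runif(1, -20, 20)
    pc <- phantom_config(width = 40, height = 30, seed = seed,
                         lipid_cv = 0.01, mass_shift_ppm = shift,
                         mz_jitter_ppm = 2,
                         rotation_deg = 0, translation = c(0, 0))
    img <- render_spectral(generate_phantom(pc))
    m <- fit_recalibration(img, pc$lipids$mz, search_ppm = 40)
    expect_lt(abs(m$shift_ppm + shift), 0.5)
  }
})

test_that("mean spectrum pools ppm bins and averages over all pixels", {
  # single pixel: its own spectrum binned
  df <- data.frame(row = 0, col = 0, mz = c(300, 500), intensity = c(2, 4))
  img1 <- make_image(df, width = 1, height = 1, mz_range = c(200, 1000))
  ms1 <- mean_spectrum(img1, 5)
  expect_equal(nrow(ms1), 2)
  expect_equal(ms1$mean_intensity, c(2, 4))
  # two identical pixels: unchanged mean
  df2 <- rbind(df, transform(df, col = 1))
  img2 <- make_image(df2, width = 2, height = 1, mz_range = c(200, 1000))
  expect_equal(mean_spectrum(img2, 5)$mean_intensity, ms1$mean_intensity)
  # an empty third pixel dilutes the mean by contributing zeros
  img3 <- make_image(df2, width = 3, height = 1, mz_range = c(200, 1000))
  expect_equal(mean_spectrum(img3, 5)$mean_intensity,
               ms1$mean_intensity * 2 / 3)
})

test_that("mean spectrum matches the pooled-binning oracle", {
  for (seed in 1:20) {
    img <- rand_image(seed, width = 3, height = 3, max_peaks = 6)
    bw <- runif(1, 2, 500)
    got <- mean_spectrum(img, bw)
    want <- oracle_mean_spectrum(img, bw)
    expect_equal(got$mz, want$mz, tolerance = 1e-9)
    expect_equal(got$mean_intensity, want$mean_intensity,
                 tolerance = 1e-12)
  }
})
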