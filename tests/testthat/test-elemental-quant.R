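# Line-scan rasterization and external calibration.

test_that("rasterize_lines bins readings by pixel dwell intervals", {
  # 750 um/s at 30 um pixels: 0.04 s dwell; t = 0.01, 0.03 -> pixel 0,
  # t = 0.05 -> pixel 1
  l <- laser_line(time_s = c(0.01, 0.03, 0.05),
                  counts = data.frame("66Zn" = c(10, 20, 40),
                                      check.names = FALSE),
                  y_offset = 0, scan_speed = 750, beam_diameter = 30)
  st <- rasterize_lines(list(l), pixel_size = 30)
  expect_equal(st$channels[["66Zn"]][1, ], c(mean(c(10, 20)), 40))
  expect_equal(unname(st$units[["66Zn"]]), "counts_per_second")

  # one reading per pixel at pixel centers: raster equals readings
  l2 <- laser_line(time_s = (0:4 + 0.5) * 0.04,
                   counts = data.frame(Fe = 1:5), y_offset = 0)
  st2 <- rasterize_lines(list(l2))
  expect_equal(st2$channels$Fe[1, ], as.numeric(1:5))

  # rows ordered by y_offset regardless of list order; ragged ends padded
  la <- laser_line(time_s = c(0.02, 0.06), counts = data.frame(Fe = c(1, 2)),
                   y_offset = 30)
  lb <- laser_line(time_s = c(0.02, 0.06, 0.10),
                   counts = data.frame(Fe = c(3, 4, 5)), y_offset = 0)
  st3 <- rasterize_lines(list(la, lb))
  expect_equal(st3$channels$Fe[1, ], c(3, 4, 5))
  expect_equal(st3$channels$Fe[2, ], c(1, 2, NA))

  expect_error(rasterize_lines(list()), "empty")
  expect_error(rasterize_lines(list(la, la)), "overlapping")
})

test_that("rasterize_lines matches the per-reading oracle and conserves
           every reading", {
  for (seed in 1:20) {
    set.seed(seed)
    n_lines <- sample(2:4, 1)
    lines <- lapply(seq_len(n_lines), function(r) {
      n <- sample(5:20, 1)
      laser_line(time_s = sort(runif(n, 0, 0.5)),
                 counts = data.frame(A = rpois(n, 50), B = rpois(n, 10)),
                 y_offset = (r - 1) * 30)
    })
    st <- rasterize_lines(lines, pixel_size = 30)
    want <- oracle_rasterize(lines, 30)
    expect_equal(st$channels$A, want$A)
    expect_equal(st$channels$B, want$B)
    # conservation: pixel counts weighted by readings-per-pixel reproduce
    # the grand total of readings
    for (r in seq_len(n_lines)) {
      l <- lines[[r]]
      pix <- floor(l$time_s * l$scan_speed / 30)
      sums <- tapply(l$counts$A, pix, sum)
      got_sums <- st$channels$A[r, as.numeric(names(sums)) + 1] *
        as.numeric(table(pix))
      expect_equal(unname(got_sums), as.numeric(sums))
    }
  }
})

test_that("calibration fit is exact on collinear standards", {
  # (0, 10, 20) mg/kg with mean counts (100, 1100, 2100)
  std <- list(calibration_standard("66Zn", 0, c(90, 110)),
              calibration_standard("66Zn", 10, c(1100, 1100)),
              calibration_standard("66Zn", 20, c(2050, 2150)))
  cv <- fit_calibration(std)
  expect_equal(cv$slope, 100)
  expect_equal(cv$intercept, 100)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$n_standards, 3)
  expect_false(cv$negative_slope)

  # two standards: the line passes through both means exactly
  two <- list(calibration_standard("Fe", 5, c(400, 600)), # mean 500
              calibration_standard("Fe", 15, 1500))
  cv2 <- fit_calibration(two)
  expect_equal(cv2$slope * 5 + cv2$intercept, 500)
  expect_equal(cv2$slope * 15 + cv2$intercept, 1500)

  expect_error(fit_calibration(list(std[[1]], std[[1]])), "distinct")
  expect_error(fit_calibration(list(std[[1]], two[[1]])), "mix")
  expect_warning(
    fit_calibration(list(calibration_standard("Cu", 0, 1000),
                         calibration_standard("Cu", 10, 100))),
    "slope")
})

test_that("calibration slope is recovered from Poisson-noised standards", {
  for (seed in 1:5) {
    set.seed(seed)
    std <- simulate_standards("66Zn", c(0, 10, 20, 40), slope = 50,
                              intercept = 200, n_readings = 200)
    cv <- fit_calibration(std)
    expect_lt(abs(cv$slope - 50) / 50, 0.05)
  }
})

test_that("apply_calibration inverts the line, passes through the rest", {
  st <- elemental_stack(list(
    "66Zn" = matrix(c(600, 100, 50, NA), 2, 2),
    "23Na" = matrix(c(1, 2, 3, 4), 2, 2)))
  cv <- structure(list(element = "66Zn", slope = 100, intercept = 100,
                       r_squared = 1, n_standards = 3,
                       negative_slope = FALSE),
                  class = "calibration_curve")
  out <- apply_calibration(st, list("66Zn" = cv))
  expect_equal(out$channels[["66Zn"]][1, 1], 5.0) # (600-100)/100
  expect_equal(out$channels[["66Zn"]][2, 1], 0.0) # value == intercept
  expect_equal(out$channels[["66Zn"]][1, 2], -0.5) # negative kept
  expect_true(is.na(out$channels[["66Zn"]][2, 2])) # missing stays missing
  expect_equal(unname(out$units[["66Zn"]]), "mg_per_kg")
  # passthrough channel bitwise identical, unit unchanged
  expect_identical(out$channels[["23Na"]], st$channels[["23Na"]])
  expect_equal(unname(out$units[["23Na"]]), "counts_per_second")
  # QC flag counts negative pixels
  expect_equal(out$metadata$negative_concentration_pixels[["66Zn"]], 1)
  expect_error(apply_calibration(st, list(), elements = "66Zn"),
               "no calibration curve")
})

test_that("fit then apply recovers nominal concentrations exactly when
           noiseless", {
  std <- simulate_standards("Cu", c(0, 5, 10, 25), slope = 80,
                            intercept = 150, poisson = FALSE,
                            n_readings = 3)
  cv <- fit_calibration(std)
  counts <- matrix(80 * c(0, 5, 10, 25) + 150, 2, 2)
  st <- elemental_stack(list(Cu = counts))
  out <- apply_calibration(st, list(Cu = cv))
  expect_equal(out$channels$Cu, matrix(c(0, 5, 10, 25), 2, 2),
               tolerance = 1e-10)
})

test_that("quantification is affine, so Pearson correlation is unchanged", {
  set.seed(42)
  x <- matrix(runif(100), 10, 10)
  counts <- matrix(rpois(100, 500), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  st_counts <- elemental_stack(list(Zn = counts))
  cv <- structure(list(element = "Zn", slope = 37.5, intercept = 112,
                       r_squared = 1, n_standards = 3,
                       negative_slope = FALSE),
                  class = "calibration_curve")
  st_mgkg <- apply_calibration(st_counts, list(Zn = cv))
  r1 <- pearson_matrix(list(lip = x), st_counts, mask)$r[1, 1]
  r2 <- pearson_matrix(list(lip = x), st_mgkg, mask)$r[1, 1]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("line scans round-trip through the CSV + run-sheet reader", {
  dir <- withr::local_tempdir()
  for (r in 1:2)
    utils::write.csv(data.frame(time_s = c(0.01, 0.05, 0.09),
                                Zn = c(1, 2, 3) * r, Fe = c(4, 5, 6) * r),
                     file.path(dir, sprintf("line%d.csv", r)),
                     row.names = FALSE)
  yaml::write_yaml(list(scan_speed = 750, beam_diameter = 30,
                        lines = list(
                          list(file = "line1.csv", y_offset = 0),
                          list(file = "line2.csv", y_offset = 30))),
                   rs <- file.path(dir, "run.yaml"))
  lines <- read_line_scans(rs)
  expect_length(lines, 2)
  expect_equal(lines[[2]]$counts$Fe, c(8, 10, 12))
  st <- rasterize_lines(lines)
  expect_equal(st$channels$Zn[1, ], c(1, 2, 3))
})
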