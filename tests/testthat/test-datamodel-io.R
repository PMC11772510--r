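# Containers and file formats: construction invariants, imzML round trips,
# CSV grids, landmark TSVs.

test_that("spectral_image enforces its invariants", {
  img <- make_image(data.frame(row = 0, col = 0, mz = 500, intensity = 10),
                    width = 2, height = 2)
  expect_equal(length(img$peaks), 4)
  expect_equal(pixel_spectrum(img, 0, 0)$intensity, 10)
  expect_equal(pixel_spectrum(img, 1, 1)$mz, numeric(0))

  # unsorted m/z re-sorted; negative intensity refused; range enforced
  p <- list(list(mz = c(700, 300), intensity = c(1, 2)))
  img2 <- spectral_image(c(p, rep(list(NULL), 3)), 2, 2)
  expect_equal(img2$peaks[[1]]$mz, c(300, 700))
  expect_equal(img2$peaks[[1]]$intensity, c(2, 1))
  expect_error(spectral_image(list(list(mz = 1, intensity = -1)), 1, 1),
               "negative")
  expect_error(spectral_image(c(p, rep(list(NULL), 3)), 2, 2,
                              mz_range = c(400, 1000)),
               "outside")
  expect_error(spectral_image(p, 2, 2), "width \\* height")
})

test_that("tic_image sums all peak intensities per pixel", {
  img <- make_image(data.frame(row = c(0, 0, 1), col = c(0, 0, 1),
                               mz = c(300, 400, 500),
                               intensity = c(1, 2, 7)),
                    width = 2, height = 2)
  expect_equal(tic_image(img), matrix(c(3, 0, 0, 7), 2, 2, byrow = TRUE))
})

test_that("imzML round-trips spectral images exactly", {
  dir <- withr::local_tempdir()
  for (seed in c(1, 2)) {
    img <- rand_image(seed, width = 3, height = 2)
    path <- file.path(dir, sprintf("rt%d.imzML", seed))
    write_imzml(img, path)
    back <- read_imzml(path)
    expect_equal(back$width, img$width)
    expect_equal(back$height, img$height)
    expect_equal(back$pixel_size, img$pixel_size)
    expect_equal(back$mz_range, img$mz_range)
    expect_equal(back$peaks, img$peaks, tolerance = 1e-12)
  }
  # degenerate 1x1 empty image
  e <- spectral_image(list(NULL), 1, 1, mz_range = c(200, 1000))
  p <- file.path(dir, "empty.imzML")
  write_imzml(e, p)
  back <- read_imzml(p)
  expect_equal(back$peaks[[1]]$mz, numeric(0))
  # phantom render round-trips too
  ph <- generate_phantom(phantom_config(width = 12, height = 10, seed = 3))
  simg <- render_spectral(ph)
  p2 <- file.path(dir, "ph.imzML")
  write_imzml(simg, p2)
  expect_equal(read_imzml(p2)$peaks, simg$peaks, tolerance = 1e-12)
})

test_that("writing identical images yields byte-identical files", {
  dir <- withr::local_tempdir()
  img <- rand_image(5, width = 2, height = 2)
  f1 <- file.path(dir, "a.imzML"); f2 <- file.path(dir, "b.imzML")
  write_imzml(img, f1); write_imzml(img, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(unname(tools::md5sum(ibd <- sub("imzML$", "ibd", f1))),
                   unname(tools::md5sum(sub("imzML$", "ibd", f2))))
})

test_that("imzML reader fills absent pixels and flags unsorted spectra", {
  dir <- withr::local_tempdir()
  img <- rand_image(7, width = 2, height = 2, max_peaks = 4)
  path <- file.path(dir, "mod.imzML")
  write_imzml(img, path)
  # drop the spectrum for pixel (1,1) from the XML: reader must fill it
  txt <- readLines(path)
  xml <- paste(txt, collapse = "\n")
  xml2_doc <- xml2::read_xml(xml)
  xml2::xml_ns_strip(xml2_doc)
  sp <- xml2::xml_find_all(xml2_doc, ".//spectrum")
  xml2::xml_remove(sp[[4]])
  xml2::write_xml(xml2_doc, path)
  back <- read_imzml(path)
  expect_equal(length(back$peaks), 4) # grid still complete
  expect_equal(back$peaks[[4]]$mz, numeric(0))

  # swap one spectrum's m/z order in the binary: reader warns and sorts
  img2 <- make_image(data.frame(row = 0, col = 0, mz = c(300, 400),
                                intensity = c(1, 2)), 1, 1)
  p2 <- file.path(dir, "unsorted.imzML")
  write_imzml(img2, p2)
  ibd <- sub("imzML$", "ibd", p2)
  raw <- readBin(ibd, "raw", file.size(ibd))
  con <- file(ibd, "wb")
  writeBin(raw[1:16], con)
  writeBin(c(400, 300), con, size = 8, endian = "little") # reversed m/z
  writeBin(c(2, 1), con, size = 8, endian = "little")
  close(con)
  expect_warning(back2 <- read_imzml(p2), "re-sorted")
  expect_equal(back2$peaks[[1]]$mz, c(300, 400))
  expect_equal(back2$peaks[[1]]$intensity, c(1, 2))
})

test_that("imzML reader rejects broken or unsupported inputs", {
  dir <- withr::local_tempdir()
  expect_error(read_imzml(file.path(dir, "nope.imzML")), "not found")
  img <- rand_image(1, width = 1, height = 1)
  path <- file.path(dir, "x.imzML")
  write_imzml(img, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "companion")
  writeLines("<mzML><broken", path2 <- file.path(dir, "bad.imzML"))
  writeLines("", sub("imzML$", "ibd", path2))
  expect_error(read_imzml(path2), "malformed")
  # profile-mode flag rejected loudly
  write_imzml(img, path3 <- file.path(dir, "prof.imzML"))
  txt <- readLines(path3)
  txt <- sub('accession="MS:1000127" name="centroid spectrum"',
             'accession="MS:1000128" name="profile spectrum"', txt)
  writeLines(txt, path3)
  expect_error(read_imzml(path3), "profile")
})

test_that("element CSV grids round-trip with NA markers and units", {
  dir <- withr::local_tempdir()
  writeLines(c("1,2,3", "4,NA,6"), file.path(dir, "66Zn.csv"))
  st <- read_element_csv(dir)
  expect_equal(st$width, 3); expect_equal(st$height, 2)
  expect_equal(st$channels[["66Zn"]][2, 2], NA_real_)
  expect_equal(st$channels[["66Zn"]][1, ], c(1, 2, 3))
  expect_equal(unname(st$units[["66Zn"]]), "counts_per_second")

  # two channels, order and exact values preserved; sidecar units respected
  st2 <- elemental_stack(list("56Fe" = matrix(rnorm(6), 2, 3),
                              "66Zn" = matrix(c(0, 1, NA, 3, 4, 5), 2, 3)),
                         units = c("mg_per_kg", "counts_per_second"))
  out <- file.path(dir, "stack")
  write_element_csv(st2, out)
  back <- read_element_csv(out)
  expect_equal(names(back$channels), c("56Fe", "66Zn"))
  expect_equal(back$channels, st2$channels, tolerance = 1e-12)
  expect_equal(back$units, st2$units)
})

test_that("element CSV reader reports structural problems precisely", {
  dir <- withr::local_tempdir()
  writeLines(c("1,2,3", "4,5"), file.path(dir, "ragged.csv"))
  expect_error(read_element_csv(file.path(dir, "ragged.csv")), "row 2")
  dir2 <- file.path(dir, "mixed"); dir.create(dir2)
  writeLines(c("1,2", "3,4"), file.path(dir2, "a.csv"))
  writeLines("1,2,3", file.path(dir2, "b.csv"))
  expect_error(read_element_csv(dir2), "dimensions")
})

test_that("long-format element CSV is accepted", {
  dir <- withr::local_tempdir()
  df <- expand.grid(row = 0:1, col = 0:2)
  df$element <- "23Na"; df$value <- seq_len(6)
  utils::write.csv(df, f <- file.path(dir, "long.csv"), row.names = FALSE)
  st <- read_element_csv(f, format = "long")
  expect_equal(dim(st$channels[["23Na"]]), c(2, 3))
  expect_equal(st$channels[["23Na"]][cbind(df$row + 1, df$col + 1)],
               as.numeric(df$value))
})

test_that("landmark TSVs parse in order, keep labels, reject empties", {
  dir <- withr::local_tempdir()
  lm <- landmark_set(fixed = cbind(c(1, 2, 3), c(4, 5, 6)),
                     moving = cbind(c(0, 1, 2), c(3, 4, 5)),
                     labels = c("a", "b", "c"))
  path <- file.path(dir, "lm.tsv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$fixed, lm$fixed, ignore_attr = TRUE)
  expect_equal(back$moving, lm$moving, ignore_attr = TRUE)
  expect_equal(back$labels, c("a", "b", "c"))

  writeLines("x_fixed\ty_fixed\tx_moving\ty_moving", path)
  expect_error(read_landmarks(path), "no landmarks")
  writeLines(c("x_fixed\ty_fixed\tx_moving\ty_moving",
               "1\ttwo\t3\t4"), path)
  expect_error(read_landmarks(path), "non-numeric")
})

test_that("round-trip preserves every pixel: no reader drops data", {
  dir <- withr::local_tempdir()
  for (seed in 1:5) {
    img <- rand_image(seed, width = sample(2:5, 1), height = sample(2:4, 1))
    f <- file.path(dir, sprintf("p%d.imzML", seed))
    write_imzml(img, f)
    back <- read_imzml(f)
    expect_equal(length(back$peaks), back$width * back$height)
    expect_equal(length(back$peaks), length(img$peaks))
  }
})
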