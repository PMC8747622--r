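make_cube <- function(value, nr = 4, nc = 5, p = 6,
                      kind = "raw_dn", wl = seq(400, 900, length.out = p)) {
  hypercube(array(value, dim = c(nr, nc, p)), wl, kind)
}

test_that("calibration returns 1, 0 and 0.5 for raw = white, dark and midpoint", {
  white <- make_cube(3000, kind = "white_dn")
  dark <- make_cube(100, kind = "dark_dn")
  expect_equal(calibrate(make_cube(3000), white, dark)$data,
               array(1, dim = c(4, 5, 6)))
  expect_equal(calibrate(make_cube(100), white, dark)$data,
               array(0, dim = c(4, 5, 6)))
  expect_equal(calibrate(make_cube(1550), white, dark)$data,
               array(0.5, dim = c(4, 5, 6)))
})

test_that("zero denominators are masked, not infinite", {
  white <- make_cube(3000, kind = "white_dn")
  dark <- make_cube(100, kind = "dark_dn")
  white$data[1, 1, ] <- 100  # equals dark there
  suppressWarnings(out <- calibrate(make_cube(500), white, dark))
  expect_true(all(is.na(out$data[1, 1, ])))
  expect_true(all(is.finite(out$data[-1, , ])))
  expect_error(calibrate(make_cube(500), make_cube(7), make_cube(7)),
               "identical")
})

test_that("out-of-range reflectance is kept but counted", {
  white <- make_cube(1000, kind = "white_dn")
  dark <- make_cube(0, kind = "dark_dn")
  raw <- make_cube(500)
  raw$data[2, 2, 1] <- 2000  # reflectance 2 > 1.5
  expect_warning(out <- calibrate(raw, white, dark), "outside")
  expect_equal(attr(out, "out_of_range"), 1)
  expect_equal(out$data[2, 2, 1], 2)
})

test_that("single-row reference frames broadcast down the rows", {
  wl <- seq(400, 900, length.out = 6)
  white <- hypercube(array(rep(1000 + 1:5, times = 6), dim = c(1, 5, 6)),
                     wl, "white_dn")
  dark <- hypercube(array(50, dim = c(1, 5, 6)), wl, "dark_dn")
  raw <- make_cube(525)
  raw$data[] <- rep(525 + (1:5) / 2, each = 1)  # column pattern irrelevant
  out <- calibrate(make_cube(525), white, dark)
  for (col in 1:5) {
    expected <- (525 - 50) / (1000 + col - 50)
    expect_equal(out$data[, col, ], array(expected, dim = c(4, 6)))
  }
  bad <- hypercube(array(1, dim = c(2, 5, 6)), wl, "white_dn")
  expect_error(calibrate(raw, bad, dark), "broadcast")
})

test_that("a 1x1 ROI returns that pixel's spectrum and constant cubes give constant spectra", {
  cube <- make_cube(0, kind = "reflectance")
  cube$data[] <- seq_len(prod(dim(cube$data))) / 100
  out <- extract_roi_spectra(cube, list(roi(2, 2, 3, 3)))
  expect_equal(out$per_roi[1, ], cube$data[2, 3, ])
  expect_equal(out$combined, cube$data[2, 3, ])

  const <- make_cube(0.4, kind = "reflectance")
  out2 <- extract_roi_spectra(const, list(roi(1, 2, 1, 2), roi(3, 4, 2, 5)))
  expect_equal(out2$combined, rep(0.4, 6))
})

test_that("pixel-count weighting matches the brute-force per-pixel average", {
  set.seed(10)
  cube <- make_cube(0, nr = 8, nc = 8, kind = "reflectance")
  cube$data[] <- runif(length(cube$data))
  rois <- list(roi(1, 3, 1, 4), roi(5, 7, 3, 6))  # equal 3x4 blocks
  out <- extract_roi_spectra(cube, rois)
  expect_equal(out$combined, colMeans(out$per_roi))
  # brute force over every ROI pixel
  brute <- sapply(seq_len(6), function(b) {
    vals <- c(cube$data[1:3, 1:4, b], cube$data[5:7, 3:6, b])
    mean(vals)
  })
  expect_equal(out$combined, brute, tolerance = 1e-12)
})

test_that("ROI extraction is permutation-invariant and combined stays in the envelope", {
  set.seed(11)
  cube <- make_cube(0, nr = 9, nc = 9, kind = "reflectance")
  cube$data[] <- runif(length(cube$data))
  rois <- list(roi(1, 2, 1, 5), roi(4, 8, 2, 3), roi(6, 9, 6, 9))
  a <- extract_roi_spectra(cube, rois)
  b <- extract_roi_spectra(cube, rev(rois))
  expect_equal(a$combined, b$combined, tolerance = 1e-12)
  env_min <- apply(a$per_roi, 2, min)
  env_max <- apply(a$per_roi, 2, max)
  expect_true(all(a$combined >= env_min - 1e-12 & a$combined <= env_max + 1e-12))
})

test_that("invalid ROI requests fail loudly", {
  cube <- make_cube(0.3, kind = "reflectance")
  expect_error(extract_roi_spectra(cube, list(roi(1, 10, 1, 2))), "outside")
  expect_error(extract_roi_spectra(cube, list()), "at least one")
  expect_error(extract_roi_spectra(make_cube(5), list(roi(1, 1, 1, 1))),
               "reflectance")
  expect_error(roi(3, 2, 1, 1), "empty")
})

test_that("ROI config files parse rectangles and optional weights", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# rois", "1 2 3 4", "2 5 1 2 0.5"), path)
  rois <- read_roi_file(path)
  expect_length(rois, 2)
  expect_equal(rois[[1]]$col_min, 3)
  expect_true(is.na(rois[[1]]$weight))
  expect_equal(rois[[2]]$weight, 0.5)
})

test_that("ENVI write/read round-trips BSQ and BIL cubes", {
  set.seed(12)
  cube <- make_cube(0, nr = 5, nc = 7, p = 4, kind = "reflectance",
                    wl = c(450.5, 550.1, 650.9, 800.2))
  cube$data[] <- round(runif(length(cube$data)), 4)
  for (il in c("bsq", "bil")) {
    path <- withr::local_tempfile(fileext = ".dat")
    write_envi(cube, path, interleave = il)
    back <- read_envi(path)
    expect_equal(back$data, cube$data, tolerance = 1e-6)
    expect_equal(back$wavelengths, cube$wavelengths, tolerance = 1e-4)
    expect_identical(back$kind, "reflectance")
  }
})
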