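make_scene_cube <- function(spad = 55, noise_sd = 0, nr = 20, nc = 28,
                            seed = 15, n_bands = 30) {
  cfg <- sim_config(n_samples = 10, n_bands = n_bands, noise_sd = noise_sd,
                    seed = seed)
  scene <- synthetic_leaf(nr, nc, spad)
  cubes <- generate_hypercube(scene$spad_field, scene$leaf_mask, cfg)
  list(cfg = cfg, scene = scene,
       refl = calibrate(cubes$raw, cubes$white, cubes$dark),
       truth = cubes$truth)
}

test_that("the exact mask is recovered from a noiseless cube", {
  sc <- make_scene_cube(spad = 60, noise_sd = 0)
  expect_identical(leaf_mask(sc$refl), sc$scene$leaf_mask)
})

test_that("an all-background cube yields an empty mask and downstream refusal", {
  cfg <- sim_config(n_samples = 5, n_bands = 20, noise_sd = 0, seed = 16)
  cubes <- generate_hypercube(matrix(0, 8, 8), matrix(FALSE, 8, 8), cfg)
  refl <- calibrate(cubes$raw, cubes$white, cubes$dark)
  m <- leaf_mask(refl)
  expect_false(any(m))
  ds <- tiny_dataset(n = 30, p = 20, seed = 16)
  model <- fit_model(ds, model_spec("plsr"))
  expect_error(predict_map(refl, model, mask = m), "empty")
})

test_that("mask recovery stays accurate under noise (Jaccard >= 0.95)", {
  sc <- make_scene_cube(spad = 60, noise_sd = 0.01, seed = 17)
  m <- leaf_mask(sc$refl)
  truth <- sc$scene$leaf_mask
  jaccard <- sum(m & truth) / sum(m | truth)
  expect_gte(jaccard, 0.95)
})

test_that("leaf_mask requires an NIR band", {
  cube <- hypercube(array(0.5, dim = c(4, 4, 3)), c(450, 550, 650),
                    "reflectance")
  expect_error(leaf_mask(cube), "750")
})

test_that("a constant-spectrum cube maps to the model's constant prediction", {
  sc <- make_scene_cube(spad = 58, noise_sd = 0)
  ds <- generate_dataset(sim_config(n_samples = 60, n_bands = 30,
                                    noise_sd = 0.002, seed = 18))
  model <- fit_model(ds, model_spec("plsr"))
  map <- predict_map(sc$refl, model, mask = sc$scene$leaf_mask)
  vals <- map$values[map$mask]
  expect_lt(max(vals) - min(vals), 1e-9)
  spectrum <- vapply(seq_len(30), function(b)
    sc$refl$data[, , b][which(sc$scene$leaf_mask)[1]], numeric(1))
  expect_equal(vals[1], unname(predict(model, t(spectrum[model$bands]))),
               tolerance = 1e-9)
})

test_that("a SPAD gradient is recovered pixel-wise (Spearman rho >= 0.9)", {
  cfg <- sim_config(n_samples = 150, n_bands = 30, noise_sd = 0.002, seed = 19)
  ds <- generate_dataset(cfg)
  model <- fit_model(ds, model_spec("plsr"), bands = run_ca(ds))
  scene <- synthetic_leaf(24, 36, spad = c(40, 70))
  cubes <- generate_hypercube(scene$spad_field, scene$leaf_mask, cfg)
  refl <- calibrate(cubes$raw, cubes$white, cubes$dark)
  map <- predict_map(refl, model)
  ok <- map$mask & scene$leaf_mask
  rho <- cor(map$values[ok], cubes$truth[ok], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("map statistics match an independent flat-array computation", {
  sc <- make_scene_cube(spad = c(45, 65), noise_sd = 0.003, seed = 20)
  ds <- generate_dataset(sim_config(n_samples = 80, n_bands = 30,
                                    noise_sd = 0.002, seed = 20))
  model <- fit_model(ds, model_spec("plsr"))
  map <- predict_map(sc$refl, model, mask = sc$scene$leaf_mask)
  vals <- as.numeric(map$values[map$mask])
  expect_equal(map$stats$min, min(vals))
  expect_equal(map$stats$max, max(vals))
  expect_equal(map$stats$mean, mean(vals))
  expect_equal(map$stats$sd, sd(vals))
  expect_true(map$stats$min <= map$stats$mean &&
                map$stats$mean <= map$stats$max)
  expect_true(all(is.na(map$values[!map$mask])))
})

test_that("wavelength matching refuses gaps beyond the tolerance", {
  ds <- tiny_dataset(n = 30, p = 10, seed = 21)
  model <- fit_model(ds, model_spec("plsr"))
  cube <- hypercube(array(0.4, dim = c(4, 4, 3)), c(500, 600, 800),
                    "reflectance")
  expect_error(predict_map(cube, model, mask = matrix(TRUE, 4, 4)), "nm of")
})

test_that("rendering is byte-deterministic and hits palette endpoints at the limits", {
  sc <- make_scene_cube(spad = 55, noise_sd = 0)
  ds <- generate_dataset(sim_config(n_samples = 50, n_bands = 30,
                                    noise_sd = 0.002, seed = 22))
  model <- fit_model(ds, model_spec("plsr"))
  map <- predict_map(sc$refl, model, mask = sc$scene$leaf_mask)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_map(map, p1)
  render_map(map, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # constant map -> one colour over the leaf
  img <- png::readPNG(p1)
  leaf_px <- which(map$mask)
  for (ch in 1:3)
    expect_equal(length(unique(img[, , ch][leaf_px])), 1)

  # endpoint mapping: values at the limits take the palette end colours
  map2 <- map
  map2$values[leaf_px[1]] <- 0
  map2$values[leaf_px[2]] <- 100
  p3 <- withr::local_tempfile(fileext = ".png")
  render_map(map2, p3, limits = c(0, 100))
  img3 <- png::readPNG(p3)
  pal <- spad_palette()
  low <- grDevices::col2rgb(pal[1]) / 255
  high <- grDevices::col2rgb(pal[length(pal)]) / 255
  got_low <- c(img3[, , 1][leaf_px[1]], img3[, , 2][leaf_px[1]],
               img3[, , 3][leaf_px[1]])
  got_high <- c(img3[, , 1][leaf_px[2]], img3[, , 2][leaf_px[2]],
                img3[, , 3][leaf_px[2]])
  expect_equal(got_low, as.numeric(low), tolerance = 0.005)
  expect_equal(got_high, as.numeric(high), tolerance = 0.005)
})
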