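#' Segment the leaf from the background
#'
#' NDVI thresholding: with the reflectance at the nearest band to `red_wl`
#' and the nearest band above 750 nm to `nir_wl`, a pixel is leaf when
#' `(NIR - red) / (NIR + red)` exceeds the threshold. The largest
#' 4-connected component of the thresholded image is kept, discarding
#' speckle.
#'
#' @param cube a reflectance [hypercube()] with at least one band above
#'   750 nm.
#' @param threshold NDVI cutoff (default 0.3).
#' @param red_wl,nir_wl target wavelengths (nm) of the red and NIR bands.
#' @return Logical leaf mask (rows x cols); may be all-`FALSE`.
#' @export
leaf_mask <- function(cube, threshold = 0.3, red_wl = 670, nir_wl = 800) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") stop("leaf_mask expects a reflectance cube")
  nir_candidates <- which(cube$wavelengths > 750)
  if (!length(nir_candidates))
    stop("no band above 750 nm; cannot compute NDVI")
  nir_band <- nir_candidates[which.min(abs(cube$wavelengths[nir_candidates] -
                                             nir_wl))]
  red_band <- which.min(abs(cube$wavelengths - red_wl))
  nir <- cube$data[, , nir_band]
  red <- cube$data[, , red_band]
  ndvi <- (nir - red) / (nir + red)
  mask <- !is.na(ndvi) & ndvi > threshold
  if (!any(mask)) return(mask)
  labels <- EBImage::bwlabel(mask)
  counts <- tabulate(labels[labels > 0])
  mask & (labels == which.max(counts))
}

#' Pixel-wise SPAD prediction map
#'
#' Applies a fitted model to every leaf pixel of a reflectance cube: the
#' model's wavelengths are matched to cube bands by nearest neighbour
#' (within half the median band spacing unless overridden), each leaf
#' pixel's selected-band spectrum is assembled, and the model predicts its
#' SPAD. Background pixels stay `NA`. Predictions are not clipped to the
#' SPAD meter range, so linear-model excursions remain visible.
#'
#' @param cube a reflectance [hypercube()].
#' @param model a [fit_model()] result.
#' @param mask logical leaf mask; default [leaf_mask()] of the cube.
#' @param match_tol wavelength matching tolerance in nm; default half the
#'   cube's median band spacing.
#' @return Object of class `spad_map`: `values` (rows x cols, `NA` off
#'   leaf), `mask`, and `stats` (min, max, mean, sd over leaf pixels).
#' @export
predict_map <- function(cube, model, mask = NULL, match_tol = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "spad_model"))
  if (cube$kind != "reflectance") stop("predict_map expects a reflectance cube")
  if (is.null(mask)) mask <- leaf_mask(cube)
  if (!any(mask)) stop("leaf mask is empty; nothing to predict")
  if (is.null(match_tol))
    match_tol <- stats::median(diff(cube$wavelengths)) / 2
  band_idx <- vapply(model$wavelengths, function(w) {
    j <- which.min(abs(cube$wavelengths - w))
    if (abs(cube$wavelengths[j] - w) > match_tol)
      stop(sprintf("no cube band within %.2f nm of %.1f nm", match_tol, w))
    j
  }, integer(1))
  leaf_idx <- which(mask)
  spectra <- vapply(band_idx, function(b) cube$data[, , b][leaf_idx],
                    numeric(length(leaf_idx)))
  spectra <- matrix(spectra, nrow = length(leaf_idx))
  pred <- predict(model, spectra)
  values <- matrix(NA_real_, nrow(mask), ncol(mask))
  values[leaf_idx] <- pred
  structure(list(values = values, mask = mask,
                 stats = list(min = min(pred), max = max(pred),
                              mean = mean(pred), sd = sd(pred))),
            class = "spad_map")
}

#' @export
print.spad_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<spad_map> %d leaf pixels; SPAD %.1f-%.1f (mean %.1f, sd %.2f)\n",
              sum(x$mask), s$min, s$max, s$mean, s$sd))
  invisible(x)
}

#' Green-yellow-red SPAD palette
#'
#' @param n number of colours.
#' @return Character vector of hex colours from green through yellow to red.
#' @export
spad_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("#1a9850", "#ffffbf", "#d73027"))(n)
}

#' Render a SPAD map to image files
#'
#' Writes an 8-bit colour PNG of the map and a companion grayscale PNG
#' (`*_gray.png`). Values are mapped to colours with fixed global limits so
#' maps of different leaves share one scale; values at the limits hit the
#' palette endpoints, values beyond them are clamped. Background pixels
#' are white in the colour map and black in the grayscale map. Output is
#' byte-deterministic for identical inputs.
#'
#' @param map a [predict_map()] result.
#' @param out_path output PNG path.
#' @param palette colour vector (default [spad_palette()]).
#' @param limits length-2 SPAD limits of the colour scale (default
#'   `c(0, 100)`).
#' @return Named character vector with the colour and grayscale paths,
#'   invisibly.
#' @export
render_map <- function(map, out_path, palette = spad_palette(),
                       limits = c(0, 100)) {
  stopifnot(inherits(map, "spad_map"))
  if (!any(map$mask)) stop("cannot render an empty map")
  if (limits[2] <= limits[1]) stop("limits must be increasing")
  v <- map$values
  scaled <- (v - limits[1]) / (limits[2] - limits[1])
  scaled <- pmin(1, pmax(0, scaled))
  idx <- 1L + round(scaled * (length(palette) - 1))

  rgb_vals <- grDevices::col2rgb(palette) / 255
  img <- array(1, dim = c(nrow(v), ncol(v), 3))  # white background
  on_leaf <- which(map$mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[on_leaf] <- rgb_vals[ch, idx[on_leaf]]
    img[, , ch] <- plane
  }
  png::writePNG(img, out_path)

  gray <- matrix(0, nrow(v), ncol(v))  # black background
  gray[on_leaf] <- scaled[on_leaf]
  gray_path <- sub("\\.png$", "_gray.png", out_path)
  if (identical(gray_path, out_path)) gray_path <- paste0(out_path, "_gray.png")
  png::writePNG(gray, gray_path)
  invisible(c(colour = out_path, gray = gray_path))
}

#' Per-leaf map statistics as a data frame
#'
#' @param maps named list of [predict_map()] results (one per leaf).
#' @param model_name label recorded in the output.
#' @return Data frame: leaf id, model, min, max, mean, sd.
#' @export
map_stats <- function(maps, model_name = "") {
  do.call(rbind, lapply(names(maps), function(nm) {
    s <- maps[[nm]]$stats
    data.frame(leaf = nm, model = model_name, min = s$min, max = s$max,
               mean = s$mean, sd = s$sd)
  }))
}
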