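#' Rectangular region of interest
#'
#' A rectangle of pixels, 1-based inclusive bounds, with a nonnegative
#' weight used when combining several ROI spectra into one sample spectrum.
#'
#' @param row_min,row_max,col_min,col_max 1-based inclusive pixel bounds.
#' @param weight nonnegative weight; `NA` (default) means "weight by pixel
#'   count" when combining.
#' @return An object of class `roi`.
#' @export
roi <- function(row_min, row_max, col_min, col_max, weight = NA_real_) {
  if (row_min > row_max || col_min > col_max)
    stop("ROI rectangle is empty")
  if (row_min < 1 || col_min < 1)
    stop("ROI bounds must be >= 1")
  if (!is.na(weight) && weight < 0) stop("ROI weight must be nonnegative")
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max),
                 weight = weight),
            class = "roi")
}

#' Reflectance calibration of a raw hypercube
#'
#' Converts raw digital numbers to reflectance using white and dark
#' reference frames: `R = (DNraw - DNdark) / (DNwhite - DNdark)`,
#' elementwise. Where the denominator is zero the result is `NA` (masked),
#' never infinite. Reflectance outside `[0, 1.5]` is kept, but the count of
#' such pixels is attached as attribute `"out_of_range"` and a warning is
#' raised.
#'
#' White and dark references may be full cubes of the same shape as `raw`,
#' or single-row frames (1 x cols x bands) that are broadcast down the rows
#' — the usual line-scanner geometry where references are acquired once per
#' scan line position.
#'
#' @param raw,white,dark [hypercube()]s sharing the wavelength grid; `white`
#'   and `dark` must match `raw`'s shape or be single-row frames.
#' @return A [hypercube()] of kind `"reflectance"`.
#' @export
calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, dark$wavelengths)))
    stop("wavelength grids of raw/white/dark do not match")
  d <- dim(raw$data)
  w <- broadcast_frame(white$data, d, "white")
  k <- broadcast_frame(dark$data, d, "dark")
  denom <- w - k
  if (all(denom == 0)) stop("white and dark references are identical everywhere")
  refl <- (raw$data - k) / denom
  refl[denom == 0] <- NA_real_
  oor <- sum(refl < 0 | refl > 1.5, na.rm = TRUE)
  if (oor > 0)
    warning(sprintf("%d reflectance values outside [0, 1.5] (kept, not clipped)", oor))
  out <- hypercube(refl, raw$wavelengths, "reflectance")
  attr(out, "out_of_range") <- oor
  out
}

# Broadcast a reference frame to the raw cube's shape: accept an identical
# shape, or a 1 x cols x bands frame replicated along rows.
broadcast_frame <- function(arr, target_dim, what) {
  d <- dim(arr)
  if (identical(d, target_dim)) return(arr)
  if (d[1] == 1L && d[2] == target_dim[2] && d[3] == target_dim[3]) {
    out <- array(0, dim = target_dim)
    for (b in seq_len(target_dim[3]))
      out[, , b] <- matrix(arr[1, , b], target_dim[1], target_dim[2],
                           byrow = TRUE)
    return(out)
  }
  stop(what, " reference shape ", paste(d, collapse = "x"),
       " does not match raw cube ", paste(target_dim, collapse = "x"),
       " and is not a broadcastable single-row frame")
}

#' Extract ROI-averaged spectra from a reflectance cube
#'
#' Each ROI yields the mean spectrum over its pixels; the combined spectrum
#' is the weighted average of the ROI spectra. ROIs with `NA` weight are
#' weighted by their pixel count (so the combined spectrum then equals the
#' plain mean over all ROI pixels).
#'
#' @param cube a reflectance [hypercube()].
#' @param rois list of [roi()] objects (at least one).
#' @return List with `per_roi` (k x p matrix, one row per ROI) and
#'   `combined` (length-p weighted average spectrum).
#' @export
extract_roi_spectra <- function(cube, rois) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance")
    stop("extract_roi_spectra expects a reflectance cube")
  if (!length(rois)) stop("at least one ROI is required")
  if (inherits(rois, "roi")) rois <- list(rois)
  d <- dim(cube$data)
  p <- d[3]
  k <- length(rois)
  per_roi <- matrix(NA_real_, k, p)
  npix <- numeric(k)
  weights <- numeric(k)
  for (i in seq_len(k)) {
    r <- rois[[i]]
    stopifnot(inherits(r, "roi"))
    if (r$row_max > d[1] || r$col_max > d[2])
      stop(sprintf("ROI %d extends outside the %dx%d image", i, d[1], d[2]))
    block <- cube$data[r$row_min:r$row_max, r$col_min:r$col_max, ,
                       drop = FALSE]
    per_roi[i, ] <- apply(block, 3, mean)
    npix[i] <- prod(dim(block)[1:2])
    weights[i] <- if (is.na(r$weight)) NA_real_ else r$weight
  }
  if (anyNA(weights)) {
    if (!all(is.na(weights)))
      stop("ROI weights must be all explicit or all pixel-count defaults")
    weights <- npix
  }
  if (sum(weights) <= 0) stop("ROI weights sum to zero")
  combined <- drop(crossprod(per_roi, weights / sum(weights)))
  list(per_roi = per_roi, combined = as.numeric(combined), n_pixels = npix)
}

#' Read ROI rectangles from a plain-text config block
#'
#' One rectangle per line: `row_min row_max col_min col_max [weight]`,
#' whitespace separated; lines starting with `#` are ignored.
#'
#' @param path text file path.
#' @return List of [roi()] objects.
#' @export
read_roi_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(ln, "\\s+")[[1]])
    if (length(v) < 4) stop("ROI line needs at least 4 numbers: ", ln)
    roi(v[1], v[2], v[3], v[4],
        weight = if (length(v) >= 5) v[5] else NA_real_)
  })
}
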