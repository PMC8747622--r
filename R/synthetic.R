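#' Simulation configuration for synthetic leaf spectra
#'
#' Describes the generative model used by [generate_dataset()] and
#' [generate_hypercube()]: a fixed vegetation-like reflectance template
#' (green peak near 550 nm, chlorophyll absorption trough near 670 nm, red
#' edge, NIR plateau) plus a band-localised linear dependence of reflectance
#' on standardised SPAD, plus spectrally correlated noise.
#'
#' SPAD values are drawn per leaf tier (lower/middle/upper) from normal
#' distributions whose default means (66, 61, 48.3) follow the measured
#' tier means of seedling-stage pepper leaves; tier spreads default to 4
#' SPAD units. The SPAD -> reflectance link is negative in the visible
#' bands and positive in the NIR, so higher-chlorophyll leaves are darker
#' in the visible and brighter in the NIR.
#'
#' @param n_samples number of leaf samples (split evenly over the 3 tiers).
#' @param n_bands number of spectral bands.
#' @param wl_min,wl_max wavelength range in nm.
#' @param informative_bands integer band indices (1-based) carrying the SPAD
#'   signal. Default: ten bands nearest 550, 670, 700, 710, 720, 850, 880,
#'   910, 940 and 970 nm.
#' @param effect_sizes per-informative-band slope of reflectance on
#'   standardised SPAD (reflectance units per SD of SPAD). Default:
#'   -0.02 below 750 nm, +0.02 above.
#' @param noise_sd marginal standard deviation of the additive reflectance
#'   noise.
#' @param spectral_corr_length smoothing length (in bands) of the noise: a
#'   Gaussian kernel of this standard deviation is convolved along the
#'   spectral axis, preserving the marginal SD.
#' @param position_means,position_sds length-3 SPAD mean/SD per tier, in the
#'   order lower, middle, upper.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `sim_config`.
#' @seealso [generate_dataset()], [generate_hypercube()]
#' @export
sim_config <- function(n_samples = 150L,
                       n_bands = 176L,
                       wl_min = 400, wl_max = 1000,
                       informative_bands = NULL,
                       effect_sizes = NULL,
                       noise_sd = 0.005,
                       spectral_corr_length = 5,
                       position_means = c(lower = 66, middle = 61, upper = 48.3),
                       position_sds = c(lower = 4, middle = 4, upper = 4),
                       seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop("n_samples must be a positive count")
  if (!is.numeric(n_bands) || length(n_bands) != 1L || n_bands < 2)
    stop("n_bands must be >= 2")
  if (!is.numeric(wl_min) || !is.numeric(wl_max) || wl_min >= wl_max)
    stop("wl_min must be strictly less than wl_max")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be nonnegative")
  if (spectral_corr_length < 0)
    stop("spectral_corr_length must be nonnegative (0 = white noise)")
  if (length(position_means) != 3L || length(position_sds) != 3L)
    stop("position_means and position_sds must have length 3 (lower, middle, upper)")
  if (any(position_sds < 0)) stop("position_sds must be nonnegative")

  wavelengths <- seq(wl_min, wl_max, length.out = as.integer(n_bands))
  if (is.null(informative_bands)) {
    anchors <- c(550, 670, 700, 710, 720, 850, 880, 910, 940, 970)
    anchors <- anchors[anchors >= wl_min & anchors <= wl_max]
    informative_bands <- unique(vapply(anchors, function(a)
      which.min(abs(wavelengths - a)), integer(1)))
  }
  informative_bands <- as.integer(informative_bands)
  if (any(informative_bands < 1L) || any(informative_bands > n_bands))
    stop("informative_bands must lie within [1, n_bands]")
  if (anyDuplicated(informative_bands))
    stop("informative_bands must be distinct")
  if (is.null(effect_sizes)) {
    effect_sizes <- ifelse(wavelengths[informative_bands] < 750, -0.02, 0.02)
  }
  if (length(effect_sizes) != length(informative_bands))
    stop("effect_sizes must match informative_bands in length")

  structure(list(
    n_samples = as.integer(n_samples),
    n_bands = as.integer(n_bands),
    wl_min = wl_min, wl_max = wl_max,
    wavelengths = wavelengths,
    informative_bands = informative_bands,
    effect_sizes = as.numeric(effect_sizes),
    noise_sd = noise_sd,
    spectral_corr_length = spectral_corr_length,
    position_means = stats::setNames(as.numeric(position_means),
                                     c("lower", "middle", "upper")),
    position_sds = stats::setNames(as.numeric(position_sds),
                                   c("lower", "middle", "upper")),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Fixed smooth vegetation template: baseline + green-peak Gaussian + red-edge
# logistic rising to the NIR plateau. Values stay within [0, 1] for the
# default SPAD range and effect sizes.
base_reflectance <- function(wavelengths) {
  0.04 +
    0.10 * exp(-((wavelengths - 550)^2) / (2 * 35^2)) +
    0.45 / (1 + exp(-(wavelengths - 715) / 12))
}

# Reference standardisation of SPAD used by the reflectance link: the
# population mean/SD implied by the configured tier mixture (tiers equally
# weighted), so datasets and hypercubes share one link scale.
spad_standardiser <- function(cfg) {
  mu <- mean(cfg$position_means)
  v <- mean(cfg$position_sds^2) + mean((cfg$position_means - mu)^2)
  list(mean = mu, sd = sqrt(v))
}

# Spectrally correlated noise: white noise convolved along the band axis
# with a Gaussian kernel of SD `corr_len` bands, rescaled to marginal `sd`.
# corr_len = 0 gives plain white noise.
correlated_noise <- function(n, p, sd, corr_len) {
  if (sd == 0) return(matrix(0, n, p))
  if (corr_len == 0) return(matrix(sd * rnorm(n * p), n, p))
  half <- max(1L, ceiling(3 * corr_len))
  kern <- exp(-((-half:half)^2) / (2 * corr_len^2))
  kern <- kern / sqrt(sum(kern^2))  # preserves marginal variance
  z <- matrix(rnorm(n * (p + 2 * half)), n)
  out <- matrix(0, n, p)
  for (j in seq_len(p)) {
    idx <- j:(j + 2 * half)
    out[, j] <- z[, idx, drop = FALSE] %*% kern
  }
  sd * out
}

# Reflectance matrix (n x p) for a vector of SPAD values under cfg's link.
spectra_from_spad <- function(spad, cfg, noise = TRUE) {
  base <- base_reflectance(cfg$wavelengths)
  std <- spad_standardiser(cfg)
  z <- (spad - std$mean) / std$sd
  X <- matrix(rep(base, each = length(spad)), nrow = length(spad))
  for (k in seq_along(cfg$informative_bands)) {
    j <- cfg$informative_bands[k]
    X[, j] <- X[, j] + cfg$effect_sizes[k] * z
  }
  if (noise && cfg$noise_sd > 0) {
    X <- X + correlated_noise(length(spad), cfg$n_bands, cfg$noise_sd,
                              cfg$spectral_corr_length)
  }
  X
}

#' Spectral dataset container
#'
#' Bundles an n x p reflectance matrix with per-sample SPAD values, the
#' wavelength grid, sample identifiers and leaf-position labels. This is the
#' modelling unit consumed by the band selectors and regression models.
#'
#' @param X n x p numeric reflectance matrix.
#' @param y length-n numeric SPAD vector.
#' @param wavelengths length-p strictly increasing wavelength grid (nm).
#' @param sample_ids optional character ids (default `S001`, ...).
#' @param position_labels optional character leaf-tier labels.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, y, wavelengths, sample_ids = NULL,
                             position_labels = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (ncol(X) != length(wavelengths))
    stop("columns of X must align with wavelengths")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(X)))
  if (is.null(position_labels))
    position_labels <- rep(NA_character_, nrow(X))
  structure(list(X = X, y = as.numeric(y),
                 wavelengths = as.numeric(wavelengths),
                 sample_ids = as.character(sample_ids),
                 position_labels = as.character(position_labels)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  SPAD: %.1f-%.1f (mean %.1f)\n",
              min(x$y), max(x$y), mean(x$y)))
  tab <- table(x$position_labels, useNA = "no")
  if (length(tab)) cat("  tiers:", paste(names(tab), tab, sep = "=",
                                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$X)

#' Generate a synthetic leaf spectral dataset
#'
#' Draws SPAD values per leaf tier, builds each sample's reflectance spectrum
#' from the vegetation template plus the band-localised SPAD link, and adds
#' spectrally correlated noise. Fully reproducible under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A [spectral_dataset()].
#' @examples
#' ds <- generate_dataset(sim_config(n_samples = 30, seed = 7))
#' dim(ds$X)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  n_lower <- ceiling(n / 3)
  n_middle <- ceiling((n - n_lower) / 2)
  n_upper <- n - n_lower - n_middle
  tiers <- rep(c("lower", "middle", "upper"),
               times = c(n_lower, n_middle, n_upper))
  spad <- rnorm(n, mean = cfg$position_means[tiers],
                sd = cfg$position_sds[tiers])
  X <- spectra_from_spad(spad, cfg)
  spectral_dataset(X, spad, cfg$wavelengths,
                   sample_ids = sprintf("S%03d", seq_len(n)),
                   position_labels = tiers)
}

#' Generate a synthetic hypercube with reference frames
#'
#' Builds a raw-DN hypercube from a per-pixel SPAD image: each leaf pixel's
#' reflectance spectrum comes from the same generative model as
#' [generate_dataset()], background pixels get a flat low-reflectance
#' spectrum, and the reflectance is encoded to digital numbers as
#' `raw = dark + R * (white - dark)` using a 12-bit scale (dark frame at 2%,
#' white at 95% of full scale), so reflectance calibration inverts the
#' encoding exactly when `quantize = FALSE`.
#'
#' @param spad_field numeric matrix of per-pixel SPAD values.
#' @param leaf_mask logical matrix, `TRUE` on leaf pixels; same shape as
#'   `spad_field`.
#' @param cfg a [sim_config()]; its seed drives the pixel noise.
#' @param background_reflectance flat reflectance of non-leaf pixels.
#' @param quantize round DN values to integers (breaks the exact calibration
#'   round-trip by up to half a DN); default `FALSE`.
#' @return A list with components `raw`, `white`, `dark` (hypercubes of kind
#'   `raw_dn`/`white_dn`/`dark_dn`) and `truth` (the SPAD matrix with `NA`
#'   outside the mask).
#' @export
generate_hypercube <- function(spad_field, leaf_mask, cfg,
                               background_reflectance = 0.05,
                               quantize = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  spad_field <- as.matrix(spad_field)
  if (!is.logical(leaf_mask)) leaf_mask <- as.matrix(leaf_mask) > 0
  if (!identical(dim(spad_field), dim(leaf_mask)))
    stop("spad_field and leaf_mask must have the same shape")
  nr <- nrow(spad_field); nc <- ncol(spad_field); p <- cfg$n_bands
  set.seed(cfg$seed)

  refl <- array(background_reflectance, dim = c(nr, nc, p))
  leaf_idx <- which(leaf_mask)
  if (length(leaf_idx)) {
    spectra <- spectra_from_spad(spad_field[leaf_idx], cfg)
    for (j in seq_len(p)) {
      plane <- refl[, , j]
      plane[leaf_idx] <- spectra[, j]
      refl[, , j] <- plane
    }
  }

  dark_dn <- 0.02 * 4095
  white_dn <- 0.95 * 4095
  raw <- dark_dn + refl * (white_dn - dark_dn)
  if (quantize) raw <- round(raw)
  white <- array(white_dn, dim = c(nr, nc, p))
  dark <- array(dark_dn, dim = c(nr, nc, p))
  truth <- spad_field
  truth[!leaf_mask] <- NA_real_

  list(raw = hypercube(raw, cfg$wavelengths, "raw_dn"),
       white = hypercube(white, cfg$wavelengths, "white_dn"),
       dark = hypercube(dark, cfg$wavelengths, "dark_dn"),
       truth = truth)
}

#' Build an elliptical synthetic leaf scene
#'
#' Convenience constructor of a SPAD field plus leaf mask for end-to-end
#' tests and demos: an ellipse inscribed in the image, with either a
#' constant SPAD value or a left-to-right linear gradient.
#'
#' @param nrow,ncol image dimensions in pixels.
#' @param spad single value, or length-2 range for a column-wise gradient.
#' @return List with `spad_field` and `leaf_mask` matrices.
#' @export
synthetic_leaf <- function(nrow = 40, ncol = 60, spad = 55) {
  rr <- (seq_len(nrow) - (nrow + 1) / 2) / (nrow * 0.42)
  cc <- (seq_len(ncol) - (ncol + 1) / 2) / (ncol * 0.42)
  mask <- outer(rr^2, cc^2, "+") <= 1
  if (length(spad) == 1L) {
    field <- matrix(spad, nrow, ncol)
  } else {
    grad <- seq(spad[1], spad[2], length.out = ncol)
    field <- matrix(grad, nrow, ncol, byrow = TRUE)
  }
  field[!mask] <- 0
  list(spad_field = field, leaf_mask = mask)
}

#' Write / read a spectral dataset as CSV
#'
#' One row per sample: `id`, `position`, `spad`, then one column per
#' wavelength, with the wavelength in nm (1 decimal) as column header.
#'
#' @param ds a [spectral_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly (write); a [spectral_dataset()] (read).
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(id = ds$sample_ids, position = ds$position_labels,
                   spad = ds$y, check.names = FALSE)
  spec <- as.data.frame(ds$X)
  names(spec) <- sprintf("%.1f", ds$wavelengths)
  write.csv(cbind(df, spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl_cols <- grep("^[0-9]+(\\.[0-9]+)?$", names(df))
  if (length(wl_cols) < 2) stop("no wavelength columns found in ", path)
  spectral_dataset(as.matrix(df[, wl_cols]), df$spad,
                   as.numeric(names(df)[wl_cols]),
                   sample_ids = df$id, position_labels = df$position)
}
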