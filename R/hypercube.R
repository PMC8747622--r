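#' Hypercube container
#'
#' A 3-D hyperspectral image: rows x cols x bands, with its wavelength grid
#' and a `kind` tag distinguishing raw digital numbers, white/dark reference
#' frames and calibrated reflectance.
#'
#' @param data 3-D numeric array (rows x cols x bands).
#' @param wavelengths length-bands wavelength grid in nm.
#' @param kind one of `"raw_dn"`, `"white_dn"`, `"dark_dn"`, `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths,
                      kind = c("raw_dn", "white_dn", "dark_dn", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array (rows x cols x bands)")
  if (dim(data)[3] != length(wavelengths))
    stop("bands dimension must match the wavelength grid length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube:%s> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              x$kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Write a hypercube in ENVI format
#'
#' Writes the binary data file (band-sequential, 32-bit float, little
#' endian) plus the text `.hdr` companion carrying dimensions, interleave
#' and the wavelength list.
#'
#' @param cube a [hypercube()].
#' @param path output path for the data file; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bsq"` (band sequential) or `"bil"` (band interleaved
#'   by line).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  con <- file(path, "wb")
  on.exit(close(con))
  if (interleave == "bsq") {
    # ENVI BSQ stores each band as lines x samples, row-major per line
    for (b in seq_len(d[3]))
      writeBin(as.numeric(t(cube$data[, , b])), con, size = 4,
               endian = "little")
  } else {
    for (r in seq_len(d[1]))
      for (b in seq_len(d[3]))
        writeBin(as.numeric(cube$data[r, , b]), con, size = 4,
                 endian = "little")
  }
  hdr <- c("ENVI",
           "description = {spadspec hypercube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("kind = %s", cube$kind),
           sprintf("wavelength units = Nanometers"),
           sprintf("wavelength = {%s}",
                   paste(sprintf("%.4f", cube$wavelengths), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

# Parse an ENVI header into a named list; values of `key = {...}` blocks
# (possibly spanning lines) are returned as the inner string.
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  # brace-delimited entries first
  m <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*\\{([^}]*)\\}", txt)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
      key <- trimws(sub("=.*", "", piece))
      val <- sub(".*\\{", "", piece)
      val <- sub("\\}.*", "", val)
      out[[tolower(key)]] <- trimws(gsub("\n", " ", val))
    }
    txt <- gsub("([a-zA-Z ]+?)\\s*=\\s*\\{[^}]*\\}", "", txt)
  }
  for (ln in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub(".*?=", "", ln))
    if (nzchar(key)) out[[key]] <- val
  }
  out
}

#' Read an ENVI-format hypercube
#'
#' Supports BSQ and BIL interleaves, data types 4 (float32), 5 (float64),
#' 2 (int16) and 12 (uint16), little endian, with the wavelength list taken
#' from the header.
#'
#' @param path path to the ENVI data file; the header is looked up at
#'   `paste0(path, ".hdr")` (or `path` with its extension replaced).
#' @param kind kind tag for the resulting [hypercube()]; defaults to the
#'   `kind` recorded in the header, else `"raw_dn"`.
#' @return A [hypercube()].
#' @export
read_envi <- function(path, kind = NULL) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found for ", path)
  h <- parse_envi_header(hdr_path)
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h$interleave)
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (length(wl) != nb) stop("wavelength list does not match band count")
  size <- switch(as.character(dtype), "2" = 2L, "12" = 2L, "4" = 4L,
                 "5" = 8L, stop("unsupported ENVI data type ", dtype))
  what <- if (dtype %in% c(2L, 12L)) integer() else numeric()
  signed <- dtype != 12L

  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what, n = ns * nl * nb, size = size,
                  endian = "little", signed = if (size == 2) signed else TRUE)
  vals <- as.numeric(vals)
  arr <- array(NA_real_, dim = c(nl, ns, nb))
  if (interleave == "bsq") {
    cube <- array(vals, dim = c(ns, nl, nb))  # samples fastest, then lines
    for (b in seq_len(nb)) arr[, , b] <- t(cube[, , b])
  } else if (interleave == "bil") {
    cube <- array(vals, dim = c(ns, nb, nl))
    for (b in seq_len(nb)) arr[, , b] <- t(cube[, b, ])
  } else stop("unsupported interleave ", interleave)

  if (is.null(kind)) kind <- if (!is.null(h$kind)) h$kind else "raw_dn"
  hypercube(arr, wl, kind)
}
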