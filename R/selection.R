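#' Band selection result
#'
#' Common container returned by all three wavelength selectors: the chosen
#' band indices (1-based, sorted by wavelength), their wavelengths, and
#' per-algorithm diagnostics.
#'
#' @param method selector name (`"ca"`, `"scars"`, `"iriv"`, ...).
#' @param indices integer band indices, 1-based.
#' @param wavelengths wavelengths (nm) of the selected bands.
#' @param n_bands_total size of the full band set the selection came from.
#' @param diagnostics method-specific list (correlogram, RMSECV trace,
#'   round history, ...).
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, indices, wavelengths, n_bands_total,
                             diagnostics = list()) {
  o <- order(wavelengths)
  indices <- as.integer(indices)[o]
  wavelengths <- as.numeric(wavelengths)[o]
  if (anyDuplicated(indices)) stop("selected band indices must be unique")
  structure(list(method = method, indices = indices,
                 wavelengths = wavelengths,
                 n_bands_total = as.integer(n_bands_total),
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result:%s> %d / %d bands (%.2f%%)\n",
              x$method, length(x$indices), x$n_bands_total,
              100 * length(x$indices) / x$n_bands_total))
  if (length(x$wavelengths))
    cat("  ", paste(sprintf("%.1f", head(x$wavelengths, 8)), collapse = ", "),
        if (length(x$wavelengths) > 8) "..." else "", "nm\n")
  invisible(x)
}

#' Write a selection result to CSV
#'
#' One row per band of the full grid: band index, wavelength, selected flag,
#' plus any per-band diagnostic columns the selector provides (e.g. rho and
#' p for correlation screening).
#'
#' @param sel a [selection_result()].
#' @param path output CSV path.
#' @param wavelengths optional full wavelength grid; if omitted only the
#'   selected bands are written.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(sel, path, wavelengths = NULL) {
  stopifnot(inherits(sel, "selection_result"))
  if (is.null(wavelengths)) {
    df <- data.frame(band = sel$indices, wavelength = sel$wavelengths,
                     selected = TRUE)
  } else {
    df <- data.frame(band = seq_along(wavelengths),
                     wavelength = wavelengths,
                     selected = seq_along(wavelengths) %in% sel$indices)
    if (!is.null(sel$diagnostics$rho)) df$rho <- sel$diagnostics$rho
    if (!is.null(sel$diagnostics$pvalue)) df$p <- sel$diagnostics$pvalue
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Compare band selections from several methods
#'
#' Computes per-method counts and fractions of the full band set, all
#' pairwise intersections, and the global intersection, by wavelength.
#'
#' @param results named list of two or more [selection_result()]s on the
#'   same wavelength grid (same `n_bands_total`).
#' @return List with `counts`, `fractions` (percent, 2 decimals),
#'   `pairwise` (named list of intersection wavelength vectors),
#'   `common` (wavelengths selected by every method) and `table`
#'   (a per-method summary data frame).
#' @export
compare_selections <- function(results) {
  if (length(results) < 2) stop("need at least two selections to compare")
  stopifnot(all(vapply(results, inherits, logical(1), "selection_result")))
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(results, `[[`, character(1), "method")
  totals <- vapply(results, `[[`, integer(1), "n_bands_total")
  if (length(unique(totals)) != 1)
    stop("selections come from different band grids")
  total <- totals[[1]]
  counts <- vapply(results, function(r) length(r$indices), integer(1))
  fractions <- round(100 * counts / total, 2)
  wls <- lapply(results, `[[`, "wavelengths")
  pair_names <- utils::combn(names(results), 2, paste, collapse = "&")
  pairwise <- utils::combn(names(results), 2, function(nm)
    intersect(wls[[nm[1]]], wls[[nm[2]]]), simplify = FALSE)
  names(pairwise) <- pair_names
  common <- Reduce(intersect, wls)
  list(counts = counts, fractions = fractions, pairwise = pairwise,
       common = common,
       table = data.frame(method = names(results), n_selected = counts,
                          n_total = total, percent = fractions,
                          row.names = NULL))
}

#' Plot the distribution of selected bands per method
#'
#' One horizontal track per method with a tick at every selected
#' wavelength; bands common to all methods are overplotted in blue.
#'
#' @param results named list of [selection_result()]s.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the [compare_selections()] report.
#' @export
plot_selection_overlap <- function(results, ...) {
  rep <- compare_selections(results)
  n <- length(results)
  wl_range <- range(unlist(lapply(results, `[[`, "wavelengths")))
  graphics::plot(NA, xlim = wl_range, ylim = c(0.5, n + 0.5),
                 xlab = "wavelength (nm)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(n), labels = names(rep$counts), las = 1)
  for (i in seq_len(n)) {
    wl <- results[[i]]$wavelengths
    graphics::segments(wl, i - 0.3, wl, i + 0.3, col = "grey30")
    in_common <- wl %in% rep$common
    if (any(in_common))
      graphics::segments(wl[in_common], i - 0.3, wl[in_common], i + 0.3,
                         col = "blue", lwd = 2)
  }
  invisible(rep)
}

#' Read a band list from a plain-text file
#'
#' One wavelength (nm) per line; lines starting with `#` are ignored. Used
#' for entering published band lists as fixtures for overlap analysis.
#'
#' @param path text file path.
#' @param method label for the resulting selection.
#' @param n_bands_total size of the full band grid the list refers to.
#' @return A [selection_result()] (band indices are the rank order of the
#'   listed wavelengths).
#' @export
read_band_list <- function(path, method, n_bands_total) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  wl <- sort(as.numeric(lines))
  if (anyNA(wl)) stop("non-numeric wavelength in ", path)
  selection_result(method, seq_along(wl), wl, n_bands_total)
}
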