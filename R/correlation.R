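#' Spearman correlogram of reflectance against SPAD
#'
#' For every band, Spearman's rho between the band's reflectance and the
#' SPAD values: the product-moment correlation formula applied to
#' rank-transformed data, with average ranks for ties. Two-sided p-values
#' use the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' A band with constant reflectance (or constant SPAD) has undefined rho,
#' reported as `NA` rather than 0.
#'
#' @param ds a [spectral_dataset()] with at least 3 samples.
#' @return An object of class `correlogram`: list with `rho`, `pvalue`,
#'   `wavelengths` and `n`.
#' @export
spearman_correlogram <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$X)
  if (n < 3) stop("need at least 3 samples for a correlogram")
  ry <- rank(ds$y)
  if (sd(ry) == 0) {
    rho <- rep(NA_real_, ncol(ds$X))
  } else {
    rX <- apply(ds$X, 2, rank)
    sds <- apply(rX, 2, sd)
    rho <- suppressWarnings(as.numeric(cor(rX, ry)))
    rho[sds == 0] <- NA_real_
  }
  # guard rounding excursions beyond +-1
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pvalue <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(rho = rho, pvalue = pvalue,
                 wavelengths = ds$wavelengths, n = n),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d bands, n = %d; |rho| range %.3f-%.3f\n",
              length(x$rho), x$n,
              min(abs(x$rho), na.rm = TRUE), max(abs(x$rho), na.rm = TRUE)))
  invisible(x)
}

#' Select bands by correlation screening
#'
#' Keeps every band with `|rho| > rho_threshold` and `p < alpha`. The
#' absolute value is deliberate: strong negative correlations (typical of
#' visible green bands, where more chlorophyll means less reflectance) are
#' as informative as positive ones. No multiple-testing correction is
#' applied; the per-band test at `alpha` is the screening rule itself.
#'
#' @param cg a [spearman_correlogram()].
#' @param rho_threshold absolute-correlation cutoff (default 0.65).
#' @param alpha per-band significance level (default 0.01).
#' @return A [selection_result()] carrying the correlogram as diagnostics.
#' @export
select_by_correlation <- function(cg, rho_threshold = 0.65, alpha = 0.01) {
  stopifnot(inherits(cg, "correlogram"))
  if (rho_threshold < 0 || rho_threshold > 1) stop("rho_threshold must be in [0, 1]")
  keep <- which(!is.na(cg$rho) & abs(cg$rho) > rho_threshold &
                  cg$pvalue < alpha)
  selection_result("ca", keep, cg$wavelengths[keep],
                   n_bands_total = length(cg$rho),
                   diagnostics = list(rho = cg$rho, pvalue = cg$pvalue,
                                      rho_threshold = rho_threshold,
                                      alpha = alpha))
}

#' Correlation screening in one step
#'
#' Convenience wrapper: [spearman_correlogram()] followed by
#' [select_by_correlation()].
#'
#' @inheritParams spearman_correlogram
#' @inheritParams select_by_correlation
#' @return A [selection_result()].
#' @export
run_ca <- function(ds, rho_threshold = 0.65, alpha = 0.01) {
  select_by_correlation(spearman_correlogram(ds), rho_threshold, alpha)
}
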