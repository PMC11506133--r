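#' Scanline flattening of a raw topograph
#'
#' The only preprocessing this pipeline applies, mirroring standard AFM
#' practice: a per-scanline polynomial of the given order is fitted to
#' non-object pixels and subtracted, removing per-line offsets and tilt
#' without touching height differences inside a line. The object mask is
#' refined iteratively: fit, mask pixels more than `mask_threshold_nm` above
#' the fit, refit on the rest. After the final pass the global median of
#' unmasked (substrate) pixels is shifted to 0, which establishes the bare
#' substrate as the height reference for every downstream measurement.
#'
#' @param map a [heightmap()] (raw topograph).
#' @param order polynomial order per scanline: 0 (offset), 1 (offset +
#'   slope, default) or 2.
#' @param iterations mask-refinement iterations (>= 1; default 2).
#' @param mask_threshold_nm residual height above the fit beyond which a
#'   pixel is treated as object during refitting (default 1.0 nm).
#' @return list with `map` (flattened `heightmap`) and `report` (class
#'   `flatten_report`: per-row offsets, mean tilt coefficients, masked
#'   fraction, iterations, rows that fell back to the global fit).
#' @export
flatten <- function(map, order = 1, iterations = 2, mask_threshold_nm = 1.0) {
  stopifnot(inherits(map, "heightmap"), order %in% 0:2, iterations >= 1)
  h0 <- map$heights
  nr <- nrow(h0); nc <- ncol(h0)
  x <- seq_len(nc) - (nc + 1) / 2          # centred column coordinate
  X <- stats::poly(x, degree = max(order, 1), raw = TRUE)
  X <- cbind(1, X[, seq_len(order), drop = FALSE])
  mask <- matrix(FALSE, nr, nc)
  coef_rows <- matrix(0, nr, order + 1)
  fallback_rows <- integer(0)
  resid <- h0
  # each iteration refines the object mask; a final fit then uses the last
  # mask, so even heavily covered scanlines converge onto the substrate
  fit_pass <- function() {
    fallback <- integer(0)
    for (i in seq_len(nr)) {
      use <- !mask[i, ]
      if (sum(use) < 8) { fallback <- c(fallback, i); next }
      fit <- stats::lm.fit(X[use, , drop = FALSE], h0[i, use])
      coef_rows[i, ] <<- fit$coefficients
    }
    if (length(fallback) > 0) {
      good <- setdiff(seq_len(nr), fallback)
      if (length(good) == 0)
        stop("flatten: no scanline has 8 unmasked pixels", call. = FALSE)
      gcoef <- colMeans(coef_rows[good, , drop = FALSE])
      coef_rows[fallback, ] <<- matrix(gcoef, length(fallback),
                                       order + 1, byrow = TRUE)
    }
    fallback
  }
  for (it in seq_len(iterations)) {
    fit_pass()
    resid <- h0 - coef_rows %*% t(X)
    mask <- resid > mask_threshold_nm
  }
  fallback_rows <- fit_pass()
  resid <- h0 - coef_rows %*% t(X)
  med <- stats::median(resid[!mask])
  resid <- resid - med
  report <- structure(
    list(row_offsets_nm = coef_rows[, 1] + med,
         tilt_coefficients = if (order >= 1)
           colMeans(coef_rows[, -1, drop = FALSE]) else numeric(0),
         masked_fraction = mean(mask),
         iterations = iterations,
         order = order,
         fallback_rows = fallback_rows),
    class = "flatten_report")
  list(map = set_heights(map, resid), report = report)
}

#' @export
print.flatten_report <- function(x, ...) {
  cat(sprintf(
    "<flatten_report> order %d, %d iteration(s); %.1f%% pixels masked as objects; %d row(s) used the global fit\n",
    x$order, x$iterations, 100 * x$masked_fraction, length(x$fallback_rows)))
  invisible(x)
}

#' Robust substrate baseline of a flattened map
#'
#' Median height of non-object pixels: the bare-substrate level against
#' which all object heights are reported. Requires at least 5% of pixels to
#' be bare substrate.
#'
#' @param map flattened [heightmap()].
#' @param mask logical matrix marking object pixels (TRUE = object); when
#'   omitted, pixels above 1.0 nm are treated as objects.
#' @return Baseline height (nm).
#' @export
substrate_baseline <- function(map, mask = NULL) {
  stopifnot(inherits(map, "heightmap"))
  if (is.null(mask)) mask <- map$heights > 1.0
  frac_free <- mean(!mask)
  if (frac_free < 0.05)
    stop(sprintf(
      "substrate_baseline: only %.1f%% of pixels are bare substrate (>= 5%% required); use a larger field or lower coverage",
      100 * frac_free), call. = FALSE)
  stats::median(map$heights[!mask])
}
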