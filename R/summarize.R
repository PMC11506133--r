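#' Population statistics for a measurement selection
#'
#' Mean, SD and histogram of one metric over a record selection, as used
#' for per-timepoint population reporting. The SD uses the population
#' denominator n (matching "mean +/- SD" reporting of a measured
#' population, not an inferential estimate). Histograms use fixed bin
#' widths (default 0.5 nm for diameters, 100 nm for lengths) anchored at 0,
#' so bins are comparable across frames and runs.
#'
#' @param values numeric vector of measurements (or a records data.frame,
#'   in which case `metric` selects the column and `class` filters rows).
#' @param metric,class column and class filter when `values` is a
#'   data.frame.
#' @param bin_width_nm histogram bin width; default 0.5 for diameter
#'   metrics, 100 for length metrics.
#' @return A `summary_stats` list: `n`, `mean`, `sd`, `breaks`, `counts`.
#'   An empty selection gives an explicit empty summary (`n = 0`, NA
#'   moments).
#' @export
summarize_population <- function(values, metric = "diameter_nm", class = NULL,
                                 bin_width_nm = NULL) {
  if (is.data.frame(values)) {
    df <- values
    if (!is.null(class)) df <- df[df$class %in% class, , drop = FALSE]
    values <- df[[metric]]
  }
  values <- values[is.finite(values)]
  if (is.null(bin_width_nm))
    bin_width_nm <- if (grepl("length", metric)) 100 else 0.5
  n <- length(values)
  if (n == 0)
    return(structure(list(n = 0L, mean = NA_real_, sd = NA_real_,
                          breaks = numeric(0), counts = integer(0),
                          bin_width_nm = bin_width_nm),
                     class = "summary_stats"))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))          # population denominator
  breaks <- seq(0, (floor(max(values) / bin_width_nm) + 1) * bin_width_nm,
                by = bin_width_nm)
  counts <- as.integer(table(cut(values, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(n = n, mean = m, sd = s, breaks = breaks, counts = counts,
                 bin_width_nm = bin_width_nm), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  if (x$n == 0) cat("<summary_stats> empty selection\n")
  else cat(sprintf("<summary_stats> n = %d, mean = %.3g, SD = %.3g\n",
                   x$n, x$mean, x$sd))
  invisible(x)
}

#' Growth curves of a metric over time
#'
#' Orders per-timepoint summaries into (time, mean, SD, n) tables, one per
#' trial, and computes (never asserts) monotonicity flags. Time comes from
#' frame metadata (`time_min`), never from file names.
#'
#' @param records measurement data.frame with `time_min` and the metric
#'   column; an optional `trial` column keeps independent trials separate.
#' @param metric metric column (e.g. `"length_nm"`, `"diameter_nm"`).
#' @param class optional class filter.
#' @return A `growth_curves` list: per trial a data.frame
#'   `(time_min, mean, sd, n)` sorted by time, plus `increasing` /
#'   `decreasing` flags per trial.
#' @export
growth_curves <- function(records, metric = "length_nm", class = NULL) {
  if (!is.null(class)) records <- records[records$class %in% class, , drop = FALSE]
  if (is.null(records$trial)) records$trial <- "trial1"
  if (nrow(records) == 0) stop("growth_curves: no records", call. = FALSE)
  out <- list()
  for (tr in sort(unique(records$trial))) {
    sub <- records[records$trial == tr, , drop = FALSE]
    # a trial must not contain two distinct frames at the same nominal time
    ft <- unique(sub[, c("frame_id", "time_min")])
    if (anyDuplicated(ft$time_min))
      stop("growth_curves: duplicate time_min within trial ", tr, call. = FALSE)
    by_time <- split(sub, sub$time_min)
    tab <- do.call(rbind, lapply(by_time, function(d) {
      v <- d[[metric]]; v <- v[is.finite(v)]
      data.frame(time_min = d$time_min[1], mean = mean(v),
                 sd = sqrt(mean((v - mean(v))^2)), n = length(v))
    }))
    tab <- tab[order(tab$time_min), , drop = FALSE]
    rownames(tab) <- NULL
    out[[tr]] <- tab
  }
  flags <- lapply(out, function(tab)
    list(increasing = all(diff(tab$mean) > 0) && nrow(tab) >= 2,
         decreasing = all(diff(tab$mean) < 0) && nrow(tab) >= 2))
  structure(list(curves = out, flags = flags, metric = metric),
            class = "growth_curves")
}

#' @export
print.growth_curves <- function(x, ...) {
  cat(sprintf("<growth_curves> %s, %d trial(s)\n", x$metric, length(x$curves)))
  for (tr in names(x$curves)) {
    cat(" ", tr, ":\n"); print(x$curves[[tr]])
  }
  invisible(x)
}
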