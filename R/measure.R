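# Height-based morphometry: everything is measured from heights above the
# local support, never from apparent lateral widths, because heights are
# independent of tip geometry while widths are dilated by it.

#' Decompose a backbone apex profile into baseline, stacked runs and bumps
#'
#' The fibril's own level is the 25th percentile of the apex profile
#' (robust to substantial adsorbate coverage). Contiguous stretches more
#' than `run_delta_nm` above that level and at least `min_run_nm` long are
#' stacked secondary fibril runs, read off a wide (~75 nm) running median
#' in which corrugation valleys are attenuated and discrete particles
#' vanish. With runs masked, adsorbed particles are contiguous regions
#' more than `bump_prominence_nm` above the host's median level and at
#' most `max_bump_width_nm` wide: particle bumps of the populations of
#' interest (>= ~6 nm) stand above even the strongest primary corrugation
#' crests (<= ~4 nm), so a height cut separates cargo from texture where
#' a width cut cannot (bump and corrugation widths overlap).
#'
#' @param apex apex height profile (nm), evenly spaced.
#' @param spacing_nm profile spacing (nm).
#' @param run_delta_nm,min_run_nm stacked-run height offset and minimum
#'   length.
#' @param bump_prominence_nm height above the host median defining a bump.
#' @param max_bump_width_nm widest credible single-particle bump region.
#' @param median_window_nm half the running-median window used for run
#'   detection (nm).
#' @return list: `level_nm`, `runs` (data.frame from/to indices), `bumps`
#'   (table: index, height, prominence, width_nm, left, right),
#'   `run_mask` (TRUE in stacked runs), `mask`
#'   (TRUE where apex belongs to a run or bump).
#' @keywords internal
profile_bumps <- function(apex, spacing_nm, run_delta_nm = 3, min_run_nm = 50,
                          bump_prominence_nm = 5, max_bump_width_nm = 32,
                          median_window_nm = 35) {
  n <- length(apex)
  level <- stats::quantile(apex, 0.25, names = FALSE)
  # running median, padded with the baseline level so features at the
  # profile ends are referenced against the fibril's own level rather than
  # against themselves
  pad_runmed <- function(win_nm) {
    k <- max(3L, round(win_nm / spacing_nm))
    if (k %% 2L == 0L) k <- k + 1L
    padded <- c(rep(level, k), apex, rep(level, k))
    as.numeric(stats::runmed(padded, k))[(k + 1):(k + n)]
  }
  # stacked runs are read off a wide (~1.5 corrugation wavelengths) running
  # median, where corrugation valleys are strongly attenuated and discrete
  # particles vanish entirely; short residual gaps are bridged
  base_run <- pad_runmed(2 * median_window_nm + 5)
  high <- base_run > level + run_delta_nm
  r0 <- rle(high)
  gap <- !r0$values & r0$lengths * spacing_nm <= 12
  if (length(gap) > 0) gap[c(1, length(gap))] <- FALSE
  r0$values[gap] <- TRUE
  high <- inverse.rle(r0)
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths * spacing_nm >= min_run_nm)
  # a genuine stacked fibril keeps the raw apex elevated over most of its
  # span (median well above the host level); a bridged cluster of discrete
  # particles does not
  if (length(long) > 0) {
    solid <- vapply(long, function(k) {
      span <- starts[k]:ends[k]
      stats::median(apex[span]) > level + run_delta_nm + 1.5
    }, TRUE)
    long <- long[solid]
  }
  # "runs" covering most of the trace are not stacked cargo but the
  # fibril's own (strongly skewed) texture
  if (length(long) > 0 &&
      sum(r$lengths[long]) > 0.6 * n) long <- integer(0)
  runs <- if (length(long) > 0)
    data.frame(from = starts[long], to = ends[long]) else
    data.frame(from = integer(0), to = integer(0))
  # guard band: the rising cap slopes of a stacked run extend a few nm
  # beyond the detected span and must not leak into roughness windows
  guard <- round(8 / spacing_nm)
  run_mask <- rep(FALSE, n)
  for (k in seq_len(nrow(runs)))
    run_mask[max(1L, runs$from[k] - guard):min(n, runs$to[k] + guard)] <- TRUE
  # particle bumps: contiguous regions standing more than
  # bump_prominence_nm above the host's median level (runs excluded).
  # Height separates cargo (>= ~6 nm above the host) from even the
  # strongest primary corrugation crests (<= ~4 nm) where a width cut
  # cannot, because bump and corrugation widths overlap.
  med_host <- stats::median(apex[!run_mask])
  hot <- apex > med_host + bump_prominence_nm & !run_mask
  rb <- rle(hot)
  bends <- cumsum(rb$lengths)
  bstarts <- bends - rb$lengths + 1L
  rows <- list()
  mask <- run_mask
  for (k in which(rb$values)) {
    wid <- rb$lengths[k] * spacing_nm
    if (wid > max_bump_width_nm) next
    span <- bstarts[k]:bends[k]
    p <- span[which.max(apex[span])]
    rows[[length(rows) + 1L]] <- data.frame(
      index = p, height = apex[p], prominence = apex[p] - med_host,
      width_nm = wid, left = bstarts[k], right = bends[k])
    # mask the sub-threshold flanks too (cap slopes plus tip broadening
    # extend ~8 nm beyond the height-cut crossing) so they cannot bias
    # support estimates or roughness windows
    bg <- round(8 / spacing_nm)
    mask[max(1L, bstarts[k] - bg):min(n, bends[k] + bg)] <- TRUE
  }
  peaks <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(index = integer(0), height = numeric(0),
               prominence = numeric(0), width_nm = numeric(0),
               left = integer(0), right = integer(0))
  list(level_nm = level, runs = runs, bumps = peaks, run_mask = run_mask,
       mask = mask)
}

#' Fibril diameter from apex heights
#'
#' The diameter of a surface-lying cylindrical fibril equals its apex
#' height above its support ("height equals diameter"). The estimator is
#' the trimmed mean (central 80%) of the per-point apex heights minus the
#' support, robust to adsorbed oligomers and to the hemispherical end caps.
#'
#' @param trace a `fibril_trace` (or any list with `apex_nm`).
#' @param support_nm support level beneath the fibril: the substrate
#'   baseline (default 0) or the host fibril apex for stacked fibrils.
#' @param exclude optional logical mask of apex samples to ignore (e.g.
#'   adsorbate bumps from [profile_bumps()]).
#' @return list: `diameter_nm`, `n_sections`, `low_confidence` (fewer than
#'   10 usable sections).
#' @export
fibril_diameter <- function(trace, support_nm = 0, exclude = NULL) {
  apex <- trace$apex_nm
  if (!is.null(exclude)) apex <- apex[!exclude]
  apex <- apex[is.finite(apex)]
  list(diameter_nm = mean(apex, trim = 0.1) - support_nm,
       n_sections = length(apex),
       low_confidence = length(apex) < 10)
}

#' Measure a particle by multi-section height profiling
#'
#' Takes `n_sections` cross-sections through the particle centre at equally
#' spaced orientations, refines each section's maximum by a quadratic fit,
#' and averages: the mean apex height minus the support height is the
#' particle diameter ("height equals diameter in a sphere").
#'
#' @param center_xy particle centre (nm), e.g. the height-weighted centroid
#'   of its component or the apex of its bump.
#' @param map flattened [heightmap()].
#' @param support_nm support height (0 on the substrate, host fibril apex
#'   for adsorbed particles).
#' @param n_sections number of sections (3--5, default 5).
#' @param halfwidth_nm section half-length (nm).
#' @return list: `centroid`, `mean_apex_nm`, `diameter_nm`, `support_nm`,
#'   `n_sections`, `section_apex_nm`.
#' @export
measure_particle <- function(center_xy, map, support_nm = 0, n_sections = 5,
                             halfwidth_nm = 12) {
  stopifnot(inherits(map, "heightmap"), n_sections >= 3, n_sections <= 5)
  px <- map$pixel_size_nm
  # first re-centre onto the particle apex (two orthogonal ridge
  # refinements): a section line missing the apex laterally by b
  # underestimates the height by ~b^2/d
  for (ang in c(0, pi / 2, 0, pi / 2)) {
    rf <- refine_ridge_point(map$heights, px, center_xy,
                             c(cos(ang), sin(ang)), halfwidth_nm / 2,
                             interp = "bicubic")
    if (!is.null(rf)) center_xy <- rf$pt
  }
  apexes <- numeric(n_sections)
  for (k in seq_len(n_sections)) {
    ang <- (k - 1) * pi / n_sections
    rf <- refine_ridge_point(map$heights, px, center_xy,
                             c(cos(ang), sin(ang)), halfwidth_nm,
                             interp = "bicubic")
    apexes[k] <- if (is.null(rf)) NA_real_ else rf$apex
  }
  mean_apex <- mean(apexes, na.rm = TRUE)
  list(centroid = center_xy, mean_apex_nm = mean_apex,
       diameter_nm = mean_apex - support_nm, support_nm = support_nm,
       n_sections = sum(is.finite(apexes)), section_apex_nm = apexes)
}

#' Resolve the host fibril of an object and its local support height
#'
#' The host is the trace whose backbone is nearest to the object's centre.
#' Ambiguity (two backbones within `tie_nm` of each other in distance) is
#' broken deterministically toward the lower id and flagged. The support is
#' the median apex height of the host within a +/- `window_nm` arc window
#' around the contact point, excluding samples masked as adsorbate bumps.
#'
#' @param center_xy object centre (nm).
#' @param traces named list of `fibril_trace` objects.
#' @param max_dist_nm objects farther than this from every backbone have no
#'   host (`host_id = NA`, support 0: substrate level).
#' @param window_nm arc half-window for the support median (default 30 nm).
#' @param masks optional named list of logical bump masks per trace.
#' @param tie_nm distance difference regarded as a tie.
#' @return list: `host_id`, `support_nm`, `arc_nm` (contact arc position),
#'   `dist_nm`, `tie_flag`.
#' @export
resolve_host <- function(center_xy, traces, max_dist_nm = Inf, window_nm = 30,
                         masks = NULL, tie_nm = 0.5) {
  if (length(traces) == 0)
    return(list(host_id = NA_character_, support_nm = 0, arc_nm = NA_real_,
                dist_nm = Inf, tie_flag = FALSE))
  ids <- names(traces)
  dists <- rep(Inf, length(traces)); arcs <- rep(NA_real_, length(traces))
  for (k in seq_along(traces)) {
    bb <- traces[[k]]$backbone
    d2 <- (bb[, 1] - center_xy[1])^2 + (bb[, 2] - center_xy[2])^2
    i <- which.min(d2)
    dists[k] <- sqrt(d2[i])
    arcs[k] <- (i - 1) * traces[[k]]$spacing_nm
  }
  ord <- order(dists, ids)
  best <- ord[1]
  tie_flag <- length(ord) > 1 && (dists[ord[2]] - dists[ord[1]]) < tie_nm
  if (tie_flag) {
    cand <- ord[dists[ord] - dists[ord[1]] < tie_nm]
    best <- cand[order(ids[cand])][1]
  }
  if (dists[best] > max_dist_nm)
    return(list(host_id = NA_character_, support_nm = 0, arc_nm = NA_real_,
                dist_nm = dists[best], tie_flag = FALSE))
  tr <- traces[[best]]
  s <- (seq_along(tr$apex_nm) - 1) * tr$spacing_nm
  win <- abs(s - arcs[best]) <= window_nm
  if (!is.null(masks) && !is.null(masks[[ids[best]]]))
    win <- win & !masks[[ids[best]]]
  support <- if (any(win)) stats::median(tr$apex_nm[win]) else
    stats::median(tr$apex_nm)
  list(host_id = ids[best], support_nm = support, arc_nm = arcs[best],
       dist_nm = dists[best], tie_flag = tie_flag)
}

#' Support height beneath a stacked object
#'
#' Convenience wrapper around [resolve_host()] implementing the
#' stacked-object height subtraction: the primary fibril's height is
#' subtracted from the total measured height to yield the height of the
#' object riding on it. Substrate objects get support 0.
#'
#' @inheritParams resolve_host
#' @return `support_nm` (0 when no host is within `max_dist_nm`).
#' @export
subtract_support <- function(center_xy, traces, max_dist_nm = Inf,
                             window_nm = 30, masks = NULL) {
  resolve_host(center_xy, traces, max_dist_nm, window_nm, masks)$support_nm
}
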