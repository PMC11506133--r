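#' Classify the adsorption site of a particle
#'
#' A particle is on the substrate when its centre is farther than `eps_on`
#' from every backbone; otherwise it sits on a fibril: at the fibril
#' *edge* when its arc distance to the nearest backbone endpoint is at most
#' `eps_edge_nm`, on the *backbone* elsewhere. The default on-fibril gate
#' is the host half-width plus the particle radius plus one pixel; the
#' 20 nm edge window is the lower end of the observed 20--100 nm spacing of
#' adsorbed oligomers.
#'
#' @param center_xy particle centre (nm).
#' @param traces named list of `fibril_trace` objects.
#' @param particle_radius_nm particle radius (nm), for the default gate.
#' @param pixel_size_nm pixel size (nm), for the default gate.
#' @param eps_on_nm on-fibril distance gate; `NULL` for the default.
#' @param eps_edge_nm edge window along the backbone (default 20 nm).
#' @return list: `site` in `{edge, backbone, substrate}`, `host_id`,
#'   `arc_to_end_nm`.
#' @export
classify_site <- function(center_xy, traces, particle_radius_nm = 4,
                          pixel_size_nm = 2, eps_on_nm = NULL,
                          eps_edge_nm = 20) {
  res <- resolve_host(center_xy, traces)
  if (is.na(res$host_id))
    return(list(site = "substrate", host_id = NA_character_,
                arc_to_end_nm = NA_real_))
  tr <- traces[[res$host_id]]
  if (is.null(eps_on_nm)) {
    half_width <- stats::median(tr$apex_nm) / 2  # height = diameter
    eps_on_nm <- half_width + particle_radius_nm + pixel_size_nm
  }
  if (res$dist_nm > eps_on_nm)
    return(list(site = "substrate", host_id = NA_character_,
                arc_to_end_nm = NA_real_))
  # the stored backbone is already cropped to the true fibril extent, so
  # arc distance to an endpoint is read off directly
  L <- (length(tr$apex_nm) - 1) * tr$spacing_nm
  arc_end <- min(res$arc_nm, L - res$arc_nm)
  site <- if (arc_end <= eps_edge_nm) "edge" else "backbone"
  list(site = site, host_id = res$host_id, arc_to_end_nm = arc_end)
}

#' Backbone RMS roughness (Rq) of a fibril
#'
#' The apex-height profile along the backbone is split into windows
#' (default 100 nm), each window is linearly detrended, and Rq is the mean
#' of the per-window RMS residuals. Detrending removes backbone height
#' drift so corrugation, not bending or tilt, is measured. Samples flagged
#' as adsorbate bumps can be excluded so that cargo does not masquerade as
#' surface texture.
#'
#' @param trace a `fibril_trace` (>= 20 apex samples recommended; shorter
#'   traces fall back to a single flagged window).
#' @param window_nm window length (default 100 nm).
#' @param detrend detrend mode per window (see [windowed_rq()]).
#' @param exclude optional logical mask of apex samples to drop before
#'   windowing.
#' @param side `"both"` (ordinary Rq) or `"lower"` (lower-sided Rq, immune
#'   to one-sided cargo; see [windowed_rq()]).
#' @return A `roughness_record`: `rq_nm`, `window_rq_nm`, `n_windows`,
#'   `short_flag`, `detrend`.
#' @export
rq_roughness <- function(trace, window_nm = 100, detrend = "linear",
                         exclude = NULL, side = "both") {
  apex <- trace$apex_nm
  spacing <- trace$spacing_nm
  keep <- is.finite(apex) & if (is.null(exclude)) TRUE else !exclude
  # window each contiguous unmasked stretch separately: splicing across a
  # removed stacked run would create artificial steps inside a window
  segs <- rle(keep)
  hi <- cumsum(segs$lengths)
  lo <- hi - segs$lengths + 1L
  win_rqs <- numeric(0)
  min_pts <- max(8L, round(0.4 * window_nm / spacing))
  for (k in which(segs$values)) {
    if (segs$lengths[k] < min_pts) next
    wr <- windowed_rq(apex[lo[k]:hi[k]], spacing, window_nm, detrend, side)
    win_rqs <- c(win_rqs, wr$window_rq_nm)
  }
  short <- FALSE
  if (length(win_rqs) == 0) {   # nothing long enough: pool what there is
    wr <- windowed_rq(apex[keep], spacing, window_nm, detrend, side)
    win_rqs <- wr$window_rq_nm
    short <- TRUE
  }
  structure(list(rq_nm = mean(win_rqs), window_rq_nm = win_rqs,
                 n_windows = length(win_rqs),
                 short_flag = short || sum(keep) * spacing < window_nm,
                 detrend = detrend), class = "roughness_record")
}

#' Classify fibril generation from surface roughness
#'
#' Primary fibrils show backbone Rq of roughly 0.4--2.2 nm; secondary
#' fibrils, grown catalytically on fibril surfaces, show roughly
#' 2.5--8.5 nm. The default threshold 2.35 nm is the midpoint of the gap
#' between those ranges; the boundary itself classifies as secondary.
#'
#' @param rq_nm roughness value or a `roughness_record`.
#' @param threshold_nm decision threshold (default 2.35 nm).
#' @return `"primary"` or `"secondary"` (vectorised over `rq_nm`).
#' @export
classify_generation <- function(rq_nm, threshold_nm = 2.35) {
  if (inherits(rq_nm, "roughness_record")) rq_nm <- rq_nm$rq_nm
  ifelse(rq_nm >= threshold_nm, "secondary", "primary")
}

#' Classify catalytic activity of primary fibrils
#'
#' For each primary fibril, lambda is the number of adsorbed secondary
#' objects (oligomers plus stacked secondary fibrils) per micrometre of
#' backbone. A fibril with no cargo is dormant. Among non-dormant fibrils
#' of a frame, one whose lambda is at least `factor` times the frame median
#' is a superspreader (the rule is inert in frames with fewer than 3
#' non-dormant fibrils); the rest are active.
#'
#' @param counts named integer vector: adsorbed object count per primary
#'   fibril id.
#' @param lengths_nm named numeric vector: backbone length per fibril id.
#' @param factor superspreader multiplier on the median lambda (default 3).
#' @return data.frame: `id`, `count`, `length_nm`, `lambda_per_um`,
#'   `activity` in `{dormant, active, superspreader}`; row order follows
#'   `sort(names(lengths_nm))`, independent of input order.
#' @export
classify_activity <- function(counts, lengths_nm, factor = 3) {
  ids <- sort(names(lengths_nm))
  cnt <- ifelse(is.na(counts[ids]), 0L, counts[ids])
  len <- lengths_nm[ids]
  lambda <- cnt / (len / 1000)
  activity <- rep("active", length(ids))
  activity[cnt == 0] <- "dormant"
  nd <- which(cnt > 0)
  if (length(nd) >= 3) {
    med <- stats::median(lambda[nd])
    activity[nd][lambda[nd] >= factor * med & lambda[nd] > med] <- "superspreader"
  }
  data.frame(id = ids, count = as.integer(cnt), length_nm = unname(len),
             lambda_per_um = unname(lambda), activity = activity,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-frame adsorption-site distribution
#'
#' Counts and normalized fractions of particle sites. Fractions are
#' reported both over all classes and over the on-fibril classes alone
#' (edge vs backbone); with zero on-fibril particles the on-fibril
#' fractions are absent (`NULL`), not 0/0. The normalization area is
#' recorded as metadata and never rescales counts.
#'
#' @param sites character vector of per-particle sites.
#' @param frame_id,time_min frame metadata.
#' @param norm_area_nm2 normalization area recorded with the distribution.
#' @return A `site_distribution`: `counts`, `fractions`,
#'   `on_fibril_fractions` (or NULL), `frame_id`, `time_min`,
#'   `norm_area_nm2`.
#' @export
site_distribution <- function(sites, frame_id = "frame", time_min = NA_real_,
                              norm_area_nm2 = 500) {
  classes <- c("edge", "backbone", "substrate")
  counts <- vapply(classes, function(cl) sum(sites == cl), 0L)
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else
    stats::setNames(rep(NA_real_, 3), classes)
  on_total <- counts[["edge"]] + counts[["backbone"]]
  on_frac <- if (on_total > 0)
    c(edge = counts[["edge"]] / on_total,
      backbone = counts[["backbone"]] / on_total) else NULL
  structure(list(counts = counts, fractions = fractions,
                 on_fibril_fractions = on_frac, frame_id = frame_id,
                 time_min = time_min, norm_area_nm2 = norm_area_nm2),
            class = "site_distribution")
}

#' @export
print.site_distribution <- function(x, ...) {
  cat(sprintf("<site_distribution> %s: edge %d, backbone %d, substrate %d",
              x$frame_id, x$counts[["edge"]], x$counts[["backbone"]],
              x$counts[["substrate"]]))
  if (!is.null(x$on_fibril_fractions))
    cat(sprintf(" (on-fibril: %.0f%% edge / %.0f%% backbone)",
                100 * x$on_fibril_fractions[["edge"]],
                100 * x$on_fibril_fractions[["backbone"]]))
  cat("\n")
  invisible(x)
}
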