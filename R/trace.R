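# Sub-pixel fibril backbone tracing.
#
# A fibril component is thinned to a skeleton, the skeleton's longest path
# becomes the initial backbone, and every backbone point is refined to the
# ridge apex by a quadratic fit to the perpendicular height profile. Ends
# are then extended along the ridge to the half-maximum contour and the
# arc length is corrected by one fibril radius per end (a swept-sphere
# ridge reaches half its apex height exactly one radius beyond the true
# backbone endpoint), making length nearly independent of the threshold
# and of tip broadening.

runmean <- function(v, k) {
  if (k <= 1 || length(v) < 3) return(v)
  n <- length(v)
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# parabola through (-1,y1),(0,y2),(1,y3): returns c(delta, peak value)
quad_peak <- function(y1, y2, y3) {
  den <- y1 - 2 * y2 + y3
  if (!is.finite(den) || den >= 0) return(c(0, y2))
  delta <- 0.5 * (y1 - y3) / den
  delta <- max(-1, min(1, delta))
  c(delta, y2 - 0.25 * (y1 - y3) * delta)
}

# refine a point to the ridge apex along the normal direction; returns
# list(pt, apex) or NULL when the profile leaves the grid
refine_ridge_point <- function(heights, px, pt, normal, halfwidth_nm = 8,
                               step_nm = NULL, interp = "bilinear") {
  if (is.null(step_nm)) step_nm <- px / 2
  off <- seq(-halfwidth_nm, halfwidth_nm, by = step_nm)
  xs <- pt[1] + off * normal[1]
  ys <- pt[2] + off * normal[2]
  prof <- if (interp == "bicubic") bicubic_cpp(heights, px, xs, ys) else
    bilinear_cpp(heights, px, xs, ys)
  if (all(is.na(prof))) return(NULL)
  i <- which.max(prof)
  if (is.na(prof[i])) return(NULL)
  if (i == 1 || i == length(prof) || is.na(prof[i - 1]) || is.na(prof[i + 1])) {
    return(list(pt = c(xs[i], ys[i]), apex = prof[i]))
  }
  qp <- quad_peak(prof[i - 1], prof[i], prof[i + 1])
  d <- off[i] + qp[1] * step_nm
  list(pt = c(pt[1] + d * normal[1], pt[2] + d * normal[2]), apex = qp[2])
}

path_normals <- function(pts) {
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                if (n > 2) pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
                pts[n, ] - pts[n - 1, ])
  len <- sqrt(rowSums(tang^2))
  tang <- tang / pmax(len, 1e-9)
  cbind(-tang[, 2], tang[, 1])
}

# longest path through an 8-connected skeleton (graph diameter heuristic:
# exact for trees, which pruned skeletons effectively are)
skeleton_longest_path <- function(sk_ij) {
  n <- nrow(sk_ij)
  if (n < 2) return(sk_ij)
  edges <- NULL; weights <- NULL
  key <- paste(sk_ij[, 1], sk_ij[, 2])
  idx <- seq_len(n)
  lookup <- stats::setNames(idx, key)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb <- lookup[paste(sk_ij[, 1] + d[1], sk_ij[, 2] + d[2])]
    hit <- which(!is.na(nb))
    if (length(hit) > 0) {
      edges <- rbind(edges, cbind(hit, nb[hit]))
      weights <- c(weights, rep(sqrt(sum(d^2)), length(hit)))
    }
  }
  if (is.null(edges)) return(sk_ij[1, , drop = FALSE])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vmain <- which(comp$membership == main)
  d0 <- igraph::distances(g, v = vmain[1])[1, ]
  a <- vmain[which.max(d0[vmain])]
  da <- igraph::distances(g, v = a)[1, ]
  b <- vmain[which.max(da[vmain])]
  path <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1]]
  sk_ij[as.integer(path), , drop = FALSE]
}

#' Trace the sub-pixel backbone of a fibril component
#'
#' @param labels integer label matrix from [segment_objects()].
#' @param label the component to trace.
#' @param map the flattened [heightmap()].
#' @param min_length_nm components whose traced backbone is shorter than
#'   this are demoted to particles (`demoted = TRUE` in the result).
#' @param halfwidth_nm half-width of the perpendicular search profile.
#' @param stop_frac end extension follows the ridge until the apex falls
#'   below this fraction of the trace's median apex height.
#' @return A `fibril_trace`: `backbone` (n x 2 nm, evenly spaced),
#'   `apex_nm` (per-point ridge apex height), `spacing_nm`, `length_nm`
#'   (end-corrected arc length), `endpoints`, `demoted`, `low_confidence`.
#' @export
trace_backbone <- function(labels, label, map, min_length_nm = 50,
                           halfwidth_nm = 8, stop_frac = 0.5) {
  stopifnot(inherits(map, "heightmap"))
  px <- map$pixel_size_nm
  h <- map$heights
  idx <- which(labels == label)
  nr <- nrow(h)
  ij <- arrayInd(idx, dim(h))
  r0 <- min(ij[, 1]); r1 <- max(ij[, 1]); c0 <- min(ij[, 2]); c1 <- max(ij[, 2])
  sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(ij[, 1] - r0 + 1L, ij[, 2] - c0 + 1L)] <- TRUE
  skel <- thin_mask_cpp(sub)
  sk <- which(skel, arr.ind = TRUE)
  path <- skeleton_longest_path(sk)
  # pixel (row, col) -> physical (x, y): x = (col-1)*px, y = (row-1)*px
  pts <- cbind((path[, 2] + c0 - 2) * px, (path[, 1] + r0 - 2) * px)
  if (nrow(pts) < 3)
    return(structure(list(demoted = TRUE, length_nm = 0), class = "fibril_trace"))

  # two refinement passes with smoothing in between
  for (pass in 1:2) {
    pts[, 1] <- runmean(pts[, 1], 5)
    pts[, 2] <- runmean(pts[, 2], 5)
    s <- arc_lengths(pts)
    if (max(s) < 2 * px)
      return(structure(list(demoted = TRUE, length_nm = max(s)), class = "fibril_trace"))
    even <- seq(0, max(s), by = px)
    pts <- arc_interp(pts, even)
    nrm <- path_normals(pts)
    apex <- numeric(nrow(pts))
    for (k in seq_len(nrow(pts))) {
      rf <- refine_ridge_point(h, px, pts[k, ], nrm[k, ], halfwidth_nm)
      if (!is.null(rf)) { pts[k, ] <- rf$pt; apex[k] <- rf$apex }
      else apex[k] <- NA_real_
    }
    keep <- !is.na(apex)
    pts <- pts[keep, , drop = FALSE]; apex <- apex[keep]
    if (nrow(pts) < 3)
      return(structure(list(demoted = TRUE, length_nm = 0), class = "fibril_trace"))
  }

  ref_apex <- stats::median(apex)
  extend_end <- function(pts, apex, from_start) {
    if (from_start) { pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]; apex <- rev(apex) }
    n <- nrow(pts)
    dir <- pts[n, ] - pts[max(1, n - 3), ]
    dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
    pos <- pts[n, ]
    add_pts <- NULL; add_apex <- NULL
    for (step in seq_len(400)) {
      cand <- pos + dir * (px / 2)
      nrm <- c(-dir[2], dir[1])
      rf <- refine_ridge_point(h, px, cand, nrm, halfwidth_nm)
      if (is.null(rf) || rf$apex < stop_frac * ref_apex) break
      if (sqrt(sum((rf$pt - pos)^2)) > 2 * px) break  # ridge lost sideways
      newdir <- rf$pt - pos
      nlen <- sqrt(sum(newdir^2))
      if (nlen > 1e-9) dir <- 0.7 * dir + 0.3 * newdir / nlen
      dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
      pos <- rf$pt
      add_pts <- rbind(add_pts, rf$pt); add_apex <- c(add_apex, rf$apex)
    }
    if (from_start) {
      list(pts = rbind(add_pts[rev(seq_len(NROW(add_pts))), , drop = FALSE],
                       pts[rev(seq_len(nrow(pts))), , drop = FALSE]),
           apex = c(rev(add_apex), rev(apex)))
    } else {
      list(pts = rbind(pts, add_pts), apex = c(apex, add_apex))
    }
  }
  e1 <- extend_end(pts, apex, from_start = FALSE)
  e2 <- extend_end(e1$pts, e1$apex, from_start = TRUE)
  pts <- e2$pts; apex <- e2$apex

  # heavier final smoothing: residual lateral jitter of the refined points
  # inflates arc length quadratically, while backbone curvature at the
  # persistence lengths of these fibrils is negligible over ~20 nm
  pts[, 1] <- runmean(pts[, 1], 9)
  pts[, 2] <- runmean(pts[, 2], 9)

  # even resampling of backbone and apex profile
  s <- arc_lengths(pts)
  even <- seq(0, max(s), by = px)
  apex_even <- stats::approx(s, apex, xout = even)$y
  pts_even <- arc_interp(pts, even)

  # the traced half-maximum contour overshoots the true backbone by one
  # fibril radius per end (hemispherical end caps); crop the cap regions so
  # the stored backbone, apex profile and endpoints all refer to the true
  # backbone extent
  r_hat <- max(stats::median(apex_even) / 2, 0)
  length_nm <- max(s) - 2 * r_hat
  demoted <- length_nm < min_length_nm
  n_e <- length(apex_even)
  lvl <- 0.8 * stats::quantile(apex_even, 0.25, names = FALSE)
  k_min <- round(r_hat / px)                  # at least the end-cap radius
  k_max <- min(round((r_hat + 8) / px), (n_e - 5) %/% 2)
  crop_lo <- 0; while (crop_lo < k_max && apex_even[crop_lo + 1] < lvl)
    crop_lo <- crop_lo + 1
  crop_hi <- 0; while (crop_hi < k_max && apex_even[n_e - crop_hi] < lvl)
    crop_hi <- crop_hi + 1
  crop_lo <- min(max(crop_lo, k_min), k_max)
  crop_hi <- min(max(crop_hi, k_min), k_max)
  if (crop_lo + crop_hi > 0) {
    keep <- (crop_lo + 1):(n_e - crop_hi)
    apex_even <- apex_even[keep]
    pts_even <- pts_even[keep, , drop = FALSE]
  }
  structure(list(
    backbone = pts_even, apex_nm = apex_even, spacing_nm = px,
    length_nm = length_nm,
    endpoints = pts_even[c(1, nrow(pts_even)), , drop = FALSE],
    demoted = demoted,
    low_confidence = length(apex_even) < 10), class = "fibril_trace")
}

#' @export
print.fibril_trace <- function(x, ...) {
  if (isTRUE(x$demoted)) {
    cat("<fibril_trace> demoted to particle (too short)\n")
  } else {
    cat(sprintf("<fibril_trace> length %.0f nm, %d backbone points, median apex %.2f nm\n",
                x$length_nm, nrow(x$backbone), stats::median(x$apex_nm)))
  }
  invisible(x)
}
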