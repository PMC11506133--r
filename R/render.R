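# Scene rendering: ground-truth geometry -> ideal (pre-tip) surface.
#
# Geometry conventions ("height equals diameter"): a fibril of diameter d is
# the visible upper envelope of a cylinder of radius d/2 lying on its
# support, i.e. a ridge of apex height d and footprint width d; an oligomer
# of diameter d is the upper envelope of a sphere resting on its support
# (apex d, footprint radius d/2). Overlapping objects compose by upper
# envelope (pointwise max). Secondary fibrils carry a longitudinal
# corrugation c(s) that modulates the local diameter; c is calibrated so
# the realized windowed detrended Rq of the apex profile equals the
# configured target exactly.

# ---- polyline helpers -------------------------------------------------------

arc_lengths <- function(poly) {
  if (nrow(poly) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
}

# resample a polyline at arc positions s (nm)
arc_interp <- function(poly, s) {
  cs <- arc_lengths(poly)
  x <- stats::approx(cs, poly[, 1], xout = pmin(pmax(s, 0), max(cs)))$y
  y <- stats::approx(cs, poly[, 2], xout = pmin(pmax(s, 0), max(cs)))$y
  cbind(x, y)
}

# minimum distance between two point sets, with bbox short-circuit
pointset_min_dist <- function(a, b, cutoff) {
  if (min(a[, 1]) > max(b[, 1]) + cutoff || min(b[, 1]) > max(a[, 1]) + cutoff ||
      min(a[, 2]) > max(b[, 2]) + cutoff || min(b[, 2]) > max(a[, 2]) + cutoff)
    return(Inf)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}

# smoothed random-walk backbone of arc length L inside [margin, field-margin]
gen_backbone <- function(L, persistence, field_nm, margin, ds = 4) {
  n <- max(3L, ceiling(L / ds))
  start <- stats::runif(2, margin, field_nm - margin)
  theta <- stats::runif(1, 0, 2 * pi)
  dtheta <- stats::rnorm(n - 1, 0, sqrt(ds / persistence))
  angles <- theta + cumsum(c(0, dtheta))[seq_len(n - 1)]
  pts <- matrix(0, n, 2)
  pts[1, ] <- start
  steps <- cbind(cos(angles), sin(angles)) * ds
  pts[-1, ] <- cbind(start[1] + cumsum(steps[, 1]),
                     start[2] + cumsum(steps[, 2]))
  if (any(pts < margin) || any(pts[, 1] > field_nm[1] - margin) ||
      any(pts[, 2] > field_nm[2] - margin))
    return(NULL)
  pts
}

# ---- corrugation ------------------------------------------------------------

smooth_vec <- function(z, k) {
  if (k <= 1) return(z)
  kern <- stats::dnorm(seq(-2, 2, length.out = 2 * k + 1))
  kern <- kern / sum(kern)
  n <- length(z)
  zp <- c(rev(z[seq_len(k)]), z, rev(z[n - seq_len(k) + 1L]))
  as.numeric(stats::filter(zp, kern, sides = 2))[(k + 1):(k + n)]
}

# corrugation offsets c(s) on a dense arc grid, calibrated so the realized
# windowed detrended Rq of (d + c) equals rq_target; local diameter is
# clamped at >= 3 nm so corrugation valleys never sever the segmentation
# mask. Upward excursions are unbounded, so calibration by scaling always
# reaches the target (bisection on the scale).
gen_corrugation <- function(n, spacing_nm, wavelength_nm, rq_target, diameter_nm,
                            noise_frac = 0.2, window_nm = 100) {
  if (rq_target <= 0 || n < 8) return(numeric(n))
  s <- (seq_len(n) - 1) * spacing_nm
  phase <- stats::runif(1, 0, 2 * pi)
  base <- sin(2 * pi * s / wavelength_nm + phase)
  noise <- smooth_vec(stats::rnorm(n), max(2L, round(wavelength_nm / 4 / spacing_nm)))
  noise <- noise / max(stats::sd(noise), 1e-9)
  base <- base + noise_frac * noise
  clamp <- -(diameter_nm - 3)
  # scale, re-centre (clamping lifts the mean), then clamp again: the local
  # diameter must never drop below 3 nm or the segmentation mask severs.
  # For heavy targets the result is necessarily upward-skewed ("beaded").
  shape <- function(k) {
    v <- pmax(k * base, clamp)
    pmax(v - mean(v), clamp)
  }
  realized <- function(k) windowed_rq(shape(k), spacing_nm, window_nm)$rq_nm
  k_lo <- 0; k_hi <- rq_target * sqrt(2) * 2
  while (realized(k_hi) < rq_target) k_hi <- k_hi * 2
  for (i in 1:50) {
    k <- (k_lo + k_hi) / 2
    if (realized(k) < rq_target) k_lo <- k else k_hi <- k
  }
  shape((k_lo + k_hi) / 2)
}

# ---- low-level rasterizer ---------------------------------------------------

#' Render explicit objects to an ideal height map
#'
#' Low-level rasterizer behind [render_scene()], exposed so tests and users
#' can render exact geometry (e.g. an axis-aligned ridge or a quarter-circle
#' arc). Each fibril is a swept sphere along its backbone; each oligomer a
#' single sphere; everything composes by pointwise max.
#'
#' @param field_nm field size `c(width, height)` in nm (scalar recycled).
#' @param pixel_size_nm grid pitch (nm/px).
#' @param fibrils list of `list(poly = <n x 2 nm coords>, diameter_nm =,
#'   corrugation = <optional per-sample diameter offsets>, support_nm =
#'   <scalar or per-sample>)`.
#' @param oligomers list of `list(x =, y =, diameter_nm =, support_nm = 0)`.
#' @param frame_id,time_min metadata for the output map.
#' @return A [heightmap()] of the ideal (pre-tip, noise-free) surface.
#' @export
render_objects <- function(field_nm, pixel_size_nm, fibrils = list(),
                           oligomers = list(), frame_id = "render",
                           time_min = NA_real_) {
  if (length(field_nm) == 1) field_nm <- c(field_nm, field_nm)
  nc <- max(16L, floor(field_nm[1] / pixel_size_nm) + 1L)
  nr <- max(16L, floor(field_nm[2] / pixel_size_nm) + 1L)
  grid <- matrix(0, nr, nc)
  ds <- min(1, pixel_size_nm / 2)
  for (f in fibrils) {
    L <- max(arc_lengths(f$poly))
    s <- seq(0, L, by = ds)
    pts <- arc_interp(f$poly, s)
    corr <- if (is.null(f$corrugation)) numeric(length(s)) else {
      if (length(f$corrugation) == length(s)) f$corrugation
      else stats::approx(seq(0, L, length.out = length(f$corrugation)),
                         f$corrugation, xout = s)$y
    }
    supp <- if (is.null(f$support_nm)) rep(0, length(s)) else
      rep_len(f$support_nm, length(s))
    r <- pmax(f$diameter_nm + corr, 3) / 2
    grid <- stamp_tubes_cpp(grid, pixel_size_nm, pts[, 1], pts[, 2], r, supp)
  }
  for (o in oligomers) {
    supp <- if (is.null(o$support_nm)) 0 else o$support_nm
    grid <- stamp_tubes_cpp(grid, pixel_size_nm, o$x, o$y,
                            o$diameter_nm / 2, supp)
  }
  heightmap(grid, pixel_size_nm, time_min = time_min, frame_id = frame_id)
}

# ---- population draws -------------------------------------------------------

draw_fibril_population <- function(fp, stratified) {
  n <- fp$count
  d <- draw_population(n, function(p)
    pmax(stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6),
                      fp$diameter_mean_nm, fp$diameter_sd_nm), 3), stratified)
  L <- draw_population(n, function(p)
    pmax(stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6),
                      fp$length_mean_nm, fp$length_sd_nm), 80), stratified)
  rng <- fp$rq_range_nm
  rq <- draw_population(n, function(p)
    rng[1] + diff(rng) * stats::qbeta(p, fp$rq_shape[1], fp$rq_shape[2]),
    stratified)
  list(d = d, L = L, rq = rq)
}

# ---- scene rendering --------------------------------------------------------

#' Render a synthetic scene to an ideal surface plus ground truth
#'
#' Places the configured fibril and oligomer populations (non-crossing
#' smoothed-random-walk backbones, bounded retries), generates calibrated
#' corrugation, and rasterizes the ideal pre-tip surface. All randomness
#' flows from `spec$seed`; a fixed seed gives a bit-identical scene.
#'
#' @param spec a [scene_spec()].
#' @return list with `ideal` (a [heightmap()]) and `truth` (ground-truth
#'   list: per-object table plus backbone polylines).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  field <- spec$field_nm
  px <- spec$pixel_size_nm
  margin <- 40
  ds_dense <- min(1, px / 2)

  fibrils <- list()
  polys_coarse <- list()   # ds = 4 nm samples for crossing checks

  place_fibril_class <- function(fp, class, start_index) {
    pop <- draw_fibril_population(fp, spec$stratified)
    out <- list()
    for (i in seq_len(fp$count)) {
      poly <- NULL
      for (try in seq_len(300)) {
        cand <- gen_backbone(pop$L[i], fp$persistence_nm, field, margin)
        if (is.null(cand)) next
        ok <- TRUE
        for (k in seq_along(polys_coarse)) {
          # keep dilated footprints from merging: half-widths plus tip
          # broadening (~4 nm) on both sides plus a safety gap
          lim <- (pop$d[i] + fibrils[[k]]$d) / 2 + 16
          if (pointset_min_dist(cand, polys_coarse[[k]], lim) < lim) {
            ok <- FALSE; break
          }
        }
        if (ok) { poly <- cand; break }
      }
      if (is.null(poly))
        stop(sprintf(
          "render_scene: could not place %s %d of %d after 300 attempts (field too crowded or too small)",
          class, i, fp$count), call. = FALSE)
      L <- max(arc_lengths(poly))
      s <- seq(0, L, by = ds_dense)
      corr <- gen_corrugation(length(s), ds_dense, fp$corrugation_wavelength_nm,
                              pop$rq[i], pop$d[i])
      rq_real <- if (pop$rq[i] > 0)
        windowed_rq(pop$d[i] + corr, ds_dense)$rq_nm else 0
      id <- sprintf("f%02d", start_index + i)
      fib <- list(id = id, class = class, d = pop$d[i], L = L,
                  poly = poly, s = s, pts = arc_interp(poly, s),
                  corr = corr, support = rep(0, length(s)),
                  host_id = NA_character_, rq = rq_real)
      fibrils[[length(fibrils) + 1L]] <<- fib
      polys_coarse[[length(polys_coarse) + 1L]] <<- poly
      out <- c(out, list(fib))
    }
    out
  }

  place_fibril_class(spec$primary_fibrils, "primary_fibril", 0L)
  n_prim <- length(fibrils)

  sec <- spec$secondary_fibrils
  if (sec$count > 0 && isTRUE(sec$stacked_on_primary)) {
    if (n_prim == 0)
      stop("render_scene: stacked secondary fibrils require primary fibrils",
           call. = FALSE)
    pop <- draw_fibril_population(sec, spec$stratified)
    for (i in seq_len(sec$count)) {
      placed <- FALSE
      for (try in seq_len(100)) {
        h <- sample.int(n_prim, 1)
        host <- fibrils[[h]]
        Ls <- pop$L[i]
        if (host$L < Ls + 40) next
        u0 <- round(stats::runif(1, 15, host$L - Ls - 15))
        # one stacked secondary at a time on any stretch of the host, and
        # keep total stacked coverage below ~45% so the host's own level
        # stays identifiable in the apex profile
        taken <- fibrils[[h]]$blocked
        if (!is.null(taken)) {
          if (any(u0 < taken[, 2] + 20 & u0 + Ls > taken[, 1] - 20)) next
          cover <- sum(pmin(taken[, 2], host$L) - pmax(taken[, 1], 0) - 50)
          if (cover + Ls > 0.45 * host$L) next
        }
        idx <- which(host$s >= u0 & host$s <= u0 + Ls)
        if (length(idx) < 8) next
        corr <- gen_corrugation(length(idx), ds_dense,
                                sec$corrugation_wavelength_nm,
                                pop$rq[i], pop$d[i])
        id <- sprintf("f%02d", length(fibrils) + 1L)
        fib <- list(id = id, class = "secondary_fibril", d = pop$d[i],
                    L = max(host$s[idx]) - min(host$s[idx]),
                    poly = host$pts[idx[seq(1, length(idx), by = 4)], , drop = FALSE],
                    s = host$s[idx] - host$s[idx[1]],
                    pts = host$pts[idx, , drop = FALSE],
                    corr = corr,
                    support = host$d + host$corr[idx],
                    host_id = host$id,
                    rq = windowed_rq(pop$d[i] + corr, ds_dense)$rq_nm)
        fibrils[[length(fibrils) + 1L]] <- fib
        # oligomers must not be placed underneath the stacked span
        fibrils[[h]]$blocked <- rbind(fibrils[[h]]$blocked,
                                      c(u0 - 25, u0 + Ls + 25))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "render_scene: could not stack secondary fibril %d of %d on a primary host",
          i, sec$count), call. = FALSE)
    }
  } else if (sec$count > 0) {
    place_fibril_class(sec, "secondary_fibril", length(fibrils))
  }

  placements <- place_oligomers(spec, fibrils)

  # rasterize
  hm <- render_objects(field, px,
    fibrils = lapply(fibrils, function(f)
      list(poly = f$poly, diameter_nm = f$d, corrugation = f$corr,
           support_nm = f$support)),
    oligomers = if (nrow(placements) > 0) lapply(seq_len(nrow(placements)),
      function(k) list(x = placements$x[k], y = placements$y[k],
                       diameter_nm = placements$diameter_nm[k],
                       support_nm = placements$support_nm[k])) else list(),
    frame_id = spec$frame_id, time_min = spec$time_min)

  objects <- rbind(
    if (length(fibrils) > 0) do.call(rbind, lapply(fibrils, function(f)
      data.frame(id = f$id, class = f$class, true_diameter_nm = f$d,
                 true_length_nm = f$L, placement = NA_character_,
                 host_id = f$host_id, true_rq_nm = f$rq,
                 stringsAsFactors = FALSE))),
    if (nrow(placements) > 0) data.frame(
      id = placements$id, class = "oligomer",
      true_diameter_nm = placements$diameter_nm,
      true_length_nm = NA_real_, placement = placements$placement,
      host_id = placements$host_id, true_rq_nm = NA_real_,
      stringsAsFactors = FALSE))
  rownames(objects) <- NULL

  backbones <- lapply(fibrils, function(f) {
    keep <- seq(1, nrow(f$pts), by = max(1L, round(8 / ds_dense)))
    unname(f$pts[unique(c(keep, nrow(f$pts))), , drop = FALSE])
  })
  names(backbones) <- vapply(fibrils, `[[`, "", "id")

  truth <- list(field_nm = field, pixel_size_nm = px, seed = spec$seed,
                objects = objects, backbones = backbones,
                oligomer_xy = if (nrow(placements) > 0)
                  placements[, c("id", "x", "y", "arc_nm")] else NULL)
  list(ideal = hm, truth = truth)
}

#' Assign oligomer adsorption sites and positions
#'
#' Each oligomer is assigned a placement class (edge / backbone / substrate)
#' by the configured probabilities, then a physical position: edge sites lie
#' on a host backbone within the 20 nm edge window of an endpoint; backbone
#' sites lie elsewhere on the backbone with nearest-neighbour spacing drawn
#' in the 20--100 nm range; substrate sites keep clear of all fibril
#' footprints. Only primary fibrils host oligomers.
#'
#' @param spec a [scene_spec()].
#' @param fibrils list of fibril descriptors as built by [render_scene()]
#'   (fields `id`, `class`, `poly`, `L`; and `s`, `pts`, `corr`, `d` when
#'   support heights are wanted).
#' @return data.frame with one row per oligomer: `id`, `group`,
#'   `diameter_nm`, `placement`, `host_id`, `arc_nm`, `x`, `y`,
#'   `support_nm`.
#' @export
place_oligomers <- function(spec, fibrils) {
  groups <- spec$oligomers
  hosts <- Filter(function(f) f$class == "primary_fibril", fibrils)
  total_on <- sum(vapply(groups, function(g)
    g$count * (g$p_edge + g$p_backbone), 0))
  if (total_on > 0 && length(hosts) == 0)
    stop("place_oligomers: p_edge + p_backbone > 0 but the scene has no primary fibrils",
         call. = FALSE)
  w <- rep(1, length(hosts))
  if (!is.null(spec$hotspot) && length(hosts) >= spec$hotspot$index)
    w[spec$hotspot$index] <- spec$hotspot$factor
  max_r <- if (length(fibrils) > 0)
    max(vapply(fibrils, function(f)
      (f$d + max(c(0, f$corr))) / 2, 0)) else 0

  rows <- list()
  occupied <- lapply(hosts, function(h) numeric(0))  # arc positions per host
  placed_xy <- matrix(numeric(0), ncol = 2)
  placed_r <- numeric(0)
  oid <- 0L
  edge_window <- 20

  # an adsorbed oligomer (~8 nm footprint) bridges the corrugation crests
  # of its host rather than sinking into a valley; its support is the mean
  # fibril level
  host_apex <- function(h, u) hosts[[h]]$d
  host_point <- function(h, u) arc_interp(hosts[[h]]$poly, u)

  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (g$count == 0) next
    cls <- sample_placement_classes(g$count, g$p_edge, g$p_backbone, g$p_substrate)
    diam <- draw_population(g$count, function(p)
      pmax(stats::qnorm(pmin(pmax(p, 1e-6), 1 - 1e-6),
                        g$diameter_mean_nm, g$diameter_sd_nm), 3),
      spec$stratified)
    for (k in seq_len(g$count)) {
      oid <- oid + 1L
      id <- sprintf("o%03d", oid)
      r_o <- diam[k] / 2
      if (cls[k] == "substrate") {
        pos <- NULL
        for (try in seq_len(200)) {
          cand <- stats::runif(2, 30 + r_o, spec$field_nm - 30 - r_o)
          clear <- max_r + r_o + 14
          ok <- TRUE
          for (f in fibrils) {
            if (pointset_min_dist(matrix(cand, 1), f$poly, clear) < clear) {
              ok <- FALSE; break
            }
          }
          if (ok && nrow(placed_xy) > 0) {
            dd <- sqrt((placed_xy[, 1] - cand[1])^2 + (placed_xy[, 2] - cand[2])^2)
            if (any(dd < placed_r + r_o + 8)) ok <- FALSE
          }
          if (ok) { pos <- cand; break }
        }
        if (is.null(pos))
          stop(sprintf("place_oligomers: could not place substrate oligomer %s after 200 attempts", id),
               call. = FALSE)
        placed_xy <- rbind(placed_xy, pos)
        placed_r <- c(placed_r, r_o)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, group = gi, diameter_nm = diam[k], placement = "substrate",
          host_id = NA_character_, arc_nm = NA_real_,
          x = pos[1], y = pos[2], support_nm = 0, stringsAsFactors = FALSE)
      } else {
        placed <- FALSE
        for (try in seq_len(200)) {
          h <- sample.int(length(hosts), 1, prob = w)
          L <- hosts[[h]]$L
          blocked <- hosts[[h]]$blocked
          is_blocked <- function(u) {
            !is.null(blocked) &&
              any(u >= blocked[, 1] - r_o & u <= blocked[, 2] + r_o)
          }
          if (cls[k] == "edge") {
            end <- sample(c(0, 1), 1)
            u <- stats::runif(1, 2, min(edge_window - 2, L / 3))
            u <- if (end == 1) L - u else u
            if (is_blocked(u)) next
            occ <- occupied[[h]]
            if (length(occ) > 0 && min(abs(occ - u)) < 20) next
          } else {
            if (L < 60) next
            occ <- occupied[[h]]
            if (length(occ) == 0) {
              u <- stats::runif(1, edge_window + 5, L - edge_window - 5)
            } else {
              u <- sample(occ, 1) + sample(c(-1, 1), 1) * stats::runif(1, 20, 100)
              if (u < edge_window + 5 || u > L - edge_window - 5) next
            }
            if (length(occ) > 0 && min(abs(occ - u)) < 20) next
            if (is_blocked(u)) next
          }
          pt <- host_point(h, u)
          placed <- TRUE
          occupied[[h]] <- c(occupied[[h]], u)
          rows[[length(rows) + 1L]] <- data.frame(
            id = id, group = gi, diameter_nm = diam[k], placement = cls[k],
            host_id = hosts[[h]]$id, arc_nm = u,
            x = pt[1], y = pt[2], support_nm = host_apex(h, u),
            stringsAsFactors = FALSE)
          break
        }
        if (!placed)
          stop(sprintf("place_oligomers: could not place %s oligomer %s after 200 attempts",
                       cls[k], id), call. = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(id = character(0), group = integer(0),
                      diameter_nm = numeric(0), placement = character(0),
                      host_id = character(0), arc_nm = numeric(0),
                      x = numeric(0), y = numeric(0), support_nm = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Sample oligomer placement classes
#'
#' Multinomial class assignment underlying [place_oligomers()], exposed so
#' the sampling itself can be validated independently of the geometric
#' placement rules.
#'
#' @param n number of oligomers.
#' @param p_edge,p_backbone,p_substrate class probabilities, summing to 1.
#' @return character vector in `{edge, backbone, substrate}`.
#' @export
sample_placement_classes <- function(n, p_edge, p_backbone, p_substrate) {
  stopifnot(abs(p_edge + p_backbone + p_substrate - 1) < 1e-8)
  sample(c("edge", "backbone", "substrate"), n, replace = TRUE,
         prob = c(p_edge, p_backbone, p_substrate))
}

#' Add raster-scan artifacts to a height map
#'
#' Adds what real AFM acquisition adds and flattening later removes:
#' per-scanline constant offsets (Normal, SD `line_offset_sigma_nm`), a
#' deterministic tilt plane (`tilt_nm_per_um` in x and y), correlated
#' substrate roughness (RMS `substrate_sigma_nm`, ~3 px correlation length),
#' and i.i.d. pixel noise. Reproducible from the seed.
#'
#' @param map a [heightmap()].
#' @param spec a [scene_spec()] (its `artifacts` and `substrate_sigma_nm`
#'   blocks are used).
#' @param seed integer; defaults to `spec$seed + 1` so the scene geometry
#'   and its artifacts are independent streams of one scene seed.
#' @return The degraded `heightmap`.
#' @export
add_scan_artifacts <- function(map, spec, seed = NULL) {
  stopifnot(inherits(map, "heightmap"))
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  a <- spec$artifacts
  h <- map$heights
  nr <- nrow(h); nc <- ncol(h); px <- map$pixel_size_nm
  if (spec$substrate_sigma_nm > 0) {
    rough <- matrix(stats::rnorm(nr * nc), nr, nc)
    rough <- apply(rough, 2, smooth_vec, k = 3L)
    rough <- t(apply(rough, 1, smooth_vec, k = 3L))
    rough <- rough / stats::sd(rough) * spec$substrate_sigma_nm
    h <- h + rough
  }
  if (a$line_offset_sigma_nm > 0)
    h <- h + stats::rnorm(nr, 0, a$line_offset_sigma_nm)  # recycled per column
  tilt <- a$tilt_nm_per_um
  if (any(tilt != 0)) {
    x <- (seq_len(nc) - 1) * px / 1000
    y <- (seq_len(nr) - 1) * px / 1000
    h <- h + outer(y * tilt[2], x * tilt[1], "+")
  }
  if (a$pixel_noise_sigma_nm > 0)
    h <- h + matrix(stats::rnorm(nr * nc, 0, a$pixel_noise_sigma_nm), nr, nc)
  set_heights(map, h)
}

#' Simulate a complete topograph: scene, tip convolution, scan artifacts
#'
#' @param spec a [scene_spec()].
#' @return list with `map` (the simulated topograph as imaged), `ideal`
#'   (pre-tip surface), and `truth` (ground truth).
#' @export
simulate_topograph <- function(spec) {
  sc <- render_scene(spec)
  dilated <- apply_tip(sc$ideal, spec$tip)
  map <- add_scan_artifacts(dilated, spec)
  list(map = map, ideal = sc$ideal, truth = sc$truth)
}
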