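# Shared fixtures: all synthetic, generated in code at test time.

scene_file <- function(name) {
  system.file("extdata", "scenes", name, package = "afmtrace")
}

# a small fig2-style frame: primaries plus substrate oligomers
small_primary_spec <- function(seed, n_fib = 8, n_olig = 8) {
  scene_spec(field_nm = 2000, pixel_size_nm = 2, seed = seed,
    primary_fibrils = list(count = n_fib),
    oligomers = list(count = n_olig, diameter_mean_nm = 7.3,
                     diameter_sd_nm = 1.9,
                     p_edge = 0, p_backbone = 0, p_substrate = 1))
}

# match measured fibril traces to ground-truth backbones by midpoint
match_fibrils <- function(an, truth) {
  bb <- truth$backbones
  tr <- truth$objects
  rows <- lapply(names(an$traces), function(fid) {
    pts <- an$traces[[fid]]$backbone
    mid <- pts[round(nrow(pts) / 2), ]
    dmin <- vapply(bb, function(B)
      min(sqrt((B[, 1] - mid[1])^2 + (B[, 2] - mid[2])^2)), 0)
    tid <- names(bb)[which.min(dmin)]
    i <- which(tr$id == tid)
    j <- which(an$records$object_id == fid)
    data.frame(meas_id = fid, true_id = tid, dist = min(dmin),
               d_meas = an$records$diameter_nm[j],
               L_meas = an$records$length_nm[j],
               rq_meas = an$records$rq_nm[j],
               class_meas = an$records$class[j],
               d_true = tr$true_diameter_nm[i],
               L_true = tr$true_length_nm[i],
               rq_true = tr$true_rq_nm[i],
               class_true = tr$class[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# match detected particles to ground-truth oligomers by centre distance
match_oligomers <- function(an, truth, max_dist = 12) {
  xy <- truth$oligomer_xy
  tr <- truth$objects
  rows <- list(); fp <- 0L
  for (oid in names(an$olig_centers)) {
    c0 <- an$olig_centers[[oid]]
    dd <- sqrt((xy$x - c0[1])^2 + (xy$y - c0[2])^2)
    if (min(dd) < max_dist) {
      k <- which.min(dd)
      i <- which(tr$id == xy$id[k])
      j <- which(an$records$object_id == oid)
      rows[[length(rows) + 1L]] <- data.frame(
        meas_id = oid, true_id = xy$id[k],
        d_meas = an$records$diameter_nm[j],
        site_meas = an$records$site[j],
        d_true = tr$true_diameter_nm[i],
        placement_true = tr$placement[i],
        stringsAsFactors = FALSE)
    } else fp <- fp + 1L
  }
  list(matched = if (length(rows)) do.call(rbind, rows) else NULL,
       n_true = nrow(xy), fp = fp)
}

# synthetic straight-line trace for geometric classifier oracles
straight_trace <- function(length_nm = 800, apex = 8.3, spacing = 2,
                           y = 100) {
  n <- length_nm / spacing + 1
  structure(list(
    backbone = cbind(seq(0, length_nm, by = spacing) + 50, rep(y, n)),
    apex_nm = rep(apex, n), spacing_nm = spacing, length_nm = length_nm,
    endpoints = rbind(c(50, y), c(50 + length_nm, y)),
    demoted = FALSE, low_confidence = FALSE), class = "fibril_trace")
}

# brute-force grayscale dilation oracle (independent of the C++ path)
dilate_brute <- function(f, se) {
  nr <- nrow(f); nc <- ncol(f)
  kr <- (nrow(se) - 1) / 2; kc <- (ncol(se) - 1) / 2
  g <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- -Inf
    for (di in -kr:kr) for (dj in -kc:kc) {
      s <- se[di + kr + 1, dj + kc + 1]
      if (is.na(s)) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      v <- f[ii, jj] + s
      if (v > best) best <- v
    }
    g[i, j] <- best
  }
  g
}
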