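#' Segment objects in a flattened height map
#'
#' Foreground is everything more than `threshold_nm` above the substrate
#' baseline; connected components (8-connectivity) become objects. A
#' component is provisionally a fibril when its skeleton is at least
#' `min_skeleton_nm` long and its elongation (skeleton length / mean width)
#' is at least `elongation_min`; otherwise it is a particle. The default
#' 1.5 nm threshold sits between substrate noise (sigma <= 0.3 nm) and the
#' smallest oligomers of interest (~4 nm).
#'
#' @param map flattened [heightmap()].
#' @param threshold_nm foreground height threshold above baseline.
#' @param baseline_nm substrate baseline (0 after [flatten()]).
#' @param min_skeleton_nm minimum skeleton length for a fibril.
#' @param elongation_min minimum skeleton-length / mean-width ratio for a
#'   fibril.
#' @param min_area_px components smaller than this many pixels are noise
#'   and dropped.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `objects` (data.frame: `label`, `type` in `{fibril, particle}`,
#'   `area_px`, `skeleton_nm`, `width_nm`, `elongation`, `border`).
#'   An empty foreground gives zero rows (with a warning).
#' @export
segment_objects <- function(map, threshold_nm = 1.5, baseline_nm = 0,
                            min_skeleton_nm = 50, elongation_min = 3,
                            min_area_px = 4) {
  stopifnot(inherits(map, "heightmap"))
  px <- map$pixel_size_nm
  mask <- map$heights > baseline_nm + threshold_nm
  labels <- label_components_cpp(mask)
  n <- max(labels)
  empty <- data.frame(label = integer(0), type = character(0),
                      area_px = integer(0), skeleton_nm = numeric(0),
                      width_nm = numeric(0), elongation = numeric(0),
                      border = logical(0), stringsAsFactors = FALSE)
  if (n == 0) {
    warning("segment_objects: empty foreground", call. = FALSE)
    return(list(labels = labels, objects = empty))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- vector("list", n)
  keep_id <- 0L
  relabel <- integer(n)
  for (lab in seq_len(n)) {
    idx <- which(labels == lab)
    if (length(idx) < min_area_px) { labels[idx] <- 0L; next }
    ij <- arrayInd(idx, c(nr, nc))
    border <- any(ij[, 1] == 1L | ij[, 1] == nr | ij[, 2] == 1L | ij[, 2] == nc)
    # skeletonize within the bounding box
    r0 <- min(ij[, 1]); r1 <- max(ij[, 1]); c0 <- min(ij[, 2]); c1 <- max(ij[, 2])
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(ij[, 1] - r0 + 1L, ij[, 2] - c0 + 1L)] <- TRUE
    skel <- thin_mask_cpp(sub)
    sk_ij <- which(skel, arr.ind = TRUE)
    skeleton_nm <- skeleton_path_length(sk_ij) * px
    width_nm <- length(idx) * px^2 / max(skeleton_nm, px)
    elong <- skeleton_nm / max(width_nm, px)
    type <- if (skeleton_nm >= min_skeleton_nm && elong >= elongation_min)
      "fibril" else "particle"
    keep_id <- keep_id + 1L
    relabel[lab] <- keep_id
    rows[[lab]] <- data.frame(
      label = keep_id, type = type, area_px = length(idx),
      skeleton_nm = skeleton_nm, width_nm = width_nm, elongation = elong,
      border = border, stringsAsFactors = FALSE)
  }
  objects <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(objects)) objects <- empty
  # compact labels to 1..k in scan order
  labels[labels > 0] <- relabel[labels[labels > 0]]
  rownames(objects) <- NULL
  list(labels = labels, objects = objects)
}

# total length of an 8-connected skeleton: count of step transitions,
# diagonal steps weighted sqrt(2). Approximate but only used for the
# fibril/particle split; measured lengths come from traced backbones.
skeleton_path_length <- function(sk_ij) {
  if (nrow(sk_ij) < 2) return(0)
  # count adjacent pairs
  key <- sk_ij[, 1] * 1e6 + sk_ij[, 2]
  set <- new.env(hash = TRUE, size = nrow(sk_ij))
  for (k in seq_len(nrow(sk_ij))) assign(as.character(key[k]), TRUE, envir = set)
  straight <- 0; diag <- 0
  for (k in seq_len(nrow(sk_ij))) {
    i <- sk_ij[k, 1]; j <- sk_ij[k, 2]
    if (exists(as.character((i + 1) * 1e6 + j), envir = set)) straight <- straight + 1
    if (exists(as.character(i * 1e6 + j + 1), envir = set)) straight <- straight + 1
    if (exists(as.character((i + 1) * 1e6 + j + 1), envir = set)) diag <- diag + 1
    if (exists(as.character((i + 1) * 1e6 + j - 1), envir = set)) diag <- diag + 1
  }
  straight + diag * sqrt(2)
}
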