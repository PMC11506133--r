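#' Calibrated AFM height map
#'
#' The universal currency of the pipeline: a rows x cols grid of surface
#' heights in nanometres with a physical pixel size. The grid is row-major
#' with the origin at the top-left corner; physical coordinates are
#' `x = column index * pixel_size`, `y = row index * pixel_size`, with
#' 0-based pixel indices addressing pixel centres. Heights are in nm
#' everywhere in this package; no other length unit is used internally.
#'
#' @param heights numeric matrix of heights (nm), at least 16 x 16, all
#'   values finite.
#' @param pixel_size_nm physical size of one pixel (nm), positive scalar.
#' @param time_min optional acquisition time in minutes since deposition of
#'   the secondary oligomer solution (`NA` when not applicable).
#' @param frame_id short identifier of the frame.
#' @return An object of class `heightmap`.
#' @examples
#' hm <- heightmap(matrix(0, 32, 32), pixel_size_nm = 2)
#' dim(hm)
#' @export
heightmap <- function(heights, pixel_size_nm, time_min = NA_real_,
                      frame_id = "frame") {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("`heights` must be a numeric matrix", call. = FALSE)
  if (nrow(heights) < 16L || ncol(heights) < 16L)
    stop("height map must be at least 16 x 16 pixels", call. = FALSE)
  if (!all(is.finite(heights)))
    stop("all heights must be finite", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar", call. = FALSE)
  structure(
    list(heights = unname(heights),
         pixel_size_nm = as.numeric(pixel_size_nm),
         time_min = as.numeric(time_min),
         frame_id = as.character(frame_id)),
    class = "heightmap")
}

#' @export
dim.heightmap <- function(x) dim(x$heights)

#' @export
as.matrix.heightmap <- function(x, ...) x$heights

#' @export
print.heightmap <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<heightmap> %s: %d x %d px @ %.3g nm/px (%.3g x %.3g nm), z [%.2f, %.2f] nm%s\n",
    x$frame_id, d[1], d[2], x$pixel_size_nm,
    (d[2] - 1) * x$pixel_size_nm, (d[1] - 1) * x$pixel_size_nm,
    min(x$heights), max(x$heights),
    if (is.finite(x$time_min)) sprintf(", t = %g min", x$time_min) else ""))
  invisible(x)
}

#' Replace the height grid of a height map, keeping metadata
#'
#' @param map a [heightmap()].
#' @param heights replacement numeric matrix of identical dimensions.
#' @return A `heightmap` with the new grid.
#' @keywords internal
set_heights <- function(map, heights) {
  stopifnot(inherits(map, "heightmap"),
            identical(dim(heights), dim(map$heights)))
  map$heights <- heights
  map
}
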