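#' AFM tip model
#'
#' Radially symmetric tip described by its structuring function
#' `s(dx, dy) <= 0` with the apex at the origin (`s(0,0) = 0`), opening
#' downward. Two shapes are supported: a paraboloid of apex radius R,
#' `s = -rho^2 / (2R)`, and a sphere-capped cone which follows the sphere of
#' radius R near the apex and continues as a cone of the given half-angle
#' beyond the tangency circle `rho = R cos(alpha)`.
#'
#' @param shape `"paraboloid"` or `"cone"` (sphere-capped cone).
#' @param radius_nm apex radius of curvature R (nm), positive.
#' @param half_angle_deg cone half-angle (degrees), cone only.
#' @return A `tip_model` object.
#' @examples
#' tip <- tip_model("paraboloid", radius_nm = 2)
#' @export
tip_model <- function(shape = c("paraboloid", "cone"), radius_nm = 2,
                      half_angle_deg = 15) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(radius_nm), radius_nm > 0)
  if (shape == "cone")
    stopifnot(half_angle_deg > 0, half_angle_deg < 90)
  structure(list(shape = shape, radius_nm = radius_nm,
                 half_angle_deg = half_angle_deg),
            class = "tip_model")
}

#' Evaluate the tip structuring function at radial distance rho (nm)
#' @keywords internal
tip_profile <- function(tip, rho) {
  R <- tip$radius_nm
  if (tip$shape == "paraboloid") return(-rho^2 / (2 * R))
  a <- tip$half_angle_deg * pi / 180
  rho_t <- R * cos(a)
  z <- ifelse(rho <= rho_t,
              R - sqrt(pmax(R^2 - rho^2, 0)),
              (R - sqrt(R^2 - rho_t^2)) + (rho - rho_t) / tan(a))
  -z
}

#' Discretise a tip onto the pixel grid as a structuring-function matrix
#'
#' The support is truncated where the tip sits deeper than `z_range` below
#' its apex (such contact points can never win the dilation max for features
#' of that height range). NA marks pixels outside the support.
#'
#' @param tip a [tip_model()].
#' @param pixel_size_nm grid pitch (nm).
#' @param z_range height range of the surface (nm); controls the support
#'   radius.
#' @return Odd-sized square numeric matrix with `0` at the centre.
#' @keywords internal
tip_matrix <- function(tip, pixel_size_nm, z_range) {
  z_range <- max(z_range, pixel_size_nm)
  # solve tip_profile(rho) = -z_range for the support radius
  lo <- 0; hi <- tip$radius_nm
  while (tip_profile(tip, hi) > -z_range) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (tip_profile(tip, mid) > -z_range) lo <- mid else hi <- mid
  }
  k <- max(1L, ceiling(hi / pixel_size_nm))
  off <- (-k:k) * pixel_size_nm
  rho <- sqrt(outer(off^2, off^2, "+"))
  se <- tip_profile(tip, rho)
  se[se < -z_range] <- NA_real_
  se[k + 1L, k + 1L] <- 0
  se
}

#' Apply tip-sample convolution (grayscale dilation) to a height map
#'
#' The imaged topograph is the grayscale dilation of the true surface by the
#' tip shape: `g(p) = max_q [f(q) + s(p - q)]`. Dilation is extensive
#' (`g >= f` pointwise), translation-equivariant, and preserves the height
#' of isolated convex bumps -- which is why this pipeline measures sizes
#' from heights, never from apparent widths.
#'
#' @param map a [heightmap()].
#' @param tip a [tip_model()]; the discretised support must be at least one
#'   pixel.
#' @return The dilated `heightmap`.
#' @export
apply_tip <- function(map, tip) {
  stopifnot(inherits(map, "heightmap"), inherits(tip, "tip_model"))
  zr <- diff(range(map$heights))
  se <- tip_matrix(tip, map$pixel_size_nm, zr)
  set_heights(map, grey_dilate_cpp(map$heights, se))
}

#' Erode a topograph with the tip shape (certified reconstruction)
#'
#' Eroding the dilated image with the same tip gives the tightest surface
#' consistent with the image: the reconstruction r satisfies
#' `f <= r <= g` for the true surface f and the topograph g. Exposed for
#' validation; the measurement pipeline itself works on heights, which the
#' dilation preserves.
#'
#' @inheritParams apply_tip
#' @return The eroded `heightmap`.
#' @export
erode_tip <- function(map, tip) {
  stopifnot(inherits(map, "heightmap"), inherits(tip, "tip_model"))
  zr <- diff(range(map$heights))
  se <- tip_matrix(tip, map$pixel_size_nm, zr)
  set_heights(map, grey_erode_cpp(map$heights, se))
}
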