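#' Synthetic scene specification
#'
#' Describes a sub-monolayer AFM scene of amyloid fibrils and oligomers on a
#' flat substrate, plus the imaging tip and raster-scan artifacts. Defaults
#' are the conditions of the study this package models: primary fibrils of
#' diameter 8.3 +/- 0.85 nm and length 842 +/- 133.5 nm with backbone RMS
#' corrugation (Rq) in 0.4--2.2 nm; secondary fibrils of diameter
#' 6.5 +/- 0.2 nm with Rq in 2.5--8.5 nm; spherical oligomers; 2 nm pixels
#' (a 1 um scan at 512 px).
#'
#' Fibril population blocks take `count`, `diameter_mean_nm`,
#' `diameter_sd_nm`, `length_mean_nm`, `length_sd_nm`, `persistence_nm`
#' (backbone bending persistence length), `rq_range_nm` (2-vector),
#' `rq_shape` (Beta shape pair over that range; `c(1, 1)` = uniform),
#' `corrugation_wavelength_nm`, and for secondaries `stacked_on_primary`.
#' `oligomers` is one group or a list of groups, each with `count`,
#' `diameter_mean_nm`, `diameter_sd_nm` and placement probabilities
#' `p_edge`, `p_backbone`, `p_substrate` summing to 1.
#'
#' @param field_nm field size (nm), `c(width, height)` or a scalar.
#' @param pixel_size_nm grid pitch in nm/px.
#' @param seed mandatory integer seed; every random choice in the scene
#'   flows from it.
#' @param time_min nominal acquisition time (minutes), carried to metadata.
#' @param frame_id frame identifier.
#' @param primary_fibrils,secondary_fibrils fibril population blocks (lists;
#'   see Details). A `count` of 0 disables a block.
#' @param oligomers oligomer group or list of groups (see Details).
#' @param tip list with `shape` and `radius_nm` (and `half_angle_deg` for
#'   cones), passed to [tip_model()].
#' @param artifacts list with `line_offset_sigma_nm`, `tilt_nm_per_um`
#'   (2-vector, x and y), `pixel_noise_sigma_nm`.
#' @param substrate_sigma_nm RMS roughness of the bare substrate (nm).
#' @param hotspot list or NULL; `list(index = i, factor = w)` makes primary
#'   fibril `i` receive `w`-fold weight when hosting oligomers (a designated
#'   high-activity fibril).
#' @param stratified logical; draw population parameters by shuffled
#'   quantile stratification instead of iid sampling, so the realized
#'   population mean matches the configured mean (calibrated benchmark
#'   scenes).
#' @return A validated object of class `scene_spec`.
#' @export
scene_spec <- function(field_nm = c(2000, 2000),
                       pixel_size_nm = 2,
                       seed,
                       time_min = NA_real_,
                       frame_id = "sim",
                       primary_fibrils = list(),
                       secondary_fibrils = list(),
                       oligomers = list(),
                       tip = list(shape = "paraboloid", radius_nm = 2),
                       artifacts = list(),
                       substrate_sigma_nm = 0.15,
                       hotspot = NULL,
                       stratified = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("scene_spec: `seed` is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  if (length(field_nm) == 1) field_nm <- c(field_nm, field_nm)

  prim_defaults <- list(count = 0L, diameter_mean_nm = 8.3, diameter_sd_nm = 0.85,
                        length_mean_nm = 842, length_sd_nm = 133.5,
                        persistence_nm = 6000, rq_range_nm = c(0.4, 2.2),
                        rq_shape = c(1, 1), corrugation_wavelength_nm = 50)
  sec_defaults <- list(count = 0L, diameter_mean_nm = 6.5, diameter_sd_nm = 0.2,
                       length_mean_nm = 250, length_sd_nm = 55,
                       persistence_nm = 6000, rq_range_nm = c(2.5, 8.5),
                       rq_shape = c(1.4, 4.6), corrugation_wavelength_nm = 50,
                       stacked_on_primary = TRUE)
  primary_fibrils <- utils::modifyList(prim_defaults, as.list(primary_fibrils))
  secondary_fibrils <- utils::modifyList(sec_defaults, as.list(secondary_fibrils))

  olig_defaults <- list(count = 0L, diameter_mean_nm = 7.9, diameter_sd_nm = 0.2,
                        p_edge = 0, p_backbone = 0, p_substrate = 1)
  if (length(oligomers) > 0 && !is.null(names(oligomers)) &&
      any(names(oligomers) != ""))
    oligomers <- list(oligomers)  # single group given flat
  oligomers <- lapply(oligomers, function(g)
    utils::modifyList(olig_defaults, as.list(g)))

  art_defaults <- list(line_offset_sigma_nm = 1.0, tilt_nm_per_um = c(2, 2),
                       pixel_noise_sigma_nm = 0.15)
  artifacts <- utils::modifyList(art_defaults, as.list(artifacts))
  if (length(artifacts$tilt_nm_per_um) == 1)
    artifacts$tilt_nm_per_um <- rep(artifacts$tilt_nm_per_um, 2)

  spec <- structure(
    list(field_nm = as.numeric(field_nm), pixel_size_nm = pixel_size_nm,
         seed = seed, time_min = time_min, frame_id = frame_id,
         primary_fibrils = primary_fibrils,
         secondary_fibrils = secondary_fibrils,
         oligomers = oligomers,
         tip = do.call(tip_model, tip),
         artifacts = artifacts,
         substrate_sigma_nm = substrate_sigma_nm,
         hotspot = hotspot,
         stratified = isTRUE(stratified)),
    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    stopifnot(all(field_nm > 0), pixel_size_nm > 0,
              substrate_sigma_nm >= 0,
              artifacts$line_offset_sigma_nm >= 0,
              artifacts$pixel_noise_sigma_nm >= 0)
    for (fp in list(primary_fibrils, secondary_fibrils)) {
      stopifnot(fp$count >= 0, fp$diameter_mean_nm > 0, fp$diameter_sd_nm >= 0,
                fp$length_mean_nm > 0, fp$length_sd_nm >= 0,
                fp$persistence_nm > 0, length(fp$rq_range_nm) == 2,
                all(fp$rq_range_nm >= 0), diff(fp$rq_range_nm) >= 0)
    }
    for (g in oligomers) {
      stopifnot(g$count >= 0, g$diameter_mean_nm > 0, g$diameter_sd_nm >= 0,
                g$p_edge >= 0, g$p_backbone >= 0, g$p_substrate >= 0)
      if (abs(g$p_edge + g$p_backbone + g$p_substrate - 1) > 1e-8)
        stop("oligomer placement probabilities must sum to 1", call. = FALSE)
    }
  })
  invisible(spec)
}

#' Stratified or iid draws from a population distribution
#'
#' Quantile-stratified sampling (one shuffled draw per probability stratum,
#' jittered within the stratum) keeps the realized population mean at the
#' configured mean, so recovery tests measure pipeline bias rather than
#' sampling noise.
#'
#' @param n number of draws.
#' @param qfun quantile function, e.g. `function(p) qnorm(p, mean, sd)`.
#' @param stratified logical.
#' @return numeric vector of length `n`.
#' @keywords internal
draw_population <- function(n, qfun, stratified = TRUE) {
  if (n == 0) return(numeric(0))
  p <- if (stratified)
    sample((seq_len(n) - stats::runif(n)) / n)
  else stats::runif(n)
  qfun(p)
}
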