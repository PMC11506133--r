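#' Write a height map to float32 TIFF plus JSON sidecar
#'
#' Heights are stored as an uncompressed single-channel 32-bit float TIFF
#' (nm). Metadata (pixel size, acquisition time, frame id, optional generator
#' seed) goes to a JSON sidecar with the same stem and extension `.json`.
#' The round trip `write_heightmap()` then [read_heightmap()] is the identity
#' on metadata and on heights up to float32 representation.
#'
#' @param map a [heightmap()].
#' @param path output TIFF path (`.tif`/`.tiff`).
#' @param generator_seed optional integer recorded in the sidecar when the
#'   map came from the simulator.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(map, path, generator_seed = NULL) {
  stopifnot(inherits(map, "heightmap"))
  write_tiff_f32(map$heights, path)
  meta <- list(schema_version = 1L,
               pixel_size_nm = map$pixel_size_nm,
               time_min = map$time_min,
               frame_id = map$frame_id)
  if (!is.null(generator_seed)) meta$generator_seed <- as.integer(generator_seed)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[Tt][Ii][Ff][Ff]?$", "", path), ".json")

#' Read a height map from float32 TIFF plus JSON sidecar
#'
#' The sidecar is mandatory: pixel size is never guessed or defaulted.
#' Integer, compressed, or multi-channel TIFFs are rejected with an error
#' naming the violation.
#'
#' @param path TIFF path written by [write_heightmap()] (or any conforming
#'   single-channel float32 TIFF with a sidecar).
#' @return A [heightmap()].
#' @export
read_heightmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar: expected metadata file ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_nm))
    stop("sidecar ", sc, " lacks pixel_size_nm; refusing to default it",
         call. = FALSE)
  heights <- read_tiff_f32(path)
  heightmap(heights, pixel_size_nm = meta$pixel_size_nm,
            time_min = if (is.null(meta$time_min)) NA_real_ else as.numeric(meta$time_min),
            frame_id = if (is.null(meta$frame_id)) "frame" else meta$frame_id)
}

#' Measurement table columns, in their documented fixed order.
#' @keywords internal
measurement_columns <- function() {
  c("frame_id", "time_min", "object_id", "class", "diameter_nm",
    "length_nm", "rq_nm", "site", "activity", "host_id")
}

#' Write a measurement table to CSV
#'
#' Columns are written in the fixed documented order
#' (`frame_id, time_min, object_id, class, diameter_nm, length_nm, rq_nm,
#' site, activity, host_id`) and rows are sorted by frame id then object id,
#' so output is byte-identical across runs for identical inputs. Fields that
#' do not apply to an object class (e.g. `length_nm` for an oligomer) are
#' `NA`; the mandatory columns (`frame_id`, `object_id`, `class`,
#' `diameter_nm`) must not contain NaN/NA.
#'
#' @param records data.frame of per-object measurements.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  cols <- measurement_columns()
  if (nrow(records) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    utils::write.csv(empty, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(records))
  for (mc in missing_cols) records[[mc]] <- NA
  mandatory <- c("frame_id", "object_id", "class", "diameter_nm")
  for (mc in mandatory) {
    v <- records[[mc]]
    if (any(is.na(v)))
      stop("NaN/NA in mandatory column `", mc, "`", call. = FALSE)
  }
  records <- records[order(records$frame_id, records$object_id), cols]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @return data.frame with the documented columns.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(frame_id = "character", class = "character",
                                 site = "character", activity = "character",
                                 host_id = "character"))
}

#' Write / read simulator ground truth as JSON
#'
#' @param gt ground-truth object from [render_scene()].
#' @param path JSON path.
#' @return `path` (write) or the ground-truth list (read).
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load a scene specification from YAML
#'
#' The YAML maps directly onto the arguments of [scene_spec()]; the seed may
#' be given in the file or supplied/overridden here (a seed is mandatory one
#' way or the other).
#'
#' @param path YAML file.
#' @param seed optional integer seed overriding the file's.
#' @return A validated `scene_spec`.
#' @export
read_scene_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  frames <- cfg$frames
  cfg$frames <- NULL
  cfg$description <- NULL
  spec <- do.call(scene_spec, cfg)
  attr(spec, "frames") <- if (is.null(frames)) 1L else as.integer(frames)
  spec
}
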