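# Plain-text interchange: all linear dimensions are micrometres and column
# names carry the unit suffix (_um, _um3); readers reject tables declaring
# other units.

geometry_cols <- c("case_id", "region", "neuron_id", "segment_id",
                   "spine_id", "point_index", "x_um", "y_um", "z_um",
                   "diameter_um", "voxel_count", "voxel_x_um", "voxel_y_um",
                   "voxel_z_um")
spine_csv_cols <- c("case_id", "region", "neuron_id", "segment_id",
                    "spine_id", "length_um", "head_diameter_um",
                    "neck_diameter_um", "volume_um3")
segment_csv_cols <- c("case_id", "region", "neuron_id", "segment_id",
                      "length_um")

check_unit_columns <- function(found, required, what) {
  miss <- setdiff(required, found)
  if (length(miss))
    stop(what, " is missing required micrometre-unit columns: ",
         paste(miss, collapse = ", "),
         " (other unit declarations are rejected)")
  unit_like <- grepl("_(nm|mm|cm|px|nm3|mm3)$", found)
  if (any(unit_like))
    stop(what, " declares unsupported units in column(s): ",
         paste(found[unit_like], collapse = ", "))
  invisible(TRUE)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits spine CSV (pre-measured schema), segment CSV, case CSV, a geometry
#' CSV when the cohort carries geometry, and a truth JSON with the
#' generating coefficients.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "spine_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(spines = file.path(dir, "spines.csv"),
             segments = file.path(dir, "segments.csv"),
             cases = file.path(dir, "cases.csv"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(cohort$spines, paths["spines"])
  data.table::fwrite(cohort$segments, paths["segments"])
  data.table::fwrite(cohort$cases, paths["cases"])
  truth <- cohort$truth
  truth$case_latent <- as.data.frame(truth$case_latent)
  truth$mean_head_diameter <- as.data.frame(truth$mean_head_diameter)
  truth$sex_coding <- list(female = 0, male = 1)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(cohort$geometry)) {
    paths <- c(paths, geometry = file.path(dir, "geometry.csv"))
    data.table::fwrite(cohort$geometry, paths["geometry"])
  }
  invisible(paths)
}

#' Read a per-point spine geometry CSV
#' @param path CSV path in the geometry schema.
#' @return data.table of backbone points.
#' @export
read_geometry_csv <- function(path) {
  g <- data.table::fread(path)
  check_unit_columns(names(g), geometry_cols, "geometry CSV")
  g
}

#' Read a pre-measured spine CSV
#' @param path CSV path in the measured-spine schema.
#' @return data.table, one row per spine.
#' @export
read_spine_csv <- function(path) {
  s <- data.table::fread(path)
  check_unit_columns(names(s), spine_csv_cols, "spine CSV")
  s
}

#' Read a segment CSV
#' @param path CSV path with per-segment lengths.
#' @return data.table, one row per segment.
#' @export
read_segment_csv <- function(path) {
  s <- data.table::fread(path)
  check_unit_columns(names(s), segment_csv_cols, "segment CSV")
  s
}

#' Read a per-case covariate CSV
#' @param path CSV path with case_id plus covariate/score columns.
#' @return data.table, one row per case.
#' @export
read_case_csv <- function(path) {
  ct <- data.table::fread(path)
  if (!"case_id" %in% names(ct)) stop("case CSV needs a case_id column")
  ct
}
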