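# File contracts.
#
# Trace CSV:    time_s, o2_value, o2_unit, temp_C (optional)
# Manifest CSV: trial_id, animal_id, group_psu, salinity_psu, temp_C,
#               chamber_volume_L, animal_mass_g, trial_type, start_po2_kpa,
#               trace_file
# All CSVs are UTF-8, comma-separated, '.' decimal, with a header row.

MANIFEST_COLUMNS <- c("trial_id", "animal_id", "group_psu", "salinity_psu",
                      "temp_C", "chamber_volume_L", "animal_mass_g",
                      "trial_type", "start_po2_kpa", "trace_file")

#' Read a trace CSV
#'
#' @param path CSV file with columns `time_s`, `o2_value`, `o2_unit`
#'   (`percent_sat` or `kpa`, constant within a file) and optionally
#'   `temp_C`.
#' @param cond a [water_conditions()] object for the trial.
#' @return An [o2_trace()] (phases not yet labelled).
#' @export
read_trace <- function(path, cond) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "o2_value", "o2_unit")
  if (!all(need %in% names(df)))
    stop(sprintf("trace file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  unit <- unique(df$o2_unit)
  if (length(unit) != 1 || !unit %in% c("percent_sat", "kpa"))
    stop(sprintf("trace file '%s': unknown or mixed o2_unit '%s'", path,
                 paste(unit, collapse = "/")), call. = FALSE)
  d <- diff(df$time_s)
  if (length(d) && any(d <= 0))
    stop(sprintf("trace file '%s': time_s not strictly increasing at row %d",
                 path, which(d <= 0)[1] + 1L), call. = FALSE)
  o2_trace(df$time_s, df$o2_value, unit = unit, cond = cond)
}

#' Write a trace CSV
#'
#' @param trace an [o2_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s, o2_value = trace$o2_value,
                   o2_unit = trace_unit(trace),
                   temp_C = trace_cond(trace)$temperature_C)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial manifest CSV
#'
#' Validates the column set and, when `dir` is given, that every referenced
#' trace file exists.
#'
#' @param path manifest CSV.
#' @param dir directory that trace files are resolved against (default: the
#'   manifest's directory); `NULL` skips the existence check.
#' @return Data frame with the manifest columns.
#' @export
read_manifest <- function(path, dir = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) stop("manifest is empty", call. = FALSE)
  bad_type <- !df$trial_type %in% c("mmr", "hypoxia", "blank")
  if (any(bad_type))
    stop("manifest has unknown trial_type for trial_id: ",
         paste(df$trial_id[bad_type], collapse = ", "), call. = FALSE)
  if (!is.null(dir)) {
    paths <- file.path(dir, df$trace_file)
    absent <- !file.exists(paths)
    if (any(absent))
      stop("manifest references absent trace files for trial_id: ",
           paste(df$trial_id[absent], collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a simulated cohort to disk
#'
#' Emits `manifest.csv`, per-trial `trace_<id>.csv`, the per-animal ground
#' truth `truth.csv` (labelled synthetic: it exists only for simulated
#' data) and a `generator_config.json` sidecar echoing every generation
#' parameter and the master seed.
#'
#' @param cohort result of [simulate_cohort()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth_table, file.path(outdir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(cohort$traces))
    write_trace(cohort$traces[[id]],
                file.path(outdir, sprintf("trace_%s.csv", id)))
  sidecar <- c(cohort$config, list(master_seed = cohort$seed))
  jsonlite::write_json(sidecar, file.path(outdir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(outdir)
}

#' Write per-animal metrics and group statistics CSVs
#'
#' @param metrics per-animal metrics data frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the statistical report JSON
#'
#' @param report nested list of test results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
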