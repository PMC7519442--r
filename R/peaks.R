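#' @keywords internal
peak_columns <- function() {
  c("compound", "tissue", "sample_kind", "nominal_conc", "time_min",
    "animal_id", "sex", "group", "analyte_area", "is_area")
}

#' Read and validate a peak-area table
#'
#' The peak table is the pipeline's exchange format: one row per injection,
#' carrying the integrated analyte and internal-standard (IS) peak areas
#' together with the sample metadata. Quantification downstream always uses
#' the analyte/IS area ratio, so `is_area` must be strictly positive.
#'
#' Required columns: `compound`, `tissue`, `sample_kind`
#' (`calibration`/`qc`/`study`/`blank`), `analyte_area`, `is_area`.
#' Kind-dependent columns: `nominal_conc` (ng/mL, calibration and QC rows),
#' `time_min`, `animal_id`, `sex`, `group` (study rows). Extra columns
#' (e.g. `day`, `condition` on QC rows) are preserved untouched.
#'
#' Structural problems (missing columns, tissues absent from the design)
#' abort with an error. Row-level invariant violations do not abort: the
#' offending rows are dropped with a warning, and the dropped row numbers
#' with reasons are attached as the `"rejected"` attribute of the result.
#'
#' @param path CSV file path (UTF-8, `.` decimal separator).
#' @param design A [study_design()]; used to check tissue names, time points
#'   and sex consistency of study rows.
#' @return A `data.frame` of validated peak records, with attribute
#'   `rejected` (a `data.frame` with columns `row`, `reason`; zero rows when
#'   everything validated).
#' @export
read_peak_table <- function(path, design) {
  stopifnot(inherits(design, "study_design"))
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  validate_peak_records(df, design)
}

#' @rdname read_peak_table
#' @param records A data.frame shaped like a peak table (e.g. from
#'   [generate_study()]), validated in memory without a file round-trip.
#' @export
validate_peak_records <- function(records, design) {
  required <- c("compound", "tissue", "sample_kind", "analyte_area", "is_area")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L)
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(peak_columns(), names(records))) records[[col]] <- NA
  unknown <- setdiff(unique(records$tissue), design$tissues)
  if (length(unknown) > 0L)
    stop("tissue(s) not in study design: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  reasons <- character(nrow(records))
  flag <- function(idx, why) {
    idx <- which(idx)
    reasons[idx] <<- ifelse(nzchar(reasons[idx]),
                            paste(reasons[idx], why, sep = "; "), why)
  }
  flag(!records$sample_kind %in% c("calibration", "qc", "study", "blank"),
       "unknown sample_kind")
  flag(is.na(records$is_area) | records$is_area <= 0, "is_area <= 0")
  flag(is.na(records$analyte_area) | records$analyte_area < 0,
       "analyte_area < 0")
  needs_nominal <- records$sample_kind %in% c("calibration", "qc")
  flag(needs_nominal & (is.na(records$nominal_conc) | records$nominal_conc <= 0),
       "nominal_conc missing or <= 0")
  is_study <- records$sample_kind == "study"
  flag(is_study & !records$group %in% design$groups, "unknown group")
  flag(is_study & !records$time_min %in% design$time_points_min,
       "time_min not a design time point")
  flag(is_study & (is.na(records$sex) | !records$sex %in% c("M", "F")),
       "sex must be M or F")
  rule <- design$sex_specific[records$tissue]
  flag(is_study & rule == "female_only" & records$sex == "M",
       "male sample of a female-only tissue")
  flag(is_study & rule == "male_only" & records$sex == "F",
       "female sample of a male-only tissue")

  bad <- nzchar(reasons)
  rejected <- data.frame(row = which(bad), reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L)
    warning(sprintf("rejected %d peak record(s): %s", nrow(rejected),
                    paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                          collapse = "; ")),
            call. = FALSE)
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a peak table to CSV
#'
#' Inverse of [read_peak_table()]; the round-trip is lossless for all
#' standard columns at full double precision.
#'
#' @param records Peak-record data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(records, path) {
  keep <- c(peak_columns(), setdiff(names(records), peak_columns()))
  utils::write.csv(records[, intersect(keep, names(records)), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
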