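#' Accuracy as relative error (RE %)
#'
#' \deqn{RE = 100 (\bar{x} - x_{nom}) / x_{nom}}
#'
#' @param measured_mean Measured mean concentration(s), ng/mL.
#' @param nominal Nominal (spiked) concentration(s), ng/mL; must be > 0.
#' @return Relative error in percent (negative = under-recovery).
#' @examples
#' relative_error(247.43, 250)   # -1.028
#' @export
relative_error <- function(measured_mean, nominal) {
  if (any(!is.finite(nominal)) || any(nominal <= 0))
    stop("nominal concentration must be > 0", call. = FALSE)
  100 * (measured_mean - nominal) / nominal
}

#' Precision as relative standard deviation (RSD %)
#'
#' `rsd()` computes `100 * sd(values) / mean(values)` from raw replicates
#' (sample SD, n-1 denominator); `rsd_from_summary()` computes the same
#' quantity from an already-summarised mean and SD pair, as printed in
#' validation tables.
#'
#' @param values Numeric replicates; at least two, non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd_from_summary(85.67, 5.13)  # 5.99
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for RSD", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' @rdname rsd
#' @param mean,sd Summary mean and standard deviation.
#' @export
rsd_from_summary <- function(mean, sd) {
  if (any(mean == 0)) stop("RSD undefined: mean is zero", call. = FALSE)
  100 * sd / mean
}

#' Extraction recovery and matrix effect
#'
#' Extraction recovery compares the response of QC samples spiked *before*
#' extraction with neat standard solutions at the same concentration; the
#' matrix effect compares blank-extract samples spiked *after* extraction
#' with the neat standards (ionization suppression/enhancement). Both are
#' reported as `100 * mean(numerator) / mean(denominator)`, with an SD
#' propagated over replicate pairs taken in input order.
#'
#' @param extracted_qc_areas,neat_standard_areas Peak areas (or area
#'   ratios) of the extracted QC replicates and the neat standards.
#' @return A list with `percent`, `sd` (NA when the replicates cannot be
#'   paired one-to-one), and `rsd`.
#' @export
recovery <- function(extracted_qc_areas, neat_standard_areas) {
  ratio_stat(extracted_qc_areas, neat_standard_areas)
}

#' @rdname recovery
#' @param postextraction_spiked_areas Peak areas of blank extracts spiked
#'   after extraction.
#' @export
matrix_effect <- function(postextraction_spiked_areas, neat_standard_areas) {
  ratio_stat(postextraction_spiked_areas, neat_standard_areas)
}

#' @keywords internal
ratio_stat <- function(num, den) {
  if (length(num) == 0L || length(den) == 0L)
    stop("empty replicate list", call. = FALSE)
  if (mean(den) == 0) stop("denominator mean is zero", call. = FALSE)
  pct <- 100 * mean(num) / mean(den)
  if (length(num) == length(den) && length(num) >= 2L) {
    pair <- 100 * num / den
    s <- stats::sd(pair)
    list(percent = pct, sd = s, rsd = 100 * s / mean(pair))
  } else {
    list(percent = pct, sd = NA_real_, rsd = NA_real_)
  }
}

#' Stability relative error per storage condition
#'
#' QC samples are re-assayed after storage stress (three freeze-thaw
#' cycles, 4 h bench-top at 25 degrees C, 30 days at -20 degrees C, or time
#' in the autosampler before injection) and compared against nominal by
#' relative error; an analyte is considered stable under a condition when
#' |RE| stays within the accuracy acceptance band.
#'
#' @param batches A `data.frame` with columns `compound`, `tissue`, `level`,
#'   `nominal`, `condition`, `value` (back-calculated ng/mL, one row per
#'   replicate).
#' @param conditions Allowed condition labels.
#' @param re_limit Pass threshold on |RE|, percent.
#' @return A `data.frame` with one row per compound x tissue x level x
#'   condition: `measured_mean`, `measured_sd`, `re`, `pass`.
#' @export
stability_re <- function(batches,
                         conditions = c("freeze_thaw", "short_term",
                                        "long_term", "preinjection"),
                         re_limit = 15) {
  needed <- c("compound", "tissue", "level", "nominal", "condition", "value")
  missing <- setdiff(needed, names(batches))
  if (length(missing) > 0L)
    stop("stability batches missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(batches$condition), conditions)
  if (length(unknown) > 0L)
    stop("unknown stability condition(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(value ~ compound + tissue + level + nominal +
                            condition, data = batches,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v)))
  out <- agg[, c("compound", "tissue", "level", "nominal", "condition")]
  out$measured_mean <- agg$value[, "m"]
  out$measured_sd <- agg$value[, "s"]
  out$re <- relative_error(out$measured_mean, out$nominal)
  out$pass <- abs(out$re) <= re_limit
  out[order(out$compound, out$tissue, out$nominal, out$condition), ,
      drop = FALSE]
}

#' Precision and accuracy report from QC replicates
#'
#' Computes the standard bioanalytical precision/accuracy table: intra-day
#' metrics from the replicates of a single day (the first day present) and
#' inter-day metrics from all replicates pooled across days (grand mean and
#' SD, matching how such tables print a single inter-day mean +/- SD per
#' level). Acceptance follows the usual regulatory bands: |RE| and RSD
#' within 15 %, relaxed to 20 % at the LLOQ level.
#'
#' @param qc A `data.frame` with columns `compound`, `tissue`, `level`
#'   (`"lloq"`, `"low"`, `"mid"`, `"high"`), `nominal`, `day`, `value`
#'   (back-calculated ng/mL, one row per replicate).
#' @param re_limit,rsd_limit Acceptance thresholds, percent.
#' @param lloq_limit Relaxed threshold applied at `level == "lloq"`.
#' @return A `data.frame`, one row per compound x tissue x level, with
#'   intra/inter mean, SD, RSD (precision) and RE (accuracy), logical
#'   `pass`, and `note` flagging insufficient replication. Inter-day
#'   columns are `NA` (with a note) when only one day is present.
#' @export
assess_precision_accuracy <- function(qc, re_limit = 15, rsd_limit = 15,
                                      lloq_limit = 20) {
  needed <- c("compound", "tissue", "level", "nominal", "day", "value")
  missing <- setdiff(needed, names(qc))
  if (length(missing) > 0L)
    stop("QC table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keys <- unique(qc[, c("compound", "tissue", "level", "nominal")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- qc[qc$compound == k$compound & qc$tissue == k$tissue &
                qc$level == k$level & qc$nominal == k$nominal, ]
    lim <- if (identical(k$level, "lloq")) lloq_limit else NA
    re_lim <- if (is.na(lim)) re_limit else lim
    rsd_lim <- if (is.na(lim)) rsd_limit else lim
    day1 <- sub[sub$day == min(sub$day), ]
    note <- character(0)
    if (nrow(day1) >= 2L) {
      intra_mean <- mean(day1$value); intra_sd <- stats::sd(day1$value)
      intra_rsd <- rsd(day1$value)
      intra_re <- relative_error(intra_mean, k$nominal)
    } else {
      intra_mean <- intra_sd <- intra_rsd <- intra_re <- NA_real_
      note <- c(note, "intra-day: <2 replicates")
    }
    if (length(unique(sub$day)) >= 2L) {
      inter_mean <- mean(sub$value); inter_sd <- stats::sd(sub$value)
      inter_rsd <- rsd(sub$value)
      inter_re <- relative_error(inter_mean, k$nominal)
    } else {
      inter_mean <- inter_sd <- inter_rsd <- inter_re <- NA_real_
      note <- c(note, "inter-day: <2 days")
    }
    pass <- all(c(abs(intra_re) <= re_lim, intra_rsd <= rsd_lim,
                  abs(inter_re) <= re_lim, inter_rsd <= rsd_lim), na.rm = TRUE)
    rows[[i]] <- data.frame(
      compound = k$compound, tissue = k$tissue, level = k$level,
      nominal = k$nominal,
      intra_mean = intra_mean, intra_sd = intra_sd,
      intra_rsd = intra_rsd, intra_re = intra_re,
      inter_mean = inter_mean, inter_sd = inter_sd,
      inter_rsd = inter_rsd, inter_re = inter_re,
      pass = pass,
      note = paste(note, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$compound, out$tissue, out$nominal), , drop = FALSE]
}

#' Full method-validation report
#'
#' Assembles precision/accuracy, recovery, matrix effect and stability into
#' one `validation_report` object from the tables produced by
#' [generate_validation_batches()] (or equivalently shaped real data).
#'
#' @param qc Precision/accuracy replicate table (see
#'   [assess_precision_accuracy()]).
#' @param recovery_tbl Optional `data.frame` with columns `compound`,
#'   `tissue`, `level`, `nominal`, `extracted_area`, `spiked_area`,
#'   `neat_area` (one row per replicate).
#' @param stability_tbl Optional stability replicate table (see
#'   [stability_re()]).
#' @inheritParams assess_precision_accuracy
#' @return A `validation_report`: list of data.frames
#'   `precision_accuracy`, `recovery_matrix`, `stability` (the latter two
#'   `NULL` when their inputs are absent), plus the thresholds used.
#' @export
assess <- function(qc, recovery_tbl = NULL, stability_tbl = NULL,
                   re_limit = 15, rsd_limit = 15, lloq_limit = 20) {
  pa <- assess_precision_accuracy(qc, re_limit, rsd_limit, lloq_limit)
  rec <- NULL
  if (!is.null(recovery_tbl)) {
    keys <- unique(recovery_tbl[, c("compound", "tissue", "level", "nominal")])
    rows <- vector("list", nrow(keys))
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      sub <- recovery_tbl[recovery_tbl$compound == k$compound &
                            recovery_tbl$tissue == k$tissue &
                            recovery_tbl$level == k$level &
                            recovery_tbl$nominal == k$nominal, ]
      rc <- recovery(sub$extracted_area, sub$neat_area)
      me <- matrix_effect(sub$spiked_area, sub$neat_area)
      rows[[i]] <- data.frame(
        compound = k$compound, tissue = k$tissue, level = k$level,
        nominal = k$nominal,
        recovery = rc$percent, recovery_sd = rc$sd, recovery_rsd = rc$rsd,
        matrix_effect = me$percent, matrix_effect_sd = me$sd,
        matrix_effect_rsd = me$rsd, stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    rec <- rec[order(rec$compound, rec$tissue, rec$nominal), , drop = FALSE]
  }
  stab <- if (!is.null(stability_tbl))
    stability_re(stability_tbl, re_limit = re_limit) else NULL
  structure(list(precision_accuracy = pa, recovery_matrix = rec,
                 stability = stab,
                 thresholds = c(re = re_limit, rsd = rsd_limit,
                                lloq = lloq_limit)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  pa <- x$precision_accuracy
  cat(sprintf("Method validation report: %d compound x tissue x level rows, %d pass / %d fail\n",
              nrow(pa), sum(pa$pass), sum(!pa$pass)))
  if (!is.null(x$recovery_matrix))
    cat(sprintf("  recovery %.1f-%.1f %%, matrix effect %.1f-%.1f %%\n",
                min(x$recovery_matrix$recovery),
                max(x$recovery_matrix$recovery),
                min(x$recovery_matrix$matrix_effect),
                max(x$recovery_matrix$matrix_effect)))
  if (!is.null(x$stability))
    cat(sprintf("  stability: %d/%d condition cells within +/-%g %%\n",
                sum(x$stability$pass), nrow(x$stability), x$thresholds["re"]))
  invisible(x)
}

#' Write a validation report to CSV files
#'
#' Emits `precision_accuracy.csv`, and when present `recovery_matrix.csv`
#' and `stability.csv`, into `dir`.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("precision_accuracy", "recovery_matrix", "stability")) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
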