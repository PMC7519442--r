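#' Convert study peak records into concentration-time profiles
#'
#' Each study injection's analyte/IS area ratio is back-calculated through
#' the matching compound-tissue calibration curve; per-animal concentrations
#' are then summarised into mean, SD and n per compound x tissue x group x
#' time point. Values flagged below the LLOQ are handled by the censoring
#' policy; values above the calibrated range are kept but counted and
#' reported via the `above_range` attribute, never silently extrapolated
#' away.
#'
#' Sexes are pooled within a group for shared organs (n = 6 per point with
#' the default design); sex-specific organs only ever receive samples from
#' the relevant sex (n = 3). `per_sex = TRUE` instead summarises each sex
#' separately.
#'
#' @param records Validated study peak records (see [read_peak_table()];
#'   rows with `sample_kind != "study"` are ignored).
#' @param curves Named list of [calibration_curve()] objects keyed
#'   `"compound|tissue"` as produced by [reference_curves()] or
#'   [read_curve_table()].
#' @param design A [study_design()].
#' @param policy Censoring policy for below-LLOQ values: `"zero"` (default;
#'   conservative for AUC), `"lloq2"` (impute LLOQ/2), or `"drop"`.
#' @param per_sex Summarise per sex instead of pooling.
#' @return An object of class `concentration_profiles`: list with
#'   `profiles` (`compound,tissue,group[,sex],time_min,mean,sd,n,gap`) and
#'   `animals` (long per-animal table with `conc` and `flag`), plus the
#'   policy used. Attribute `above_range` counts flagged records.
#' @export
quantify_study <- function(records, curves, design,
                           policy = c("zero", "lloq2", "drop"),
                           per_sex = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(design, "study_design"))
  st <- records[records$sample_kind == "study", , drop = FALSE]
  if (nrow(st) == 0L)
    stop("no study records to quantify", call. = FALSE)
  keys <- unique(curve_key(st$compound, st$tissue))
  missing <- setdiff(keys, names(curves))
  if (length(missing) > 0L)
    stop("no calibration curve for: ", paste(missing, collapse = ", "),
         call. = FALSE)

  st$ratio <- st$analyte_area / st$is_area
  st$conc <- NA_real_
  st$flag <- NA_character_
  for (key in keys) {
    idx <- curve_key(st$compound, st$tissue) == key
    bc <- back_calculate(curves[[key]], st$ratio[idx])
    st$conc[idx] <- bc$conc
    st$flag[idx] <- bc$flag
  }
  n_above <- sum(st$flag == "above_range")

  st$used <- st$conc
  below <- st$flag == "below_lloq"
  if (policy == "zero") {
    st$used[below] <- 0
  } else if (policy == "lloq2") {
    lloqs <- vapply(curves[curve_key(st$compound, st$tissue)],
                    function(cv) cv$lloq, numeric(1))
    st$used[below] <- lloqs[below] / 2
  } else {
    st$used[below] <- NA_real_
  }

  grp_cols <- c("compound", "tissue", "group",
                if (per_sex) "sex", "time_min")
  split_key <- interaction(st[grp_cols], drop = TRUE, lex.order = TRUE)
  pieces <- split(st, split_key)
  rows <- lapply(pieces, function(p) {
    v <- p$used[!is.na(p$used)]
    out <- p[1, grp_cols, drop = FALSE]
    out$mean <- if (length(v) > 0L) mean(v) else NA_real_
    out$sd <- if (length(v) > 1L) stats::sd(v) else
      if (length(v) == 1L) 0 else NA_real_
    out$n <- length(v)
    out$gap <- length(v) == 0L
    out
  })
  profiles <- do.call(rbind, rows)
  profiles <- profiles[order(profiles$compound, profiles$tissue,
                             profiles$group, profiles$time_min), ,
                       drop = FALSE]
  rownames(profiles) <- NULL
  if (any(profiles$gap))
    warning(sum(profiles$gap),
            " profile point(s) have n = 0 after censoring", call. = FALSE)

  animals <- st[, c("compound", "tissue", "group", "sex", "animal_id",
                    "time_min", "conc", "flag", "used")]
  rownames(animals) <- NULL
  out <- structure(list(profiles = profiles, animals = animals,
                        policy = policy, per_sex = per_sex),
                   class = "concentration_profiles")
  attr(out, "above_range") <- n_above
  out
}

#' @export
print.concentration_profiles <- function(x, ...) {
  p <- x$profiles
  cat(sprintf("Concentration profiles: %d compound(s) x %d tissue(s) x %d group(s), %d points\n",
              length(unique(p$compound)), length(unique(p$tissue)),
              length(unique(p$group)), nrow(p)))
  cat(sprintf("  censoring policy: %s; %d record(s) above calibrated range\n",
              x$policy, attr(x, "above_range")))
  invisible(x)
}

#' Write concentration profiles to CSV
#'
#' Writes the summary profile table (`profiles.csv`) and the long
#' per-animal table (`profiles_animals.csv`).
#'
#' @param profiles A `concentration_profiles` object.
#' @param dir Output directory (created if needed).
#' @return Written paths, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  stopifnot(inherits(profiles, "concentration_profiles"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "profiles.csv")
  p2 <- file.path(dir, "profiles_animals.csv")
  pr <- profiles$profiles
  names(pr)[names(pr) == "mean"] <- "mean_ng_ml"
  names(pr)[names(pr) == "sd"] <- "sd_ng_ml"
  utils::write.csv(pr, p1, row.names = FALSE)
  utils::write.csv(profiles$animals, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
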