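#' Fit a weighted linear calibration curve
#'
#' Calibration of LC-MS/MS peak-area ratios against spiked concentration is
#' performed by weighted linear least squares with weights \eqn{w_i = 1/x_i^2}
#' (the bioanalytical convention: it equalises the *relative* error across a
#' range spanning three orders of magnitude, so the low end of the curve is
#' not drowned out by the high standards). The model is
#' \deqn{y = a x + b, \quad \min_a{}_b \sum_i w_i (y_i - a x_i - b)^2}
#' with `y` the analyte/IS area ratio and `x` the nominal concentration in
#' ng/mL. The reported correlation coefficient `r` is the weighted Pearson
#' correlation computed with the same weights.
#'
#' @param x Nominal concentrations (ng/mL); all must be > 0, at least three
#'   distinct values.
#' @param y Analyte/IS area ratios, same length as `x`.
#' @param compound,tissue Identifiers stored on the curve.
#' @param weighting `"1/x^2"` (default) or `"none"` for ordinary least
#'   squares.
#' @param lloq Lower limit of quantification in ng/mL. Defaults to the
#'   lowest calibration level, the operational convention when quantifying
#'   study samples (the signal-to-noise procedure in
#'   [estimate_lloq_llod()] serves method development).
#' @param llod Lower limit of detection in ng/mL, if known (default `NA`).
#'
#' @return An object of class `calibration_curve`: a list with elements
#'   `compound`, `tissue`, `slope`, `intercept`, `r`, `range_low`,
#'   `range_high`, `lloq`, `llod`, `weighting`, `n`.
#' @examples
#' cal <- fit_weighted_linear(c(1, 10, 100, 1000),
#'                            0.005 * c(1, 10, 100, 1000) + 0.02)
#' cal$slope     # 0.005
#' cal$r         # 1
#' @export
fit_weighted_linear <- function(x, y, compound = NA_character_,
                                tissue = NA_character_,
                                weighting = c("1/x^2", "none"),
                                lloq = NULL, llod = NA_real_) {
  weighting <- match.arg(weighting)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite calibration point", call. = FALSE)
  if (any(x <= 0))
    stop("calibration concentrations must be > 0", call. = FALSE)
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct concentration levels", call. = FALSE)
  w <- if (weighting == "1/x^2") 1 / x^2 else rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2)
  if (sxx <= 0) stop("degenerate design: zero weighted variance in x",
                     call. = FALSE)
  sxy <- sum(w * (x - mx) * (y - my))
  syy <- sum(w * (y - my)^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r <- if (syy <= 0) {
    # flat responses: correlation undefined; report 0
    0
  } else sxy / sqrt(sxx * syy)
  rng <- range(x)
  calibration_curve(compound = compound, tissue = tissue, slope = slope,
                    intercept = intercept, r = r,
                    range_low = rng[1], range_high = rng[2],
                    lloq = if (is.null(lloq)) rng[1] else lloq,
                    llod = llod, weighting = weighting, n = length(x))
}

#' Construct a calibration curve from known coefficients
#'
#' Used both by [fit_weighted_linear()] and to instantiate published curve
#' parameters (see [reference_curves()]).
#'
#' @inheritParams fit_weighted_linear
#' @param slope,intercept Line coefficients (area ratio per ng/mL; area
#'   ratio).
#' @param r Correlation coefficient.
#' @param range_low,range_high Validated linear range (ng/mL).
#' @param n Number of calibration points behind the fit (`NA` if unknown).
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(compound, tissue, slope, intercept, r = NA_real_,
                              range_low, range_high, lloq = range_low,
                              llod = NA_real_, weighting = "1/x^2",
                              n = NA_integer_) {
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  if (range_low > range_high) stop("range_low > range_high", call. = FALSE)
  structure(list(compound = compound, tissue = tissue,
                 slope = slope, intercept = intercept, r = r,
                 range_low = range_low, range_high = range_high,
                 lloq = lloq, llod = llod, weighting = weighting,
                 n = n),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve %s / %s\n",
              x$compound, x$tissue))
  cat(sprintf("  Y = %.4g X + %.4g   (r = %s, weighting %s)\n", x$slope,
              x$intercept, formatC(x$r, format = "f", digits = 4),
              x$weighting))
  cat(sprintf("  range %g-%g ng/mL, LLOQ %g ng/mL\n", x$range_low,
              x$range_high, x$lloq))
  invisible(x)
}

#' Predicted area ratio at a concentration
#' @param curve A `calibration_curve`.
#' @param x Concentration(s), ng/mL.
#' @return Area ratio(s) `slope * x + intercept`.
#' @export
predict_response <- function(curve, x) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * x + curve$intercept
}

#' Back-calculate concentration from an area ratio
#'
#' Inverts the calibration line: `x = (y - intercept) / slope`. Values are
#' never clamped; instead each is flagged `below_lloq` (including negative
#' inversions), `above_range`, or `in_range`, and the censoring policy is
#' applied downstream (see [quantify_study()]).
#'
#' @param curve A `calibration_curve`.
#' @param y Area ratio(s).
#' @return A `data.frame` with columns `conc` (ng/mL) and `flag`.
#' @examples
#' cal <- calibration_curve("psoralen", "kidney", slope = 3.44e-3,
#'                          intercept = 1.21e-1, range_low = 2,
#'                          range_high = 1000)
#' back_calculate(cal, 0.465)  # 100 ng/mL, in range
#' @export
back_calculate <- function(curve, y) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (y - curve$intercept) / curve$slope
  flag <- rep("in_range", length(conc))
  flag[conc > curve$range_high] <- "above_range"
  flag[conc < curve$lloq] <- "below_lloq"
  data.frame(conc = conc, flag = flag, stringsAsFactors = FALSE)
}

#' Signal-to-noise based LLOQ and LLOD
#'
#' The limit of quantification is the lowest candidate level whose predicted
#' net signal reaches ten times the blank noise (S/N >= 10); the limit of
#' detection uses S/N >= 3. The net signal of a level is `slope * level`
#' (the intercept is baseline and contributes to neither signal nor noise).
#'
#' @param blank_noise Noise amplitude of the blank, on the area-ratio scale;
#'   must be > 0.
#' @param curve A `calibration_curve`.
#' @param candidate_levels Candidate concentrations (ng/mL), sorted
#'   ascending.
#' @return A list with `lloq`, `llod` (ng/mL, `NA` when no level qualifies)
#'   and logical `lloq_determined`, `llod_determined`.
#' @export
estimate_lloq_llod <- function(blank_noise, curve, candidate_levels) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(blank_noise) || blank_noise <= 0)
    stop("blank_noise must be > 0", call. = FALSE)
  if (is.unsorted(candidate_levels, strictly = TRUE))
    stop("candidate_levels must be sorted strictly ascending", call. = FALSE)
  sn <- curve$slope * candidate_levels / blank_noise
  pick <- function(threshold) {
    ok <- which(sn >= threshold)
    if (length(ok) == 0L) NA_real_ else candidate_levels[min(ok)]
  }
  lloq <- pick(10)
  llod <- pick(3)
  list(lloq = lloq, llod = llod,
       lloq_determined = !is.na(lloq), llod_determined = !is.na(llod))
}

#' Published reference calibration curves
#'
#' Loads the packaged table of curve parameters (slope, intercept, r, linear
#' range, LLOQ) for the 12 study compounds in each of the 8 tissues, as a
#' named list of `calibration_curve` objects keyed `"compound|tissue"`.
#' These serve as the forward model for the synthetic-study generator and as
#' fixtures for the quantification stage.
#'
#' @param path CSV of curve parameters; defaults to the packaged table.
#' @return Named list of `calibration_curve` objects.
#' @export
reference_curves <- function(path = system.file("extdata",
                                                "reference_curves.csv",
                                                package = "tissuerte",
                                                mustWork = TRUE)) {
  read_curve_table(path)
}

#' Write / read a curve table
#'
#' CSV with columns `compound,tissue,slope,intercept,r,range_low,range_high,
#' lloq,llod`; coefficients are kept at full precision on write.
#'
#' @param curves Named list of `calibration_curve` objects.
#' @param path CSV path.
#' @return `write_curve_table()`: `path` invisibly. `read_curve_table()`:
#'   named list of curves keyed `"compound|tissue"`.
#' @export
write_curve_table <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(compound = cv$compound, tissue = cv$tissue, slope = cv$slope,
               intercept = cv$intercept, r = cv$r, range_low = cv$range_low,
               range_high = cv$range_high, lloq = cv$lloq, llod = cv$llod,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_curve_table
#' @export
read_curve_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("compound", "tissue", "slope", "intercept", "range_low",
              "range_high")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("curve table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(df$r)) df$r <- NA_real_
  if (is.null(df$lloq)) df$lloq <- df$range_low
  if (is.null(df$llod)) df$llod <- NA_real_
  curves <- vector("list", nrow(df))
  for (i in seq_len(nrow(df)))
    curves[[i]] <- calibration_curve(df$compound[i], df$tissue[i],
                                     df$slope[i], df$intercept[i], df$r[i],
                                     df$range_low[i], df$range_high[i],
                                     df$lloq[i], df$llod[i])
  names(curves) <- paste(df$compound, df$tissue, sep = "|")
  curves
}

#' @keywords internal
curve_key <- function(compound, tissue) paste(compound, tissue, sep = "|")
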