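#' Kinetic ground truth for a synthetic tissue-distribution study
#'
#' The generator needs a plausible rise-and-fall concentration shape over
#' the 10-720 min sampling window; a one-compartment extravascular model
#' \deqn{C(t) = scale \,(e^{-k_e t} - e^{-k_a t}), \qquad k_a > k_e > 0}
#' provides it with an analytic AUC to infinity of
#' \eqn{scale\,(1/k_e - 1/k_a)}. This is a simulation device with known
#' truth, not a physiological claim. Defaults: absorption half-life about
#' 23 min (`ka = 0.03`), elimination half-life about 87 min
#' (`ke = 0.008`), peak near 60 min, and late concentrations that fall
#' below typical LLOQs so the censoring policy is actually exercised.
#'
#' Variability is multiplicative lognormal (concentrations are positive and
#' bioanalytical CVs are relative): a between-animal multiplier
#' (`cv_between`, default 0.15 — within the 10-30 % inter-individual range
#' typical of rodent tissue kinetics, and low enough that with 6 animals
#' per point the null-case RTE noise floor stays under the 0.05 design
#' criterion) and an analytical multiplier (`cv_analytical`, default 0.05,
#' the mid-range assay RSD of a validated LC-MS/MS method). Both lognormals
#' are mean-1.
#'
#' `salt_shift` injects a targeting effect: a named per-tissue multiplier
#' applied to `scale` in the salt-processed group only, so the expected RTE
#' sign per tissue is known by construction.
#'
#' @param compounds Character vector of compound identifiers.
#' @param design A [study_design()].
#' @param ka,ke Absorption and elimination rate constants, 1/min.
#' @param tissue_scale Named numeric: per-tissue `scale` (ng/mL); tissues
#'   missing from the vector fall back to `default_scale`.
#' @param default_scale Fallback `scale`, ng/mL.
#' @param salt_shift Named numeric per-tissue multiplier for the
#'   salt-processed group (default none = null effect).
#' @param cv_between,cv_analytical Lognormal coefficients of variation, in
#'   `[0, 1)`.
#' @param content_crude,content_salt Per-compound extract contents (mass per
#'   g of extract), recycled across `compounds`; used by the content
#'   normalization stage.
#' @return An object of class `sim_truth`: list with a `kinetics`
#'   data.frame (compound, tissue, group, ka, ke, scale, auc_inf), a
#'   `contents` data.frame, and the CVs.
#' @export
sim_truth <- function(compounds, design = study_design(),
                      ka = 0.03, ke = 0.008,
                      tissue_scale = c(heart = 200, liver = 600,
                                       spleen = 250, lung = 300,
                                       kidney = 700, uterus = 150,
                                       ovary = 150, testes = 150),
                      default_scale = 300,
                      salt_shift = NULL,
                      cv_between = 0.15, cv_analytical = 0.05,
                      content_crude = 1, content_salt = 1) {
  stopifnot(inherits(design, "study_design"))
  if (!(ka > ke && ke > 0))
    stop("need ka > ke > 0", call. = FALSE)
  if (cv_between < 0 || cv_between >= 1 || cv_analytical < 0 ||
      cv_analytical >= 1)
    stop("CVs must lie in [0, 1)", call. = FALSE)
  grid <- expand.grid(compound = compounds, tissue = design$tissues,
                      group = design$groups, stringsAsFactors = FALSE)
  sc <- tissue_scale[grid$tissue]
  sc[is.na(sc)] <- default_scale
  if (!is.null(salt_shift)) {
    mult <- salt_shift[grid$tissue]
    mult[is.na(mult)] <- 1
    sc <- sc * ifelse(grid$group == design$groups[2], mult, 1)
  }
  grid$ka <- ka; grid$ke <- ke; grid$scale <- as.numeric(sc)
  grid$auc_inf <- grid$scale * (1 / ke - 1 / ka)
  contents <- data.frame(compound = compounds,
                         content_crude = rep_len(content_crude,
                                                 length(compounds)),
                         content_salt = rep_len(content_salt,
                                                length(compounds)),
                         stringsAsFactors = FALSE)
  structure(list(kinetics = grid, contents = contents,
                 cv_between = cv_between, cv_analytical = cv_analytical),
            class = "sim_truth")
}

#' True concentration of the simulation model
#' @param truth A `sim_truth`.
#' @param compound,tissue,group Cell selector.
#' @param t Times, minutes.
#' @return C(t), ng/mL.
#' @export
true_concentration <- function(truth, compound, tissue, group, t) {
  k <- truth$kinetics
  i <- which(k$compound == compound & k$tissue == tissue & k$group == group)
  if (length(i) != 1L) stop("no unique truth cell", call. = FALSE)
  k$scale[i] * (exp(-k$ke[i] * t) - exp(-k$ka[i] * t))
}

#' @keywords internal
lognormal_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic two-group destructive-sampling study
#'
#' Emits a full study peak table: for every compound, tissue (restricted to
#' the matching sex), time point, group and animal, the true concentration
#' is perturbed by the between-animal and analytical lognormal multipliers
#' and pushed through the forward calibration line to produce analyte and
#' IS areas. The IS area is fixed at 1e5 counts; analyte areas are floored
#' at zero (a negative predicted ratio is a blank-level signal). The output
#' is deterministic given `seed`.
#'
#' @param design A [study_design()].
#' @param truth A [sim_truth()] covering every compound x tissue x group.
#' @param curves Calibration curves keyed `"compound|tissue"`; every truth
#'   compound/tissue must have one.
#' @param seed Integer RNG seed (`NULL` = use current RNG state).
#' @return A peak-record `data.frame` (`sample_kind = "study"`). Points
#'   whose true concentration exceeds the curve's calibrated range are
#'   counted in a warning.
#' @export
generate_study <- function(design, truth, curves, seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "sim_truth"))
  compounds <- unique(truth$kinetics$compound)
  keys <- curve_key(rep(compounds, each = length(design$tissues)),
                    rep(design$tissues, length(compounds)))
  missing <- setdiff(unique(keys), names(curves))
  if (length(missing) > 0L)
    stop("no calibration curve for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  with_seed(seed, {
    n <- design$animals_per_point_per_group
    animal_sex <- rep(c("M", "F"), length.out = n)
    rows <- list()
    saturated <- 0L
    for (grp in design$groups) {
      for (ti in seq_along(design$time_points_min)) {
        tp <- design$time_points_min[ti]
        ids <- sprintf("%s_t%d_a%d", grp, ti, seq_len(n))
        for (cp in compounds) {
          for (tis in design$tissues) {
            ok_sex <- sexes_for_tissue(design, tis)
            use <- animal_sex %in% ok_sex
            if (!any(use)) next
            ct <- true_concentration(truth, cp, tis, grp, tp)
            m <- sum(use)
            conc <- ct * lognormal_mult(m, truth$cv_between) *
              lognormal_mult(m, truth$cv_analytical)
            cv <- curves[[curve_key(cp, tis)]]
            saturated <- saturated + sum(conc > cv$range_high)
            ratio <- pmax(predict_response(cv, conc), 0)
            rows[[length(rows) + 1L]] <- data.frame(
              compound = cp, tissue = tis, sample_kind = "study",
              nominal_conc = NA_real_, time_min = tp,
              animal_id = ids[use], sex = animal_sex[use], group = grp,
              analyte_area = ratio * 1e5, is_area = 1e5,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (saturated > 0L)
      warning(saturated,
              " simulated point(s) exceed the calibrated range",
              call. = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Expected record count of a generated study
#'
#' Combinatorial prediction used as a generator invariant:
#' compounds x tissues (sex-adjusted animal counts) x time points x groups.
#'
#' @param design A [study_design()].
#' @param n_compounds Number of compounds.
#' @return Integer record count.
#' @export
expected_study_records <- function(design, n_compounds) {
  per_tissue <- vapply(design$tissues, function(tt)
    animals_for_tissue(design, tt), integer(1))
  n_compounds * sum(per_tissue) * length(design$time_points_min) *
    length(design$groups)
}

#' Generate synthetic method-validation batches
#'
#' Builds the three QC tables consumed by [assess()]:
#' \itemize{
#'   \item precision/accuracy: `n_reps` replicates x `n_days` days at four
#'     levels (LLOQ plus low/mid/high, placed at 2.5x LLOQ, 0.5x and 0.8x
#'     the upper range limit — the conventional QC placement);
#'   \item recovery/matrix effect: paired extracted / post-extraction
#'     spiked / neat areas at low/mid/high, with mean recovery
#'     `recovery_mean` and mean matrix factor `matrix_mean`;
#'   \item stability: `n_reps` replicates per condition x level with a
#'     condition-specific multiplicative bias (e.g. `freeze_thaw = -0.02`
#'     for a 2 % loss).
#' }
#' All measurement noise is mean-1 lognormal with CV `cv`.
#'
#' @param curves Calibration curves keyed `"compound|tissue"`; one batch
#'   set is generated per curve.
#' @param cv Analytical CV of a single replicate.
#' @param recovery_mean,matrix_mean True mean recovery and matrix factor
#'   (fractions).
#' @param stability_bias Named numeric, fractional bias per condition.
#' @param n_reps,n_days Replication structure.
#' @param seed Integer RNG seed.
#' @return List of data.frames `qc`, `recovery`, `stability` (see
#'   [assess()] for their columns).
#' @export
generate_validation_batches <- function(curves, cv = 0.05,
                                        recovery_mean = 0.88,
                                        matrix_mean = 0.93,
                                        stability_bias = c(freeze_thaw = -0.02,
                                                           short_term = -0.01,
                                                           long_term = -0.03,
                                                           preinjection = -0.01),
                                        n_reps = 6L, n_days = 3L,
                                        seed = NULL) {
  with_seed(seed, {
    qc <- list(); rec <- list(); stab <- list()
    for (cvr in curves) {
      levels <- c(lloq = cvr$lloq, low = 2.5 * cvr$lloq,
                  mid = 0.5 * cvr$range_high, high = 0.8 * cvr$range_high)
      for (lv in names(levels)) {
        nominal <- levels[[lv]]
        for (d in seq_len(n_days)) {
          qc[[length(qc) + 1L]] <- data.frame(
            compound = cvr$compound, tissue = cvr$tissue, level = lv,
            nominal = nominal, day = d,
            value = nominal * lognormal_mult(n_reps, cv),
            stringsAsFactors = FALSE)
        }
        if (lv != "lloq") {
          neat <- predict_response(cvr, nominal) *
            lognormal_mult(n_reps, cv)
          rec[[length(rec) + 1L]] <- data.frame(
            compound = cvr$compound, tissue = cvr$tissue, level = lv,
            nominal = nominal,
            extracted_area = recovery_mean * predict_response(cvr, nominal) *
              lognormal_mult(n_reps, cv),
            spiked_area = matrix_mean * predict_response(cvr, nominal) *
              lognormal_mult(n_reps, cv),
            neat_area = neat, stringsAsFactors = FALSE)
          for (cond in names(stability_bias)) {
            stab[[length(stab) + 1L]] <- data.frame(
              compound = cvr$compound, tissue = cvr$tissue, level = lv,
              nominal = nominal, condition = cond,
              value = nominal * (1 + stability_bias[[cond]]) *
                lognormal_mult(n_reps, cv),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(qc = do.call(rbind, qc), recovery = do.call(rbind, rec),
         stability = do.call(rbind, stab))
  })
}

#' Generate noisy calibration responses from a known line
#'
#' Produces area ratios at the given levels from the forward model of
#' `curve` with mean-1 lognormal noise, for exercising
#' [fit_weighted_linear()] against a known truth.
#'
#' @param curve A `calibration_curve` (the generating truth).
#' @param levels Concentrations, ng/mL.
#' @param cv Relative noise of each response.
#' @param seed Integer RNG seed.
#' @return `data.frame` with `x` and `y`.
#' @export
generate_calibration_points <- function(curve, levels, cv = 0.03,
                                        seed = NULL) {
  with_seed(seed,
    data.frame(x = levels,
               y = predict_response(curve, levels) *
                 lognormal_mult(length(levels), cv)))
}
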