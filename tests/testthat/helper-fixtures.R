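# Shared fixtures and independent oracles. Everything is built in code;
# no binary fixtures.

# the published kidney curve used as a recurring numeric anchor
kidney_psoralen <- function() {
  calibration_curve("psoralen", "kidney", slope = 3.44e-3,
                    intercept = 1.21e-1, r = 0.9996,
                    range_low = 2, range_high = 1000, lloq = 2)
}

# independent WLS oracle: solve the 2x2 weighted normal equations directly
wls_oracle <- function(x, y, w) {
  s0 <- sum(w); s1 <- sum(w * x); s2 <- sum(w * x^2)
  t0 <- sum(w * y); t1 <- sum(w * x * y)
  sol <- solve(matrix(c(s2, s1, s1, s0), 2), c(t1, t0))
  list(slope = sol[1], intercept = sol[2])
}

# independent AUC oracle: adaptive quadrature of the linear interpolant
auc_oracle <- function(times, means) {
  f <- stats::approxfun(c(0, times), c(0, means))
  stats::integrate(f, 0, max(times), subdivisions = 2000L,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# a truth whose concentrations stay inside the psoralen calibrated ranges
# and above every LLOQ at all seven design points (no censoring, for
# identity/unbiasedness checks): C(720) = scale * 0.0555 >= 8 ng/mL
uncensored_truth <- function(design, ...) {
  sim_truth("psoralen", design, ka = 0.03, ke = 0.004,
            tissue_scale = c(heart = 200, liver = 600, spleen = 250,
                             lung = 300, kidney = 700, uterus = 150,
                             ovary = 150, testes = 150), ...)
}

# single-tissue design for cheap repeated simulation
mini_design <- function() {
  study_design(tissues = "kidney", sex_specific = c(kidney = "both"))
}

# hand-built auc_result for compare_groups arithmetic checks
fake_auc <- function(auc, se, df = Inf, compound = "x", tissue = "kidney",
                     group = "g") {
  structure(list(compound = compound, tissue = tissue, group = group,
                 auc = auc, se = se, df = df, n_points = 7L,
                 method = "linear trapezoid, sparse"),
            class = "auc_result")
}

# minimal valid study record
study_row <- function(compound = "psoralen", tissue = "kidney",
                      time_min = 10, animal_id = "a1", sex = "M",
                      group = "crude", analyte_area = 100,
                      is_area = 1e5) {
  data.frame(compound = compound, tissue = tissue, sample_kind = "study",
             nominal_conc = NA_real_, time_min = time_min,
             animal_id = animal_id, sex = sex, group = group,
             analyte_area = analyte_area, is_area = is_area,
             stringsAsFactors = FALSE)
}
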