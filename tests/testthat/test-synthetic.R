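test_that("generation is deterministic under a fixed seed", {
  design <- load_design()
  curves <- reference_curves()
  truth <- uncensored_truth(design)
  p1 <- generate_study(design, truth, curves, seed = 99)
  p2 <- generate_study(design, truth, curves, seed = 99)
  expect_identical(p1, p2)
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(p1, t1)
  write_peak_table(p2, t2)
  expect_identical(readLines(t1), readLines(t2))
  p3 <- generate_study(design, truth, curves, seed = 100)
  expect_false(identical(p1$analyte_area, p3$analyte_area))
  # the caller's RNG stream is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_study(mini_design(),
                                        uncensored_truth(mini_design()),
                                        curves, seed = 7))
  expect_identical(stats::runif(1), before)
})

test_that("record counts match the combinatorial prediction", {
  design <- load_design()
  curves <- reference_curves()
  for (cps in list("psoralen", c("psoralen", "isopsoralen"))) {
    truth <- sim_truth(cps, design)
    peaks <- suppressWarnings(generate_study(design, truth, curves,
                                             seed = 12))
    expect_equal(nrow(peaks), expected_study_records(design, length(cps)))
  }
})

test_that("zero-CV pipeline recovers the discretized closed-form AUC", {
  design <- load_design()
  curves <- reference_curves()
  truth <- uncensored_truth(design, cv_between = 0, cv_analytical = 0)
  peaks <- generate_study(design, truth, curves, seed = 4)
  tab <- auc_table(quantify_study(peaks, curves, design))
  tp <- design$time_points_min
  for (i in seq_len(nrow(tab))) {
    ct <- true_concentration(truth, tab$compound[i], tab$tissue[i],
                             tab$group[i], tp)
    expect_equal(tab$auc[i], auc_trapezoid(tp, ct)$auc, tolerance = 1e-9)
    expect_equal(tab$se[i], 0)
  }
  # and the discretized trapezoid undershoots the analytic AUC to infinity
  k <- truth$kinetics[1, ]
  expect_lt(auc_trapezoid(tp, true_concentration(
    truth, k$compound, k$tissue, k$group, tp))$auc, k$auc_inf)
})

test_that("sim_truth validates its kinetic parameters", {
  expect_error(sim_truth("x", ka = 0.001, ke = 0.01), "ka > ke")
  expect_error(sim_truth("x", cv_between = 1.2), "CVs")
  tr <- sim_truth("x", ka = 0.03, ke = 0.008, default_scale = 100,
                  tissue_scale = c(kidney = 500))
  expect_equal(unique(tr$kinetics$auc_inf[tr$kinetics$tissue == "kidney"]),
               500 * (1 / 0.008 - 1 / 0.03))
})

test_that("an injected stability bias is recovered by stability_re", {
  cv <- reference_curves()["psoralen|kidney"]
  val <- generate_validation_batches(cv, cv = 0.02,
                                     stability_bias = c(freeze_thaw = -0.02,
                                                        short_term = 0,
                                                        long_term = -0.05,
                                                        preinjection = 0),
                                     n_reps = 24L, seed = 31)
  out <- stability_re(val$stability)
  ft <- out$re[out$condition == "freeze_thaw"]
  expect_equal(mean(ft), -2, tolerance = 0.5)
  lt <- out$re[out$condition == "long_term"]
  expect_equal(mean(lt), -5, tolerance = 0.3)
  expect_true(all(out$pass))
})

test_that("intra-day RSD tracks the generating CV across repeated batches", {
  cv <- reference_curves()["psoralen|kidney"]
  # generating CV matched to the published low-level intra-day RSD 5.46 %
  rsds <- vapply(1:60, function(i) {
    val <- generate_validation_batches(cv, cv = 0.0546, n_days = 1L,
                                       seed = 1000 + i)
    qc <- val$qc[val$qc$level == "low", ]
    rsd(qc$value)
  }, numeric(1))
  expect_lt(abs(mean(rsds) - 5.46), 2)
})

test_that("end-to-end AUC is unbiased within Monte-Carlo error", {
  design <- mini_design()
  curves <- reference_curves()
  truth <- uncensored_truth(design)
  tp <- design$time_points_min
  target <- auc_trapezoid(tp, true_concentration(truth, "psoralen",
                                                 "kidney", "crude", tp))$auc
  est <- vapply(1:200, function(i) {
    peaks <- generate_study(design, truth, curves, seed = 5000 + i)
    tab <- auc_table(quantify_study(peaks, curves, design))
    tab$auc[tab$group == "crude"]
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 3 * mc_se + 0.002 * target)
})
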