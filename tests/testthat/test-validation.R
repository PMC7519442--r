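test_that("relative error reproduces printed accuracy cells", {
  # measured means / nominals from the published kidney QC table
  expect_equal(round(relative_error(247.43, 250), 2), -1.03)
  expect_equal(round(relative_error(490.30, 500), 2), -1.94)
  expect_equal(round(relative_error(956.47, 1000), 2), -4.35)
  expect_equal(round(relative_error(46.32, 50), 2), -7.36)
  expect_equal(relative_error(500, 500), 0)
  expect_error(relative_error(1, 0), "> 0")
})

test_that("relative error is antisymmetric in over/under-recovery", {
  nom <- c(5, 50, 500)
  delta <- c(0.3, 1.2, 11)
  expect_equal(relative_error(nom + delta, nom),
               -relative_error(nom - delta, nom), tolerance = 1e-12)
})

test_that("rsd reproduces printed precision cells and is scale-invariant", {
  expect_equal(round(rsd_from_summary(85.67, 5.13), 2), 5.99)
  expect_equal(round(rsd_from_summary(93.42, 8.77), 2), 9.39)
  expect_equal(round(rsd_from_summary(88.99, 1.58), 2), 1.78)
  expect_equal(round(rsd_from_summary(94.20, 4.04), 2), 4.29)
  expect_equal(rsd(c(7, 7, 7)), 0)
  set.seed(201)
  v <- stats::rlnorm(10, 2, 0.2)
  for (c in c(0.1, 3, 1000))
    expect_equal(rsd(c * v), rsd(v), tolerance = 1e-12)
  expect_error(rsd(5), ">= 2")
  expect_error(rsd(c(-1, 1)), "mean is zero")
})

test_that("recovery and matrix effect behave as paired area ratios", {
  a <- c(100, 110, 95, 105)
  expect_equal(recovery(a, a)$percent, 100)
  expect_equal(matrix_effect(a, a)$percent, 100)
  expect_equal(recovery(a, a)$sd, 0)
  r <- recovery(0.9 * a, a)
  expect_equal(r$percent, 90, tolerance = 1e-12)
  expect_equal(r$sd, 0, tolerance = 1e-12)
  expect_equal(matrix_effect(0.95 * a, a)$percent, 95, tolerance = 1e-12)
  expect_error(recovery(numeric(0), a), "empty")
  expect_error(recovery(a, c(1, -1)), "zero")
})

test_that("synthetic batches recover the generating recovery/matrix truth", {
  cv <- reference_curves()["psoralen|kidney"]
  # generator pinned to the published low-level kidney values
  val <- generate_validation_batches(cv, cv = 0.07, recovery_mean = 0.8798,
                                     matrix_mean = 0.9420, n_reps = 60L,
                                     seed = 321)
  low <- val$recovery[val$recovery$level == "low", ]
  r <- recovery(low$extracted_area, low$neat_area)
  m <- matrix_effect(low$spiked_area, low$neat_area)
  expect_equal(r$percent, 87.98, tolerance = 0.05)  # 5 % relative
  expect_equal(m$percent, 94.20, tolerance = 0.05)
})

test_that("stability RE reproduces printed cells and flags conditions", {
  batches <- data.frame(compound = "psoralen", tissue = "kidney",
                        level = c("low", "mid"), nominal = c(5, 500),
                        condition = c("freeze_thaw", "short_term"),
                        value = c(4.90, 493.47), stringsAsFactors = FALSE)
  # single replicate per cell: mean is the value itself
  batches <- rbind(batches, batches)  # 2 replicates so sd is defined
  out <- stability_re(batches)
  expect_equal(round(out$re[out$condition == "freeze_thaw"], 2), -2.00)
  expect_equal(round(out$re[out$condition == "short_term"], 2), -1.31)
  expect_true(all(out$pass))

  exact <- data.frame(compound = "x", tissue = "kidney", level = "low",
                      nominal = 5,
                      condition = rep(c("freeze_thaw", "short_term",
                                        "long_term", "preinjection"),
                                      each = 2),
                      value = 5, stringsAsFactors = FALSE)
  expect_equal(stability_re(exact)$re, rep(0, 4))
  bad <- exact; bad$condition <- "microwave"
  expect_error(stability_re(bad), "unknown stability condition")
})

test_that("assess produces an all-pass report on zero-noise batches", {
  cv <- reference_curves()["psoralen|kidney"]
  val <- generate_validation_batches(cv, cv = 0, stability_bias = c(
    freeze_thaw = 0, short_term = 0, long_term = 0, preinjection = 0),
    seed = 55)
  rep <- assess(val$qc, val$recovery, val$stability)
  pa <- rep$precision_accuracy
  expect_equal(nrow(pa), 4L)  # lloq/low/mid/high
  expect_equal(pa$intra_re, rep(0, 4), tolerance = 1e-12)
  expect_equal(pa$intra_rsd, rep(0, 4), tolerance = 1e-12)
  expect_equal(pa$inter_re, rep(0, 4), tolerance = 1e-12)
  expect_true(all(pa$pass))
  expect_true(all(rep$stability$re == 0))
  expect_equal(rep$recovery_matrix$recovery, rep(88, 3), tolerance = 1e-9)
})

test_that("insufficient replication is flagged, not silently computed", {
  qc <- data.frame(compound = "x", tissue = "kidney", level = "mid",
                   nominal = 100, day = 1, value = 98,
                   stringsAsFactors = FALSE)
  out <- assess_precision_accuracy(qc)
  expect_true(is.na(out$intra_rsd))
  expect_true(is.na(out$inter_rsd))
  expect_match(out$note, "intra-day")
  expect_match(out$note, "inter-day")
})

test_that("synthetic kidney batches at published noise produce a plausible report", {
  cv <- reference_curves()["psoralen|kidney"]
  val <- generate_validation_batches(cv, cv = 0.0546, seed = 77)
  rep <- assess(val$qc, val$recovery, val$stability)
  pa <- rep$precision_accuracy
  expect_setequal(pa$level, c("lloq", "low", "mid", "high"))
  # low level nominal = 2.5 x LLOQ 2.0 = 5 ng/mL, the published QC placement
  expect_equal(pa$nominal[pa$level == "low"], 5)
  expect_equal(pa$nominal[pa$level == "mid"], 500)
  expect_equal(pa$nominal[pa$level == "high"], 800)
  expect_true(all(is.finite(pa$intra_rsd)))
  expect_true(all(pa$intra_rsd < 15))
})
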