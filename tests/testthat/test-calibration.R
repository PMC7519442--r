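test_that("a noiseless line is recovered exactly, regardless of weighting", {
  x <- c(1, 10, 100, 1000)
  y <- 0.005 * x + 0.02
  for (w in c("1/x^2", "none")) {
    fit <- fit_weighted_linear(x, y, weighting = w)
    expect_equal(fit$slope, 0.005, tolerance = 1e-12)
    expect_equal(fit$intercept, 0.02, tolerance = 1e-12)
    expect_equal(fit$r, 1, tolerance = 1e-12)
    expect_equal(fit$range_low, 1)
    expect_equal(fit$range_high, 1000)
  }
})

test_that("fit matches the weighted normal-equations oracle on noisy designs", {
  set.seed(101)
  levels <- c(1, 5, 10, 50, 250, 500, 1000)
  for (i in 1:25) {
    slope <- stats::runif(1, 1e-4, 1e-1)
    intercept <- stats::runif(1, -0.05, 0.2)
    y <- (slope * levels + intercept) * exp(stats::rnorm(7, 0, 0.05))
    fit <- fit_weighted_linear(levels, y)
    ora <- wls_oracle(levels, y, 1 / levels^2)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-9)
  }
})

test_that("equal weights reduce to ordinary least squares", {
  set.seed(102)
  x <- c(2, 5, 20, 80, 300)
  y <- 0.01 * x + 0.1 + stats::rnorm(5, 0, 0.02)
  fit <- fit_weighted_linear(x, y, weighting = "none")
  ols <- stats::lm(y ~ x)
  expect_equal(fit$slope, unname(stats::coef(ols)[2]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-9)
})

test_that("1/x^2 weighting is scale-equivariant in y", {
  set.seed(103)
  x <- c(1, 5, 10, 50, 250, 500, 1000)
  y <- 0.004 * x + 0.05 + stats::rnorm(7, 0, 0.01)
  f1 <- fit_weighted_linear(x, y)
  f2 <- fit_weighted_linear(x, 7.5 * y)
  expect_equal(f2$slope, 7.5 * f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, 7.5 * f1$intercept, tolerance = 1e-12)
  expect_equal(f2$r, f1$r, tolerance = 1e-12)
})

test_that("r stays in [-1, 1] and hits 1 only for zero residuals", {
  set.seed(104)
  for (i in 1:20) {
    x <- sort(stats::runif(7, 1, 1000))
    y <- 0.003 * x + 0.1 + stats::rnorm(7, 0, 0.05)
    fit <- fit_weighted_linear(x, y)
    expect_lte(fit$r^2, 1 + 1e-12)
    resid <- y - (fit$slope * x + fit$intercept)
    if (abs(fit$r - 1) < 1e-12) expect_lt(max(abs(resid)), 1e-8)
    else expect_gt(max(abs(resid)), 0)
  }
  exact <- fit_weighted_linear(c(1, 10, 100), 0.01 * c(1, 10, 100) + 0.2)
  expect_equal(exact$r, 1, tolerance = 1e-12)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_weighted_linear(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_weighted_linear(c(5, 5, 5), c(1, 2, 3)), "3 distinct")
  expect_error(fit_weighted_linear(c(0, 1, 2), c(1, 2, 3)), "> 0")
  expect_error(fit_weighted_linear(c(-1, 1, 2), c(1, 2, 3)), "> 0")
})

test_that("back-calculation inverts the published kidney curve", {
  cal <- kidney_psoralen()
  # forward at X = 100: 3.44e-3 * 100 + 0.121 = 0.465
  expect_equal(predict_response(cal, 100), 0.465, tolerance = 1e-12)
  bc <- back_calculate(cal, 0.465)
  expect_equal(bc$conc, 100, tolerance = 1e-9)
  expect_equal(bc$flag, "in_range")

  bc0 <- back_calculate(cal, cal$intercept)
  expect_equal(bc0$conc, 0, tolerance = 1e-12)
  expect_equal(bc0$flag, "below_lloq")

  hi <- back_calculate(cal, predict_response(cal, 1500))
  expect_equal(hi$flag, "above_range")
  # below-zero inversions are retained, flagged, never clamped
  neg <- back_calculate(cal, 0)
  expect_lt(neg$conc, 0)
  expect_equal(neg$flag, "below_lloq")
})

test_that("back_calculate(forward(x)) is the identity within 1e-9 relative", {
  set.seed(105)
  for (i in 1:10) {
    cal <- fit_weighted_linear(c(1, 5, 10, 50, 250, 500, 1000),
                               stats::runif(1, 1e-3, 1e-1) *
                                 c(1, 5, 10, 50, 250, 500, 1000) +
                                 stats::runif(1, 0, 0.2))
    x <- stats::runif(20, 2, 1000)
    expect_equal(back_calculate(cal, predict_response(cal, x))$conc, x,
                 tolerance = 1e-9)
  }
})

test_that("S/N limits pick the lowest qualifying level and scale with noise", {
  cal <- kidney_psoralen()
  levels <- c(0.5, 1, 2, 5, 10, 50)
  # noise placed so that level 2 is the first with S/N >= 10
  noise <- cal$slope * 2 / 10
  est <- estimate_lloq_llod(noise, cal, levels)
  expect_equal(est$lloq, 2)
  expect_lte(est$llod, est$lloq)
  # brute-force oracle over all levels, and monotonicity in noise
  for (mult in c(1, 2, 5, 10)) {
    e <- estimate_lloq_llod(noise * mult, cal, levels)
    sn <- cal$slope * levels / (noise * mult)
    brute_lloq <- suppressWarnings(min(levels[sn >= 10]))
    expect_equal(e$lloq, if (is.finite(brute_lloq)) brute_lloq else NA_real_)
    brute_llod <- suppressWarnings(min(levels[sn >= 3]))
    expect_equal(e$llod, if (is.finite(brute_llod)) brute_llod else NA_real_)
  }
  none <- estimate_lloq_llod(1e6, cal, levels)
  expect_false(none$lloq_determined)
  expect_true(is.na(none$lloq))
  expect_error(estimate_lloq_llod(0, cal, levels), "> 0")
  expect_error(estimate_lloq_llod(1, cal, c(2, 1)), "ascending")
})

test_that("packaged reference curves load with the published parameters", {
  curves <- reference_curves()
  expect_length(curves, 96L)  # 12 compounds x 8 tissues
  kp <- curves[["psoralen|kidney"]]
  expect_equal(kp$slope, 3.44e-3)
  expect_equal(kp$intercept, 1.21e-1)
  expect_equal(kp$lloq, 2.0)
  expect_equal(kp$range_high, 1000)
  expect_equal(kp$r, 0.9996)
  # every curve satisfies its own invariants
  for (cv in curves) {
    expect_gt(cv$slope, 0)
    expect_true(cv$range_low <= cv$lloq && cv$lloq <= cv$range_high)
  }
})

test_that("curve table round-trips through CSV", {
  curves <- reference_curves()[c("psoralen|kidney", "bavachin|liver")]
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_curve_table(curves, tmp)
  back <- read_curve_table(tmp)
  expect_equal(names(back), names(curves))
  expect_equal(back[["psoralen|kidney"]]$slope, 3.44e-3, tolerance = 1e-12)
  expect_equal(back[["bavachin|liver"]]$intercept,
               curves[["bavachin|liver"]]$intercept, tolerance = 1e-12)
})
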