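# Three-stage recalibration: formula identities, temperature recovery,
# nesting, monotone flattening, prior consistency.

test_that("temperature scaling identities and limits", {
  z <- c(2, 0)
  # T = 1 is the identity
  expect_equal(temperature_scale(z, c(1, 1))$probs, oracle_softmax(z),
               tolerance = 1e-12)
  # equal T = 2 halves the logits
  expect_equal(temperature_scale(z, c(2, 2))$probs, oracle_softmax(c(1, 0)),
               tolerance = 1e-12)
  expect_equal(temperature_scale(z, c(2, 2))$probs[1], 0.7311, tolerance = 1e-4)
  # T -> T_max flattens toward uniform
  pT <- temperature_scale(c(8, 0, -8), rep(20, 3))$probs
  expect_lt(max(abs(pT - 1 / 3)), 0.15)
  expect_error(temperature_scale(z, c(1, -1)), "positive")
  # matrix input: every row normalized
  zm <- matrix(rnorm(30), 10, 3)
  expect_equal(rowSums(temperature_scale(zm, c(1.3, 0.7, 2))$probs),
               rep(1, 10), tolerance = 1e-9)
})

test_that("global temperature fitting recovers a known miscalibration", {
  val <- simulate_miscalibrated_logits(4000, miscal = 2, seed = 101)
  z <- as.matrix(val[c("z1", "z2")])
  Tg <- fit_temperatures(z, val$label, mode = "global")
  expect_lt(abs(Tg[1] - 2) / 2, 0.05)
  # cross-check against an independent grid-search oracle
  T_oracle <- oracle_fit_temperature_grid(z[1:1500, ], val$label[1:1500])
  Tg2 <- fit_temperatures(z[1:1500, ], val$label[1:1500], mode = "global")
  expect_lt(abs(Tg2[1] - T_oracle) / T_oracle, 0.02)
  # already-calibrated logits give T ~ 1
  valc <- simulate_miscalibrated_logits(4000, miscal = 1, seed = 103)
  Tc <- fit_temperatures(as.matrix(valc[c("z1", "z2")]), valc$label,
                         mode = "global")
  expect_lt(abs(Tc[1] - 1), 0.05)
})

test_that("per-class temperatures never fit worse than the global scalar", {
  val <- simulate_miscalibrated_logits(2000, miscal = 2, seed = 7)
  z <- as.matrix(val[c("z1", "z2")])
  # make the miscalibration class-asymmetric
  z[, 2] <- z[, 2] * 1.5
  Tg <- fit_temperatures(z, val$label, mode = "global")
  Tp <- fit_temperatures(z, val$label, mode = "per_class")
  expect_lte(attr(Tp, "nll"), attr(Tg, "nll") + 1e-6)
  # and the global fit never beats the raw NLL it optimizes
  raw_nll <- mmcalib:::nll_of(mmcalib:::softmax_rows(z), val$label)
  expect_lte(attr(Tg, "nll"), raw_nll + 1e-9)
  expect_error(fit_temperatures(z[val$label == 1, ], val$label[val$label == 1],
                                mode = "per_class"),
               "every class")
})

test_that("uncertainty adjustment shrinks logits without changing the argmax", {
  z <- c(2, 0.5, -1)
  expect_equal(uncertainty_adjust(z, 0, 5), z)
  expect_equal(uncertainty_adjust(z, 3, 0), z)
  zt <- uncertainty_adjust(z, 10, 1)
  expect_equal(zt, z / 11)
  expect_equal(which.max(zt), which.max(z))
  # flattening toward uniform as u grows
  p_inf <- oracle_softmax(uncertainty_adjust(z, 1e6, 1))
  expect_lt(max(abs(p_inf - 1 / 3)), 1e-4)
  expect_error(uncertainty_adjust(z, -1, 1), "nonnegative")
  # entropy non-decreasing in u
  us <- c(0, 0.5, 1, 2, 5, 20)
  ents <- sapply(us, function(u) entropy_of(oracle_softmax(
    uncertainty_adjust(z, u, 1))))
  expect_true(all(diff(ents) >= -1e-12))
})

test_that("entropy under equal temperatures is non-decreasing in T", {
  z <- c(3, 1, -2)
  Ts <- c(0.1, 0.5, 1, 2, 5, 20)
  ents <- sapply(Ts, function(Tv) entropy_of(
    temperature_scale(z, rep(Tv, 3))$probs))
  expect_true(all(diff(ents) >= -1e-12))
})

test_that("log-odds conversion follows its closed form", {
  expect_equal(log_odds(0.5), 0)
  expect_equal(log_odds(0.9), log(9))
  expect_equal(log_odds(0.1), -log_odds(0.9))
  expect_error(log_odds(c(0.3, 1)), "strictly")
  expect_error(log_odds(0), "strictly")
})

test_that("prior smoothing is the stated convex combination", {
  expect_equal(smooth_prior(c(0.8, 0.3), c(0.4, 0.5), 1), c(0.8, 0.3))
  expect_equal(smooth_prior(c(0.8, 0.3), c(0.4, 0.5), 0), c(0.4, 0.5))
  expect_equal(smooth_prior(0.8, 0.4, 0.5), 0.6)
  expect_error(smooth_prior(0.5, 0.5, 1.5), "\\[0, 1\\]")
})

test_that("prior injection adds weighted log-odds to the logits", {
  zt <- c(1, 0, -1)
  delta <- log_odds(c(0.6, 0.5, 0.4))
  expect_equal(adjust_logits(zt, delta, 0), zt)
  # symmetric binary prior changes nothing
  expect_equal(adjust_logits(c(2, -1), log_odds(c(0.5, 0.5)), 3), c(2, -1))
  # K = 3 arithmetic oracle
  zhat <- adjust_logits(zt, delta, 1)
  expect_equal(zhat, zt + c(log(0.6 / 0.4), 0, log(0.4 / 0.6)),
               tolerance = 1e-12)
  expect_equal(calibrated_probs(zhat),
               oracle_softmax(c(1 + log(1.5), 0, -1 - log(1.5))),
               tolerance = 1e-12)
})

test_that("zero logits with unit prior weight reproduce the prior odds", {
  pi_t <- c(0.7, 0.2, 0.4)
  delta <- log_odds(pi_t)
  p <- calibrated_probs(adjust_logits(c(0, 0, 0), delta, 1))
  odds <- pi_t / (1 - pi_t)
  expect_equal(p, odds / sum(odds), tolerance = 1e-12)
})

test_that("the pipeline applies stages in order and records intermediates", {
  set.seed(15)
  z <- matrix(rnorm(20, sd = 2), 10, 2)
  u <- runif(10)
  counts <- c(60, 40)
  cal <- structure(
    list(T_vec = c(2, 1.5), gamma_u = 1, lambda_prior = 0.5, beta = 0.5,
         prior = c(0.6, 0.4), empirical = c(0.6, 0.4),
         smoothed = c(0.6, 0.4), delta = log_odds(c(0.6, 0.4)),
         temperature_mode = "per_class", val_nll = c()),
    class = "mm_calibration"
  )
  out <- calibrate_pipeline(z, cal, u = u)
  zT <- sweep(z, 2, c(2, 1.5), `/`)
  zU <- zT / (1 + 1 * u)
  zP <- sweep(zU, 2, 0.5 * cal$delta, `+`)
  expect_equal(out$stages$temperature, zT, tolerance = 1e-12)
  expect_equal(out$stages$uncertainty, zU, tolerance = 1e-12)
  expect_equal(out$stages$prior, zP, tolerance = 1e-12)
  expect_equal(as.matrix(out$probs[, 1:2]), mmcalib:::softmax_rows(zP),
               ignore_attr = TRUE, tolerance = 1e-12)
  # normalization after the final softmax
  expect_equal(rowSums(as.matrix(out$probs[, 1:2])), rep(1, 10),
               tolerance = 1e-9)
})

test_that("identity parameters leave softmax(z) untouched, with shift invariance", {
  set.seed(16)
  z <- matrix(rnorm(30), 10, 3)
  cal <- structure(
    list(T_vec = rep(1, 3), gamma_u = 0, lambda_prior = 0, beta = 0.5,
         prior = rep(0.5, 3), empirical = rep(0.5, 3), smoothed = rep(0.5, 3),
         delta = rep(0, 3), temperature_mode = "global", val_nll = c()),
    class = "mm_calibration"
  )
  out <- calibrate_pipeline(z, cal)
  expect_equal(as.matrix(out$probs[, 1:3]), mmcalib:::softmax_rows(z),
               ignore_attr = TRUE, tolerance = 1e-12)
  cal$T_vec <- rep(1.7, 3)
  o1 <- calibrate_pipeline(z, cal)
  o2 <- calibrate_pipeline(z + 3, cal)
  expect_equal(o1$probs, o2$probs, tolerance = 1e-12)
  expect_error(calibrate_pipeline(z, list(T_vec = 1)), "fit_calibration")
})

test_that("full calibration fitting halves held-out calibration error", {
  val <- simulate_miscalibrated_logits(4000, miscal = 2, seed = 101)
  te <- simulate_miscalibrated_logits(4000, miscal = 2, seed = 102)
  cal <- fit_calibration(as.matrix(val[c("z1", "z2")]), val$label,
                         train_class_counts = tabulate(val$label, 2))
  zt <- as.matrix(te[c("z1", "z2")])
  before <- expected_calibration_error(mmcalib:::softmax_rows(zt), te$label)
  out <- calibrate_pipeline(zt, cal)
  after <- expected_calibration_error(as.matrix(out$probs[, 1:2]), te$label)
  expect_lt(after, 0.5 * before)
  # staged validation NLLs never increase along the pipeline
  expect_true(all(diff(cal$val_nll) <= 1e-9))
})

test_that("calibration parameters round-trip through JSON", {
  val <- simulate_miscalibrated_logits(800, miscal = 2, seed = 5)
  cal <- fit_calibration(as.matrix(val[c("z1", "z2")]), val$label,
                         train_class_counts = c(400, 400),
                         prior = c(0.7, 0.3), beta = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(cal2$T_vec, cal$T_vec, tolerance = 1e-12)
  expect_equal(cal2$delta, cal$delta, tolerance = 1e-12)
  z <- matrix(rnorm(10), 5, 2)
  expect_equal(calibrate_pipeline(z, cal2)$probs,
               calibrate_pipeline(z, cal)$probs, tolerance = 1e-12)
  # smoothed prior invariant
  expect_equal(cal$smoothed, 0.25 * cal$prior + 0.75 * cal$empirical,
               tolerance = 1e-12)
  expect_equal(cal$delta, log(cal$smoothed / (1 - cal$smoothed)),
               tolerance = 1e-12)
})
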