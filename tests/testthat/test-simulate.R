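# Synthetic generator: apportionment, noise, missingness, imputation,
# determinism, file round-trips.

test_that("class counts are the exact largest-remainder apportionment", {
  expect_identical(apportion_counts(1000, c(0.9, 0.1)), c(900L, 100L))
  expect_identical(apportion_counts(100, c(0.7, 0.2, 0.1)), c(70L, 20L, 10L))
  # remainders force rounding; counts still conserve the total
  expect_identical(sum(apportion_counts(101, c(1, 1, 1) / 3)), 101L)
  expect_identical(apportion_counts(10, c(0.55, 0.45)), c(6L, 4L))

  b <- simulate_multimodal(mm_spec(1000, class_proportions = c(0.9, 0.1),
                                   seed = 3))
  expect_identical(b$class_counts, c(900L, 100L))
  expect_equal(imbalance_ratio(b$class_counts), 9)
})

test_that("imbalance ratio follows max/min and rejects empty classes", {
  expect_equal(imbalance_ratio(c(90, 10)), 9)
  expect_equal(imbalance_ratio(c(50, 50)), 1)
  expect_equal(imbalance_ratio(c(70, 20, 10)), 7)
  expect_error(imbalance_ratio(c(10, 0)), "degenerate")
})

test_that("spec validation rejects malformed generative descriptions", {
  expect_error(mm_spec(100, n_classes = 3, class_proportions = c(0.5, 0.5)),
               "length")
  expect_error(mm_spec(100, class_proportions = c(0.7, 0.2)), "sum to 1")
  expect_error(mm_spec(100, label_noise = matrix(c(0.5, 0.5, 0.3, 0.3), 2,
                                                 byrow = TRUE)),
               "sum to 1")
  expect_error(mm_spec(100, missing_rate = 1), "missing_rate")
  expect_error(mm_spec(1, n_classes = 2), "at least one sample")
})

test_that("identical specs reproduce the bundle bit-identically", {
  s <- mm_spec(200, class_proportions = c(0.6, 0.4), missing_rate = 0.2,
               label_noise = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
               cross_modal_coupling = 0.5, seed = 11)
  b1 <- simulate_multimodal(s)
  b2 <- simulate_multimodal(s)
  expect_identical(b1$data, b2$data)
  b3 <- simulate_multimodal(mm_spec(200, class_proportions = c(0.6, 0.4),
                                    seed = 12))
  expect_true(is.numeric(b1$data$imaging_01))
  expect_false(identical(b1$data$imaging_01, b3$data$imaging_01))
})

test_that("label noise: identity and permutation matrices act exactly", {
  y <- sample(1:3, 500, replace = TRUE)
  expect_identical(apply_label_noise(y, diag(3), seed = 1), y)
  perm <- diag(3)[c(2, 3, 1), ] # row l says: true l observed as ...
  yp <- apply_label_noise(y, perm, seed = 1)
  expect_identical(yp, c(2L, 3L, 1L)[y])
})

test_that("empirical flip rate matches the transition matrix within 3 sigma", {
  eta <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE)
  y <- rep(1:2, each = 5000)
  obs <- apply_label_noise(y, eta, seed = 42)
  flip <- mean(obs != y)
  expect_lt(abs(flip - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # row-wise confusion converges to eta
  emp <- prop.table(table(y, obs), margin = 1)
  expect_lt(max(abs(emp - eta)), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("missingness flags appear at the configured rate and only then", {
  b0 <- tiny_bundle(200)
  expect_false(anyNA(b0$data))

  b <- simulate_multimodal(mm_spec(1000, modality_dims = c(a = 5L, o = 5L),
                                   missing_rate = 0.3, seed = 5))
  frac <- mean(is.na(as.matrix(b$data[-(1:4)])))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))

  b2 <- apply_missingness(tiny_bundle(400), 0.25, seed = 9)
  frac2 <- mean(is.na(as.matrix(b2$data[-(1:4)])))
  expect_lt(abs(frac2 - 0.25), 3 * sqrt(0.25 * 0.75 / (400 * 5)))
  expect_identical(apply_missingness(b0, 0), b0)
})

test_that("imputation uses train-split means only", {
  b <- tiny_bundle(300, missing_rate = 0.2)
  bi <- impute_missing(b)
  expect_false(anyNA(bi$data))
  # recompute a train mean by hand and find it at an imputed position
  col <- "img_01"
  tr_mean <- mean(b$data[[col]][b$data$split == "train"], na.rm = TRUE)
  was_na <- which(is.na(b$data[[col]]))
  expect_true(length(was_na) > 0)
  expect_equal(unique(bi$data[[col]][was_na]), tr_mean)
  # and that it is NOT the all-split mean
  all_mean <- mean(b$data[[col]], na.rm = TRUE)
  expect_false(isTRUE(all.equal(tr_mean, all_mean)))

  b$data$split <- "test"
  expect_error(impute_missing(b), "train split")
})

test_that("splits are disjoint, cover all samples, and stratify classes", {
  b <- simulate_multimodal(mm_spec(500, class_proportions = c(0.8, 0.2),
                                   seed = 2))
  expect_setequal(unique(b$data$split), c("train", "val", "test"))
  expect_equal(nrow(b$data), 500)
  # every class present in every split (needed for calibration fitting)
  tab <- table(b$data$split, b$data$observed_label)
  expect_true(all(tab > 0))
})

test_that("zero separation carries no class signal for an external classifier", {
  b <- simulate_multimodal(mm_spec(4000, class_proportions = c(0.7, 0.3),
                                   class_separation = 0, seed = 13))
  d <- b$data
  tr <- d$split == "train"
  te <- d$split == "test"
  form <- stats::as.formula(paste(
    "y ~", paste(grep("^(img|mol|imaging|molecular|mod)", names(d),
                      value = TRUE), collapse = "+")
  ))
  d$y <- as.integer(d$observed_label == 1)
  fit <- suppressWarnings(stats::glm(form, data = d[tr, ], family = "binomial"))
  pred <- as.integer(predict(fit, d[te, ], type = "response") > 0.5)
  acc <- mean(pred == d$y[te])
  maj <- max(mean(d$y[te]), 1 - mean(d$y[te]))
  n_te <- sum(te)
  # accuracy statistically indistinguishable from the majority rate
  expect_lt(acc, maj + 3 * sqrt(maj * (1 - maj) / n_te))
})

test_that("interaction labels depend on the cross-modal sign product", {
  b <- simulate_multimodal(mm_spec(500, interaction_label_mode = TRUE,
                                   modality_dims = c(a = 2L, b = 2L),
                                   seed = 17))
  s <- sign(b$data$a_01) * sign(b$data$b_01)
  expect_identical(b$data$true_label, ifelse(s > 0, 1L, 2L))
})

test_that("bundle round-trips through the plain-text format", {
  b <- tiny_bundle(80, missing_rate = 0.1,
                   label_noise = matrix(c(0.95, 0.05, 0.05, 0.95), 2,
                                        byrow = TRUE))
  dir <- withr::local_tempdir()
  write_mm_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  b2 <- read_mm_bundle(dir)
  expect_equal(b2$class_counts, b$class_counts)
  expect_equal(as.data.frame(b2$data[order(names(b2$data))]),
               as.data.frame(b$data[order(names(b$data))]),
               tolerance = 1e-12)
})
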