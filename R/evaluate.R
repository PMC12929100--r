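# Discrimination and calibration metrics, reliability tables, paired
# significance tests, and the factorial ablation harness.

#' Expected calibration error
#'
#' Bins samples by confidence (the maximum predicted probability) into
#' `n_bins` equal-width bins on `[0, 1]` and returns the bin-weighted mean
#' absolute gap between within-bin accuracy and mean confidence:
#' `ECE = sum_b (n_b / n) |acc_b - conf_b|`. Empty bins contribute zero.
#'
#' @param probs `n x K` probability matrix (or tibble of probability columns).
#' @param labels Integer labels in `1..K`.
#' @param n_bins Number of equal-width confidence bins (default 15).
#' @return Scalar ECE in `[0, 1]`.
#' @export
expected_calibration_error <- function(probs, labels, n_bins = 15L) {
  if (n_bins < 1) stop_mm("n_bins must be >= 1")
  p <- as.matrix(probs)
  conf <- apply(p, 1L, max)
  pred <- apply(p, 1L, argmax_first)
  correct <- as.numeric(pred == labels)
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  n <- length(labels)
  ece <- 0
  for (b in unique(bin)) {
    inb <- bin == b
    ece <- ece + sum(inb) / n * abs(mean(correct[inb]) - mean(conf[inb]))
  }
  ece
}

#' Reliability-diagram table
#'
#' Per-confidence-bin counts, mean confidence and accuracy — the data behind
#' a reliability diagram and behind [expected_calibration_error()].
#'
#' @inheritParams expected_calibration_error
#' @return Tibble with `bin`, `lower`, `upper`, `n`, `confidence`, `accuracy`.
#' @export
reliability_table <- function(probs, labels, n_bins = 15L) {
  p <- as.matrix(probs)
  conf <- apply(p, 1L, max)
  pred <- apply(p, 1L, argmax_first)
  correct <- as.numeric(pred == labels)
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  purrr::map_dfr(seq_len(n_bins), function(b) {
    inb <- bin == b
    tibble::tibble(
      bin = b,
      lower = (b - 1) / n_bins,
      upper = b / n_bins,
      n = sum(inb),
      confidence = if (any(inb)) mean(conf[inb]) else NA_real_,
      accuracy = if (any(inb)) mean(correct[inb]) else NA_real_
    )
  })
}

# rank-statistic (Mann-Whitney) one-vs-rest AUC, ties by mid-rank
ovr_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrimination and calibration metrics
#'
#' Hard labels via arg-max (ties to the lowest class index); macro averages
#' over the classes present in `labels`; AUC is the unweighted mean of
#' per-class one-vs-rest areas (rank statistic). A class absent from the
#' labels has undefined recall/AUC and is excluded from macro averages with a
#' warning.
#'
#' @param probs `n x K` probability matrix (or tibble of probability columns).
#' @param labels Integer labels in `1..K`.
#' @param n_bins Confidence bins for ECE/MCE (default 15).
#' @return An object of class `mm_eval`: overall metrics, the `K x K`
#'   confusion matrix (rows = true), and a per-class tibble.
#' @export
classification_metrics <- function(probs, labels, n_bins = 15L) {
  p <- as.matrix(probs)
  K <- ncol(p)
  n <- length(labels)
  pred <- apply(p, 1L, argmax_first)
  present <- sort(unique(labels))
  if (length(present) < K) {
    warning("classes absent from labels excluded from macro averages: ",
            paste(setdiff(seq_len(K), present), collapse = ", "),
            call. = FALSE)
  }
  cm <- matrix(0L, K, K, dimnames = list(true = seq_len(K), pred = seq_len(K)))
  for (i in seq_len(n)) cm[labels[i], pred[i]] <- cm[labels[i], pred[i]] + 1L

  per_class <- purrr::map_dfr(seq_len(K), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else if (!is.na(rec) && rec == 0) 0 else NA_real_
    tibble::tibble(
      class = k, n = sum(cm[k, ]),
      precision = prec, recall = rec, f1 = f1,
      auc = ovr_auc(p[, k], labels == k)
    )
  })
  pc <- per_class[per_class$class %in% present, ]

  py <- pmax(p[cbind(seq_len(n), labels)], 1e-12)
  onehot <- matrix(0, n, K)
  onehot[cbind(seq_len(n), labels)] <- 1

  conf <- apply(p, 1L, max)
  correct <- as.numeric(pred == labels)
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  gaps <- purrr::map_dbl(unique(bin), function(b) {
    abs(mean(correct[bin == b]) - mean(conf[bin == b]))
  })

  structure(
    list(
      accuracy = mean(pred == labels),
      macro_recall = mean(pc$recall, na.rm = TRUE),
      macro_f1 = mean(pc$f1, na.rm = TRUE),
      macro_auc = mean(pc$auc, na.rm = TRUE),
      nll = mean(-log(py)),
      brier = mean(rowSums((p - onehot)^2)),
      ece = expected_calibration_error(p, labels, n_bins),
      mce = max(gaps),
      confusion = cm,
      per_class = per_class,
      n_samples = n
    ),
    class = "mm_eval"
  )
}

#' @export
print.mm_eval <- function(x, ...) {
  cat("<mm_eval>", x$n_samples, "samples\n")
  cat(sprintf("  accuracy %.4f  macro recall %.4f  macro F1 %.4f  macro AUC %.4f\n",
              x$accuracy, x$macro_recall, x$macro_f1, x$macro_auc))
  cat(sprintf("  NLL %.4f  Brier %.4f  ECE %.4f  MCE %.4f\n",
              x$nll, x$brier, x$ece, x$mce))
  invisible(x)
}

#' Per-class metrics of an evaluation
#'
#' @param x An `mm_eval`.
#' @param ... Unused.
#' @return Tibble with one row per class.
#' @export
tidy.mm_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation
#'
#' @param x An `mm_eval`.
#' @param ... Unused.
#' @return Tibble with the headline metrics.
#' @export
glance.mm_eval <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1, macro_auc = x$macro_auc,
    nll = x$nll, brier = x$brier, ece = x$ece, mce = x$mce,
    n_samples = x$n_samples
  )
}

#' Paired significance tests between two systems
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test (exact for up to 25
#' pairs) on per-run metric values aligned by seed. Degenerate all-zero
#' differences return `p = 1` for both tests by decision, so ablation tables
#' never fail on identical runs.
#'
#' @param metric_a,metric_b Numeric vectors of equal length (>= 2), one entry
#'   per paired run.
#' @return One-row tibble: `n_pairs`, `mean_diff` (a minus b), `t_p_value`,
#'   `wilcoxon_p_value`.
#' @export
paired_tests <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop_mm("runs must be paired")
  if (length(metric_a) < 2) stop_mm("need at least 2 paired runs")
  d <- metric_a - metric_b
  if (all(d == 0)) {
    return(tibble::tibble(n_pairs = length(d), mean_diff = 0,
                          t_p_value = 1, wilcoxon_p_value = 1))
  }
  t_p <- if (stats::sd(d) == 0) {
    0 # identical nonzero shift: t statistic is infinite
  } else {
    stats::t.test(metric_a, metric_b, paired = TRUE)$p.value
  }
  w_p <- suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                       exact = length(d) <= 25)$p.value
  )
  tibble::tibble(n_pairs = length(d), mean_diff = mean(d),
                 t_p_value = t_p, wilcoxon_p_value = w_p)
}

# One full train -> uncertainty -> calibrate -> evaluate cycle on a bundle.
# Returns glance() of the test-split evaluation plus the fitted pieces.
run_pipeline <- function(bundle, seed = 1L,
                         fusion = TRUE, uncertainty = TRUE,
                         priors = TRUE, class_weighting = TRUE,
                         prior = NULL, n_passes = 20L,
                         encoder_args = list(), train_args = list()) {
  cfg <- do.call(encoder_config, c(
    list(modality_dims = bundle$manifest$modality_dims,
         n_classes = bundle$manifest$n_classes,
         fusion = fusion, seed = seed),
    encoder_args
  ))
  fit <- do.call(fit_encoder, c(
    list(bundle = bundle, config = cfg,
         use_class_weights = class_weighting, seed = seed),
    train_args
  ))
  data <- if (anyNA(bundle$data[unlist(feature_columns(bundle$manifest))])) {
    impute_missing(bundle)$data
  } else {
    bundle$data
  }
  va <- data[data$split == "val", ]
  te <- data[data$split == "test", ]
  z_va <- as.matrix(predict(fit, va, type = "logit")[, -1L])
  z_te <- as.matrix(predict(fit, te, type = "logit")[, -1L])
  u_va <- u_te <- NULL
  if (uncertainty) {
    u_va <- batch_uncertainty(fit, va, n_passes = n_passes, seed = seed)$u
    u_te <- batch_uncertainty(fit, te, n_passes = n_passes, seed = seed)$u
  }
  cal <- fit_calibration(
    z_va, va$observed_label, u = u_va,
    train_class_counts = fit$class_counts, prior = prior,
    lambda_grid = if (priors) c(0, 0.25, 0.5, 1, 2) else 0
  )
  out <- calibrate_pipeline(z_te, cal, u = u_te)
  ev <- classification_metrics(out$probs[, seq_len(ncol(z_te))],
                               te$observed_label)
  list(fit = fit, calibration = cal, eval = ev, glance = glance(ev))
}

#' Factorial ablation harness
#'
#' Runs one full train + calibrate + evaluate cycle per component
#' configuration per seed and returns a tidy table. Components that can be
#' switched off: cross-modal `fusion` (self-attention restricted to each
#' token and cross-attention removed), `uncertainty` adjustment,
#' `priors` injection, and `class_weighting` of the loss.
#'
#' @param bundle An `mm_bundle`.
#' @param flags Tibble with logical columns `fusion`, `uncertainty`, `priors`,
#'   `class_weighting` — one row per configuration. Defaults to the
#'   full model plus each single-component knockout.
#' @param seeds Integer vector of seeds; every configuration is run once per
#'   seed with seed-aligned pairing.
#' @param prior Optional expert prior passed to [fit_calibration()].
#' @param ... Passed on to the internal pipeline (e.g. `n_passes`,
#'   `encoder_args`, `train_args`).
#' @return Tibble: one row per configuration x seed with the flags, the seed
#'   and the test-split metrics.
#' @export
ablation_run <- function(bundle, flags = NULL, seeds = 1:3, prior = NULL,
                         ...) {
  if (is.null(flags)) {
    full <- tibble::tibble(fusion = TRUE, uncertainty = TRUE,
                           priors = TRUE, class_weighting = TRUE)
    flags <- dplyr::bind_rows(
      full,
      dplyr::mutate(full, fusion = FALSE),
      dplyr::mutate(full, uncertainty = FALSE),
      dplyr::mutate(full, priors = FALSE),
      dplyr::mutate(full, class_weighting = FALSE)
    )
  }
  purrr::map_dfr(seq_len(nrow(flags)), function(i) {
    fl <- flags[i, ]
    purrr::map_dfr(seeds, function(s) {
      res <- run_pipeline(bundle, seed = s,
                          fusion = fl$fusion, uncertainty = fl$uncertainty,
                          priors = fl$priors,
                          class_weighting = fl$class_weighting,
                          prior = prior, ...)
      dplyr::bind_cols(fl, tibble::tibble(seed = s), res$glance)
    })
  })
}
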