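# Synthetic multimodal generator: imbalanced K-class labels, Gaussian
# class-conditional modalities with an optional shared latent coupling factor,
# row-stochastic label noise, missing-completely-at-random entries, and
# stratified train/val/test splits. Ground truth is retained so every
# downstream stage (training, uncertainty, calibration, evaluation) can be
# tested without external data.

#' Specify a synthetic multimodal dataset
#'
#' Describes the full generative process for [simulate_multimodal()]: class
#' mix, per-modality dimensions, separation between class-conditional means,
#' cross-modal coupling, label-noise transition matrix, missingness rate and
#' seed. An identical spec (including the seed) reproduces a dataset
#' bit-identically.
#'
#' @param n_samples Number of samples to generate.
#' @param n_classes Number of diagnostic classes `K` (>= 2).
#' @param class_proportions Probability vector of length `K`; class counts are
#'   the largest-remainder apportionment of `n_samples`, so the realized
#'   imbalance ratio is exact.
#' @param modality_dims Named integer vector of per-modality feature counts,
#'   e.g. `c(imaging = 8, molecular = 8)`.
#' @param class_separation Distance between class-conditional mean vectors in
#'   within-class standard-deviation units (per modality). `0` gives
#'   label-independent features.
#' @param cross_modal_coupling Weight in `[0, 1]` of a shared per-sample latent
#'   scalar added to every coordinate of every modality, inducing cross-modal
#'   correlation.
#' @param interaction_label_mode If `TRUE`, labels are a deterministic function
#'   of the sign product of the first coordinates of modalities 1 and 2
#'   (before label noise): an interaction no additive single-modality
#'   classifier can express. Forces `n_classes = 2`.
#' @param label_noise Optional `K x K` row-stochastic transition matrix; the
#'   observed label is drawn from the row indexed by the true label.
#' @param missing_rate Probability in `[0, 1)` that a feature entry is missing
#'   (missing completely at random).
#' @param split_fractions Named numeric vector (`train`, `val`, `test`)
#'   summing to 1; splits are stratified by observed label.
#' @param seed Integer seed; all sub-steps (means, features, labels, noise,
#'   missingness, splits) draw from named sub-streams derived from it.
#' @return An object of class `mm_spec`.
#' @seealso [simulate_multimodal()]
#' @export
mm_spec <- function(n_samples,
                    n_classes = 2L,
                    class_proportions = rep(1 / n_classes, n_classes),
                    modality_dims = c(imaging = 8L, molecular = 8L),
                    class_separation = 2,
                    cross_modal_coupling = 0,
                    interaction_label_mode = FALSE,
                    label_noise = NULL,
                    missing_rate = 0,
                    split_fractions = c(train = 0.6, val = 0.2, test = 0.2),
                    seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_samples <- as.integer(n_samples)
  if (n_classes < 2L) stop_mm("n_classes must be >= 2")
  if (n_samples < n_classes) stop_mm("need at least one sample per class")
  if (length(class_proportions) != n_classes) {
    stop_mm("class_proportions must have length n_classes")
  }
  check_prob_vector(class_proportions, "class_proportions")
  if (is.null(names(modality_dims))) {
    names(modality_dims) <- paste0("mod", seq_along(modality_dims))
  }
  if (any(modality_dims < 1L)) stop_mm("modality_dims must all be >= 1")
  if (class_separation < 0) stop_mm("class_separation must be nonnegative")
  if (cross_modal_coupling < 0 || cross_modal_coupling > 1) {
    stop_mm("cross_modal_coupling must lie in [0, 1]")
  }
  if (interaction_label_mode) {
    if (n_classes != 2L) stop_mm("interaction_label_mode requires n_classes = 2")
    if (length(modality_dims) < 2L) {
      stop_mm("interaction_label_mode requires at least two modalities")
    }
  }
  if (!is.null(label_noise)) {
    check_row_stochastic(label_noise, "label_noise")
    if (nrow(label_noise) != n_classes) {
      stop_mm("label_noise must be ", n_classes, " x ", n_classes)
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_mm("missing_rate must lie in [0, 1)")
  }
  if (!setequal(names(split_fractions), c("train", "val", "test"))) {
    stop_mm("split_fractions needs names train, val, test")
  }
  check_prob_vector(split_fractions[c("train", "val", "test")],
                    "split_fractions")
  structure(
    list(
      n_samples = n_samples,
      n_classes = n_classes,
      class_proportions = as.numeric(class_proportions),
      modality_dims = stats::setNames(as.integer(modality_dims),
                                      names(modality_dims)),
      class_separation = class_separation,
      cross_modal_coupling = cross_modal_coupling,
      interaction_label_mode = isTRUE(interaction_label_mode),
      label_noise = label_noise,
      missing_rate = missing_rate,
      split_fractions = split_fractions[c("train", "val", "test")],
      seed = as.integer(seed)
    ),
    class = "mm_spec"
  )
}

#' @export
print.mm_spec <- function(x, ...) {
  cat("<mm_spec>", x$n_samples, "samples,", x$n_classes, "classes\n")
  cat("  proportions:", paste(signif(x$class_proportions, 4), collapse = ", "), "\n")
  cat("  modalities: ",
      paste(names(x$modality_dims), x$modality_dims, sep = "=", collapse = ", "), "\n")
  cat("  separation:", x$class_separation,
      " coupling:", x$cross_modal_coupling,
      " missing:", x$missing_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Largest-remainder apportionment of class counts
#'
#' Deterministically splits `n` into integer counts proportional to
#' `proportions`: floors first, then assigns the leftover units to the classes
#' with the largest fractional remainders (ties to the lower class index).
#' Counts always sum to `n` exactly.
#'
#' @param n Total count.
#' @param proportions Probability vector.
#' @return Integer vector of counts summing to `n`.
#' @export
#' @examples
#' apportion_counts(1000, c(0.9, 0.1)) # 900 100
apportion_counts <- function(n, proportions) {
  check_prob_vector(proportions, "proportions")
  quota <- n * proportions
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- quota - counts
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Imbalance ratio of class counts
#'
#' The ratio of the largest to the smallest class count,
#' `rho = max_k N_k / min_k N_k`.
#'
#' @param class_counts Integer vector of per-class sample counts, all >= 1.
#' @return A single number >= 1.
#' @export
#' @examples
#' imbalance_ratio(c(90, 10)) # 9
imbalance_ratio <- function(class_counts) {
  if (any(class_counts < 1)) {
    stop_mm("degenerate class: every class count must be >= 1")
  }
  max(class_counts) / min(class_counts)
}

#' Apply a label-noise transition matrix
#'
#' Draws each observed label from the row of the row-stochastic matrix `eta`
#' indexed by the true label: `Pr(obs = k | true = l) = eta[l, k]`.
#'
#' @param labels Integer vector of true labels in `1..K`.
#' @param eta `K x K` row-stochastic transition matrix.
#' @param seed Integer seed (reproducible).
#' @return Integer vector of observed labels.
#' @export
apply_label_noise <- function(labels, eta, seed = 1L) {
  check_row_stochastic(eta, "eta")
  K <- nrow(eta)
  if (any(labels < 1L | labels > K)) stop_mm("labels out of 1..K")
  with_seed(seed, {
    u <- stats::runif(length(labels))
    cum <- t(apply(eta, 1L, cumsum))
    out <- integer(length(labels))
    for (l in seq_len(K)) {
      idx <- which(labels == l)
      if (length(idx)) {
        out[idx] <- findInterval(u[idx], cum[l, ], left.open = TRUE) + 1L
      }
    }
    pmin(out, K)
  })
}

# Columns of `data` holding features, grouped by modality, in manifest order.
feature_columns <- function(manifest) {
  purrr::imap(as.list(manifest$modality_dims), function(d, nm) {
    sprintf("%s_%02d", nm, seq_len(d))
  })
}

#' Generate a synthetic multimodal dataset
#'
#' Realizes an [mm_spec()]: exact largest-remainder class counts; per-modality
#' Gaussian class-conditional features with unit within-class scale and class
#' means rescaled so their mean pairwise distance equals `class_separation`;
#' an optional shared latent scalar coupling the modalities; optional
#' sign-product interaction labels; label noise through the transition matrix;
#' missing-completely-at-random entries (stored as `NA`); and stratified
#' train/val/test splits. Identical specs reproduce the bundle bit-identically.
#'
#' @param spec An [mm_spec()].
#' @return An object of class `mm_bundle`: a list with `data` (tibble with
#'   `sample_id`, `split`, `true_label`, `observed_label` and one column per
#'   feature), `manifest` (modality names/dims, classes, feature column map,
#'   spec echo) and `class_counts` (tally of observed labels).
#' @export
#' @examples
#' b <- simulate_multimodal(mm_spec(60, class_proportions = c(0.75, 0.25),
#'                                  modality_dims = c(img = 3, mol = 2),
#'                                  seed = 7))
#' b$class_counts
simulate_multimodal <- function(spec) {
  stopifnot(inherits(spec, "mm_spec"))
  n <- spec$n_samples
  K <- spec$n_classes
  dims <- spec$modality_dims
  M <- length(dims)

  # -- true labels ----------------------------------------------------------
  if (spec$interaction_label_mode) {
    true_label <- NULL # assigned after features below
  } else {
    counts <- apportion_counts(n, spec$class_proportions)
    lab <- rep.int(seq_len(K), counts)
    true_label <- with_seed(substream_seed(spec$seed, "labels"),
                            sample(lab, n, replace = FALSE))
  }

  # -- class means ----------------------------------------------------------
  # Per modality: K x d_m standard-normal draws, column-centred, rescaled so
  # the mean pairwise distance between class means equals class_separation.
  means <- with_seed(substream_seed(spec$seed, "means"), {
    purrr::map(as.list(dims), function(d) {
      mu <- matrix(stats::rnorm(K * d), K, d)
      mu <- sweep(mu, 2L, colMeans(mu))
      pd <- stats::dist(mu)
      avg <- mean(pd)
      if (avg > 0) mu <- mu * (spec$class_separation / avg)
      mu
    })
  })

  # -- features -------------------------------------------------------------
  feats <- with_seed(substream_seed(spec$seed, "features"), {
    g <- stats::rnorm(n) # shared latent factor
    purrr::imap(as.list(dims), function(d, nm) {
      x <- matrix(stats::rnorm(n * d), n, d)
      if (spec$cross_modal_coupling > 0) {
        x <- x + spec$cross_modal_coupling * g
      }
      x
    })
  })

  if (spec$interaction_label_mode) {
    # Label from the sign product of the first coordinates of modalities 1, 2
    # of the noise-free features; class means are not used.
    s <- sign(feats[[1L]][, 1L]) * sign(feats[[2L]][, 1L])
    true_label <- ifelse(s > 0, 1L, 2L)
  } else {
    feats <- purrr::imap(feats, function(x, nm) {
      x + means[[nm]][true_label, , drop = FALSE]
    })
  }

  # -- label noise ----------------------------------------------------------
  observed_label <- if (!is.null(spec$label_noise)) {
    apply_label_noise(true_label, spec$label_noise,
                      substream_seed(spec$seed, "noise"))
  } else {
    true_label
  }

  # -- missingness (MCAR) ---------------------------------------------------
  if (spec$missing_rate > 0) {
    feats <- with_seed(substream_seed(spec$seed, "missing"), {
      purrr::map(feats, function(x) {
        x[matrix(stats::runif(length(x)) < spec$missing_rate,
                 nrow(x), ncol(x))] <- NA_real_
        x
      })
    })
  }

  # -- splits (stratified by observed label) --------------------------------
  split <- with_seed(substream_seed(spec$seed, "split"), {
    out <- character(n)
    for (k in seq_len(K)) {
      idx <- which(observed_label == k)
      idx <- sample(idx)
      nk <- length(idx)
      n_tr <- round(nk * spec$split_fractions[["train"]])
      n_va <- round(nk * spec$split_fractions[["val"]])
      n_va <- min(n_va, nk - n_tr)
      tags <- rep("test", nk)
      if (n_tr > 0) tags[seq_len(n_tr)] <- "train"
      if (n_va > 0) tags[n_tr + seq_len(n_va)] <- "val"
      out[idx] <- tags
    }
    out
  })

  manifest <- list(
    n_classes = K,
    classes = seq_len(K),
    modality_dims = dims,
    spec = spec
  )
  cols <- feature_columns(manifest)
  feat_mat <- do.call(cbind, feats)
  colnames(feat_mat) <- unlist(cols)
  data <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    split = split,
    true_label = as.integer(true_label),
    observed_label = as.integer(observed_label)
  )
  data <- dplyr::bind_cols(data, tibble::as_tibble(feat_mat))

  structure(
    list(
      data = data,
      manifest = manifest,
      class_counts = tabulate(observed_label, nbins = K)
    ),
    class = "mm_bundle"
  )
}

#' @export
print.mm_bundle <- function(x, ...) {
  cat("<mm_bundle>", nrow(x$data), "samples,",
      x$manifest$n_classes, "classes,",
      length(x$manifest$modality_dims), "modalities\n")
  cat("  class counts:", paste(x$class_counts, collapse = ", "),
      " (rho =", signif(imbalance_ratio(x$class_counts), 4), ")\n")
  cat("  splits:", paste(names(table(x$data$split)),
                         table(x$data$split), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Flag additional entries missing completely at random
#'
#' Sets each (still-observed) feature entry of the bundle to `NA`
#' independently with probability `missing_rate`.
#'
#' @param bundle An `mm_bundle`.
#' @param missing_rate Probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The bundle with additional `NA` entries.
#' @export
apply_missingness <- function(bundle, missing_rate, seed = 1L) {
  stopifnot(inherits(bundle, "mm_bundle"))
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_mm("missing_rate must lie in [0, 1)")
  }
  if (missing_rate == 0) return(bundle)
  cols <- unlist(feature_columns(bundle$manifest))
  x <- as.matrix(bundle$data[cols])
  with_seed(seed, {
    x[matrix(stats::runif(length(x)) < missing_rate, nrow(x), ncol(x))] <- NA_real_
  })
  bundle$data[cols] <- tibble::as_tibble(x)
  bundle
}

#' Impute missing feature entries from train-split statistics
#'
#' Replaces every `NA` feature entry (in all splits) with the mean of that
#' feature computed on the *training split only*; no statistic ever uses the
#' validation or test split. All generated features are continuous, so mean
#' imputation applies throughout (a categorical column would take the
#' train-split mode).
#'
#' @param bundle An `mm_bundle` with split assignments.
#' @return The bundle with no missing feature entries; the train-split means
#'   used are attached as `bundle$imputation_means`.
#' @export
impute_missing <- function(bundle) {
  stopifnot(inherits(bundle, "mm_bundle"))
  if (!"split" %in% names(bundle$data) || !any(bundle$data$split == "train")) {
    stop_mm("imputation requires a non-empty train split")
  }
  cols <- unlist(feature_columns(bundle$manifest))
  x <- as.matrix(bundle$data[cols])
  tr <- bundle$data$split == "train"
  mu <- colMeans(x[tr, , drop = FALSE], na.rm = TRUE)
  mu[is.nan(mu)] <- 0 # feature entirely missing in train
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- mu[nas[, 2L]]
  bundle$data[cols] <- tibble::as_tibble(x)
  bundle$imputation_means <- mu
  bundle
}

# Per-modality feature matrices (list of n x d_m) in manifest order.
modality_matrices <- function(data, manifest) {
  cols <- feature_columns(manifest)
  purrr::map(cols, function(cc) as.matrix(data[cc]))
}

#' Simulate logits with a known miscalibration factor
#'
#' A two-class, one-dimensional Gaussian location model (means `-delta/2` and
#' `+delta/2`, unit variance, equal priors) whose exact posterior is known in
#' closed form. Emitted logits are `miscal` times the true class
#' log-posterior, so a global temperature fit on them should recover
#' `T = miscal`, and `miscal = 1` yields already-calibrated logits.
#'
#' @param n Number of samples.
#' @param miscal Sharpening factor applied to the true log-posterior.
#' @param delta Distance between the class means (default 2).
#' @param seed Integer seed.
#' @return Tibble with `label` (1 or 2), logit columns `z1`, `z2`, and the
#'   true posterior probability columns `p1`, `p2`.
#' @export
simulate_miscalibrated_logits <- function(n, miscal = 2, delta = 2, seed = 1L) {
  with_seed(seed, {
    y <- sample(c(1L, 2L), n, replace = TRUE)
    x <- stats::rnorm(n, mean = ifelse(y == 1L, -delta / 2, delta / 2))
    # log p(y = k | x) up to a constant: -(x - mu_k)^2 / 2
    lp <- cbind(-(x + delta / 2)^2 / 2, -(x - delta / 2)^2 / 2)
    post <- softmax_rows(lp)
    tibble::tibble(
      label = y,
      z1 = miscal * lp[, 1L],
      z2 = miscal * lp[, 2L],
      p1 = post[, 1L],
      p2 = post[, 2L]
    )
  })
}

#' Write a dataset bundle to plain-text files
#'
#' One CSV per modality (features only, `NA` sentinel for missing), one labels
#' CSV (`sample_id`, `observed_label`, `true_label`, `split`) and a manifest
#' JSON echoing the generating spec.
#'
#' @param bundle An `mm_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mm_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mm_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- feature_columns(bundle$manifest)
  purrr::iwalk(cols, function(cc, nm) {
    readr::write_csv(bundle$data[c("sample_id", cc)],
                     file.path(dir, paste0("modality_", nm, ".csv")))
  })
  readr::write_csv(
    bundle$data[c("sample_id", "observed_label", "true_label", "split")],
    file.path(dir, "labels.csv")
  )
  spec <- bundle$manifest$spec
  spec_echo <- list(
    n_samples = spec$n_samples,
    n_classes = spec$n_classes,
    class_proportions = spec$class_proportions,
    modality_dims = as.list(spec$modality_dims),
    class_separation = spec$class_separation,
    cross_modal_coupling = spec$cross_modal_coupling,
    interaction_label_mode = spec$interaction_label_mode,
    label_noise = spec$label_noise,
    missing_rate = spec$missing_rate,
    split_fractions = as.list(spec$split_fractions),
    seed = spec$seed
  )
  spec_echo <- spec_echo[!vapply(spec_echo, is.null, logical(1))]
  manifest <- list(
    n_classes = bundle$manifest$n_classes,
    modalities = as.list(bundle$manifest$modality_dims),
    class_counts = bundle$class_counts,
    spec = spec_echo
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_mm_bundle()]
#'
#' @param dir Directory containing `manifest.json`, `labels.csv` and the
#'   per-modality CSVs.
#' @return An `mm_bundle`.
#' @export
read_mm_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  sp <- man$spec
  spec <- mm_spec(
    n_samples = sp$n_samples,
    n_classes = sp$n_classes,
    class_proportions = sp$class_proportions,
    modality_dims = unlist(sp$modality_dims),
    class_separation = sp$class_separation,
    cross_modal_coupling = sp$cross_modal_coupling,
    interaction_label_mode = sp$interaction_label_mode,
    label_noise = if (length(sp$label_noise)) as.matrix(sp$label_noise),
    missing_rate = sp$missing_rate,
    split_fractions = unlist(sp$split_fractions),
    seed = sp$seed
  )
  labels <- readr::read_csv(file.path(dir, "labels.csv"),
                            show_col_types = FALSE)
  manifest <- list(
    n_classes = man$n_classes,
    classes = seq_len(man$n_classes),
    modality_dims = stats::setNames(as.integer(unlist(man$modalities)),
                                    names(man$modalities)),
    spec = spec
  )
  cols <- feature_columns(manifest)
  feats <- purrr::imap(cols, function(cc, nm) {
    readr::read_csv(file.path(dir, paste0("modality_", nm, ".csv")),
                    show_col_types = FALSE)[cc]
  })
  data <- dplyr::bind_cols(
    labels[c("sample_id", "split", "true_label", "observed_label")],
    feats
  )
  structure(
    list(
      data = data,
      manifest = manifest,
      class_counts = tabulate(labels$observed_label, nbins = man$n_classes)
    ),
    class = "mm_bundle"
  )
}
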