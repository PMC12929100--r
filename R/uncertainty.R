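# Epistemic uncertainty by Monte-Carlo dropout: dropout stays active at
# inference, repeated stochastic forward passes give a predictive mean, a
# per-class variance, and a scalar per-sample uncertainty u (the mean of the
# per-class probability variances) consumed by the calibration stage.

#' Inverted dropout
#'
#' Zeroes each entry independently with probability `p` and rescales the
#' survivors by `1/(1-p)`, so the expectation equals the input. The variance
#' of a masked entry `x` is `p(1-p) x^2 / (1-p)^2`.
#'
#' @param x Numeric vector or matrix.
#' @param p Dropout probability in `[0, 1)`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return `x` with dropped entries.
#' @export
apply_dropout <- function(x, p, seed = NULL) {
  if (p < 0 || p >= 1) stop_mm("dropout probability must lie in [0, 1)")
  if (p == 0) return(x)
  draw <- function() x * ((stats::runif(length(x)) >= p) / (1 - p))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Pre-generate one sample's dropout masks for all passes, from the sample's
# own stream. Returns u[pass][[layer]]$attn/[[ffn]][[token]] as length-h
# vectors; draw order matches draw_dropout_masks() with n = 1.
sample_mask_stream <- function(config, n_passes, seed) {
  p <- config$dropout_rate
  h <- config$embed_dim
  M <- length(config$modality_dims)
  L <- config$n_layers
  with_seed(seed, {
    purrr::map(seq_len(n_passes), function(t) {
      purrr::map(seq_len(L), function(l) {
        list(
          attn = purrr::map(seq_len(M), function(i) {
            (stats::runif(h) >= p) / (1 - p)
          }),
          ffn = purrr::map(seq_len(M), function(i) {
            (stats::runif(h) >= p) / (1 - p)
          })
        )
      })
    })
  })
}

mc_seed_for <- function(seed, sample_id) {
  substream_seed(seed, paste0("mc/", sample_id))
}

#' Monte-Carlo-dropout prediction for one sample
#'
#' Runs `n_passes` stochastic forward passes with dropout active, each pass
#' sampling fresh Bernoulli masks, and summarizes the per-pass softmax
#' outputs: predictive mean, per-class variance, and the scalar uncertainty
#' `u = mean(class_variance)`.
#'
#' @param model An `mm_fit`.
#' @param features List of M numeric feature vectors (imputed) or a one-row
#'   tibble with the manifest's feature columns.
#' @param n_passes Number of stochastic passes (>= 2; variance is undefined
#'   below that).
#' @param p_drop Dropout probability; defaults to the model's training value.
#' @param seed Integer seed (reproducible).
#' @return An object of class `mm_uncertainty` with `mean_probs`,
#'   `class_variance`, `u`, `n_passes`, `seed`.
#' @export
mc_dropout_predict <- function(model, features, n_passes = 30L,
                               p_drop = model$config$dropout_rate,
                               seed = 1L) {
  if (n_passes < 2) stop_mm("n_passes must be >= 2 (variance undefined)")
  cfg <- model$config
  cfg$dropout_rate <- p_drop
  if (is.data.frame(features)) {
    X <- modality_matrices(features, model$manifest)
  } else {
    X <- purrr::map(features, ~ matrix(.x, nrow = 1L))
  }
  probs <- matrix(0, n_passes, cfg$n_classes)
  if (p_drop == 0) {
    fw <- forward_encoder(model$params, cfg, X)
    p1 <- drop(softmax_rows(fw$logits))
    probs <- matrix(p1, n_passes, cfg$n_classes, byrow = TRUE)
  } else {
    streams <- sample_mask_stream(cfg, n_passes, seed)
    for (t in seq_len(n_passes)) {
      masks <- purrr::map(streams[[t]], function(layer) {
        list(attn = purrr::map(layer$attn, ~ matrix(.x, nrow = 1L)),
             ffn = purrr::map(layer$ffn, ~ matrix(.x, nrow = 1L)))
      })
      fw <- forward_encoder(model$params, cfg, X, masks = masks)
      probs[t, ] <- softmax_rows(fw$logits)
    }
  }
  cv <- apply(probs, 2L, stats::var)
  structure(
    list(mean_probs = colMeans(probs), class_variance = cv,
         u = mean(cv), n_passes = as.integer(n_passes),
         seed = as.integer(seed)),
    class = "mm_uncertainty"
  )
}

#' @export
print.mm_uncertainty <- function(x, ...) {
  cat("<mm_uncertainty>", x$n_passes, "passes, u =", signif(x$u, 5), "\n")
  cat("  mean probs:", paste(signif(x$mean_probs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Monte-Carlo-dropout uncertainty for a whole dataset
#'
#' Vectorized over samples: each sample's Bernoulli mask stream is derived
#' from the global seed and its `sample_id`, so per-sample results do not
#' depend on the order or composition of the batch.
#'
#' @param model An `mm_fit`.
#' @param bundle An `mm_bundle`, or a tibble with `sample_id` and the feature
#'   columns.
#' @param n_passes Number of stochastic passes (>= 2).
#' @param p_drop Dropout probability; defaults to the model's value.
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, mean-probability columns `p1..pK`, and `u`.
#' @export
batch_uncertainty <- function(model, bundle, n_passes = 30L,
                              p_drop = model$config$dropout_rate,
                              seed = 1L) {
  if (n_passes < 2) stop_mm("n_passes must be >= 2 (variance undefined)")
  cfg <- model$config
  cfg$dropout_rate <- p_drop
  if (inherits(bundle, "mm_bundle")) {
    if (anyNA(bundle$data[unlist(feature_columns(bundle$manifest))])) {
      bundle <- impute_missing(bundle)
    }
    df <- bundle$data
  } else {
    df <- bundle
  }
  X <- modality_matrices(df, model$manifest)
  n <- nrow(df)
  K <- cfg$n_classes

  if (p_drop == 0) {
    fw <- forward_encoder(model$params, cfg, X)
    p <- softmax_rows(fw$logits)
    out <- tibble::as_tibble(p, .name_repair = ~ paste0("p", seq_len(K)))
    out <- dplyr::bind_cols(tibble::tibble(sample_id = df$sample_id), out)
    out$u <- 0
    return(out)
  }

  # per-sample mask streams, assembled into batch masks per pass
  streams <- purrr::map(df$sample_id, function(id) {
    sample_mask_stream(cfg, n_passes, mc_seed_for(seed, id))
  })
  M <- length(cfg$modality_dims)
  L <- cfg$n_layers
  sum_p <- matrix(0, n, K)
  sum_p2 <- matrix(0, n, K)
  for (t in seq_len(n_passes)) {
    masks <- purrr::map(seq_len(L), function(l) {
      list(
        attn = purrr::map(seq_len(M), function(i) {
          do.call(rbind, purrr::map(streams, ~ .x[[t]][[l]]$attn[[i]]))
        }),
        ffn = purrr::map(seq_len(M), function(i) {
          do.call(rbind, purrr::map(streams, ~ .x[[t]][[l]]$ffn[[i]]))
        })
      )
    })
    fw <- forward_encoder(model$params, cfg, X, masks = masks)
    p <- softmax_rows(fw$logits)
    sum_p <- sum_p + p
    sum_p2 <- sum_p2 + p^2
  }
  mean_p <- sum_p / n_passes
  # sample variance over passes
  cv <- pmax((sum_p2 - n_passes * mean_p^2) / (n_passes - 1), 0)
  out <- tibble::as_tibble(mean_p, .name_repair = ~ paste0("p", seq_len(K)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = df$sample_id), out)
  out$u <- rowMeans(cv)
  out
}
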