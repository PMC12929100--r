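# Imbalance-aware training: inverse-frequency class weights, weighted
# cross-entropy (optionally plus a pooled-representation norm penalty),
# minibatch Adam with decoupled weight decay, and early stopping on the
# validation loss.

#' Inverse-frequency class weights
#'
#' `w_k = N / (K * N_k)`: balanced data gives all-ones, rare classes get
#' proportionally larger weights.
#'
#' @param class_counts Per-class sample counts, all >= 1.
#' @return Numeric weight vector of length `K`.
#' @export
#' @examples
#' class_weights(c(90, 10)) # 0.556, 5
class_weights <- function(class_counts) {
  if (any(class_counts < 1)) stop_mm("every class count must be >= 1")
  N <- sum(class_counts)
  K <- length(class_counts)
  N / (K * class_counts)
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `-w[y_i] * log p_i[y_i]`. Probabilities at the true
#' class are clamped at `1e-12` (with a warning) to avoid infinite loss;
#' `w = NULL` or all-ones gives plain cross-entropy.
#'
#' @param probs `n x K` matrix of predicted probabilities (rows sum to 1).
#' @param labels Integer labels in `1..K`.
#' @param weights Optional per-class weight vector.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights = NULL) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  K <- ncol(probs)
  if (is.null(weights)) weights <- rep(1, K)
  py <- probs[cbind(seq_along(labels), labels)]
  if (any(py < 1e-12)) {
    warning("probability at true class clamped at 1e-12", call. = FALSE)
    py <- pmax(py, 1e-12)
  }
  mean(-weights[labels] * log(py))
}

#' Pooled-representation norm penalty
#'
#' `lambda * mean ||pooled_i||^2` over the batch: an optional regularizer that
#' discourages runaway feature magnitudes. Off by default in training.
#'
#' @param pooled Pooled fused representation: length-`h` vector or `n x h`
#'   matrix.
#' @param lambda_scale Nonnegative coefficient.
#' @return Scalar penalty.
#' @export
#' @examples
#' scale_regularizer(c(3, 4), 0.1) # 2.5
scale_regularizer <- function(pooled, lambda_scale) {
  if (lambda_scale < 0) stop_mm("lambda_scale must be nonnegative")
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = 1L)
  lambda_scale * mean(rowSums(pooled^2))
}

#' Train the multimodal encoder
#'
#' Minimizes weighted cross-entropy (plus the optional [scale_regularizer()]
#' term) with minibatch Adam and decoupled weight decay. Stops early after
#' `patience` epochs without validation-loss improvement and returns the
#' best-epoch parameters. Fully reproducible for a fixed seed on one device.
#'
#' @param bundle An `mm_bundle` with non-empty train and val splits; missing
#'   entries are imputed from train-split means automatically.
#' @param config An [encoder_config()]; defaults to a small two-layer model
#'   sized from the bundle's manifest.
#' @param learning_rate Adam step size (desk-scale default `1e-3`).
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param max_epochs,batch_size,patience Training schedule.
#' @param use_class_weights Weight the loss by inverse class frequency
#'   (`FALSE` gives plain cross-entropy).
#' @param lambda_scale Coefficient of the pooled-norm penalty (0 = off).
#' @param gamma_imb,beta_unc Reserved coefficients for imbalance/uncertainty
#'   loss terms; must be 0 (no functional form is defined).
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @return An object of class `mm_fit`: best-epoch parameters, config, class
#'   weights, per-epoch loss history and the best epoch index.
#' @export
fit_encoder <- function(bundle,
                        config = NULL,
                        learning_rate = 1e-3,
                        weight_decay = 1e-5,
                        max_epochs = 30L,
                        batch_size = 32L,
                        patience = 10L,
                        use_class_weights = TRUE,
                        lambda_scale = 0,
                        gamma_imb = 0,
                        beta_unc = 0,
                        seed = 1L) {
  stopifnot(inherits(bundle, "mm_bundle"))
  if (patience > max_epochs) stop_mm("patience must be <= max_epochs")
  if (gamma_imb < 0 || beta_unc < 0 || lambda_scale < 0) {
    stop_mm("loss coefficients must be nonnegative")
  }
  if (is.null(config)) {
    config <- encoder_config(bundle$manifest$modality_dims,
                             bundle$manifest$n_classes, seed = seed)
  }
  K <- config$n_classes

  data <- bundle$data
  if (anyNA(data[unlist(feature_columns(bundle$manifest))])) {
    bundle <- impute_missing(bundle)
    data <- bundle$data
  }
  tr <- data$split == "train"
  va <- data$split == "val"
  if (!any(tr) || !any(va)) stop_mm("train and val splits must be non-empty")

  X_tr <- modality_matrices(data[tr, ], bundle$manifest)
  y_tr <- data$observed_label[tr]
  X_va <- modality_matrices(data[va, ], bundle$manifest)
  y_va <- data$observed_label[va]

  counts <- tabulate(y_tr, nbins = K)
  if (any(counts == 0)) stop_mm("every class must appear in the train split")
  w <- if (use_class_weights) class_weights(counts) else rep(1, K)

  params <- init_encoder(config)
  skel <- unclass(params)
  theta <- unlist(params)
  mask <- unlist(decay_mask(params))
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n_tr <- length(y_tr)

  eval_loss <- function(params, X, y) {
    fw <- forward_encoder(params, config, X)
    weighted_cross_entropy(softmax_rows(fw$logits), y, w)
  }

  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            val_loss = numeric())
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  stall <- 0L

  with_seed(substream_seed(seed, "train"), {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = batch_size)
      for (s in starts) {
        b <- idx[s:min(s + batch_size - 1L, n_tr)]
        Xb <- purrr::map(X_tr, ~ .x[b, , drop = FALSE])
        masks <- if (config$dropout_rate > 0) {
          draw_dropout_masks(length(b), config)
        }
        lg <- encoder_loss_grad(params, config, Xb, y_tr[b], w,
                                masks = masks, lambda_scale = lambda_scale)
        if (!is.finite(lg$loss)) {
          stop_mm("training diverged (non-finite loss) at epoch ", epoch)
        }
        g <- unlist(lg$grads)
        t_step <- t_step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^t_step)
        vh <- v / (1 - b2^t_step)
        theta <- theta - learning_rate * mh / (sqrt(vh) + eps) -
          learning_rate * weight_decay * mask * theta
        params <- utils::relist(theta, skel)
      }
      tl <- eval_loss(params, X_tr, y_tr)
      vl <- eval_loss(params, X_va, y_va)
      history <- dplyr::bind_rows(history,
        tibble::tibble(epoch = epoch, train_loss = tl, val_loss = vl))
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best_params <- params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  })

  structure(
    list(
      params = best_params,
      config = config,
      class_weights = w,
      class_counts = counts,
      history = history,
      best_epoch = best_epoch,
      manifest = bundle$manifest,
      train_config = list(
        learning_rate = learning_rate, weight_decay = weight_decay,
        max_epochs = max_epochs, batch_size = batch_size,
        patience = patience, use_class_weights = use_class_weights,
        lambda_scale = lambda_scale, gamma_imb = gamma_imb,
        beta_unc = beta_unc, seed = seed
      )
    ),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>", length(unlist(x$params)), "parameters,",
      nrow(x$history), "epochs run, best epoch", x$best_epoch, "\n")
  cat("  best val loss:",
      signif(min(x$history$val_loss), 6), "\n")
  invisible(x)
}

#' Predict from a fitted encoder
#'
#' @param object An `mm_fit`.
#' @param newdata An `mm_bundle` or a tibble with the manifest's feature
#'   columns (missing entries must already be imputed).
#' @param type `"prob"` (default: probabilities + predicted class),
#'   `"class"`, or `"logit"`.
#' @param ... Unused.
#' @return A tibble, one row per sample.
#' @export
predict.mm_fit <- function(object, newdata, type = c("prob", "class", "logit"),
                           ...) {
  type <- match.arg(type)
  if (inherits(newdata, "mm_bundle")) {
    if (anyNA(newdata$data[unlist(feature_columns(newdata$manifest))])) {
      newdata <- impute_missing(newdata)
    }
    df <- newdata$data
  } else {
    df <- newdata
  }
  X <- modality_matrices(df, object$manifest)
  fw <- forward_encoder(object$params, object$config, X)
  out <- predict_probs(fw$logits)
  if ("sample_id" %in% names(df)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = df$sample_id), out)
  }
  switch(type,
    prob = out,
    class = out[c(intersect("sample_id", names(out)), ".pred")],
    logit = {
      z <- tibble::as_tibble(fw$logits,
        .name_repair = ~ paste0("z", seq_len(ncol(fw$logits))))
      if ("sample_id" %in% names(df)) {
        dplyr::bind_cols(tibble::tibble(sample_id = df$sample_id), z)
      } else {
        z
      }
    }
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch loss history of a fitted encoder
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.mm_fit <- function(x, ...) x$history

#' One-row summary of a fitted encoder
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs run, best epoch and losses.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    n_params = length(unlist(x$params)),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss),
    final_train_loss = x$history$train_loss[nrow(x$history)]
  )
}
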