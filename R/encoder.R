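# Multimodal attention-fusion encoder.
#
# One token per modality: modality m's feature vector is embedded by an
# affine map + tanh into a shared width h, a learnable positional encoding is
# added, L post-LayerNorm transformer layers (multi-head self-attention +
# position-wise feed-forward, each wrapped as LayerNorm(x + sublayer(x)))
# contextualize the M tokens, explicit pairwise cross-modality attention terms
# C(i -> j) are added to the receiving token, the fused tokens are mean-pooled
# and a linear head produces class logits.
#
# Internally a batch is a list of M matrices (one n x h matrix per token);
# loops run only over the small M and head counts, so everything heavy is a
# matrix product. The public single-sample operations below are thin wrappers
# over the same code paths.

LN_EPS <- 1e-6

#' Configure the multimodal encoder
#'
#' @param modality_dims Named integer vector of per-modality input widths.
#' @param n_classes Number of classes `K`.
#' @param embed_dim Shared token width `h` (must be divisible by `n_heads`).
#' @param n_layers Number of transformer layers `L` (>= 1).
#' @param n_heads Number of self-attention heads.
#' @param key_dim Query/key width of the cross-modality attention
#'   (default `embed_dim / n_heads`).
#' @param dropout_rate Dropout probability applied to each sub-block output in
#'   training mode (and during Monte-Carlo-dropout inference).
#' @param ffn_dim Hidden width of the position-wise feed-forward block
#'   (default `2 * embed_dim`).
#' @param fusion If `FALSE`, all information flow across modalities is
#'   disabled: self-attention is restricted to each token itself and the
#'   cross-modality terms are dropped. Used by the fusion ablation.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `mm_encoder_config`.
#' @export
encoder_config <- function(modality_dims,
                           n_classes,
                           embed_dim = 16L,
                           n_layers = 2L,
                           n_heads = 2L,
                           key_dim = embed_dim %/% n_heads,
                           dropout_rate = 0.1,
                           ffn_dim = 2L * embed_dim,
                           fusion = TRUE,
                           seed = 1L) {
  if (is.null(names(modality_dims))) {
    names(modality_dims) <- paste0("mod", seq_along(modality_dims))
  }
  if (embed_dim %% n_heads != 0) stop_mm("embed_dim must be divisible by n_heads")
  if (n_layers < 1) stop_mm("n_layers must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_mm("dropout_rate in [0, 1)")
  structure(
    list(
      modality_dims = stats::setNames(as.integer(modality_dims), names(modality_dims)),
      n_classes = as.integer(n_classes),
      embed_dim = as.integer(embed_dim),
      n_layers = as.integer(n_layers),
      n_heads = as.integer(n_heads),
      key_dim = as.integer(key_dim),
      dropout_rate = dropout_rate,
      ffn_dim = as.integer(ffn_dim),
      fusion = isTRUE(fusion),
      seed = as.integer(seed)
    ),
    class = "mm_encoder_config"
  )
}

glorot <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weight matrices, zero biases, unit LayerNorm gains and a
#' small-normal positional encoding, all drawn from the config seed.
#'
#' @param config An [encoder_config()].
#' @return Nested list of parameter arrays (class `mm_params`).
#' @export
init_encoder <- function(config) {
  h <- config$embed_dim
  M <- length(config$modality_dims)
  dk <- config$key_dim
  with_seed(substream_seed(config$seed, "init"), {
    params <- list()
    params$embed <- purrr::map(as.list(config$modality_dims), function(d) {
      list(W = glorot(d, h), b = numeric(h))
    })
    params$pos <- matrix(stats::rnorm(M * h, sd = 0.02), M, h)
    params$layers <- purrr::map(seq_len(config$n_layers), function(l) {
      list(
        Wq = glorot(h, h), Wk = glorot(h, h), Wv = glorot(h, h),
        Wo = glorot(h, h),
        ln1_g = rep(1, h), ln1_b = numeric(h),
        W1 = glorot(h, config$ffn_dim), b1 = numeric(config$ffn_dim),
        W2 = glorot(config$ffn_dim, h), b2 = numeric(h),
        ln2_g = rep(1, h), ln2_b = numeric(h)
      )
    })
    params$cross <- list()
    if (config$fusion && M > 1) {
      for (i in seq_len(M)) {
        for (j in seq_len(M)) {
          if (i != j) {
            params$cross[[paste0(i, "->", j)]] <-
              list(Wq = glorot(h, dk), Wk = glorot(h, dk), Wv = glorot(h, h))
          }
        }
      }
    }
    params$head <- list(W = glorot(h, config$n_classes),
                        b = numeric(config$n_classes))
    structure(params, class = "mm_params")
  })
}

# ---------------------------------------------------------------------------
# Public single-sample operations (matrix in, matrix out)
# ---------------------------------------------------------------------------

#' Embed one sample's modalities into tokens
#'
#' Applies each modality-specific affine map followed by `tanh`, producing one
#' token (row) per modality.
#'
#' @param features List of M numeric vectors (modality order = manifest order).
#' @param params Encoder parameters from [init_encoder()].
#' @return `M x h` token matrix.
#' @export
embed_modalities <- function(features, params) {
  stopifnot(length(features) == length(params$embed))
  rows <- purrr::map2(features, params$embed, function(x, pm) {
    if (length(x) != nrow(pm$W)) {
      stop_mm("feature length ", length(x), " does not match embedding width ",
              nrow(pm$W))
    }
    if (anyNA(x)) stop_mm("missing entries must be imputed before embedding")
    tanh(drop(x %*% pm$W) + pm$b)
  })
  do.call(rbind, unname(rows))
}

#' Add a learnable positional encoding
#'
#' @param H `M x h` token matrix.
#' @param P `M x h` positional-encoding parameter.
#' @return `H + P`.
#' @export
add_positional_encoding <- function(H, P) {
  if (!identical(dim(H), dim(P))) stop_mm("H and P shapes differ")
  H + P
}

#' Layer normalization of each row
#'
#' @param x Numeric matrix (rows are normalized independently).
#' @param g,b Gain and bias vectors of length `ncol(x)`.
#' @return Matrix of the same shape.
#' @keywords internal
layer_norm <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  sweep(xc * inv, 2L, g, `*`) + rep(b, each = nrow(x))
}

#' Cross-modality attention
#'
#' Queries from modality i's tokens, keys and values from modality j's:
#' `C(i->j) = softmax(H_i W_Q (H_j W_K)' / sqrt(d_k)) H_j W_V`. Rows of the
#' attention matrix sum to one.
#'
#' @param H_i,H_j Token matrices of the two (distinct) modalities.
#' @param W_Q,W_K Projections `h x d_k`.
#' @param W_V Value projection `h x h`.
#' @param d_k Key width used in the scaling (default `ncol(W_Q)`).
#' @param return_weights Also return the attention weight matrix.
#' @return The cross-attention output (rows aligned with `H_i`), or a list
#'   `(C, weights)` when `return_weights = TRUE`.
#' @export
cross_modal_attention <- function(H_i, H_j, W_Q, W_K, W_V,
                                  d_k = ncol(W_Q), return_weights = FALSE) {
  scores <- (H_i %*% W_Q) %*% t(H_j %*% W_K) / sqrt(d_k)
  A <- softmax_rows(scores)
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  C <- A %*% (H_j %*% W_V)
  if (return_weights) list(C = C, weights = A) else C
}

#' Fuse contextualized tokens with cross-modality signals
#'
#' Adds each cross-attention output `C(i->j)` to the row of the receiving
#' modality `i` and mean-pools the fused tokens.
#'
#' @param H_L `M x h` matrix of contextualized tokens.
#' @param cross Named list of cross-attention outputs; names `"i->j"` give the
#'   receiving row `i`. May be empty (single modality).
#' @return List with `H_fused` (`M x h`) and `pooled` (length-`h` vector).
#' @export
fuse_tokens <- function(H_L, cross = list()) {
  H_fused <- H_L
  for (nm in names(cross)) {
    i <- as.integer(sub("->.*$", "", nm))
    H_fused[i, ] <- H_fused[i, ] + drop(cross[[nm]])
  }
  list(H_fused = H_fused, pooled = colMeans(H_fused))
}

#' Class logits from a fused representation
#'
#' @param pooled Length-`h` pooled fused representation (or an `n x h` matrix).
#' @param params Encoder parameters.
#' @return Logit vector of length `K` (or `n x K` matrix).
#' @export
classify_logits <- function(pooled, params) {
  if (is.null(dim(pooled))) {
    drop(pooled %*% params$head$W) + params$head$b
  } else {
    sweep(pooled %*% params$head$W, 2L, params$head$b, `+`)
  }
}

#' Probabilities and predicted label from logits
#'
#' Softmax probabilities (summing to one) and the arg-max label with ties
#' broken toward the lowest class index. Invariant under adding a constant to
#' all logits.
#'
#' @param z Logit vector (length `K`) or `n x K` matrix.
#' @return Tibble with one row per sample: probability columns `p1..pK` and
#'   `.pred` (predicted class index).
#' @export
#' @examples
#' predict_probs(c(0, 0)) # 0.5 / 0.5, class 1 by the tie rule
predict_probs <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (any(!is.finite(z))) stop_mm("non-finite logits")
  p <- softmax_rows(z)
  out <- tibble::as_tibble(p, .name_repair = ~ paste0("p", seq_len(ncol(p))))
  out$.pred <- apply(p, 1L, argmax_first)
  out
}

# ---------------------------------------------------------------------------
# Batched forward pass
# ---------------------------------------------------------------------------

# Draw inverted-dropout masks (already scaled by 1/(1-p)) for one forward
# pass: masks[[l]]$attn[[i]], masks[[l]]$ffn[[i]], each n x h. Uses the
# current RNG state.
draw_dropout_masks <- function(n, config) {
  p <- config$dropout_rate
  if (p <= 0) return(NULL)
  h <- config$embed_dim
  M <- length(config$modality_dims)
  purrr::map(seq_len(config$n_layers), function(l) {
    list(
      attn = purrr::map(seq_len(M), function(i) {
        matrix((stats::runif(n * h) >= p) / (1 - p), n, h)
      }),
      ffn = purrr::map(seq_len(M), function(i) {
        matrix((stats::runif(n * h) >= p) / (1 - p), n, h)
      })
    )
  })
}

# row-wise layer norm with cache for backprop
ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

# Multi-head self-attention over M tokens, batched; returns output tokens and
# a cache of per-head attention weights and projections.
mhsa_forward <- function(tokens, lp, config) {
  M <- length(tokens)
  n <- nrow(tokens[[1L]])
  h <- config$embed_dim
  nh <- config$n_heads
  dk <- h %/% nh
  Q <- purrr::map(tokens, ~ .x %*% lp$Wq)
  K <- purrr::map(tokens, ~ .x %*% lp$Wk)
  V <- purrr::map(tokens, ~ .x %*% lp$Wv)
  O <- purrr::map(seq_len(M), ~ matrix(0, n, h))
  A <- vector("list", nh) # A[[head]][n, i, j]
  self_only <- !config$fusion
  for (hd in seq_len(nh)) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    if (self_only || M == 1L) {
      Ah <- array(0, c(n, M, M))
      for (i in seq_len(M)) {
        Ah[, i, i] <- 1
        O[[i]][, cols] <- V[[i]][, cols, drop = FALSE]
      }
      A[[hd]] <- Ah
    } else {
      S <- array(0, c(n, M, M))
      for (i in seq_len(M)) {
        for (j in seq_len(M)) {
          S[, i, j] <- rowSums(Q[[i]][, cols, drop = FALSE] *
                               K[[j]][, cols, drop = FALSE]) / sqrt(dk)
        }
      }
      Ah <- array(0, c(n, M, M))
      for (i in seq_len(M)) {
        Ah[, i, ] <- softmax_rows(matrix(S[, i, ], n, M))
        acc <- matrix(0, n, dk)
        for (j in seq_len(M)) {
          acc <- acc + Ah[, i, j] * V[[j]][, cols, drop = FALSE]
        }
        O[[i]][, cols] <- acc
      }
      A[[hd]] <- Ah
    }
  }
  out <- purrr::map(O, ~ .x %*% lp$Wo)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A)
}

ffn_forward <- function(x, lp) {
  pre <- sweep(x %*% lp$W1, 2L, lp$b1, `+`)
  hid <- pmax(pre, 0)
  list(out = sweep(hid %*% lp$W2, 2L, lp$b2, `+`), hid = hid)
}

# Full batched forward pass.
#
# X_list: list of M matrices (n x d_m). masks: NULL (no dropout) or the
# structure from draw_dropout_masks(). Returns logits plus (optionally) all
# intermediates needed for the backward pass.
forward_encoder <- function(params, config, X_list, masks = NULL,
                            keep_cache = FALSE) {
  M <- length(X_list)
  n <- nrow(X_list[[1L]])
  h <- config$embed_dim

  tokens <- purrr::map2(X_list, params$embed, function(x, pm) {
    tanh(sweep(x %*% pm$W, 2L, pm$b, `+`))
  })
  emb <- unname(tokens)
  tokens <- purrr::map(seq_len(M), function(i) {
    emb[[i]] + rep(params$pos[i, ], each = n)
  })
  H0 <- tokens

  layer_caches <- vector("list", config$n_layers)
  H <- H0
  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    att <- mhsa_forward(H, lp, config)
    a_out <- att$out
    if (!is.null(masks)) {
      a_out <- purrr::map2(a_out, masks[[l]]$attn, `*`)
    }
    res1 <- purrr::map2(H, a_out, `+`)
    ln1 <- purrr::map(res1, ln_forward, g = lp$ln1_g, b = lp$ln1_b)
    H1 <- purrr::map(ln1, "y")
    ff <- purrr::map(H1, ffn_forward, lp = lp)
    f_out <- purrr::map(ff, "out")
    if (!is.null(masks)) {
      f_out <- purrr::map2(f_out, masks[[l]]$ffn, `*`)
    }
    res2 <- purrr::map2(H1, f_out, `+`)
    ln2 <- purrr::map(res2, ln_forward, g = lp$ln2_g, b = lp$ln2_b)
    Hn <- purrr::map(ln2, "y")
    if (keep_cache) {
      layer_caches[[l]] <- list(H_in = H, att = att, a_out = a_out,
                                ln1 = ln1, H1 = H1, ff = ff, f_out = f_out,
                                ln2 = ln2)
    }
    H <- Hn
  }
  if (any(!is.finite(H[[1L]]))) {
    stop_mm("non-finite activations in encoder forward pass")
  }

  # Cross-modality attention: with one token per modality the softmax is over
  # a single key, so the attention weight is exactly 1 and
  # C(i -> j) = H_j W_V. The receiving token is i.
  fused <- H
  cross_out <- list()
  if (config$fusion && M > 1) {
    for (nm in names(params$cross)) {
      ij <- as.integer(strsplit(nm, "->", fixed = TRUE)[[1L]])
      C <- H[[ij[2L]]] %*% params$cross[[nm]]$Wv
      cross_out[[nm]] <- C
      fused[[ij[1L]]] <- fused[[ij[1L]]] + C
    }
  }
  pooled <- Reduce(`+`, fused) / M
  logits <- sweep(pooled %*% params$head$W, 2L, params$head$b, `+`)

  out <- list(logits = logits, pooled = pooled)
  if (keep_cache) {
    out$cache <- list(X = X_list, emb = emb, H0 = H0, layers = layer_caches,
                      HL = H, cross = cross_out, fused = fused,
                      pooled = pooled, masks = masks, n = n, M = M)
  }
  out
}

#' Contextualize tokens with stacked self-attention layers
#'
#' Runs one sample's `M x h` token matrix through the `L` transformer layers
#' (multi-head self-attention and feed-forward blocks, each wrapped in a
#' residual connection and layer normalization). Dropout is inactive here;
#' training-mode dropout lives in [fit_encoder()] and
#' [mc_dropout_predict()].
#'
#' @param H_pos `M x h` matrix of position-encoded tokens.
#' @param params,config Encoder parameters and config.
#' @return `M x h` matrix of contextualized tokens.
#' @export
transformer_encode <- function(H_pos, params, config) {
  tokens <- purrr::map(seq_len(nrow(H_pos)), function(i) H_pos[i, , drop = FALSE])
  H <- tokens
  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    att <- mhsa_forward(H, lp, config)
    res1 <- purrr::map2(H, att$out, `+`)
    H1 <- purrr::map(res1, ~ layer_norm(.x, lp$ln1_g, lp$ln1_b))
    ff <- purrr::map(H1, ~ ffn_forward(.x, lp)$out)
    res2 <- purrr::map2(H1, ff, `+`)
    H <- purrr::map(res2, ~ layer_norm(.x, lp$ln2_g, lp$ln2_b))
  }
  do.call(rbind, H)
}

#' Self-attention weights of one layer on a token matrix
#'
#' Returns the per-head attention weight matrices (each row sums to one) of
#' layer `layer` applied to `H` — a diagnostic for inspecting how modalities
#' attend to one another.
#'
#' @param H `M x h` token matrix.
#' @param params,config Encoder parameters and config.
#' @param layer Layer index.
#' @return List (one per head) of `M x M` attention weight matrices.
#' @export
self_attention_weights <- function(H, params, config, layer = 1L) {
  tokens <- purrr::map(seq_len(nrow(H)), function(i) H[i, , drop = FALSE])
  att <- mhsa_forward(tokens, params$layers[[layer]], config)
  purrr::map(att$A, function(a) matrix(a[1L, , ], dim(a)[2L], dim(a)[3L]))
}
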