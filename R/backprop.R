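# Reverse-mode gradients for the encoder, mirroring forward_encoder()
# step-by-step. Verified against central finite differences in the test
# suite. Parameters, gradients and optimizer state share one nested-list
# structure so they can be flattened to aligned numeric vectors with unlist()
# and restored with utils::relist().

zeros_like <- function(x) {
  if (is.list(x)) return(purrr::map(x, zeros_like))
  x * 0
}

# 1 for weight matrices (decoupled weight decay applies), 0 for biases,
# LayerNorm parameters and the positional encoding.
decay_mask <- function(params) {
  rec <- function(p, nm) {
    if (is.list(p)) {
      nms <- names(p) %||% rep("", length(p))
      purrr::map2(p, as.list(nms), rec)
    } else if (grepl("^W", nm)) {
      p * 0 + 1
    } else {
      p * 0
    }
  }
  rec(params, "")
}

ln_backward <- function(dy, ln, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  dx <- ln$inv * (dxhat - m1 - ln$xhat * m2)
  list(dx = dx, dg = colSums(dy * ln$xhat), db = colSums(dy))
}

mhsa_backward <- function(dout, cache, lp, config, grads_layer) {
  M <- length(dout)
  n <- nrow(dout[[1L]])
  h <- config$embed_dim
  nh <- config$n_heads
  dk <- h %/% nh
  att <- cache$att
  dO <- purrr::map(dout, ~ .x %*% t(lp$Wo))
  for (i in seq_len(M)) {
    grads_layer$Wo <- grads_layer$Wo + t(att$O[[i]]) %*% dout[[i]]
  }
  dQ <- purrr::map(seq_len(M), ~ matrix(0, n, h))
  dK <- purrr::map(seq_len(M), ~ matrix(0, n, h))
  dV <- purrr::map(seq_len(M), ~ matrix(0, n, h))
  self_only <- !config$fusion
  for (hd in seq_len(nh)) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    if (self_only || M == 1L) {
      for (i in seq_len(M)) {
        dV[[i]][, cols] <- dV[[i]][, cols] + dO[[i]][, cols, drop = FALSE]
      }
    } else {
      A <- att$A[[hd]]
      dA <- array(0, c(n, M, M))
      for (i in seq_len(M)) {
        dOh <- dO[[i]][, cols, drop = FALSE]
        for (j in seq_len(M)) {
          dA[, i, j] <- rowSums(dOh * att$V[[j]][, cols, drop = FALSE])
          dV[[j]][, cols] <- dV[[j]][, cols] + A[, i, j] * dOh
        }
      }
      for (i in seq_len(M)) {
        Ai <- matrix(A[, i, ], n, M)
        dAi <- matrix(dA[, i, ], n, M)
        dS <- (dAi - rowSums(dAi * Ai)) * Ai
        for (j in seq_len(M)) {
          dQ[[i]][, cols] <- dQ[[i]][, cols] +
            dS[, j] * att$K[[j]][, cols, drop = FALSE] / sqrt(dk)
          dK[[j]][, cols] <- dK[[j]][, cols] +
            dS[, j] * att$Q[[i]][, cols, drop = FALSE] / sqrt(dk)
        }
      }
    }
  }
  dH <- vector("list", M)
  for (i in seq_len(M)) {
    Hin <- cache$H_in[[i]]
    grads_layer$Wq <- grads_layer$Wq + t(Hin) %*% dQ[[i]]
    grads_layer$Wk <- grads_layer$Wk + t(Hin) %*% dK[[i]]
    grads_layer$Wv <- grads_layer$Wv + t(Hin) %*% dV[[i]]
    dH[[i]] <- dQ[[i]] %*% t(lp$Wq) + dK[[i]] %*% t(lp$Wk) +
      dV[[i]] %*% t(lp$Wv)
  }
  list(dH = dH, grads_layer = grads_layer)
}

# Backward pass through the whole encoder. dlogits is n x K;
# dpooled_extra (n x h or NULL) carries the pooled-norm regularizer term.
backward_encoder <- function(params, config, cache, dlogits,
                             dpooled_extra = NULL) {
  grads <- zeros_like(params)
  M <- cache$M
  n <- cache$n

  grads$head$W <- t(cache$pooled) %*% dlogits
  grads$head$b <- colSums(dlogits)
  dpooled <- dlogits %*% t(params$head$W)
  if (!is.null(dpooled_extra)) dpooled <- dpooled + dpooled_extra

  dfused_each <- dpooled / M
  dHL <- purrr::map(seq_len(M), ~ dfused_each)

  if (config$fusion && M > 1) {
    for (nm in names(params$cross)) {
      ij <- as.integer(strsplit(nm, "->", fixed = TRUE)[[1L]])
      # C(i->j) = H_j Wv (attention over a single key is identically 1, so
      # Wq/Wk receive no gradient in the one-token-per-modality pipeline)
      grads$cross[[nm]]$Wv <- t(cache$HL[[ij[2L]]]) %*% dfused_each
      dHL[[ij[2L]]] <- dHL[[ij[2L]]] + dfused_each %*% t(params$cross[[nm]]$Wv)
    }
  }

  dH <- dHL
  for (l in rev(seq_len(config$n_layers))) {
    lp <- params$layers[[l]]
    cc <- cache$layers[[l]]
    gl <- grads$layers[[l]]
    dres1_all <- vector("list", M)
    da_out <- vector("list", M)
    for (i in seq_len(M)) {
      l2 <- ln_backward(dH[[i]], cc$ln2[[i]], lp$ln2_g)
      gl$ln2_g <- gl$ln2_g + l2$dg
      gl$ln2_b <- gl$ln2_b + l2$db
      dres2 <- l2$dx
      df_out <- dres2
      if (!is.null(cache$masks)) {
        df_out <- df_out * cache$masks[[l]]$ffn[[i]]
      }
      hid <- cc$ff[[i]]$hid
      gl$W2 <- gl$W2 + t(hid) %*% df_out
      gl$b2 <- gl$b2 + colSums(df_out)
      dpre <- (df_out %*% t(lp$W2)) * (hid > 0)
      gl$W1 <- gl$W1 + t(cc$H1[[i]]) %*% dpre
      gl$b1 <- gl$b1 + colSums(dpre)
      dH1 <- dres2 + dpre %*% t(lp$W1)
      l1 <- ln_backward(dH1, cc$ln1[[i]], lp$ln1_g)
      gl$ln1_g <- gl$ln1_g + l1$dg
      gl$ln1_b <- gl$ln1_b + l1$db
      dres1_all[[i]] <- l1$dx
      da <- l1$dx
      if (!is.null(cache$masks)) {
        da <- da * cache$masks[[l]]$attn[[i]]
      }
      da_out[[i]] <- da
    }
    mb <- mhsa_backward(da_out, cc, lp, config, gl)
    grads$layers[[l]] <- mb$grads_layer
    dH <- purrr::map2(dres1_all, mb$dH, `+`)
  }

  # positional encoding and embeddings
  for (i in seq_len(M)) {
    grads$pos[i, ] <- colSums(dH[[i]])
    dpre <- dH[[i]] * (1 - cache$emb[[i]]^2)
    nm <- names(params$embed)[i]
    grads$embed[[nm]]$W <- t(cache$X[[i]]) %*% dpre
    grads$embed[[nm]]$b <- colSums(dpre)
  }
  grads
}

# Weighted cross-entropy loss (+ optional pooled-norm penalty) and its
# gradients for one batch.
encoder_loss_grad <- function(params, config, X_list, y, w,
                              masks = NULL, lambda_scale = 0) {
  fw <- forward_encoder(params, config, X_list, masks = masks,
                        keep_cache = TRUE)
  n <- nrow(fw$logits)
  p <- softmax_rows(fw$logits)
  py <- pmax(p[cbind(seq_len(n), y)], 1e-12)
  loss <- mean(-w[y] * log(py))
  onehot <- matrix(0, n, config$n_classes)
  onehot[cbind(seq_len(n), y)] <- 1
  dlogits <- (w[y] / n) * (p - onehot)
  dpooled_extra <- NULL
  if (lambda_scale > 0) {
    loss <- loss + lambda_scale * mean(rowSums(fw$pooled^2))
    dpooled_extra <- 2 * lambda_scale * fw$pooled / n
  }
  grads <- backward_encoder(params, config, fw$cache, dlogits, dpooled_extra)
  list(loss = loss, grads = grads, logits = fw$logits)
}
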