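# Independent explicit-loop oracles. These deliberately avoid the package's
# vectorized code paths: everything is scalar loops so they can disagree with
# the implementation if either is wrong.

oracle_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

oracle_ece <- function(probs, labels, n_bins = 15) {
  n <- length(labels)
  conf <- numeric(n)
  correct <- numeric(n)
  for (i in seq_len(n)) {
    conf[i] <- max(probs[i, ])
    pred <- which.max(probs[i, ])
    correct[i] <- as.numeric(pred == labels[i])
  }
  ece <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    inb <- if (b == 1) conf <= hi else conf > lo & conf <= hi
    if (any(inb)) {
      ece <- ece + sum(inb) / n * abs(mean(correct[inb]) - mean(conf[inb]))
    }
  }
  ece
}

oracle_confusion <- function(pred, labels, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(labels)) {
    cm[labels[i], pred[i]] <- cm[labels[i], pred[i]] + 1L
  }
  cm
}

oracle_weighted_ce <- function(probs, labels, w) {
  total <- 0
  for (i in seq_along(labels)) {
    total <- total - w[labels[i]] * log(probs[i, labels[i]])
  }
  total / length(labels)
}

# One post-LN transformer layer with explicit loops (any head count, but the
# tests use a single head). H is M x h.
oracle_transformer_layer <- function(H, lp, n_heads = 1, eps = 1e-6) {
  M <- nrow(H)
  h <- ncol(H)
  dk <- h %/% n_heads
  ln <- function(x, g, b) {
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(nrow(x))) {
      mu <- mean(x[i, ])
      sd2 <- mean((x[i, ] - mu)^2)
      for (j in seq_len(ncol(x))) {
        out[i, j] <- g[j] * (x[i, j] - mu) / sqrt(sd2 + eps) + b[j]
      }
    }
    out
  }
  Q <- H %*% lp$Wq; K <- H %*% lp$Wk; V <- H %*% lp$Wv
  O <- matrix(0, M, h)
  for (hd in seq_len(n_heads)) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    for (i in seq_len(M)) {
      s <- numeric(M)
      for (j in seq_len(M)) {
        s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dk)
      }
      a <- oracle_softmax(s)
      for (j in seq_len(M)) {
        O[i, cols] <- O[i, cols] + a[j] * V[j, cols]
      }
    }
  }
  att_out <- O %*% lp$Wo
  H1 <- ln(H + att_out, lp$ln1_g, lp$ln1_b)
  ffn <- matrix(0, M, h)
  for (i in seq_len(M)) {
    hid <- pmax(H1[i, ] %*% lp$W1 + lp$b1, 0)
    ffn[i, ] <- hid %*% lp$W2 + lp$b2
  }
  ln(H1 + ffn, lp$ln2_g, lp$ln2_b)
}

oracle_cross_attention <- function(H_i, H_j, W_Q, W_K, W_V, d_k) {
  Q <- H_i %*% W_Q
  K <- H_j %*% W_K
  V <- H_j %*% W_V
  C <- matrix(0, nrow(H_i), ncol(W_V))
  for (r in seq_len(nrow(H_i))) {
    s <- numeric(nrow(H_j))
    for (c in seq_len(nrow(H_j))) {
      s[c] <- sum(Q[r, ] * K[c, ]) / sqrt(d_k)
    }
    a <- oracle_softmax(s)
    for (c in seq_len(nrow(H_j))) {
      C[r, ] <- C[r, ] + a[c] * V[c, ]
    }
  }
  C
}

# grid-search NLL oracle for a global temperature
oracle_fit_temperature_grid <- function(logits, labels,
                                        grid = exp(seq(log(0.05), log(20),
                                                       length.out = 2000))) {
  nll <- sapply(grid, function(Tv) {
    total <- 0
    for (i in seq_along(labels)) {
      p <- oracle_softmax(logits[i, ] / Tv)
      total <- total - log(p[labels[i]])
    }
    total / length(labels)
  })
  grid[which.min(nll)]
}

entropy_of <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
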