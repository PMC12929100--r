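# Encoder forward operations against hand arithmetic and explicit-loop
# oracles.

make_params <- function(cfg) init_encoder(cfg)

test_that("modality embedding is the affine map through tanh", {
  cfg <- encoder_config(c(a = 2L, b = 2L), 2, embed_dim = 2L, n_layers = 1L,
                        n_heads = 1L, seed = 1)
  params <- make_params(cfg)
  # zero weights -> all-zero tokens
  params$embed$a$W[] <- 0; params$embed$a$b[] <- 0
  params$embed$b$W[] <- 0; params$embed$b$b[] <- 0
  H <- embed_modalities(list(c(1, 2), c(-3, 4)), params)
  expect_equal(H, matrix(0, 2, 2))
  # identity weights -> tanh of the input
  params$embed$a$W <- diag(2)
  H2 <- embed_modalities(list(c(0.3, -0.7), c(0, 0)), params)
  expect_equal(H2[1, ], tanh(c(0.3, -0.7)))
  # fixed tiny weights, hand arithmetic
  params$embed$b$W <- matrix(c(0.1, 0.2, -0.3, 0.4), 2, 2)
  params$embed$b$b <- c(0.05, -0.05)
  x <- c(1, 2)
  expect_equal(embed_modalities(list(c(0, 0), x), params)[2, ],
               tanh(c(0.1 * 1 + 0.2 * 2 + 0.05, -0.3 * 1 + 0.4 * 2 - 0.05)))
  # dimension mismatch
  expect_error(embed_modalities(list(c(1, 2, 3), c(1, 2)), params),
               "does not match")
  expect_error(embed_modalities(list(c(NA, 1), c(1, 2)), params), "imputed")
})

test_that("positional encoding is an elementwise addition", {
  H <- matrix(1:4, 2, 2)
  P <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_equal(add_positional_encoding(H, matrix(0, 2, 2)), H)
  expect_equal(add_positional_encoding(matrix(0, 2, 2), P), P)
  expect_equal(add_positional_encoding(H, P), H + P)
  expect_error(add_positional_encoding(H, matrix(0, 3, 2)), "shapes")
})

test_that("single-layer single-head encoding matches the explicit-loop oracle", {
  set.seed(5)
  for (M in 2:3) {
    cfg <- encoder_config(stats::setNames(rep(4L, M), paste0("m", 1:M)),
                          2, embed_dim = 4L, n_layers = 1L, n_heads = 1L,
                          seed = M)
    params <- make_params(cfg)
    H <- matrix(rnorm(M * 4), M, 4)
    got <- transformer_encode(H, params, cfg)
    want <- oracle_transformer_layer(H, params$layers[[1]], n_heads = 1)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("two-head encoding matches the oracle generalized to heads", {
  set.seed(8)
  cfg <- encoder_config(c(a = 4L, b = 4L), 2, embed_dim = 4L, n_layers = 1L,
                        n_heads = 2L, seed = 2)
  params <- make_params(cfg)
  H <- matrix(rnorm(8), 2, 4)
  expect_equal(transformer_encode(H, params, cfg),
               oracle_transformer_layer(H, params$layers[[1]], n_heads = 2),
               tolerance = 1e-6)
})

test_that("self-attention rows are probability distributions", {
  set.seed(3)
  cfg <- encoder_config(c(a = 6L, b = 6L, c = 6L), 2, embed_dim = 6L,
                        n_layers = 1L, n_heads = 3L, seed = 4)
  params <- make_params(cfg)
  H <- matrix(rnorm(18), 3, 6)
  for (A in self_attention_weights(H, params, cfg)) {
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  # M = 1: the attention matrix is the 1x1 identity
  cfg1 <- encoder_config(c(a = 4L), 2, embed_dim = 4L, n_layers = 1L,
                         n_heads = 1L, seed = 4)
  A1 <- self_attention_weights(matrix(rnorm(4), 1, 4),
                               make_params(cfg1), cfg1)
  expect_equal(A1[[1]], matrix(1, 1, 1))
})

test_that("cross-modal attention matches the oracle and its edge cases", {
  set.seed(11)
  h <- 4; dk <- 2
  H_i <- matrix(rnorm(2 * h), 2, h)
  H_j <- matrix(rnorm(3 * h), 3, h)
  W_Q <- matrix(rnorm(h * dk), h, dk)
  W_K <- matrix(rnorm(h * dk), h, dk)
  W_V <- matrix(rnorm(h * h), h, h)
  got <- cross_modal_attention(H_i, H_j, W_Q, W_K, W_V, dk)
  expect_equal(got, oracle_cross_attention(H_i, H_j, W_Q, W_K, W_V, dk),
               tolerance = 1e-10)
  # W_Q = 0: uniform attention -> mean of the value-projected rows
  gotu <- cross_modal_attention(H_i, H_j, W_Q * 0, W_K, W_V, dk)
  mu <- colMeans(H_j %*% W_V)
  expect_equal(gotu, rbind(mu, mu), ignore_attr = TRUE, tolerance = 1e-10)
  # W_V = 0: zero output
  expect_equal(cross_modal_attention(H_i, H_j, W_Q, W_K, W_V * 0, dk),
               matrix(0, 2, h))
  # attention rows sum to one
  w <- cross_modal_attention(H_i, H_j, W_Q, W_K, W_V, dk,
                             return_weights = TRUE)$weights
  expect_equal(rowSums(w), rep(1, 2), tolerance = 1e-9)
  # 1-token toy, 2x2 matrices, explicit arithmetic: single key -> weight 1
  hi <- matrix(c(1, 2), 1, 2); hj <- matrix(c(-1, 3), 1, 2)
  wv <- matrix(c(0.5, 0, 0.25, -1), 2, 2)
  expect_equal(cross_modal_attention(hi, hj, diag(2), diag(2), wv, 2),
               hj %*% wv)
})

test_that("fusion adds cross terms at the receiving row and mean-pools", {
  HL <- matrix(c(1, 2, 3, 4), 2, 2)
  # empty pair set (single modality) and all-zero cross terms are identities
  expect_equal(fuse_tokens(HL)$H_fused, HL)
  expect_equal(fuse_tokens(HL, list("1->2" = c(0, 0)))$H_fused, HL)
  cr <- list("1->2" = c(10, 20), "2->1" = c(1, 2))
  f <- fuse_tokens(HL, cr)
  expect_equal(f$H_fused[1, ], HL[1, ] + c(10, 20))
  expect_equal(f$H_fused[2, ], HL[2, ] + c(1, 2))
  expect_equal(f$pooled, colMeans(f$H_fused))
})

test_that("prediction is a normalized softmax with the lowest-index tie rule", {
  p <- predict_probs(c(0, 0))
  expect_equal(as.numeric(p[1, c("p1", "p2")]), c(0.5, 0.5))
  expect_equal(p$.pred, 1L)
  p2 <- predict_probs(c(1, 0))
  expect_equal(as.numeric(p2[1, c("p1", "p2")]),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-4)
  # shift invariance
  z <- matrix(rnorm(30), 10, 3)
  expect_equal(predict_probs(z), predict_probs(z + 5), tolerance = 1e-12)
  expect_equal(rowSums(as.matrix(predict_probs(z)[, 1:3])), rep(1, 10),
               tolerance = 1e-9)
  expect_error(predict_probs(c(Inf, 0)), "finite")
})

test_that("permuting modalities with their parameters permutes tokens only", {
  set.seed(21)
  cfg <- encoder_config(c(a = 3L, b = 3L), 2, embed_dim = 4L, n_layers = 2L,
                        n_heads = 2L, seed = 9)
  params <- init_encoder(cfg)
  X <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  fw <- mmcalib:::forward_encoder(params, cfg, X)

  swapped <- params
  swapped$embed <- params$embed[c("b", "a")]
  names(swapped$embed) <- c("a", "b")
  swapped$pos <- params$pos[c(2, 1), ]
  swapped$cross <- list("1->2" = params$cross[["2->1"]],
                        "2->1" = params$cross[["1->2"]])
  fw2 <- mmcalib:::forward_encoder(swapped, cfg, X[c(2, 1)])
  expect_equal(fw2$pooled, fw$pooled, tolerance = 1e-10)
  expect_equal(fw2$logits, fw$logits, tolerance = 1e-10)
})

test_that("disabling fusion removes all cross-modality information flow", {
  set.seed(31)
  cfg <- encoder_config(c(a = 3L, b = 3L), 2, embed_dim = 4L, n_layers = 1L,
                        n_heads = 1L, fusion = FALSE, seed = 12)
  params <- init_encoder(cfg)
  X <- list(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
  fw <- mmcalib:::forward_encoder(params, cfg, X)
  # changing modality b must leave modality a's token untouched
  X2 <- list(X[[1]], X[[2]] * 2 + 1)
  fw2 <- mmcalib:::forward_encoder(params, cfg, X2, keep_cache = TRUE)
  fw1 <- mmcalib:::forward_encoder(params, cfg, X, keep_cache = TRUE)
  expect_equal(fw1$cache$HL[[1]], fw2$cache$HL[[1]], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fw1$cache$HL[[2]], fw2$cache$HL[[2]])))
})
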