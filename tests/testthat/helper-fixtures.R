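# Small shared fixtures, built in code at test time.

tiny_bundle <- function(n = 120, seed = 7, ...) {
  simulate_multimodal(mm_spec(
    n, modality_dims = c(img = 3L, mol = 2L), class_separation = 2.5,
    seed = seed, ...
  ))
}

tiny_config <- function(bundle, ...) {
  encoder_config(bundle$manifest$modality_dims, bundle$manifest$n_classes,
                 embed_dim = 8L, n_layers = 1L, n_heads = 2L, ...)
}

quick_fit <- function(bundle, seed = 1, ...) {
  fit_encoder(bundle, tiny_config(bundle, seed = seed),
              max_epochs = 8L, patience = 8L, seed = seed, ...)
}

random_probs <- function(n, K, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * K), n, K)
  p / rowSums(p)
}
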