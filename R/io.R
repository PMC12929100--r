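# Portable model checkpointing: the encoder config plus the flattened
# parameter vector as JSON; the nested structure is rebuilt from the config.

#' Write a fitted encoder to a portable JSON checkpoint
#'
#' @param fit An `mm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mm_fit <- function(fit, path) {
  cfg_out <- unclass(fit$config)
  cfg_out$modality_dims <- as.list(cfg_out$modality_dims) # keep names in JSON
  obj <- list(
    format_version = 1L,
    config = cfg_out,
    theta = as.numeric(unlist(fit$params)),
    class_weights = fit$class_weights,
    class_counts = fit$class_counts,
    best_epoch = fit$best_epoch,
    history = as.list(fit$history),
    train_config = fit$train_config,
    modality_dims = as.list(fit$manifest$modality_dims),
    n_classes = fit$manifest$n_classes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted encoder written by [write_mm_fit()]
#'
#' @param path JSON path.
#' @return An `mm_fit`.
#' @export
read_mm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- encoder_config(
    modality_dims = stats::setNames(as.integer(unlist(cfg$modality_dims)),
                                    names(cfg$modality_dims)),
    n_classes = cfg$n_classes, embed_dim = cfg$embed_dim,
    n_layers = cfg$n_layers, n_heads = cfg$n_heads, key_dim = cfg$key_dim,
    dropout_rate = cfg$dropout_rate, ffn_dim = cfg$ffn_dim,
    fusion = cfg$fusion, seed = cfg$seed
  )
  skel <- unclass(init_encoder(config))
  params <- utils::relist(as.numeric(obj$theta), skel)
  class(params) <- "mm_params"
  manifest <- list(
    n_classes = obj$n_classes,
    classes = seq_len(obj$n_classes),
    modality_dims = stats::setNames(as.integer(unlist(obj$modality_dims)),
                                    names(obj$modality_dims))
  )
  structure(
    list(params = params, config = config,
         class_weights = obj$class_weights,
         class_counts = obj$class_counts,
         history = tibble::as_tibble(obj$history),
         best_epoch = obj$best_epoch,
         manifest = manifest,
         train_config = obj$train_config),
    class = "mm_fit"
  )
}
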