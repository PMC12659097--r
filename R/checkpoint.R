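## Checkpoint save/load: all parameters, running statistics and the
## configuration in one JSON archive with a versioned manifest.

.CKPT_SCHEMA <- 1L

#' Save a model checkpoint
#'
#' Writes parameters, batch-norm running statistics, dimensions and the full
#' configuration as a single JSON file (schema-versioned, text only).
#'
#' @param model An `mmddi_model`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mmddi_model"))
  pack <- function(m) list(dim = dim(m), data = as.numeric(m))
  obj <- list(
    manifest = list(schema = .CKPT_SCHEMA, package = "mmddi",
                    class = "mmddi_model"),
    config = unclass(model$config),
    input_dim = model$input_dim, token_len = model$token_len,
    n_tokens = model$n_tokens, seed = model$seed,
    params = lapply(model$params, pack),
    bn_stats = lapply(as.list(model$bn_stats), pack)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$manifest$schema) || obj$manifest$schema != .CKPT_SCHEMA) {
    stop("load_model: unsupported checkpoint schema")
  }
  unpack <- function(p) matrix(p$data, p$dim[1], p$dim[2])
  cfg <- obj$config
  cfg$optimizer <- as.character(cfg$optimizer)
  class(cfg) <- "mmddi_config"
  stats <- new.env(parent = emptyenv())
  for (nm in names(obj$bn_stats)) stats[[nm]] <- unpack(obj$bn_stats[[nm]])
  structure(
    list(params = lapply(obj$params, unpack), config = cfg,
         input_dim = obj$input_dim, token_len = obj$token_len,
         n_tokens = obj$n_tokens, bn_stats = stats,
         opt_state = new.env(parent = emptyenv()), seed = obj$seed),
    class = "mmddi_model"
  )
}
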