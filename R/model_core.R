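## Model configuration, parameter initialization and forward passes:
## the drug-pair autoencoder (multi-hot branch), the position-free attention
## association encoder (similarity branch) and the contrastive projection head.

#' Model and training configuration
#'
#' One configuration object covers the encoders, the disentangling head and
#' the training loop. Defaults follow the reference training recipe: batch
#' size 64, 15 epochs, InfoNCE temperature 0.05, K = 2 mechanism aspects,
#' dropout 0.4, two attention sub-layers, unit reconstruction/contrastive
#' weights and a gentle independence weight.
#'
#' @param latent_dim Width k of the autoencoder latent (compression: k is
#'   smaller than the multi-hot input).
#' @param assoc_width Token width of the association encoder.
#' @param aspect_width Width of each mechanism-aspect vector.
#' @param heads Attention heads (must divide `assoc_width` and
#'   `aspect_width`).
#' @param sublayers Attention encoder sub-layers.
#' @param k_aspects Number of disentangled mechanism aspects K.
#' @param dropout Dropout rate in (0, 1), applied to the fused representation
#'   and projection head during training.
#' @param batch_size,epochs,lr Training loop controls. The default learning
#'   rate 2e-5 matches the reference recipe at full dataset scale; small
#'   synthetic worlds train with a proportionally larger rate (see the
#'   methods vignette).
#' @param temperature InfoNCE temperature.
#' @param w_re,w_cl,w_ind Loss weights (the BPR term is unweighted). The
#'   independence weight defaults to a gentle 0.1; see the methods vignette
#'   for the calibration rationale.
#' @param clamp Independence-loss clamp.
#' @param clip_norm Global gradient-norm clip applied per step.
#' @param ind_scale Logit scale of the normalized aspect distributions inside
#'   the independence loss; controls how hard the regularizer separates
#'   aspect directions.
#' @param flip_rate,shuffle_rate Augmentation rates for the two views.
#' @param per_positive Training triples sampled per positive pair and epoch.
#' @param max_triples Cap on triples per epoch (a fresh uniform subsample of
#'   the resampled triples each epoch); keeps epochs tractable on dense
#'   interaction sets. `Inf` disables the cap.
#' @param patience Early-stopping patience (validation BPR loss), epochs.
#' @param n_folds Cross-validation folds (S1) / repetitions (S2, S3).
#' @param neg_candidates Negatives per leave-one-out candidate list.
#' @param use_contrastive,use_decoupling,use_association_encoder Module
#'   toggles reproducing the ablation variants: all on = full model;
#'   `use_contrastive = FALSE` = "w/o Con"; `use_decoupling = FALSE`
#'   (equivalently K = 1) = "w/o De"; association encoder off = multi-hot
#'   branch only.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param batchnorm Use batch normalization inside the autoencoder.
#' @param init_scale Multiplier on the uniform fan-in initialization.
#' @return A `mmddi_config` list.
#' @export
mmddi_config <- function(latent_dim = 64L, assoc_width = 32L,
                         aspect_width = 16L, heads = 2L, sublayers = 2L,
                         k_aspects = 2L, dropout = 0.4,
                         batch_size = 64L, epochs = 15L, lr = 2e-5,
                         temperature = 0.05, w_re = 1, w_cl = 1, w_ind = 0.1,
                         clamp = 5, ind_scale = 1, clip_norm = 5,
                         flip_rate = 0.1, shuffle_rate = 0.1,
                         per_positive = 1L, max_triples = 3000L,
                         patience = 3L, n_folds = 5L,
                         neg_candidates = 100L,
                         use_contrastive = TRUE, use_decoupling = TRUE,
                         use_association_encoder = TRUE,
                         optimizer = c("adam", "sgd"), batchnorm = TRUE,
                         init_scale = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(latent_dim >= 1L, sublayers >= 1L, dropout >= 0, dropout < 1,
            k_aspects >= 1L, heads >= 1L, temperature > 0,
            assoc_width %% heads == 0L, aspect_width %% heads == 0L,
            batch_size %in% c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L, 256L))
  if (!use_decoupling) k_aspects <- 1L
  cfg <- as.list(environment())
  structure(cfg, class = "mmddi_config")
}

.runif_mat <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

.init_dense <- function(params, name, nin, nout, init_scale) {
  s <- init_scale / sqrt(nin)
  params[[paste0(name, ".W")]] <- .runif_mat(nin, nout, s)
  params[[paste0(name, ".b")]] <- matrix(0, 1L, nout)
  params
}

#' Initialize an MMDDI model
#'
#' Parameters use uniform fan-in initialization under an explicit seed, so
#' identical seeds give identical models.
#'
#' @param input_dim Length of the (pair) multi-hot substructure vector fed to
#'   the autoencoder branch.
#' @param token_len Length of one association token (the drug-universe size n
#'   when tokens are per-category similarity profiles).
#' @param n_tokens Number of association tokens (2 x number of categories).
#' @param config A [mmddi_config()].
#' @param seed Integer seed for initialization.
#' @return Object of class `mmddi_model`.
#' @export
mmddi_model <- function(input_dim, token_len, n_tokens,
                        config = mmddi_config(), seed = 1L) {
  stopifnot(inherits(config, "mmddi_config"), input_dim >= 1L)
  k <- config$latent_dim; w <- config$assoc_width; wa <- config$aspect_width
  H <- config$heads; K <- config$k_aspects
  p <- as.integer(input_dim)
  sc <- config$init_scale
  .with_seed(seed, {
    P <- list()
    ## autoencoder
    P <- .init_dense(P, "ae.enc", p, k, sc)
    P[["ae.bn1.g"]] <- matrix(1, 1L, k); P[["ae.bn1.b"]] <- matrix(0, 1L, k)
    P <- .init_dense(P, "ae.encF", k, k, sc)
    P <- .init_dense(P, "ae.dec", k, p, sc)
    P[["ae.bn2.g"]] <- matrix(1, 1L, p); P[["ae.bn2.b"]] <- matrix(0, 1L, p)
    P <- .init_dense(P, "ae.decF", p, p, sc)
    ## contrastive projection head
    P <- .init_dense(P, "proj.1", k, k, sc)
    P <- .init_dense(P, "proj.2", k, k, sc)
    ## association encoder
    if (config$use_association_encoder) {
      P <- .init_dense(P, "assoc.tok", token_len, w, sc)
      dh <- w %/% H
      for (l in seq_len(config$sublayers)) {
        for (h in seq_len(H)) {
          pre <- sprintf("assoc.l%d.h%d", l, h)
          P[[paste0(pre, ".Wq")]] <- .runif_mat(w, dh, sc / sqrt(w))
          P[[paste0(pre, ".Wk")]] <- .runif_mat(w, dh, sc / sqrt(w))
          P[[paste0(pre, ".Wv")]] <- .runif_mat(w, dh, sc / sqrt(w))
        }
        P[[sprintf("assoc.l%d.Wo", l)]] <- .runif_mat(w, w, sc / sqrt(w))
        P <- .init_dense(P, sprintf("assoc.l%d.ff1", l), w, w, sc)
        P <- .init_dense(P, sprintf("assoc.l%d.ff2", l), w, w, sc)
      }
    }
    ## fusion of the two branches
    fin <- if (config$use_association_encoder) k + w else k
    P <- .init_dense(P, "fuse", fin, k, sc)
    ## aspect heads (bias-free; see .fwd_aspects)
    for (a in seq_len(K)) {
      P[[sprintf("asp%d.W", a)]] <- .runif_mat(k, wa, sc / sqrt(k))
    }
    ## aspect-fusion attention
    dh2 <- wa %/% H
    for (h in seq_len(H)) {
      pre <- sprintf("attn.h%d", h)
      P[[paste0(pre, ".Wq")]] <- .runif_mat(wa, dh2, sc / sqrt(wa))
      P[[paste0(pre, ".Wk")]] <- .runif_mat(wa, dh2, sc / sqrt(wa))
      P[[paste0(pre, ".Wv")]] <- .runif_mat(wa, dh2, sc / sqrt(wa))
    }
    P[["attn.Wo"]] <- .runif_mat(wa, wa, sc / sqrt(wa))
    ## risk head
    P <- .init_dense(P, "risk", wa, 1L, sc)

    stats <- new.env(parent = emptyenv())
    stats$ae.bn1.m <- matrix(0, 1L, k); stats$ae.bn1.v <- matrix(1, 1L, k)
    stats$ae.bn2.m <- matrix(0, 1L, p); stats$ae.bn2.v <- matrix(1, 1L, p)

    structure(
      list(params = P, config = config, input_dim = p,
           token_len = as.integer(token_len), n_tokens = as.integer(n_tokens),
           bn_stats = stats, opt_state = new.env(parent = emptyenv()),
           seed = seed),
      class = "mmddi_model"
    )
  })
}

#' @export
print.mmddi_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat("mmddi model:", format(npar, big.mark = ","), "parameters;",
      "input_dim =", x$input_dim, "| tokens =", x$n_tokens, "x", x$token_len,
      "| K =", x$config$k_aspects, "aspects\n")
  invisible(x)
}

## ---- forward context ----

## Wrap parameters as tape nodes. training = TRUE tracks gradients, uses batch
## statistics for BN and samples dropout masks.
.ctx <- function(model, training = FALSE, tape = NULL) {
  tape <- if (is.null(tape)) ad_tape() else tape
  wrap <- if (training) ad_var else ad_const
  P <- lapply(model$params, function(m) wrap(tape, m))
  list(tape = tape, P = P, model = model, training = training,
       cfg = model$config)
}

.dense <- function(ctx, x, name, act = c("relu", "none", "sigmoid")) {
  act <- match.arg(act)
  ad_affine(ctx$tape, x, ctx$P[[paste0(name, ".W")]],
            ctx$P[[paste0(name, ".b")]], act)
}

.batchnorm <- function(ctx, x, key, momentum = 0.1, eps = 1e-5) {
  t <- ctx$tape
  g <- ctx$P[[paste0(key, ".g")]]; b <- ctx$P[[paste0(key, ".b")]]
  st <- ctx$model$bn_stats
  if (ctx$training && nrow(x$val) > 1L) {
    out <- ad_bn_train(t, x, g, b, eps = eps)
    mkey <- paste0(key, ".m"); vkey <- paste0(key, ".v")
    st[[mkey]] <- (1 - momentum) * st[[mkey]] + momentum * out$batch_mean
    st[[vkey]] <- (1 - momentum) * st[[vkey]] + momentum * out$batch_var
    out
  } else {
    mu <- ad_const(t, st[[paste0(key, ".m")]])
    v <- ad_const(t, st[[paste0(key, ".v")]])
    xn <- ad_div(t, ad_sub(t, x, mu),
                 ad_sqrt(t, ad_add(t, v, ad_const(t, matrix(eps, 1L, 1L)))))
    ad_add(t, ad_mul(t, xn, g), b)
  }
}

.dropout <- function(ctx, x) {
  p <- ctx$cfg$dropout
  if (!ctx$training || p <= 0) return(x)
  mask <- matrix(stats::rbinom(length(x$val), 1L, 1 - p) / (1 - p),
                 nrow(x$val), ncol(x$val))
  ad_mul(ctx$tape, x, ad_const(ctx$tape, mask))
}

## Encoder half of the autoencoder: multi-hot -> latent z.
.fwd_encode_z <- function(ctx, x) {
  h <- .dense(ctx, x, "ae.enc", "relu")
  if (ctx$cfg$batchnorm) h <- .batchnorm(ctx, h, "ae.bn1")
  .dense(ctx, h, "ae.encF", "none")
}

.fwd_decode <- function(ctx, z) {
  h <- .dense(ctx, z, "ae.dec", "relu")
  if (ctx$cfg$batchnorm) h <- .batchnorm(ctx, h, "ae.bn2")
  .dense(ctx, h, "ae.decF", "none")
}

## Projection head for contrast; final rectifier keeps h non-negative.
.fwd_project <- function(ctx, z) {
  h <- .dropout(ctx, .dense(ctx, z, "proj.1", "relu"))
  .dense(ctx, h, "proj.2", "relu")
}

## Multi-head self-attention over a token list (no positional information).
## Returns list(tokens = transformed token list, attn = per-head list of
## per-query attention nodes (B x t)).
.fwd_mha <- function(ctx, tokens, prefix, H, out_name) {
  t <- ctx$tape
  nt <- length(tokens)
  dh <- ncol(ctx$P[[paste0(prefix, ".h1.Wq")]]$val)
  scale <- 1 / sqrt(dh)
  head_outs <- vector("list", nt)
  for (i in seq_len(nt)) head_outs[[i]] <- vector("list", H)
  attn_all <- vector("list", H)
  for (h in seq_len(H)) {
    pre <- sprintf("%s.h%d", prefix, h)
    Q <- lapply(tokens, function(x) ad_matmul(t, x, ctx$P[[paste0(pre, ".Wq")]]))
    Kk <- lapply(tokens, function(x) ad_matmul(t, x, ctx$P[[paste0(pre, ".Wk")]]))
    V <- lapply(tokens, function(x) ad_matmul(t, x, ctx$P[[paste0(pre, ".Wv")]]))
    attn_h <- vector("list", nt)
    for (i in seq_len(nt)) {
      A <- ad_softmax_rows(t, ad_pairdots(t, Q[[i]], Kk, scale))  # B x nt
      attn_h[[i]] <- A
      head_outs[[i]][[h]] <- ad_mixcols(t, A, V)
    }
    attn_all[[h]] <- attn_h
  }
  Wo <- ctx$P[[out_name]]
  new_tokens <- lapply(seq_len(nt), function(i) {
    ad_add(t, ad_matmul(t, ad_cbind(t, head_outs[[i]]), Wo), tokens[[i]])
  })
  list(tokens = new_tokens, attn = attn_all)
}

## Association encoder: token list -> pooled fixed-length representation.
## Two (by default) attention sub-layers, each followed by a residual
## position-wise feed-forward block; mean pooling keeps the output invariant
## to token permutation. All per-token projections share weights, so tokens
## are stacked row-wise into one matrix (token i occupies row block i) and
## each projection is a single matrix product.
.fwd_assoc <- function(ctx, tokens) {
  t <- ctx$tape
  nt <- length(tokens)
  stack <- ad_rbind(t, tokens)
  stack <- .dense(ctx, stack, "assoc.tok", "relu")
  H <- ctx$cfg$heads
  for (l in seq_len(ctx$cfg$sublayers)) {
    heads <- vector("list", H)
    for (h in seq_len(H)) {
      pre <- sprintf("assoc.l%d.h%d", l, h)
      Qs <- ad_matmul(t, stack, ctx$P[[paste0(pre, ".Wq")]])
      Ks <- ad_matmul(t, stack, ctx$P[[paste0(pre, ".Wk")]])
      Vs <- ad_matmul(t, stack, ctx$P[[paste0(pre, ".Wv")]])
      heads[[h]] <- ad_block_attention(t, Qs, Ks, Vs, nt,
                                       1 / sqrt(ncol(Qs$val)))
    }
    att <- ad_matmul(t, ad_cbind(t, heads),
                     ctx$P[[sprintf("assoc.l%d.Wo", l)]])
    stack <- ad_add(t, att, stack)
    ff <- .dense(ctx, .dense(ctx, stack, sprintf("assoc.l%d.ff1", l), "relu"),
                 sprintf("assoc.l%d.ff2", l), "none")
    stack <- ad_add(t, ff, stack)
  }
  ad_block_mean(t, stack, nt)
}

## Reshape a (B x n_tokens*token_len) pair-feature matrix into a token list.
.feature_tokens <- function(model, X) {
  n <- model$token_len; nt <- model$n_tokens
  stopifnot(ncol(X) == n * nt)
  lapply(seq_len(nt), function(i) X[, ((i - 1L) * n + 1L):(i * n), drop = FALSE])
}

## ---- public inference wrappers ----

#' Run the drug-pair autoencoder
#'
#' Deterministic inference pass (batch-norm running statistics, no dropout):
#' encodes the multi-hot vector to the latent `z`, reconstructs `x_hat`, and
#' returns the (non-negative) projection-head output `h` used for contrast.
#'
#' @param model An `mmddi_model`.
#' @param x Numeric vector of length `input_dim`, or a matrix with such rows.
#' @return List with matrices `z`, `x_hat`, `h` (one row per input row).
#' @export
autoencode <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != model$input_dim) {
    stop("autoencode: expected input of width ", model$input_dim,
         ", got ", ncol(X))
  }
  ctx <- .ctx(model, training = FALSE)
  xn <- ad_const(ctx$tape, X)
  z <- .fwd_encode_z(ctx, xn)
  list(z = z$val, x_hat = .fwd_decode(ctx, z)$val,
       h = .fwd_project(ctx, z)$val)
}

#' Encode a pair similarity feature with the position-free attention encoder
#'
#' The concatenated similarity feature is split into one token per
#' (drug-of-pair x category) block; two self-attention sub-layers without
#' positional encoding are applied and the tokens mean-pooled, so permuting
#' the tokens leaves the output unchanged.
#'
#' @param model An `mmddi_model` built with the association encoder enabled.
#' @param pair_features Numeric vector of length `n_tokens * token_len` or a
#'   matrix with such rows.
#' @return Matrix of pooled representations (rows match input rows).
#' @export
association_encode <- function(model, pair_features) {
  if (!model$config$use_association_encoder) {
    stop("association_encode: model built without the association encoder")
  }
  X <- if (is.matrix(pair_features)) pair_features else
    matrix(pair_features, nrow = 1L)
  ctx <- .ctx(model, training = FALSE)
  toks <- lapply(.feature_tokens(model, X),
                 function(m) ad_const(ctx$tape, m))
  .fwd_assoc(ctx, toks)$val
}
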