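## Joint training loop, candidate ranking, evaluation metrics and the
## experiment driver.

## Gather model inputs for index-aligned pairs (a_idx[i], b_idx[i]).
.pair_inputs <- function(features, a_idx, b_idx, use_assoc = TRUE) {
  X_sub <- cbind(features$multihot[a_idx, , drop = FALSE],
                 features$multihot[b_idx, , drop = FALSE])
  toks <- NULL
  if (use_assoc) {
    mats <- features$profiles$matrices
    toks <- c(
      lapply(mats, function(m) m[a_idx, , drop = FALSE]),
      lapply(mats, function(m) m[b_idx, , drop = FALSE])
    )
  }
  list(X_sub = X_sub, tokens = toks)
}

## Row-wise augmentation of a binary matrix using the ambient RNG stream.
.augment_rows <- function(X, op, rate) {
  if (rate <= 0) return(X)
  for (i in seq_len(nrow(X))) {
    X[i, ] <- if (op == "flip") aug_flip(X[i, ], rate) else
      aug_shuffle(X[i, ], rate)
  }
  X
}

## Full differentiable forward for one batch of pairs. Returns risk node and
## optional auxiliary loss nodes.
.fwd_pair_batch <- function(ctx, inputs, with_recon = FALSE,
                            with_contrast = FALSE,
                            contrast_rows = seq_len(nrow(inputs$X_sub))) {
  t <- ctx$tape
  cfg <- ctx$cfg
  x <- ad_const(t, inputs$X_sub)
  z <- .fwd_encode_z(ctx, x)
  l_re <- NULL
  if (with_recon) {
    ## reconstruct the positive-pair rows (the training inputs of the
    ## contrastive branch); the decoder is the widest layer, so this also
    ## keeps the step cost down
    if (length(contrast_rows) < nrow(inputs$X_sub)) {
      xr <- ad_const(t, inputs$X_sub[contrast_rows, , drop = FALSE])
      zr <- ad_rows(t, z, contrast_rows)
    } else {
      xr <- x; zr <- z
    }
    l_re <- .ad_reconstruction(t, xr, .fwd_decode(ctx, zr))
  }
  l_cl <- NULL
  if (with_contrast) {
    Xc <- inputs$X_sub[contrast_rows, , drop = FALSE]
    v1 <- ad_const(t, .augment_rows(Xc, "flip", cfg$flip_rate))
    v2 <- ad_const(t, .augment_rows(Xc, "shuffle", cfg$shuffle_rate))
    h1 <- .fwd_project(ctx, .fwd_encode_z(ctx, v1))
    h2 <- .fwd_project(ctx, .fwd_encode_z(ctx, v2))
    l_cl <- .ad_infonce_batch(t, h1, h2, cfg$temperature)
  }
  assoc <- NULL
  if (cfg$use_association_encoder) {
    toks <- lapply(inputs$tokens, function(m) ad_const(t, m))
    assoc <- .fwd_assoc(ctx, toks)
  }
  g <- .fwd_fuse_branches(ctx, z, assoc)
  aspects <- .fwd_aspects(ctx, g)
  l_ind <- NULL
  if (cfg$use_decoupling && cfg$k_aspects >= 2L) {
    l_ind <- .ad_independence(t, aspects, cfg$clamp, cfg$ind_scale)
  }
  fus <- .fwd_aspect_fusion(ctx, aspects)
  risk <- .fwd_risk(ctx, fus$fused)
  list(risk = risk, weights = fus$weights, l_re = l_re, l_cl = l_cl,
       l_ind = l_ind)
}

.adam_step <- function(model, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st <- model$opt_state
  if (is.null(st$t)) {
    st$t <- 0L
    st$m <- lapply(model$params, function(p) p * 0)
    st$v <- lapply(model$params, function(p) p * 0)
  }
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    model$params[[nm]] <- model$params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  model
}

.sgd_step <- function(model, grads, lr) {
  for (nm in names(grads)) {
    if (!is.null(grads[[nm]])) {
      model$params[[nm]] <- model$params[[nm]] - lr * grads[[nm]]
    }
  }
  model
}

## One gradient step on a batch of triples. The positive and negative pairs
## of the batch share a single forward pass (rows 1..B are the positive
## pairs); contrastive views are built from the positive rows only.
.train_step <- function(model, features, anchors, pos, neg) {
  cfg <- model$config
  ctx <- .ctx(model, training = TRUE)
  t <- ctx$tape
  B <- length(anchors)
  inp <- .pair_inputs(features, c(anchors, anchors), c(pos, neg),
                      cfg$use_association_encoder)
  f_pos <- .fwd_pair_batch(ctx, inp, with_recon = TRUE,
                           with_contrast = cfg$use_contrastive,
                           contrast_rows = seq_len(B))
  s_pos <- ad_rows(t, f_pos$risk, seq_len(B))
  s_neg <- ad_rows(t, f_pos$risk, B + seq_len(B))
  l_bpr <- .ad_bpr(t, s_pos, s_neg)
  total <- l_bpr
  comp <- c(bpr = l_bpr$val[1L])
  if (!is.null(f_pos$l_re)) {
    total <- ad_add(t, total, ad_scale(t, f_pos$l_re, cfg$w_re))
    comp["reconstruction"] <- f_pos$l_re$val[1L]
  }
  if (!is.null(f_pos$l_cl)) {
    total <- ad_add(t, total, ad_scale(t, f_pos$l_cl, cfg$w_cl))
    comp["contrastive"] <- f_pos$l_cl$val[1L]
  }
  if (!is.null(f_pos$l_ind)) {
    total <- ad_add(t, total, ad_scale(t, f_pos$l_ind, cfg$w_ind))
    comp["independence"] <- f_pos$l_ind$val[1L]
  }
  bad <- !is.finite(comp)
  if (any(bad)) {
    stop("training diverged: non-finite loss component(s): ",
         paste(names(comp)[bad], collapse = ", "))
  }
  ad_backward(t, total)
  grads <- lapply(ctx$P, ad_grad)
  ## global gradient-norm clipping guards the temperature-scaled contrastive
  ## term against occasional exploding steps
  gn <- sqrt(sum(vapply(grads, function(g)
    if (is.null(g)) 0 else sum(g * g), numeric(1))))
  if (is.finite(gn) && gn > cfg$clip_norm) {
    sc <- cfg$clip_norm / gn
    grads <- lapply(grads, function(g) if (is.null(g)) NULL else g * sc)
  }
  model <- if (cfg$optimizer == "adam") .adam_step(model, grads, cfg$lr) else
    .sgd_step(model, grads, cfg$lr)
  list(model = model, components = comp, total = total$val[1L])
}

## Inference risk scores (and aspect weights) for index pairs, batched.
.score_pairs <- function(model, features, a_idx, b_idx, batch = 256L) {
  n <- length(a_idx)
  risks <- numeric(n)
  W <- matrix(NA_real_, n, model$config$k_aspects)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    ctx <- .ctx(model, training = FALSE)
    inp <- .pair_inputs(features, a_idx[s:e], b_idx[s:e],
                        model$config$use_association_encoder)
    f <- .fwd_pair_batch(ctx, inp)
    risks[s:e] <- as.numeric(f$risk$val)
    W[s:e, ] <- f$weights$val
  }
  list(risk = risks, weights = W)
}

#' Score drug pairs with a trained model
#'
#' @param model An `mmddi_model`.
#' @param features `mmddi_features` for the universe the model was built on.
#' @param pairs `data.frame` with columns `drugA`, `drugB`.
#' @return `data.frame` with the pairs, their `risk` in (0, 1) and one
#'   `aspect_w<k>` column per mechanism aspect.
#' @export
predict_risk <- function(model, features, pairs) {
  a <- match(pairs$drugA, features$ids)
  b <- match(pairs$drugB, features$ids)
  if (anyNA(a) || anyNA(b)) stop("predict_risk: unknown drug id in pairs")
  sc <- .score_pairs(model, features, a, b)
  out <- data.frame(drugA = pairs$drugA, drugB = pairs$drugB, risk = sc$risk,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(sc$weights))) {
    out[[paste0("aspect_w", k)]] <- sc$weights[, k]
  }
  out
}

#' Train an MMDDI model on interaction data
#'
#' Mini-batch joint training of the weighted objective (reconstruction +
#' InfoNCE + independence + BPR) on BPR triples resampled every epoch, with
#' early stopping on held-out validation BPR loss (best parameters restored).
#' All randomness flows from `seed`, so identical calls give identical
#' models.
#'
#' @param data `interaction_data` holding the training positives. Its
#'   universe defines the negative-sampling pool, so for cold-start splits
#'   pass a universe restricted to known drugs.
#' @param features `mmddi_features` over the full drug universe.
#' @param config A [mmddi_config()].
#' @param seed Integer seed.
#' @param val_fraction Fraction of training positives held out to monitor
#'   early stopping.
#' @param verbose Print per-epoch losses.
#' @return List with `model`, `history` (per-epoch component losses) and
#'   `best_epoch`.
#' @export
train_mmddi <- function(data, features, config = mmddi_config(), seed = 1L,
                        val_fraction = 0.1, verbose = FALSE) {
  stopifnot(inherits(data, "interaction_data"),
            inherits(features, "mmddi_features"))
  if (data$m == 0L) stop("train_mmddi: empty training set")
  n_tokens <- 2L * length(features$categories)
  model <- mmddi_model(2L * features$d, features$n, n_tokens, config,
                       seed = seed)
  .with_seed(seed + 1L, {
    pos <- data$positives
    n_val <- max(0L, min(floor(val_fraction * nrow(pos)), nrow(pos) - 1L))
    vidx <- if (n_val > 0L) sample.int(nrow(pos), n_val) else integer(0)
    train_data <- interaction_data(
      if (n_val > 0L) pos[-vidx, , drop = FALSE] else pos, data$drugs)
    val_triples <- if (n_val > 0L) {
      sample_triples(interaction_data(pos[vidx, , drop = FALSE], data$drugs),
                     per_positive = 1L, full_data = data)
    } else NULL

    history <- list()
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    stale <- 0L
    for (epoch in seq_len(config$epochs)) {
      triples <- sample_triples(train_data, config$per_positive)
      triples <- triples[sample.int(nrow(triples)), , drop = FALSE]
      if (is.finite(config$max_triples) && nrow(triples) > config$max_triples) {
        triples <- triples[seq_len(config$max_triples), , drop = FALSE]
      }
      a <- match(triples$anchor, features$ids)
      p <- match(triples$pos, features$ids)
      g <- match(triples$neg, features$ids)
      nb <- ceiling(nrow(triples) / config$batch_size)
      comp_sum <- NULL
      for (bi in seq_len(nb)) {
        s <- (bi - 1L) * config$batch_size + 1L
        e <- min(bi * config$batch_size, nrow(triples))
        step <- .train_step(model, features, a[s:e], p[s:e], g[s:e])
        model <- step$model
        comp_sum <- if (is.null(comp_sum)) step$components else
          comp_sum + step$components[names(comp_sum)]
      }
      comp_mean <- comp_sum / nb
      val_loss <- if (!is.null(val_triples)) {
        va <- match(val_triples$anchor, features$ids)
        vp <- match(val_triples$pos, features$ids)
        vg <- match(val_triples$neg, features$ids)
        sp <- .score_pairs(model, features, va, vp)$risk
        sn <- .score_pairs(model, features, va, vg)$risk
        bpr_loss(sp, sn)
      } else comp_mean[["bpr"]]
      history[[epoch]] <- c(epoch = epoch, comp_mean, val_bpr = val_loss)
      if (verbose) {
        message(sprintf("epoch %2d | %s | val_bpr %.4f", epoch,
                        paste(sprintf("%s %.4f", names(comp_mean), comp_mean),
                              collapse = " | "), val_loss))
      }
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = model$params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    model$params <- best$params
    hist_df <- as.data.frame(do.call(rbind, history))
    list(model = model, history = hist_df, best_epoch = best$epoch)
  })
}

#' Rank a candidate list by descending risk
#'
#' Ties are broken by ascending drug identifier (stable and deterministic).
#'
#' @param model An `mmddi_model`.
#' @param features `mmddi_features`.
#' @param candidate_list As returned by [make_candidates()].
#' @return Character vector of candidate ids, best first.
#' @export
rank_candidates <- function(model, features, candidate_list) {
  cands <- candidate_list$candidates
  if (length(cands) == 0L) stop("rank_candidates: empty candidate list")
  a <- match(rep(candidate_list$anchor, length(cands)), features$ids)
  b <- match(cands, features$ids)
  sc <- .score_pairs(model, features, a, b)$risk
  cands[order(-sc, cands, method = "radix")]
}

#' Leave-one-out ranking metrics at cutoff K
#'
#' Each ranked list contains exactly one relevant item. HIT@K is the fraction
#' of anchors whose positive ranks in the top K; NDCG@K contributes
#' `1/log2(rank0 + 2)` and MRR@K `1/(rank0 + 1)` when the positive is inside
#' the top K (0 otherwise), with `rank0` the 0-based rank.
#'
#' @param ranked_lists List of character vectors (best first).
#' @param positives Character vector, the relevant item per list.
#' @param K Cutoff, at least 1.
#' @return List of class `ranking_metrics`: `hit`, `ndcg`, `mrr`, `K`,
#'   `n_anchors`.
#' @export
ranking_metrics <- function(ranked_lists, positives, K = 4L) {
  stopifnot(K >= 1L, length(ranked_lists) == length(positives))
  hits <- ndcg <- mrr <- numeric(length(ranked_lists))
  for (i in seq_along(ranked_lists)) {
    r0 <- match(positives[i], ranked_lists[[i]]) - 1L
    if (is.na(r0)) {
      stop("ranking_metrics: list ", i, " does not contain its positive")
    }
    if (r0 < K) {
      hits[i] <- 1
      ndcg[i] <- 1 / log2(r0 + 2)
      mrr[i] <- 1 / (r0 + 1)
    }
  }
  structure(list(hit = mean(hits), ndcg = mean(ndcg), mrr = mean(mrr),
                 K = K, n_anchors = length(ranked_lists)),
            class = "ranking_metrics")
}

#' @export
print.ranking_metrics <- function(x, ...) {
  cat(sprintf("HIT@%d %.4f | NDCG@%d %.4f | MRR@%d %.4f (n = %d anchors)\n",
              x$K, x$hit, x$K, x$ndcg, x$K, x$mrr, x$n_anchors))
  invisible(x)
}

#' Threshold classification metrics
#'
#' Predictions are positive when the score strictly exceeds the threshold.
#' AUC is the pairwise-concordance rank statistic with midrank tie handling
#' (ties get 0.5 credit); AUPR is the area under the precision-recall step
#' curve. With single-class labels, AUC and AUPR are `NA`.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold, default 0.5.
#' @return List of class `classification_metrics` with `acc`, `auc`, `f1`,
#'   `precision`, `recall`, `aupr`, `threshold`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1); fp <- sum(pred == 1L & labels == 0)
  fn <- sum(pred == 0L & labels == 1); tn <- sum(pred == 0L & labels == 0)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    auc <- NA_real_; aupr <- NA_real_
  } else {
    r <- rank(scores)                       # midranks
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(-scores, method = "radix")
    lab <- labels[ord]
    tp_c <- cumsum(lab)
    prec_c <- tp_c / seq_along(lab)
    rec_c <- tp_c / n1
    aupr <- sum(prec_c * diff(c(0, rec_c)))
  }
  structure(list(acc = acc, auc = auc, f1 = f1, precision = prec,
                 recall = rec, aupr = aupr, threshold = threshold),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "ACC %.4f | AUC %s | F1 %.4f | Prec %.4f | Rec %.4f | AUPR %s (thr %.2f)\n",
    x$acc, format(round(x$auc, 4)), x$f1, x$precision, x$recall,
    format(round(x$aupr, 4)), x$threshold))
  invisible(x)
}

## Evaluate one trained model on a split: leave-one-out ranking + threshold
## classification over the test pairs.
.evaluate_split <- function(model, features, data, split, config, seed,
                            rank_K = 4L, max_anchors = 200L) {
  test <- split$test
  if (nrow(test) > max_anchors) {
    keep <- .with_seed(seed, sample.int(nrow(test), max_anchors))
    test <- test[keep, , drop = FALSE]
  }
  ranked <- vector("list", nrow(test))
  pos <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    cl <- make_candidates(data, test$drugA[i], test$drugB[i],
                          N = config$neg_candidates, seed = seed + i)
    ranked[[i]] <- rank_candidates(model, features, cl)
    pos[i] <- cl$positive
  }
  rk <- ranking_metrics(ranked, pos, K = rank_K)

  neg_pairs <- .with_seed(seed + 7L, {
    aa <- character(0); bb <- character(0)
    tries <- 0L
    key_pos <- paste(data$positives$drugA, data$positives$drugB, sep = "\r")
    while (length(aa) < nrow(test) && tries < 50L * nrow(test)) {
      i <- sample(data$drugs, 1L); j <- sample(data$drugs, 1L)
      tries <- tries + 1L
      if (i == j) next
      cp <- .canon_pairs(i, j)
      if (paste(cp$drugA, cp$drugB, sep = "\r") %in% key_pos) next
      aa <- c(aa, cp$drugA); bb <- c(bb, cp$drugB)
    }
    data.frame(drugA = aa, drugB = bb, stringsAsFactors = FALSE)
  })
  all_pairs <- rbind(test[, c("drugA", "drugB")], neg_pairs)
  labels <- c(rep(1, nrow(test)), rep(0, nrow(neg_pairs)))
  scores <- predict_risk(model, features, all_pairs)$risk
  cm <- classification_metrics(scores, labels)
  list(ranking = rk, classification = cm, n_test = nrow(test))
}

#' Run a full split -> featurize -> train -> evaluate experiment
#'
#' Executes the chosen evaluation protocol (transductive S1 or cold-start
#' S2/S3) fold by fold, verifying split integrity before each fold, and
#' returns (optionally writes) a JSON-able report with per-fold and mean
#' metrics, a configuration echo and the seed.
#'
#' @param drug_table Drug table ([read_drug_table()] format).
#' @param interactions An `interaction_data` over the table's drugs.
#' @param mode `"S1"`, `"S2"` or `"S3"`.
#' @param config A [mmddi_config()].
#' @param seed Integer seed governing splits, training and evaluation.
#' @param categories Attribute categories to featurize.
#' @param n_folds Folds/repetitions; defaults to `config$n_folds`.
#' @param max_folds Evaluate only the first `max_folds` folds (all by
#'   default); the split structure is still built with `n_folds`.
#' @param rank_K Ranking cutoff K.
#' @param max_anchors Cap on evaluated test anchors per fold.
#' @param out_file Optional path for the JSON report.
#' @param features Optional precomputed `mmddi_features`.
#' @param verbose Print progress.
#' @return List of class `mmddi_report`.
#' @export
run_experiment <- function(drug_table, interactions, mode = "S1",
                           config = mmddi_config(), seed = 1L,
                           categories = c("substructure", "target",
                                          "enzyme", "pathway"),
                           n_folds = NULL, max_folds = NULL, rank_K = 4L,
                           max_anchors = 200L, out_file = NULL,
                           features = NULL, verbose = FALSE) {
  if (is.null(n_folds)) n_folds <- config$n_folds
  if (is.null(features)) {
    features <- featurize_drugs(drug_table, categories)
  }
  splits <- split_dataset(interactions, mode, n_folds = n_folds, seed = seed)
  if (!is.null(max_folds)) splits <- splits[seq_len(min(max_folds, length(splits)))]
  folds <- vector("list", length(splits))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    check_split_integrity(sp)
    train_universe <- if (mode == "S1") interactions$drugs else
      setdiff(interactions$drugs, sp$novel_drugs)
    train_data <- interaction_data(sp$train, train_universe)
    fit <- train_mmddi(train_data, features, config,
                       seed = seed + 1000L * f, verbose = verbose)
    ev <- .evaluate_split(fit$model, features, interactions, sp, config,
                          seed = seed + 1000L * f, rank_K = rank_K,
                          max_anchors = max_anchors)
    folds[[f]] <- list(
      fold = f, n_train = nrow(sp$train), n_test = ev$n_test,
      best_epoch = fit$best_epoch,
      hit = ev$ranking$hit, ndcg = ev$ranking$ndcg, mrr = ev$ranking$mrr,
      acc = ev$classification$acc, auc = ev$classification$auc,
      f1 = ev$classification$f1, precision = ev$classification$precision,
      recall = ev$classification$recall, aupr = ev$classification$aupr
    )
    if (verbose) {
      message(sprintf("fold %d: HIT@%d %.3f NDCG %.3f MRR %.3f ACC %.3f",
                      f, rank_K, ev$ranking$hit, ev$ranking$ndcg,
                      ev$ranking$mrr, ev$classification$acc))
    }
  }
  metric_names <- c("hit", "ndcg", "mrr", "acc", "auc", "f1", "precision",
                    "recall", "aupr")
  means <- sapply(metric_names, function(mn) {
    mean(vapply(folds, function(x) x[[mn]], numeric(1)), na.rm = TRUE)
  })
  report <- structure(list(
    mode = mode, seed = seed, rank_K = rank_K,
    run_id = sprintf("mmddi-%s-seed%d-%s", mode, seed,
                     format(Sys.time(), "%Y%m%d%H%M%S")),
    config = unclass(config), folds = folds, means = as.list(means)
  ), class = "mmddi_report")
  if (!is.null(out_file)) {
    jsonlite::write_json(unclass(report), out_file, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  report
}

#' @export
print.mmddi_report <- function(x, ...) {
  cat("mmddi experiment:", x$mode, "|", length(x$folds), "fold(s) | seed",
      x$seed, "\n")
  m <- x$means
  cat(sprintf("  mean HIT@%d %.4f | NDCG@%d %.4f | MRR@%d %.4f\n",
              x$rank_K, m$hit, x$rank_K, m$ndcg, x$rank_K, m$mrr))
  cat(sprintf("  mean ACC %.4f | AUC %.4f | F1 %.4f | AUPR %.4f\n",
              m$acc, m$auc, m$f1, m$aupr))
  invisible(x)
}
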