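## Mechanism disentanglement: K aspect heads, attention fusion with
## contribution weights, the sigmoid risk head, and the entanglement-bias
## diagnostic on fusion weights.

## Internal tape forwards -------------------------------------------------

## Aspect heads are bias-free linear maps + ReLU: a constant (input
## independent) aspect would otherwise trivially maximize the independence
## regularizer through its bias and detach the risk score from the input.
.fwd_aspects <- function(ctx, g) {
  K <- ctx$cfg$k_aspects
  t <- ctx$tape
  lapply(seq_len(K), function(a)
    ad_relu(t, ad_matmul(t, g, ctx$P[[sprintf("asp%d.W", a)]])))
}

## Aspects as a K-token set under multi-head attention. The contribution
## weight of aspect q is the attention mass it receives, averaged over heads
## and queries (each softmax row sums to one, so the average is itself a
## probability vector); fused = sum_q weight_q * attended_output_q.
.fwd_aspect_fusion <- function(ctx, aspects) {
  t <- ctx$tape
  K <- length(aspects)
  if (K == 1L) {
    out <- ad_matmul(t, aspects[[1L]], ctx$P[["attn.Wo"]])
    w <- ad_const(t, matrix(1, nrow(aspects[[1L]]$val), 1L))
    return(list(fused = out, weights = w))
  }
  mh <- .fwd_mha(ctx, aspects, "attn", ctx$cfg$heads, "attn.Wo")
  H <- ctx$cfg$heads
  ## received mass per aspect: mean over heads and query tokens
  wcols <- vector("list", K)
  for (q in seq_len(K)) {
    acc <- NULL
    for (h in seq_len(H)) {
      for (i in seq_len(K)) {
        piece <- ad_cols(t, mh$attn[[h]][[i]], q)
        acc <- if (is.null(acc)) piece else ad_add(t, acc, piece)
      }
    }
    wcols[[q]] <- ad_scale(t, acc, 1 / (H * K))
  }
  W <- ad_cbind(t, wcols)                       # B x K
  W <- ad_div(t, W, ad_rowsums(t, W))           # renormalize (already ~1)
  fused <- NULL
  for (q in seq_len(K)) {
    contrib <- ad_mul(t, ad_cols(t, W, q), mh$tokens[[q]])
    fused <- if (is.null(fused)) contrib else ad_add(t, fused, contrib)
  }
  list(fused = fused, weights = W)
}

.fwd_risk <- function(ctx, fused) {
  .dense(ctx, fused, "risk", "sigmoid")
}

## Fused pair representation from the two branch outputs.
.fwd_fuse_branches <- function(ctx, z, assoc) {
  t <- ctx$tape
  inp <- if (is.null(assoc)) z else ad_cbind(t, list(z, assoc))
  .dropout(ctx, .dense(ctx, inp, "fuse", "relu"))
}

## Public wrappers --------------------------------------------------------

#' Split a fused pair representation into K mechanism aspects
#'
#' K parallel learned affine + ReLU projections of the shared representation,
#' one per pharmacological aspect (e.g. metabolism, absorption).
#'
#' @param model An `mmddi_model`.
#' @param g Numeric vector (or matrix of rows) of width `latent_dim`.
#' @return List of K matrices of width `aspect_width`.
#' @export
split_aspects <- function(model, g) {
  G <- if (is.matrix(g)) g else matrix(g, nrow = 1L)
  ctx <- .ctx(model, training = FALSE)
  lapply(.fwd_aspects(ctx, ad_const(ctx$tape, G)), function(n) n$val)
}

#' Fuse mechanism aspects with multi-head attention
#'
#' Returns the fused vector and the per-aspect contribution weights
#' (attention mass received, head- and query-averaged, renormalized to sum
#' to one). With a single aspect the weight vector is exactly 1.
#'
#' @param model An `mmddi_model`.
#' @param aspects List of K aspect matrices (equal rows and widths).
#' @return List with `fused` (matrix) and `weights` (rows are probability
#'   vectors over the K aspects).
#' @export
fuse_aspects <- function(model, aspects) {
  stopifnot(length(aspects) >= 1L)
  ctx <- .ctx(model, training = FALSE)
  nodes <- lapply(aspects, function(a) {
    ad_const(ctx$tape, if (is.matrix(a)) a else matrix(a, nrow = 1L))
  })
  res <- .fwd_aspect_fusion(ctx, nodes)
  list(fused = res$fused$val, weights = res$weights$val)
}

#' Sigmoid risk score of a fused representation
#'
#' @param model An `mmddi_model`.
#' @param fused Numeric vector (or matrix of rows) of width `aspect_width`.
#' @return Numeric vector of risk values in (0, 1).
#' @export
risk_score <- function(model, fused) {
  Fm <- if (is.matrix(fused)) fused else matrix(fused, nrow = 1L)
  ctx <- .ctx(model, training = FALSE)
  as.numeric(.fwd_risk(ctx, ad_const(ctx$tape, Fm))$val)
}

#' Effective fusion weights under entangled mechanism mixing
#'
#' When each learned aspect is itself a stochastic mixture of the underlying
#' mechanism bases (`mixing`, rows summing to one), the fusion weights
#' reported over the learned aspects do not apply to the true mechanisms.
#' The composition `fusion %*% mixing` gives the true coefficients on the
#' underlying bases and quantifies the interpretability bias that the
#' independence regularizer removes: with 60/40 mixing, nominal weights
#' (0.8, 0.2) are effectively (0.56, 0.44).
#'
#' @param mixing K x K matrix, rows summing to 1.
#' @param fusion Length-K fusion weight vector summing to 1.
#' @return Length-K vector of effective weights (sums to 1).
#' @export
effective_fusion_weights <- function(mixing, fusion) {
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != ncol(mixing) || length(fusion) != nrow(mixing)) {
    stop("effective_fusion_weights: fusion length must match square mixing")
  }
  if (any(abs(rowSums(mixing) - 1) > 1e-8)) {
    stop("effective_fusion_weights: mixing rows must sum to 1")
  }
  as.numeric(matrix(fusion, nrow = 1L) %*% mixing)
}

#' Correlate aspect contribution weights with attribute evidence
#'
#' Descriptive post-hoc labeling aid: Pearson correlation between each
#' aspect's per-pair contribution weight and per-pair attribute overlap
#' signals (e.g. enzyme-set Tanimoto -> metabolism aspect).
#'
#' @param weights Matrix (pairs x K) of aspect contribution weights.
#' @param signals Matrix (pairs x S) of per-pair attribute signals.
#' @return K x S correlation matrix.
#' @export
aspect_attribute_correlation <- function(weights, signals) {
  weights <- as.matrix(weights); signals <- as.matrix(signals)
  stopifnot(nrow(weights) == nrow(signals))
  out <- matrix(NA_real_, ncol(weights), ncol(signals),
                dimnames = list(colnames(weights), colnames(signals)))
  for (i in seq_len(ncol(weights))) {
    for (j in seq_len(ncol(signals))) {
      if (stats::sd(weights[, i]) > 0 && stats::sd(signals[, j]) > 0) {
        out[i, j] <- stats::cor(weights[, i], signals[, j])
      }
    }
  }
  out
}

#' Label aspects by their most correlated attribute tokens
#'
#' Post-hoc mechanism labeling: correlates each aspect's per-pair
#' contribution weight with per-pair shared-token indicators (token present
#' in both drugs' attribute sets) and reports the top tokens per aspect.
#' Shared enzymes pointing at one aspect suggest a metabolism reading;
#' shared transporter-like targets an absorption reading.
#'
#' @param weights Matrix (pairs x K) of aspect contribution weights.
#' @param pairs `data.frame` with columns `drugA`, `drugB` aligned to
#'   `weights` rows.
#' @param drug_table Drug table with attribute columns.
#' @param categories Attribute categories to consider (tokens are pooled).
#' @param top Number of tokens reported per aspect.
#' @return List of K character vectors of token names (most correlated
#'   first), with the correlations as names.
#' @export
label_aspects <- function(weights, pairs, drug_table,
                          categories = c("target", "enzyme", "pathway"),
                          top = 5L) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == nrow(pairs))
  sets <- list()
  for (cat in categories) {
    s <- .category_sets(drug_table, cat)
    names(s) <- drug_table$drug_id
    toks <- unique(unlist(s, use.names = FALSE))
    for (tk in toks) {
      has <- vapply(s, function(x) tk %in% x, logical(1))
      sets[[tk]] <- has[pairs$drugA] & has[pairs$drugB]
    }
  }
  signals <- do.call(cbind, lapply(sets, as.numeric))
  colnames(signals) <- names(sets)
  cors <- aspect_attribute_correlation(weights, signals)
  lapply(seq_len(nrow(cors)), function(k) {
    r <- cors[k, ]
    r <- r[!is.na(r)]
    r <- sort(r, decreasing = TRUE)
    utils::head(stats::setNames(names(r), signif(r, 3)), top)
  })
}

#' Write per-pair explanation records as JSON
#'
#' Each record carries the pair, its risk value and the K aspect contribution
#' weights; when `aspect_tokens` (e.g. from [label_aspects()]) is given, the
#' per-aspect top correlated attribute tokens are embedded once as metadata.
#'
#' @param pairs `data.frame` with columns `drugA`, `drugB`.
#' @param risks Numeric vector of risk values.
#' @param weights Matrix (pairs x K).
#' @param path Output JSON path.
#' @param aspect_tokens Optional list of per-aspect token vectors.
#' @export
export_explanations <- function(pairs, risks, weights, path,
                                aspect_tokens = NULL) {
  recs <- lapply(seq_len(nrow(pairs)), function(i) list(
    drugA = pairs$drugA[i], drugB = pairs$drugB[i],
    risk = risks[i], aspect_weights = as.numeric(weights[i, ])
  ))
  body <- if (is.null(aspect_tokens)) recs else
    list(aspect_top_tokens = lapply(aspect_tokens, unname),
         explanations = recs)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
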