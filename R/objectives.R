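## The four training losses and their weighted combination.
##
## Public functions operate on plain numeric inputs (and are the reference
## semantics asserted in tests); the .ad_* helpers express the same losses on
## the autodiff tape for training.

#' Loss weights and temperature for the joint objective
#'
#' The total objective is `w_re * L_re + w_cl * L_InfoNCE + w_ind * L_ind +
#' L_bpr` (the ranking term is unweighted).
#'
#' @param w_re,w_cl,w_ind Non-negative weights on the reconstruction,
#'   contrastive and independence terms. Default 1 each.
#' @param temperature InfoNCE temperature, must be positive. Default 0.05.
#' @param clamp Magnitude at which per-pair symmetric KL is clamped inside the
#'   independence loss. Default 5.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_re = 1, w_cl = 1, w_ind = 1,
                         temperature = 0.05, clamp = 5) {
  if (temperature <= 0) stop("loss_weights: temperature must be > 0")
  if (any(c(w_re, w_cl, w_ind) < 0)) stop("loss_weights: weights must be >= 0")
  structure(list(w_re = w_re, w_cl = w_cl, w_ind = w_ind,
                 temperature = temperature, clamp = clamp),
            class = "loss_weights")
}

#' Mean squared reconstruction error
#'
#' @param x,x_hat Equal-length numeric vectors (or matrices).
#' @return Mean over entries of squared differences.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop("reconstruction_loss: length mismatch")
  mean((x - x_hat)^2)
}

#' Temperature-scaled InfoNCE contrastive loss for one anchor
#'
#' `-log( exp(s(h_i, h_j)/T) / (sum_neg exp(s(h_i, h0)/T) + sum_pos
#' exp(s(h_i, h+)/T)) )` with dot-product similarity, stabilized by max
#' subtraction. By default the positive set contains only `positive` itself,
#' so with `N` negatives of identical similarity the loss is `log(N + 1)`.
#'
#' @param anchor,positive Numeric vectors of equal length.
#' @param negatives Matrix with negatives as rows (at least one).
#' @param extra_positives Optional matrix of additional positives appearing in
#'   the denominator; defaults to `positive` alone.
#' @param temperature Positive temperature T.
#' @export
infonce_loss <- function(anchor, positive, negatives,
                         extra_positives = NULL, temperature = 0.05) {
  if (temperature <= 0) stop("infonce_loss: temperature must be > 0")
  negatives <- .as_mat(negatives)
  if (nrow(negatives) < 1L) stop("infonce_loss: need at least one negative")
  pos_set <- if (is.null(extra_positives)) .as_mat(positive) else
    .as_mat(extra_positives)
  s_pos <- sum(anchor * positive) / temperature
  s_den <- c(negatives %*% anchor, pos_set %*% anchor) / temperature
  m <- max(s_den, s_pos)
  -(s_pos - m) + log(sum(exp(s_den - m)))
}

#' Bayesian personalized ranking loss
#'
#' `-(1/m) * sum log sigmoid(pos - neg)` over paired positive/negative scores;
#' at zero margin the loss is `log(2)`.
#'
#' @param pos_scores,neg_scores Equal-length numeric vectors, one entry per
#'   training triple.
#' @export
bpr_loss <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L) stop("bpr_loss: empty score lists")
  if (length(pos_scores) != length(neg_scores)) {
    stop("bpr_loss: score lists must be paired")
  }
  z <- pos_scores - neg_scores
  ## -log sigmoid(z), numerically stable on both tails
  mean(ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z))))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `sum p_i (log p_i - log q_i)` after epsilon-smoothing and renormalization;
#' zero iff the distributions coincide.
#'
#' @param p,q Non-negative vectors of equal length, each summing to one
#'   (renormalized after smoothing).
#' @param eps Smoothing constant added to every cell before renormalizing.
#' @export
kl_divergence <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q)) stop("kl_divergence: length mismatch")
  if (any(p < 0) || any(q < 0)) stop("kl_divergence: negative entries")
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  sum(p * (log(p) - log(q)))
}

#' Independence loss over K aspect distributions
#'
#' Computes minus the mean (over samples and unordered aspect pairs) of the
#' symmetric KL divergence `(KL(p||q) + KL(q||p)) / 2`, with each pair's
#' divergence clamped at `clamp`. Minimizing the total objective therefore
#' pushes aspect distributions apart; the loss attains its maximum, 0, when
#' all aspects coincide, and approaches `-clamp` for well-separated peaked
#' aspects.
#'
#' @param aspects List of K numeric matrices (samples x dims) or vectors, each
#'   row a distribution.
#' @param clamp Clamp magnitude, default 5.
#' @param eps Smoothing constant.
#' @return Scalar in `[-clamp, 0]`.
#' @export
independence_loss <- function(aspects, clamp = 5, eps = 1e-12) {
  K <- length(aspects)
  if (K < 2L) {
    warning("independence_loss: fewer than 2 aspects; loss is 0")
    return(0)
  }
  aspects <- lapply(aspects, .as_mat)
  B <- nrow(aspects[[1]])
  total <- 0; npairs <- 0L
  for (k in seq_len(K - 1L)) {
    for (l in (k + 1L):K) {
      sym <- vapply(seq_len(B), function(b) {
        p <- aspects[[k]][b, ]; q <- aspects[[l]][b, ]
        0.5 * (kl_divergence(p, q, eps) + kl_divergence(q, p, eps))
      }, numeric(1))
      total <- total + mean(pmin(sym, clamp))
      npairs <- npairs + 1L
    }
  }
  -total / npairs
}

#' Weighted total training objective
#'
#' `w_re * l_re + w_cl * l_cl + w_ind * l_ind + l_bpr`; the BPR ranking term
#' carries no weight.
#'
#' @param l_re,l_cl,l_ind,l_bpr Scalar loss components.
#' @param weights A [loss_weights()] object.
#' @export
total_loss <- function(l_re, l_cl, l_ind, l_bpr, weights = loss_weights()) {
  comps <- c(reconstruction = l_re, contrastive = l_cl,
             independence = l_ind, bpr = l_bpr)
  bad <- !is.finite(comps)
  if (any(bad)) {
    stop("total_loss: non-finite component(s): ",
         paste(names(comps)[bad], collapse = ", "))
  }
  weights$w_re * l_re + weights$w_cl * l_cl + weights$w_ind * l_ind + l_bpr
}

## ---- tape-side loss expressions (training path) ----

.ad_reconstruction <- function(tape, x, x_hat) {
  d <- ad_sub(tape, x, x_hat)
  ad_mean(tape, ad_mul(tape, d, d))
}

## In-batch InfoNCE: rows of h1 are anchors, matching rows of h2 positives,
## other rows of h2 the negatives. Returns the batch-mean loss node.
.ad_infonce_batch <- function(tape, h1, h2, temperature) {
  B <- nrow(h1$val)
  logits <- ad_scale(tape, ad_matmul_bt(tape, h1, h2), 1 / temperature)
  eye <- ad_const(tape, diag(B))
  pos <- ad_rowsums(tape, ad_mul(tape, logits, eye))
  lse <- ad_logsumexp_rows(tape, logits)
  ad_mean(tape, ad_sub(tape, lse, pos))
}

## BPR on score column nodes: mean softplus(-(pos - neg)).
.ad_bpr <- function(tape, s_pos, s_neg) {
  z <- ad_sub(tape, s_pos, s_neg)
  zero <- ad_const(tape, matrix(0, nrow(z$val), 1L))
  ad_mean(tape, ad_logsumexp_rows(tape, ad_cbind(tape, list(zero, ad_neg(tape, z)))))
}

## Independence over a list of aspect pre-activation nodes (B x d each):
## per-sample softmax distributions, then minus the mean clamped symmetric KL
## across unordered aspect pairs. Log-probabilities are computed as
## a - logsumexp(a), which stays finite where softmax underflows.
.ad_independence <- function(tape, aspects, clamp, ind_scale = 1) {
  K <- length(aspects)
  if (K < 2L) return(ad_const(tape, matrix(0, 1L, 1L)))
  ## distributions over aspect dimensions from L2-normalized vectors, scaled
  ## to a fixed logit range (ind_scale): separation is rewarded in direction only, so the
  ## regularizer cannot be satisfied by inflating magnitudes (which would
  ## detach the aspects from the input)
  eps <- ad_const(tape, matrix(1e-8, 1L, 1L))
  logits <- lapply(aspects, function(a) {
    nrm <- ad_sqrt(tape, ad_add(tape, ad_rowsums(tape, ad_mul(tape, a, a)),
                                eps))
    ad_scale(tape, ad_div(tape, a, nrm), ind_scale)
  })
  dists <- lapply(logits, function(a) ad_softmax_rows(tape, a))
  logps <- lapply(logits, function(a)
    ad_sub(tape, a, ad_logsumexp_rows(tape, a)))
  terms <- list()
  for (k in seq_len(K - 1L)) {
    for (l in (k + 1L):K) {
      p <- dists[[k]]; q <- dists[[l]]
      diff <- ad_sub(tape, p, q)
      ldiff <- ad_sub(tape, logps[[k]], logps[[l]])
      sym <- ad_scale(tape, ad_rowsums(tape, ad_mul(tape, diff, ldiff)), 0.5)
      ## clamp(x) = clamp - relu(clamp - x), differentiable a.e.
      clamped <- ad_sub(tape, ad_const(tape, matrix(clamp, 1L, 1L)),
                        ad_relu(tape, ad_sub(tape,
                          ad_const(tape, matrix(clamp, 1L, 1L)), sym)))
      terms[[length(terms) + 1L]] <- ad_mean(tape, clamped)
    }
  }
  tot <- terms[[1L]]
  if (length(terms) > 1L) {
    for (i in 2L:length(terms)) tot <- ad_add(tape, tot, terms[[i]])
  }
  ad_scale(tape, tot, -1 / length(terms))
}
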