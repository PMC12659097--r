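## Minimal reverse-mode automatic differentiation over dense matrices.
##
## Every differentiable computation in the package (autoencoder, position-free
## attention encoders, projection head, aspect heads, losses) is expressed in
## these primitives. Nodes are environments recorded on a tape in creation
## order; ad_backward() walks the tape in reverse, accumulating gradients.
## Values are always stored as matrices (a scalar is 1 x 1).

ad_tape <- function() {
  new.env(parent = emptyenv())
}

.ad_new <- function(tape, val, parents = list(), back = NULL, req = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$back <- back
  nd$req <- req
  nd$vis <- FALSE
  nd
}

#' @noRd
ad_const <- function(tape, x) {
  .ad_new(tape, .as_mat(x), req = FALSE)
}

#' @noRd
ad_var <- function(tape, x) {
  .ad_new(tape, .as_mat(x), req = TRUE)
}

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

.ad_acc <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

## Broadcast x (matrix) up to dim (r, c); each dim must match or be 1.
.bc <- function(x, r, c) {
  xr <- nrow(x); xc <- ncol(x)
  if (xr == r && xc == c) return(x)
  if (xr == 1L && xc == c) return(x[rep.int(1L, r), , drop = FALSE])
  if (xr == r && xc == 1L) return(x[, rep.int(1L, c), drop = FALSE])
  if (xr == 1L && xc == 1L) return(matrix(x[1L], r, c))
  stop("ad: incompatible broadcast from (", xr, ",", xc, ") to (", r, ",", c, ")")
}

## Reduce a gradient of shape (r, c) back to the shape of x by summing over
## broadcast dimensions.
.unbc <- function(g, x) {
  xr <- nrow(x); xc <- ncol(x)
  if (nrow(g) == xr && ncol(g) == xc) return(g)
  if (xr == 1L && xc == 1L) return(matrix(sum(g), 1L, 1L))
  if (xr == 1L) return(matrix(.colSums(g, nrow(g), ncol(g)), 1L))
  if (xc == 1L) return(matrix(.rowSums(g, nrow(g), ncol(g)), ncol = 1L))
  stop("ad: cannot reduce gradient")
}

.ad_ewise <- function(tape, a, b, fwd, bwd_a, bwd_b) {
  r <- max(nrow(a$val), nrow(b$val))
  c <- max(ncol(a$val), ncol(b$val))
  av <- .bc(a$val, r, c); bv <- .bc(b$val, r, c)
  val <- fwd(av, bv)
  req <- a$req || b$req
  nd <- .ad_new(tape, val, parents = list(a, b), req = req)
  if (req) {
    nd$back <- function(g) {
      if (a$req) .ad_acc(a, .unbc(bwd_a(g, av, bv, val), a$val))
      if (b$req) .ad_acc(b, .unbc(bwd_b(g, av, bv, val), b$val))
    }
  }
  nd
}

ad_add <- function(tape, a, b) .ad_ewise(tape, a, b,
  function(x, y) x + y,
  function(g, x, y, v) g,
  function(g, x, y, v) g)

ad_sub <- function(tape, a, b) .ad_ewise(tape, a, b,
  function(x, y) x - y,
  function(g, x, y, v) g,
  function(g, x, y, v) -g)

ad_mul <- function(tape, a, b) .ad_ewise(tape, a, b,
  function(x, y) x * y,
  function(g, x, y, v) g * y,
  function(g, x, y, v) g * x)

ad_div <- function(tape, a, b) .ad_ewise(tape, a, b,
  function(x, y) x / y,
  function(g, x, y, v) g / y,
  function(g, x, y, v) -g * x / (y * y))

ad_matmul <- function(tape, a, b) {
  val <- a$val %*% b$val
  req <- a$req || b$req
  nd <- .ad_new(tape, val, parents = list(a, b), req = req)
  if (req) {
    nd$back <- function(g) {
      if (a$req) .ad_acc(a, g %*% t(b$val))
      if (b$req) .ad_acc(b, t(a$val) %*% g)
    }
  }
  nd
}

## a %*% t(b) without materializing a transposed node.
ad_matmul_bt <- function(tape, a, b) {
  val <- tcrossprod(a$val, b$val)
  req <- a$req || b$req
  nd <- .ad_new(tape, val, parents = list(a, b), req = req)
  if (req) {
    nd$back <- function(g) {
      if (a$req) .ad_acc(a, g %*% b$val)
      if (b$req) .ad_acc(b, crossprod(g, a$val))
    }
  }
  nd
}

.ad_unary <- function(tape, a, fwd, bwd) {
  val <- fwd(a$val)
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) .ad_acc(a, bwd(g, a$val, val))
  nd
}

ad_relu <- function(tape, a) .ad_unary(tape, a,
  function(x) pmax(x, 0),
  function(g, x, v) g * (x > 0))

ad_sigmoid <- function(tape, a) .ad_unary(tape, a,
  function(x) 1 / (1 + exp(-x)),
  function(g, x, v) g * v * (1 - v))

ad_exp <- function(tape, a) .ad_unary(tape, a,
  function(x) exp(x),
  function(g, x, v) g * v)

ad_log <- function(tape, a) .ad_unary(tape, a,
  function(x) log(x),
  function(g, x, v) g / x)

ad_sqrt <- function(tape, a) .ad_unary(tape, a,
  function(x) sqrt(x),
  function(g, x, v) g / (2 * v))

ad_neg <- function(tape, a) .ad_unary(tape, a,
  function(x) -x,
  function(g, x, v) -g)

ad_scale <- function(tape, a, s) .ad_unary(tape, a,
  function(x) s * x,
  function(g, x, v) s * g)

ad_rowsums <- function(tape, a) {
  val <- matrix(.rowSums(a$val, nrow(a$val), ncol(a$val)), ncol = 1L)
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, g[, rep.int(1L, ncol(a$val)), drop = FALSE])
  }
  nd
}

ad_colmeans <- function(tape, a) {
  r <- nrow(a$val)
  val <- matrix(.colMeans(a$val, r, ncol(a$val)), nrow = 1L)
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, g[rep.int(1L, r), , drop = FALSE] / r)
  }
  nd
}

ad_mean <- function(tape, a) {
  n <- length(a$val)
  val <- matrix(mean(a$val), 1L, 1L)
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, matrix(g[1L] / n, nrow(a$val), ncol(a$val)))
  }
  nd
}

ad_sum <- function(tape, a) {
  val <- matrix(sum(a$val), 1L, 1L)
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, matrix(g[1L], nrow(a$val), ncol(a$val)))
  }
  nd
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  val <- do.call(cbind, vals)
  req <- any(vapply(nodes, function(n) n$req, logical(1)))
  nd <- .ad_new(tape, val, parents = nodes, req = req)
  if (req) {
    widths <- vapply(vals, ncol, integer(1))
    ends <- cumsum(widths)
    starts <- ends - widths + 1L
    nd$back <- function(g) {
      for (i in seq_along(nodes)) {
        if (nodes[[i]]$req) {
          .ad_acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
        }
      }
    }
  }
  nd
}

## Fused affine layer with optional activation: act(x %*% W + b).
## One node replaces the matmul/add/activation chain.
ad_affine <- function(tape, x, W, b, act = "none") {
  pre <- x$val %*% W$val
  pre <- sweep(pre, 2L, b$val, `+`, check.margin = FALSE)
  val <- switch(act, relu = pre * (pre > 0), sigmoid = 1 / (1 + exp(-pre)),
                none = pre)
  req <- x$req || W$req || b$req
  nd <- .ad_new(tape, val, parents = list(x, W, b), req = req)
  if (req) {
    nd$back <- function(g) {
      gp <- switch(act, relu = g * (val > 0), sigmoid = g * val * (1 - val),
                   none = g)
      if (x$req) .ad_acc(x, gp %*% t(W$val))
      if (W$req) .ad_acc(W, crossprod(x$val, gp))
      if (b$req) .ad_acc(b, matrix(.colSums(gp, nrow(gp), ncol(gp)), 1L))
    }
  }
  nd
}

## Fused batch normalization (training mode, batch statistics, biased
## variance). Also reports the batch moments for running-statistics updates.
ad_bn_train <- function(tape, x, gamma, beta, eps = 1e-5) {
  X <- x$val
  r <- nrow(X)
  mu <- .colMeans(X, r, ncol(X))
  xc <- sweep(X, 2L, mu, `-`, check.margin = FALSE)
  v <- .colMeans(xc * xc, r, ncol(X))
  inv <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2L, inv, `*`, check.margin = FALSE)
  val <- sweep(sweep(xn, 2L, gamma$val, `*`, check.margin = FALSE),
               2L, beta$val, `+`, check.margin = FALSE)
  req <- x$req || gamma$req || beta$req
  nd <- .ad_new(tape, val, parents = list(x, gamma, beta), req = req)
  nd$batch_mean <- mu
  nd$batch_var <- v
  if (req) {
    nd$back <- function(g) {
      if (gamma$req) {
        .ad_acc(gamma, matrix(.colSums(g * xn, r, ncol(g)), 1L))
      }
      if (beta$req) .ad_acc(beta, matrix(.colSums(g, r, ncol(g)), 1L))
      if (x$req) {
        gg <- sweep(g, 2L, as.numeric(gamma$val), `*`, check.margin = FALSE)
        t1 <- .colMeans(gg, r, ncol(gg))
        t2 <- .colMeans(gg * xn, r, ncol(gg))
        dx <- sweep(gg, 2L, t1, `-`, check.margin = FALSE) -
          sweep(xn, 2L, t2, `*`, check.margin = FALSE)
        .ad_acc(x, sweep(dx, 2L, inv, `*`, check.margin = FALSE))
      }
    }
  }
  nd
}

ad_rows <- function(tape, a, idx) {
  val <- a$val[idx, , drop = FALSE]
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    full <- matrix(0, nrow(a$val), ncol(a$val))
    full[idx, ] <- g
    .ad_acc(a, full)
  }
  nd
}

## Fused pairwise dot products: column j of the result is the row-wise dot
## product of q with klist[[j]] (all B x d). One node replaces 3t.
ad_pairdots <- function(tape, q, klist, scale = 1) {
  t_ <- length(klist)
  val <- matrix(0, nrow(q$val), t_)
  B <- nrow(q$val); d_ <- ncol(q$val)
  for (j in seq_len(t_)) val[, j] <- .rowSums(q$val * klist[[j]]$val, B, d_) * scale
  req <- q$req || any(vapply(klist, function(n) n$req, logical(1)))
  nd <- .ad_new(tape, val, parents = c(list(q), klist), req = req)
  if (req) {
    nd$back <- function(g) {
      if (q$req) {
        gq <- matrix(0, nrow(q$val), ncol(q$val))
        for (j in seq_len(t_)) gq <- gq + g[, j] * klist[[j]]$val
        .ad_acc(q, gq * scale)
      }
      for (j in seq_len(t_)) {
        if (klist[[j]]$req) .ad_acc(klist[[j]], (g[, j] * q$val) * scale)
      }
    }
  }
  nd
}

## Fused convex mix of value tokens: sum_j A[, j] * vlist[[j]]. One node
## replaces 2t.
ad_mixcols <- function(tape, A, vlist) {
  t_ <- length(vlist)
  val <- matrix(0, nrow(A$val), ncol(vlist[[1L]]$val))
  for (j in seq_len(t_)) val <- val + A$val[, j] * vlist[[j]]$val
  req <- A$req || any(vapply(vlist, function(n) n$req, logical(1)))
  nd <- .ad_new(tape, val, parents = c(list(A), vlist), req = req)
  if (req) {
    nd$back <- function(g) {
      if (A$req) {
        gA <- matrix(0, nrow(A$val), t_)
        for (j in seq_len(t_)) gA[, j] <- .rowSums(g * vlist[[j]]$val, nrow(g), ncol(g))
        .ad_acc(A, gA)
      }
      for (j in seq_len(t_)) {
        if (vlist[[j]]$req) .ad_acc(vlist[[j]], A$val[, j] * g)
      }
    }
  }
  nd
}

## Fused multi-token self-attention for one head over row-stacked tokens:
## Qs/Ks/Vs are (nt*B x d), token i occupying rows ((i-1)B+1):(iB) with a
## shared batch of size B. Computes, per sample b and query token i,
## softmax_j(Q_i[b,] . K_j[b,] * scale) and the attended mix of V, returning
## the stacked (nt*B x d) output. One node; analytic backward.
ad_block_attention <- function(tape, Qs, Ks, Vs, nt, scale) {
  B <- nrow(Qs$val) %/% nt
  d <- ncol(Qs$val)
  blocks <- lapply(seq_len(nt), function(i) ((i - 1L) * B + 1L):(i * B))
  Q <- Qs$val; K <- Ks$val; V <- Vs$val
  A <- vector("list", nt)           # per query token: B x nt attention
  out <- matrix(0, nt * B, d)
  for (i in seq_len(nt)) {
    Qi <- Q[blocks[[i]], , drop = FALSE]
    S <- matrix(0, B, nt)
    for (j in seq_len(nt)) {
      S[, j] <- .rowSums(Qi * K[blocks[[j]], , drop = FALSE], B, d) * scale
    }
    m <- S[cbind(seq_len(B), max.col(S, ties.method = "first"))]
    E <- exp(S - m)
    Ai <- E / .rowSums(E, B, nt)
    A[[i]] <- Ai
    oi <- matrix(0, B, d)
    for (j in seq_len(nt)) oi <- oi + Ai[, j] * V[blocks[[j]], , drop = FALSE]
    out[blocks[[i]], ] <- oi
  }
  req <- Qs$req || Ks$req || Vs$req
  nd <- .ad_new(tape, out, parents = list(Qs, Ks, Vs), req = req)
  nd$attn <- A
  if (req) {
    Qb <- lapply(blocks, function(b) Q[b, , drop = FALSE])
    Kb <- lapply(blocks, function(b) K[b, , drop = FALSE])
    Vb <- lapply(blocks, function(b) V[b, , drop = FALSE])
    nd$back <- function(g) {
      dQ <- vector("list", nt)
      dK <- lapply(seq_len(nt), function(j) matrix(0, B, d))
      dV <- lapply(seq_len(nt), function(j) matrix(0, B, d))
      for (i in seq_len(nt)) {
        gi <- g[blocks[[i]], , drop = FALSE]
        Ai <- A[[i]]
        dA <- matrix(0, B, nt)
        for (j in seq_len(nt)) {
          dA[, j] <- .rowSums(gi * Vb[[j]], B, d)
          dV[[j]] <- dV[[j]] + Ai[, j] * gi
        }
        dS <- (dA - .rowSums(dA * Ai, B, nt)) * Ai * scale
        qacc <- matrix(0, B, d)
        for (j in seq_len(nt)) {
          qacc <- qacc + dS[, j] * Kb[[j]]
          dK[[j]] <- dK[[j]] + dS[, j] * Qb[[i]]
        }
        dQ[[i]] <- qacc
      }
      if (Qs$req) .ad_acc(Qs, do.call(rbind, dQ))
      if (Ks$req) .ad_acc(Ks, do.call(rbind, dK))
      if (Vs$req) .ad_acc(Vs, do.call(rbind, dV))
    }
  }
  nd
}

## Mean over the nt row blocks of a stacked (nt*B x d) matrix -> (B x d).
ad_block_mean <- function(tape, a, nt) {
  B <- nrow(a$val) %/% nt
  d <- ncol(a$val)
  val <- matrix(0, B, d)
  for (i in seq_len(nt)) {
    val <- val + a$val[((i - 1L) * B + 1L):(i * B), , drop = FALSE]
  }
  val <- val / nt
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, g[rep.int(seq_len(B), nt), , drop = FALSE] / nt)
  }
  nd
}

ad_rbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  val <- do.call(rbind, vals)
  req <- any(vapply(nodes, function(n) n$req, logical(1)))
  nd <- .ad_new(tape, val, parents = nodes, req = req)
  if (req) {
    heights <- vapply(vals, nrow, integer(1))
    ends <- cumsum(heights)
    starts <- ends - heights + 1L
    nd$back <- function(g) {
      for (i in seq_along(nodes)) {
        if (nodes[[i]]$req) {
          .ad_acc(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
        }
      }
    }
  }
  nd
}

ad_cols <- function(tape, a, idx) {
  val <- a$val[, idx, drop = FALSE]
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    full <- matrix(0, nrow(a$val), ncol(a$val))
    full[, idx] <- g
    .ad_acc(a, full)
  }
  nd
}

## Row-wise softmax with detached max subtraction (exact value and gradient).
ad_softmax_rows <- function(tape, a) {
  m <- a$val[cbind(seq_len(nrow(a$val)), max.col(a$val, ties.method = "first"))]
  e <- exp(a$val - m)
  val <- e / .rowSums(e, nrow(e), ncol(e))
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, (g - .rowSums(g * val, nrow(g), ncol(g))) * val)
  }
  nd
}

## Row-wise log-sum-exp -> column vector; gradient is the row softmax.
ad_logsumexp_rows <- function(tape, a) {
  m <- a$val[cbind(seq_len(nrow(a$val)), max.col(a$val, ties.method = "first"))]
  e <- exp(a$val - m)
  s <- .rowSums(e, nrow(e), ncol(e))
  val <- matrix(m + log(s), ncol = 1L)
  nd <- .ad_new(tape, val, parents = list(a), req = a$req)
  if (a$req) nd$back <- function(g) {
    .ad_acc(a, g[, rep.int(1L, ncol(a$val)), drop = FALSE] * (e / s))
  }
  nd
}

#' @noRd
ad_backward <- function(tape, loss) {
  if (length(loss$val) != 1L) stop("ad_backward: loss must be scalar")
  ## iterative DFS post-order over parents gives a topological order
  order <- vector("list", 1024L)
  no <- 0L
  stack <- list(list(nd = loss, stage = 1L))
  ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    nd <- fr$nd
    if (fr$stage == 1L) {
      if (nd$vis || !nd$req && is.null(nd$back)) {
        ns <- ns - 1L
        next
      }
      nd$vis <- TRUE
      stack[[ns]]$stage <- 2L
      for (p in nd$parents) {
        if (!p$vis && (p$req || !is.null(p$back))) {
          ns <- ns + 1L
          stack[[ns]] <- list(nd = p, stage = 1L)
        }
      }
    } else {
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- nd
      ns <- ns - 1L
    }
  }
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(no, 1L)) {
    nd <- order[[i]]
    nd$vis <- FALSE
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
  }
  invisible(NULL)
}

ad_value <- function(node) node$val

ad_grad <- function(node) node$grad
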