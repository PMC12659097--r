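# Central-difference gradient oracles for the reverse-mode tape.

fd_grad <- function(f, X, h = 1e-6) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xm <- X
    Xp[i] <- Xp[i] + h; Xm[i] <- Xm[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

check_op <- function(build, f_plain, X, tol = 1e-5) {
  t <- ad_tape()
  Xn <- ad_var(t, X)
  loss <- build(t, Xn)
  ad_backward(t, loss)
  expect_equal(ad_grad(Xn), fd_grad(f_plain, X), tolerance = tol)
  expect_equal(loss$val[1], f_plain(X), tolerance = 1e-10)
}

test_that("elementwise, matmul and reduction primitives match finite differences", {
  set.seed(41)
  X <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  check_op(
    function(t, Xn) ad_mean(t, ad_relu(t, ad_matmul(t, Xn, ad_const(t, W)))),
    function(X) mean(pmax(X %*% W, 0)), X)
  check_op(
    function(t, Xn) ad_sum(t, ad_sigmoid(t, Xn)),
    function(X) sum(plogis(X)), X)
  check_op(
    function(t, Xn) ad_mean(t, ad_mul(t, Xn, Xn)),
    function(X) mean(X * X), X)
  check_op(
    function(t, Xn) ad_mean(t, ad_logsumexp_rows(t, Xn)),
    function(X) mean(log(rowSums(exp(X)))), X)
  check_op(
    function(t, Xn) ad_mean(t, ad_softmax_rows(t, ad_mul(t, Xn, Xn))),
    function(X) {
      E <- exp(X * X - apply(X * X, 1, max)); mean(E / rowSums(E))
    }, X)
  Y <- abs(X) + 0.5
  check_op(
    function(t, Xn) ad_sum(t, ad_log(t, ad_sqrt(t, Xn))),
    function(X) sum(log(sqrt(X))), Y)
  # broadcasting: row-vector bias against a matrix
  b <- matrix(rnorm(4), 1)
  check_op(
    function(t, Xn) ad_mean(t, ad_add(t, Xn, ad_const(t, b))),
    function(X) mean(sweep(X, 2, as.numeric(b), `+`)), X)
  t <- ad_tape()
  bn <- ad_var(t, b)
  loss <- ad_mean(t, ad_mul(t, ad_add(t, ad_const(t, X), bn), ad_const(t, X)))
  ad_backward(t, loss)
  expect_equal(ad_grad(bn),
               fd_grad(function(bb) mean(sweep(X, 2, as.numeric(bb), `+`) * X), b),
               tolerance = 1e-6)
})

test_that("fused affine and batch-norm layers match finite differences", {
  set.seed(42)
  X <- matrix(rnorm(15), 5, 3)
  W <- matrix(rnorm(6), 3, 2)
  b <- matrix(rnorm(2), 1)
  for (act in c("none", "relu", "sigmoid")) {
    plain <- function(W_) {
      pre <- sweep(X %*% W_, 2, as.numeric(b), `+`)
      out <- switch(act, none = pre, relu = pmax(pre, 0), sigmoid = plogis(pre))
      mean(out * out)
    }
    t <- ad_tape()
    Wn <- ad_var(t, W)
    y <- ad_affine(t, ad_const(t, X), Wn, ad_const(t, b), act)
    loss <- ad_mean(t, ad_mul(t, y, y))
    ad_backward(t, loss)
    expect_equal(ad_grad(Wn), fd_grad(plain, W), tolerance = 1e-5)
  }
  # batch norm: gradient w.r.t. input, gamma and beta
  g <- matrix(runif(3, 0.5, 1.5), 1)
  be <- matrix(rnorm(3), 1)
  bn_plain <- function(X_) {
    mu <- colMeans(X_)
    v <- colMeans(sweep(X_, 2, mu)^2)
    xn <- sweep(sweep(X_, 2, mu), 2, sqrt(v + 1e-5), `/`)
    mean((sweep(sweep(xn, 2, as.numeric(g), `*`), 2, as.numeric(be), `+`))^2)
  }
  t <- ad_tape()
  Xn <- ad_var(t, X)
  y <- ad_bn_train(t, Xn, ad_const(t, g), ad_const(t, be))
  ad_backward(t, ad_mean(t, ad_mul(t, y, y)))
  expect_equal(ad_grad(Xn), fd_grad(bn_plain, X), tolerance = 1e-4)
})

test_that("fused block attention agrees with a naive implementation", {
  set.seed(43)
  nt <- 3L; B <- 4L; d <- 5L
  Q <- matrix(rnorm(nt * B * d), nt * B, d)
  K <- matrix(rnorm(nt * B * d), nt * B, d)
  V <- matrix(rnorm(nt * B * d), nt * B, d)
  scale <- 1 / sqrt(d)
  naive <- function(Q, K, V) {
    out <- Q * 0
    for (i in 1:nt) {
      bi <- ((i - 1) * B + 1):(i * B)
      for (b in 1:B) {
        s <- vapply(1:nt, function(j) {
          sum(Q[bi[b], ] * K[(j - 1) * B + b, ]) * scale
        }, numeric(1))
        a <- exp(s - max(s)); a <- a / sum(a)
        out[bi[b], ] <- Reduce(`+`, lapply(1:nt, function(j) {
          a[j] * V[(j - 1) * B + b, ]
        }))
      }
    }
    out
  }
  t <- ad_tape()
  Qn <- ad_var(t, Q); Kn <- ad_var(t, K); Vn <- ad_var(t, V)
  out <- ad_block_attention(t, Qn, Kn, Vn, nt, scale)
  expect_equal(out$val, naive(Q, K, V), tolerance = 1e-12)
  W <- matrix(rnorm(nt * B * d), nt * B, d)   # random linear functional
  ad_backward(t, ad_mean(t, ad_mul(t, out, ad_const(t, W))))
  expect_equal(ad_grad(Qn), fd_grad(function(Q_) mean(naive(Q_, K, V) * W), Q),
               tolerance = 1e-4)
  expect_equal(ad_grad(Kn), fd_grad(function(K_) mean(naive(Q, K_, V) * W), K),
               tolerance = 1e-4)
  expect_equal(ad_grad(Vn), fd_grad(function(V_) mean(naive(Q, K, V_) * W), V),
               tolerance = 1e-4)
})

test_that("shared parameters accumulate gradients across reuse", {
  set.seed(44)
  W <- matrix(rnorm(4), 2, 2)
  X <- matrix(rnorm(6), 3, 2)
  t <- ad_tape()
  Wn <- ad_var(t, W)
  y1 <- ad_matmul(t, ad_const(t, X), Wn)
  y2 <- ad_matmul(t, ad_relu(t, y1), Wn)      # W used twice
  ad_backward(t, ad_mean(t, ad_mul(t, y2, y2)))
  plain <- function(W_) {
    y <- pmax(X %*% W_, 0) %*% W_
    mean(y * y)
  }
  expect_equal(ad_grad(Wn), fd_grad(plain, W), tolerance = 1e-5)
})

test_that("block mean, row/col slicing and stacking backpropagate correctly", {
  set.seed(45)
  X <- matrix(rnorm(24), 8, 3)
  t <- ad_tape()
  Xn <- ad_var(t, X)
  pooled <- ad_block_mean(t, Xn, 2L)
  ad_backward(t, ad_mean(t, ad_mul(t, pooled, pooled)))
  plain <- function(X_) {
    P <- (X_[1:4, ] + X_[5:8, ]) / 2
    mean(P * P)
  }
  expect_equal(ad_grad(Xn), fd_grad(plain, X), tolerance = 1e-6)

  t <- ad_tape()
  Xn <- ad_var(t, X)
  piece <- ad_rows(t, Xn, 3:5)
  col <- ad_cols(t, piece, 2L)
  ad_backward(t, ad_sum(t, ad_mul(t, col, col)))
  plain2 <- function(X_) sum(X_[3:5, 2]^2)
  expect_equal(ad_grad(Xn), fd_grad(plain2, X), tolerance = 1e-6)
})
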