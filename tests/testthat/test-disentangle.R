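test_that("effective fusion weights compose nominal weights with mixing", {
  expect_equal(
    effective_fusion_weights(matrix(c(0.6, 0.4, 0.4, 0.6), 2, byrow = TRUE),
                             c(0.8, 0.2)),
    c(0.56, 0.44), tolerance = 1e-12)
  w <- c(0.3, 0.5, 0.2)
  expect_equal(effective_fusion_weights(diag(3), w), w)
  set.seed(51)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    M <- matrix(runif(K * K), K); M <- M / rowSums(M)
    f <- runif(K); f <- f / sum(f)
    eff <- effective_fusion_weights(M, f)
    expect_equal(eff, as.numeric(f %*% M))
    expect_equal(sum(eff), 1, tolerance = 1e-12)
  }
  expect_error(effective_fusion_weights(matrix(1, 2, 2), c(0.5, 0.5)),
               "sum to 1")
  expect_error(effective_fusion_weights(diag(2), c(1, 0, 0)), "match")
})

test_that("aspect splitting is deterministic with the stated shapes", {
  m <- small_model()
  g <- runif(m$config$latent_dim)
  a1 <- split_aspects(m, g)
  expect_length(a1, m$config$k_aspects)
  expect_equal(ncol(a1[[1]]), m$config$aspect_width)
  expect_identical(a1, split_aspects(m, g))
  expect_true(all(vapply(a1, function(x) all(x >= 0), logical(1))))

  m1 <- small_model(mmddi_config(use_decoupling = FALSE))
  expect_length(split_aspects(m1, g), 1L)
})

test_that("aspect fusion yields probability weights with symmetry limits", {
  m <- small_model()
  wa <- m$config$aspect_width
  # K identical aspects: uniform weights by symmetry
  a <- matrix(runif(3 * wa), 3)
  res <- fuse_aspects(m, list(a, a))
  expect_equal(res$weights, matrix(0.5, 3, 2), tolerance = 1e-5)
  # single aspect: weight exactly 1
  res1 <- fuse_aspects(small_model(mmddi_config(use_decoupling = FALSE)),
                       list(a))
  expect_equal(res1$weights, matrix(1, 3, 1))
  # random bundle: weights form a probability vector
  set.seed(52)
  bundle <- lapply(1:3, function(i) matrix(runif(4 * wa), 4))
  res3 <- fuse_aspects(m, bundle)
  expect_prob_vector(res3$weights)
  expect_equal(dim(res3$fused), c(4L, wa))
})

test_that("aspect fusion matches a hand-rolled attention oracle on a 2-dim toy", {
  cfg <- mmddi_config(latent_dim = 2L, assoc_width = 2L, aspect_width = 2L,
                      heads = 1L, k_aspects = 2L)
  m <- mmddi_model(4L, 2L, 1L, cfg, seed = 13)
  a1 <- matrix(c(0.9, 0.1), 1)
  a2 <- matrix(c(0.2, 0.7), 1)
  res <- fuse_aspects(m, list(a1, a2))
  # independent plain-R attention computation
  P <- m$params
  Wq <- P[["attn.h1.Wq"]]; Wk <- P[["attn.h1.Wk"]]; Wv <- P[["attn.h1.Wv"]]
  toks <- rbind(a1, a2)
  Q <- toks %*% Wq; K <- toks %*% Wk; V <- toks %*% Wv
  S <- (Q %*% t(K)) / sqrt(ncol(Wq))
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  w_recv <- colMeans(A)
  w_recv <- w_recv / sum(w_recv)
  expect_equal(as.numeric(res$weights), w_recv, tolerance = 1e-10)
  out <- (A %*% V) %*% P[["attn.Wo"]] + toks       # per-query attended + resid
  fused <- w_recv[1] * out[1, ] + w_recv[2] * out[2, ]
  expect_equal(as.numeric(res$fused), fused, tolerance = 1e-10)
})

test_that("risk head is a sigmoid affine map", {
  m <- small_model()
  wa <- m$config$aspect_width
  m0 <- m
  m0$params[["risk.W"]] <- matrix(0, wa, 1)
  m0$params[["risk.b"]] <- matrix(0, 1, 1)
  expect_equal(risk_score(m0, runif(wa)), 0.5)
  # matches sigmoid(w . fused + b) and is monotone in the logit
  set.seed(53)
  f <- runif(wa)
  expect_equal(risk_score(m, f),
               plogis(as.numeric(f %*% m$params[["risk.W"]]) +
                        m$params[["risk.b"]][1]))
  m_up <- m
  m_up$params[["risk.b"]] <- m$params[["risk.b"]] + 1
  expect_gt(risk_score(m_up, f), risk_score(m, f))
})

test_that("independence regularizer separates aspect vectors across seeds", {
  sw <- small_world()
  data <- interaction_data(sw$world$interactions, sw$world$drug_table$drug_id)
  feats <- sw$features
  mean_cos <- function(model) {
    pairs <- utils::head(sw$world$interactions, 150)
    a <- match(pairs$drugA, feats$ids); b <- match(pairs$drugB, feats$ids)
    ctx <- mmddi:::.ctx(model, training = FALSE)
    inp <- mmddi:::.pair_inputs(feats, a, b, TRUE)
    z <- mmddi:::.fwd_encode_z(ctx, ad_const(ctx$tape, inp$X_sub))
    toks <- lapply(inp$tokens, function(m) ad_const(ctx$tape, m))
    g <- mmddi:::.fwd_fuse_branches(ctx, z, mmddi:::.fwd_assoc(ctx, toks))
    asp <- lapply(mmddi:::.fwd_aspects(ctx, g), ad_value)
    num <- rowSums(asp[[1]] * asp[[2]])
    den <- sqrt(rowSums(asp[[1]]^2) * rowSums(asp[[2]]^2)) + 1e-12
    mean(abs(num / den))
  }
  lower <- vapply(1:5, function(s) {
    cfg_on <- mmddi_config(lr = 1e-3, epochs = 5L, batch_size = 32L)
    cfg_off <- mmddi_config(lr = 1e-3, epochs = 5L, batch_size = 32L,
                            w_ind = 0)
    fit_on <- train_mmddi(data, feats, cfg_on, seed = s)
    fit_off <- train_mmddi(data, feats, cfg_off, seed = s)
    mean_cos(fit_on$model) < mean_cos(fit_off$model)
  }, logical(1))
  expect_true(all(lower))
})

test_that("aspect-attribute correlation and explanation export behave", {
  set.seed(54)
  w <- matrix(runif(40), 20)
  sig <- cbind(w[, 1] + rnorm(20, sd = 0.01), rnorm(20))
  cors <- aspect_attribute_correlation(w, sig)
  expect_gt(cors[1, 1], 0.9)
  expect_equal(dim(cors), c(2L, 2L))

  pairs <- data.frame(drugA = c("a", "b"), drugB = c("c", "d"))
  path <- withr::local_tempfile(fileext = ".json")
  export_explanations(pairs, c(0.9, 0.2), matrix(c(0.6, 0.4, 0.3, 0.7), 2),
                      path)
  rec <- jsonlite::read_json(path)
  expect_length(rec, 2L)
  expect_equal(rec[[1]]$risk, 0.9)
  expect_length(rec[[1]]$aspect_weights, 2L)
})

test_that("aspect labeling surfaces tokens shared by high-weight pairs", {
  tab <- tiny_drug_table()
  # pairs sharing enzyme e1 get high aspect-1 weight; others low
  pairs <- data.frame(drugA = c("d1", "d2", "d1", "d3", "d2", "d4"),
                      drugB = c("d2", "d5", "d5", "d6", "d3", "d6"),
                      stringsAsFactors = FALSE)
  e1_shared <- c(1, 1, 1, 0, 0, 0)
  w1 <- 0.3 + 0.4 * e1_shared + c(0.01, -0.01, 0.02, -0.02, 0.01, 0)
  W <- cbind(w1, 1 - w1)
  labs <- label_aspects(W, pairs, tab, categories = "enzyme", top = 3)
  expect_length(labs, 2L)
  expect_equal(unname(labs[[1]][1]), "e1")
  # the annotated export embeds the labels once
  path <- withr::local_tempfile(fileext = ".json")
  export_explanations(pairs, w1, W, path, aspect_tokens = labs)
  body <- jsonlite::read_json(path)
  expect_length(body$aspect_top_tokens, 2L)
  expect_equal(body$aspect_top_tokens[[1]][[1]], "e1")
  expect_length(body$explanations, nrow(pairs))
})
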