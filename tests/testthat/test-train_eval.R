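test_that("ranking metrics reproduce their closed forms", {
  # perfect ranking
  m <- ranking_metrics(list(c("p", "a", "b")), "p", K = 4)
  expect_equal(c(m$hit, m$ndcg, m$mrr), c(1, 1, 1))
  # positive at 0-based rank 3 with K = 4
  lst <- list(c("a", "b", "c", "p", "d"))
  m3 <- ranking_metrics(lst, "p", K = 4)
  expect_equal(m3$hit, 1)
  expect_equal(m3$ndcg, 1 / log2(5))
  expect_equal(m3$mrr, 0.25)
  # just outside the cutoff: all zero
  m4 <- ranking_metrics(lst, "p", K = 3)
  expect_equal(c(m4$hit, m4$ndcg, m4$mrr), c(0, 0, 0))
  expect_error(ranking_metrics(list(c("a", "b")), "p"), "positive")
})

test_that("MRR <= NDCG <= HIT pointwise for single-relevant-item lists", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    ids <- sprintf("c%02d", 1:n)
    lst <- list(sample(ids))
    K <- sample(1:n, 1)
    m <- ranking_metrics(lst, sample(ids, 1), K = K)
    expect_lte(m$mrr, m$ndcg + 1e-12)
    expect_lte(m$ndcg, m$hit + 1e-12)
  }
})

test_that("random scorers calibrate to the K/(N+1) hit rate", {
  set.seed(62)
  N <- 20L; K <- 4L; n_anchor <- 2000L
  hits <- vapply(seq_len(n_anchor), function(i) {
    ranked <- sample(c("pos", sprintf("n%02d", 1:N)))
    as.numeric(match("pos", ranked) <= K)
  }, numeric(1))
  p <- K / (N + 1)
  mc_err <- 3 * sqrt(p * (1 - p) / n_anchor)
  expect_lt(abs(mean(hits) - p), mc_err)
})

test_that("classification metrics match hand-computed values", {
  perfect <- classification_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[c("acc", "auc", "f1", "precision", "recall",
                                "aupr")]),
               c(acc = 1, auc = 1, f1 = 1, precision = 1, recall = 1,
                 aupr = 1))
  # all scores at the threshold: strict "exceeds" rule gives zero recall,
  # midrank ties give AUC 0.5
  tied <- classification_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$recall, 0)
  expect_equal(tied$auc, 0.5)
  # 4-point toy: AUC by brute-force pairwise concordance
  toy <- classification_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(toy$auc, 0.75)
  # AUPR equals the manual step-curve area for the toy
  # ranked: 0.9(+), 0.8(-), 0.3(+), 0.1(-): prec 1, 1/2, 2/3, 1/2 at rec .5,.5,1,1
  expect_equal(toy$aupr, 1 * 0.5 + (2 / 3) * 0.5)
  single <- classification_metrics(c(0.2, 0.9), c(1, 1))
  expect_true(is.na(single$auc) && is.na(single$aupr))
  expect_equal(single$recall, sum(c(0.2, 0.9) > 0.5) / 2)
})

test_that("candidate ranking sorts by risk with lexicographic tie-break", {
  sw <- small_world()
  data <- interaction_data(sw$world$interactions, sw$world$drug_table$drug_id)
  m <- small_model()
  anchor <- data$positives$drugA[1]
  cl <- make_candidates(data, anchor, data$positives$drugB[1], N = 10,
                        seed = 3)
  ranked <- rank_candidates(m, sw$features, cl)
  expect_setequal(ranked, cl$candidates)
  # compositional oracle: same order as sorting predict_risk output
  pr <- predict_risk(m, sw$features,
                     data.frame(drugA = anchor, drugB = cl$candidates))
  expect_identical(ranked,
                   cl$candidates[order(-pr$risk, cl$candidates,
                                       method = "radix")])
  # constant scores: ascending id order, reproducibly
  m0 <- m
  m0$params[["risk.W"]][] <- 0
  m0$params[["risk.b"]][] <- 0
  r0 <- rank_candidates(m0, sw$features, cl)
  expect_identical(r0, sort(cl$candidates, method = "radix"))
  expect_identical(r0, rank_candidates(m0, sw$features, cl))
  expect_error(rank_candidates(m, sw$features,
                               list(anchor = anchor, candidates = character(0))),
               "empty")
})

test_that("training reduces ranking loss and is seed-deterministic", {
  sw <- small_world()
  data <- interaction_data(sw$world$interactions, sw$world$drug_table$drug_id)
  cfg <- mmddi_config(lr = 1e-3, epochs = 5L, batch_size = 32L,
                      patience = 10L, use_contrastive = FALSE, w_re = 0,
                      w_ind = 0)
  fit1 <- train_mmddi(data, sw$features, cfg, seed = 5)
  expect_lt(utils::tail(fit1$history$bpr, 1), fit1$history$bpr[1])
  fit2 <- train_mmddi(data, sw$features, cfg, seed = 5)
  expect_equal(utils::tail(fit1$history$bpr, 1),
               utils::tail(fit2$history$bpr, 1), tolerance = 1e-6)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("disabling decoupling is the K = 1 pipeline", {
  cfg <- mmddi_config(use_decoupling = FALSE)
  expect_equal(cfg$k_aspects, 1L)
  sw <- small_world()
  m <- small_model(cfg)
  pr <- predict_risk(m, sw$features, utils::head(sw$world$interactions, 3))
  expect_equal(pr$aspect_w1, rep(1, 3))
})

test_that("run_experiment produces a complete, reproducible report", {
  sw <- small_world()
  data <- interaction_data(sw$world$interactions, sw$world$drug_table$drug_id)
  cfg <- mmddi_config(lr = 1e-3, epochs = 2L, batch_size = 32L,
                      neg_candidates = 15L, n_folds = 2L)
  rep1 <- run_experiment(sw$world$drug_table, data, "S1", cfg, seed = 8,
                         max_folds = 1L, max_anchors = 25L,
                         features = sw$features)
  expect_s3_class(rep1, "mmddi_report")
  f <- rep1$folds[[1]]
  for (nm in c("hit", "ndcg", "mrr", "acc", "auc", "f1", "precision",
               "recall", "aupr")) {
    expect_true(is.numeric(f[[nm]]))
  }
  rep2 <- run_experiment(sw$world$drug_table, data, "S1", cfg, seed = 8,
                         max_folds = 1L, max_anchors = 25L,
                         features = sw$features)
  expect_equal(rep1$folds, rep2$folds)
  expect_equal(rep1$means, rep2$means)

  path <- withr::local_tempfile(fileext = ".json")
  rep3 <- run_experiment(sw$world$drug_table, data, "S2", cfg, seed = 9,
                         max_folds = 1L, max_anchors = 20L,
                         features = sw$features, out_file = path)
  expect_true(file.exists(path))
  body <- jsonlite::read_json(path)
  expect_equal(body$mode, "S2")
  expect_length(body$folds, 1L)
})
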