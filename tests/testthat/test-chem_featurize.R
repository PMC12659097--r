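test_that("frequent-substructure mining matches brute-force enumeration", {
  v <- mine_frequent_substructures(c("CCO", "CCN", "CCC"),
                                   min_support = 3, min_len = 2, max_len = 2)
  expect_equal(v$substructures, "CC")
  expect_equal(v$support, 3L)

  # min_support = 1, length-1 tokens: the distinct character set of the corpus
  corpus <- c("CCO", "NOP", "S")
  v1 <- mine_frequent_substructures(corpus, min_support = 1,
                                    min_len = 1, max_len = 1)
  expect_setequal(v1$substructures, unique(strsplit(paste(corpus, collapse = ""),
                                                    "")[[1]]))

  # brute-force document-frequency oracle on a random corpus
  set.seed(3)
  corpus <- replicate(8, paste(sample(c("C", "N", "O"), 6, TRUE), collapse = ""))
  v2 <- mine_frequent_substructures(corpus, min_support = 3,
                                    min_len = 2, max_len = 3)
  oracle_df <- function(tok) sum(vapply(corpus, grepl, logical(1),
                                        pattern = tok, fixed = TRUE))
  for (i in seq_along(v2$substructures)) {
    expect_equal(v2$support[i], oracle_df(v2$substructures[i]))
    expect_gte(v2$support[i], 3L)
  }
  # nothing frequent was missed
  all_subs <- unique(unlist(lapply(corpus, function(s) {
    unlist(lapply(2:3, function(l) {
      starts <- seq_len(nchar(s) - l + 1)
      substring(s, starts, starts + l - 1)
    }))
  })))
  missed <- setdiff(all_subs[vapply(all_subs, oracle_df, numeric(1)) >= 3],
                    v2$substructures)
  expect_length(missed, 0)
})

test_that("mining is deterministic and validates inputs", {
  corpus <- c("CCON", "NOCC", "CCNO")
  a <- mine_frequent_substructures(corpus, min_support = 2)
  b <- mine_frequent_substructures(corpus, min_support = 2)
  expect_identical(a$substructures, b$substructures)
  expect_identical(a$support, b$support)
  # ordering: descending support, ties lexicographic
  expect_true(all(diff(a$support) <= 0))
  ties <- split(a$substructures, a$support)
  for (grp in ties) expect_identical(grp, sort(grp, method = "radix"))

  expect_error(mine_frequent_substructures(character(0)), "empty")
  expect_error(mine_frequent_substructures(corpus, min_support = 0), "min_support")
  expect_error(mine_frequent_substructures(corpus, min_len = 3, max_len = 2),
               "min_len")
})

test_that("vocabulary TSV round-trips in order", {
  v <- mine_frequent_substructures(c("CCO", "CCN", "OCC"), min_support = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_identical(v2$substructures, v$substructures)
  expect_identical(v2$support, v$support)
  expect_identical(v2$d, v$d)
})

test_that("multi-hot encoding is the substring-membership indicator", {
  v <- structure(list(substructures = c("CC", "CO", "NN"), d = 3L,
                      support = c(1L, 1L, 1L)), class = "substructure_vocab")
  expect_equal(encode_multihot("CCO", v), c(1L, 1L, 0L))
  expect_equal(encode_multihot("", v), c(0L, 0L, 0L))
  # identity containment: a drug against its own full-SMILES token
  v_self <- structure(list(substructures = "CCO", d = 1L, support = 1L),
                      class = "substructure_vocab")
  expect_equal(encode_multihot("CCO", v_self), 1L)
  # count of ones equals substring oracle on random strings
  set.seed(5)
  v_rand <- mine_frequent_substructures(
    replicate(6, paste(sample(c("C", "N", "O"), 8, TRUE), collapse = "")),
    min_support = 2)
  s <- "CONCON"
  enc <- encode_multihot(s, v_rand)
  expect_equal(sum(enc), sum(vapply(v_rand$substructures, grepl, logical(1),
                                    x = s, fixed = TRUE)))
})

test_that("tanimoto has set-overlap semantics and its invariants", {
  expect_equal(tanimoto(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(tanimoto(c("a", "b"), c("c", "d")), 0)
  expect_equal(tanimoto(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(tanimoto(character(0), character(0)), 0)
  set.seed(8)
  for (i in 1:25) {
    x <- sample(letters[1:8], sample(0:6, 1))
    y <- sample(letters[1:8], sample(0:6, 1))
    s <- tanimoto(x, y)
    expect_identical(s, tanimoto(y, x))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, setequal(x, y) && length(x) > 0)
  }
})

test_that("similarity profiles equal brute-force pairwise tanimoto", {
  tab <- tiny_drug_table()
  prof <- build_similarity_profiles(tab, min_support = 2, min_len = 2,
                                    max_len = 3)
  expect_s3_class(prof, "similarity_profiles")
  attrs <- list(
    target = lapply(tab$targets, function(x) setdiff(strsplit(x, ";")[[1]], "")),
    enzyme = lapply(tab$enzymes, function(x) setdiff(strsplit(x, ";")[[1]], "")),
    pathway = lapply(tab$pathways, function(x) setdiff(strsplit(x, ";")[[1]], ""))
  )
  for (cat in names(attrs)) {
    m <- prof$matrices[[cat]]
    for (i in 1:6) for (j in 1:6) {
      expect_equal(m[i, j], tanimoto(attrs[[cat]][[i]], attrs[[cat]][[j]]))
    }
    expect_equal(m, t(m))
  }
  # unit diagonal for drugs with non-empty attribute sets
  expect_equal(diag(prof$matrices$enzyme), rep(1, 6), ignore_attr = TRUE)
  expect_equal(prof$matrices$target["d6", "d6"], 0)  # empty target set
  expect_error(build_similarity_profiles(tab, categories = "nope"), "unknown")
})

test_that("degenerate similarity patterns come out as stated", {
  twins <- data.frame(drug_id = c("a", "b"), smiles = c("CCO", "CCO"),
                      targets = c("t1", "t1"), enzymes = c("e1", "e1"),
                      pathways = c("p", "p"), stringsAsFactors = FALSE)
  p <- build_similarity_profiles(twins, categories = "target")
  expect_equal(p$matrices$target, matrix(1, 2, 2), ignore_attr = TRUE)

  disj <- data.frame(drug_id = c("a", "b", "c"), smiles = c("CC", "NN", "OO"),
                     targets = c("t1", "t2", "t3"),
                     enzymes = c("e1", "e2", "e3"),
                     pathways = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  p2 <- build_similarity_profiles(disj, categories = c("target", "enzyme"))
  expect_equal(p2$matrices$target, diag(3), ignore_attr = TRUE)
  expect_equal(p2$matrices$enzyme, diag(3), ignore_attr = TRUE)
})

test_that("pair features concatenate profile rows in fixed order", {
  tab <- tiny_drug_table()
  prof <- build_similarity_profiles(tab, categories = c("target", "enzyme"))
  n <- nrow(tab)
  f12 <- build_pair_feature("d1", "d2", prof)
  expect_length(f12, 2 * 2 * n)
  manual <- c(prof$matrices$target["d1", ], prof$matrices$enzyme["d1", ],
              prof$matrices$target["d2", ], prof$matrices$enzyme["d2", ])
  expect_equal(f12, manual, ignore_attr = TRUE)
  # swap permutes the halves
  f21 <- build_pair_feature("d2", "d1", prof)
  half <- length(f12) / 2
  expect_equal(f21, c(f12[(half + 1):(2 * half)], f12[1:half]),
               ignore_attr = TRUE)
  # self pair: identical halves
  f11 <- build_pair_feature("d1", "d1", prof)
  expect_equal(f11[1:half], f11[(half + 1):(2 * half)])
  expect_error(build_pair_feature("d1", "zz", prof), "unknown")
})

test_that("drug table loader applies documented filters", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,smiles,targets,enzymes,pathways",
               "a,CCO,t1,e1,p1", "b,,t2,e2,p2", "c,C,t3,e3,p3"), path)
  expect_warning(tab <- read_drug_table(path), "without SMILES")
  expect_equal(tab$drug_id, c("a", "c"))
  expect_warning(
    expect_warning(tab2 <- read_drug_table(path, drop_single_atom = TRUE),
                   "single-atom"),
    "without SMILES")
  expect_equal(tab2$drug_id, "a")
})
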