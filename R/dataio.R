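## Interaction data, training triples, evaluation candidates, S1/S2/S3 splits.

## Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

## Canonicalize an unordered pair as (min, max) by string order.
.canon_pairs <- function(a, b) {
  swap <- a > b
  data.frame(drugA = ifelse(swap, b, a), drugB = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

#' Construct an interaction dataset from a pair table
#'
#' Positive pairs are stored under the unordered convention (canonical
#' alphabetical orientation); orientation is applied downstream only.
#' Duplicates (including reversed duplicates) are merged; self-pairs are
#' dropped with a warning.
#'
#' @param pairs `data.frame` with columns `drugA`, `drugB`.
#' @param drug_ids Character vector: the drug universe S.
#' @return Object of class `interaction_data`: `drugs`, `positives`
#'   (canonical pair `data.frame`), `m` (number of positives), `n_pairs`
#'   (n(n-1)/2) and `pos_sets` (named list: drug -> interacting partners).
#' @export
interaction_data <- function(pairs, drug_ids) {
  stopifnot(is.data.frame(pairs), all(c("drugA", "drugB") %in% names(pairs)))
  drug_ids <- as.character(drug_ids)
  if (anyDuplicated(drug_ids)) stop("interaction_data: duplicated drug ids")
  a <- as.character(pairs$drugA); b <- as.character(pairs$drugB)
  bad <- setdiff(unique(c(a, b)), drug_ids)
  if (length(bad)) {
    stop("interaction_data: interaction ids missing from drug table: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropping %d self-interaction pair(s)", sum(self)))
    a <- a[!self]; b <- b[!self]
  }
  canon <- .canon_pairs(a, b)
  canon <- canon[!duplicated(paste(canon$drugA, canon$drugB, sep = "\r")), ,
                 drop = FALSE]
  rownames(canon) <- NULL
  pos_sets <- lapply(stats::setNames(nm = drug_ids), function(id) character(0))
  for (i in seq_len(nrow(canon))) {
    pos_sets[[canon$drugA[i]]] <- c(pos_sets[[canon$drugA[i]]], canon$drugB[i])
    pos_sets[[canon$drugB[i]]] <- c(pos_sets[[canon$drugB[i]]], canon$drugA[i])
  }
  n <- length(drug_ids)
  structure(
    list(drugs = drug_ids, positives = canon, m = nrow(canon),
         n_pairs = n * (n - 1) / 2, pos_sets = pos_sets),
    class = "interaction_data"
  )
}

#' Load a positive interaction list from CSV
#'
#' @param path CSV with header `drugA,drugB`.
#' @param drug_table Drug table ([read_drug_table()]); defines the universe.
#' @return An `interaction_data` object.
#' @export
load_interactions <- function(path, drug_table) {
  df <- utils::read.csv(path, colClasses = "character")
  interaction_data(df, drug_table$drug_id)
}

#' @export
print.interaction_data <- function(x, ...) {
  cat("interaction data: n =", length(x$drugs), "drugs, m =", x$m,
      "positive pairs, sparsity =", round(interaction_sparsity(x), 4), "\n")
  invisible(x)
}

#' Sparsity of the interaction matrix
#'
#' `1 - m / (n(n-1)/2)`: the fraction of unordered drug pairs with no
#' recorded interaction.
#' @param data An `interaction_data`.
#' @export
interaction_sparsity <- function(data) {
  1 - data$m / data$n_pairs
}

## Negatives available for an anchor: universe minus itself minus S+_anchor.
.neg_pool <- function(data, anchor, extra_exclude = character(0)) {
  setdiff(data$drugs, c(anchor, data$pos_sets[[anchor]], extra_exclude))
}

#' Sample BPR training triples
#'
#' For every positive pair (A, B+), taking the canonical first drug as anchor,
#' draws `per_positive` negatives B- uniformly without replacement from the
#' anchor's non-interacting drugs (sampling falls back to replacement only
#' when the pool is smaller than `per_positive`).
#'
#' @param data An `interaction_data`; typically the training portion of a
#'   split.
#' @param per_positive Number of triples per positive pair.
#' @param seed Integer seed; the sampling is reproducible given the seed.
#' @param full_data Optional `interaction_data` over the same universe whose
#'   positive pairs are additionally excluded from the negative pools
#'   (useful for leakage-free diagnostics when `data` is a training subset).
#' @return `data.frame` with columns `anchor`, `pos`, `neg`.
#' @export
sample_triples <- function(data, per_positive = 1L, seed = NULL,
                           full_data = NULL) {
  stopifnot(inherits(data, "interaction_data"), per_positive >= 1L)
  excl <- if (is.null(full_data)) data else full_data
  .with_seed(seed, {
    res <- vector("list", nrow(data$positives))
    for (i in seq_len(nrow(data$positives))) {
      anchor <- data$positives$drugA[i]
      pos <- data$positives$drugB[i]
      pool <- .neg_pool(excl, anchor)
      if (length(pool) == 0L) {
        stop("sample_triples: anchor '", anchor, "' has no available negatives")
      }
      neg <- if (length(pool) == 1L) rep(pool, per_positive) else
        sample(pool, min(per_positive, length(pool)), replace = FALSE)
      if (length(neg) < per_positive) {
        neg <- c(neg, sample(pool, per_positive - length(neg), replace = TRUE))
      }
      res[[i]] <- data.frame(anchor = anchor, pos = pos, neg = neg,
                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Build a leave-one-out candidate list for one anchor
#'
#' One held-out positive plus `N` negatives sampled uniformly without
#' replacement from the anchor's non-interacting drugs (excluding the anchor
#' and all of the anchor's positives in `data`), in randomized order.
#'
#' @param data Full `interaction_data` (so no positive can leak in as a
#'   negative).
#' @param anchor Anchor drug id.
#' @param held_out_positive The positive candidate.
#' @param N Number of negatives; reduced with a warning when the anchor has
#'   fewer available negatives.
#' @param seed Integer seed.
#' @return List with `anchor`, `positive`, `candidates` (shuffled ids).
#' @export
make_candidates <- function(data, anchor, held_out_positive, N = 100L,
                            seed = NULL) {
  stopifnot(inherits(data, "interaction_data"), N >= 0L)
  pool <- .neg_pool(data, anchor)
  if (length(pool) < N) {
    warning(sprintf("anchor '%s': only %d negatives available (requested %d)",
                    anchor, length(pool), N))
    N <- length(pool)
  }
  .with_seed(seed, {
    negs <- if (N == 0L) character(0) else sample(pool, N)
    cands <- sample(c(held_out_positive, negs))
    list(anchor = anchor, positive = held_out_positive, candidates = cands)
  })
}

#' Split interactions for transductive (S1) or cold-start (S2/S3) evaluation
#'
#' S1 partitions the positive pairs into `n_folds` cross-validation folds
#' (every drug in a test pair has training interactions with high
#' probability). S2/S3 partition the *drugs* into known and novel sets at
#' ratio `(1 - test_fraction) : test_fraction` and repeat this `n_folds`
#' times: training pairs contain no novel drug; S2 test pairs contain exactly
#' one novel drug; S3 test pairs contain two.
#'
#' @param data An `interaction_data`.
#' @param mode One of `"S1"`, `"S2"`, `"S3"`.
#' @param test_fraction Held-out fraction (pairs for S1 via `n_folds`; drugs
#'   for S2/S3). Default 0.2 (4:1).
#' @param n_folds Folds (S1) or repetitions (S2/S3).
#' @param seed Integer seed.
#' @return List of split specs, each with `mode`, `fold`, `seed`, `train`,
#'   `test` (pair `data.frame`s) and `novel_drugs`.
#' @export
split_dataset <- function(data, mode = c("S1", "S2", "S3"),
                          test_fraction = 0.2, n_folds = 5L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "interaction_data"))
  pos <- data$positives
  .with_seed(seed, {
    if (mode == "S1") {
      idx <- sample.int(nrow(pos))
      fold_of <- rep(seq_len(n_folds), length.out = nrow(pos))[order(idx)]
      lapply(seq_len(n_folds), function(f) {
        list(mode = mode, fold = f, seed = seed,
             train = pos[fold_of != f, , drop = FALSE],
             test = pos[fold_of == f, , drop = FALSE],
             novel_drugs = character(0))
      })
    } else {
      lapply(seq_len(n_folds), function(f) {
        novel <- sample(data$drugs, max(1L, round(test_fraction * length(data$drugs))))
        a_nov <- pos$drugA %in% novel
        b_nov <- pos$drugB %in% novel
        n_nov <- a_nov + b_nov
        test <- pos[n_nov == (if (mode == "S2") 1L else 2L), , drop = FALSE]
        if (mode == "S3" && nrow(test) == 0L) {
          stop("split_dataset: S3 split has no novel-novel test pairs; ",
               "increase test_fraction or dataset density")
        }
        list(mode = mode, fold = f, seed = seed,
             train = pos[n_nov == 0L, , drop = FALSE],
             test = test,
             novel_drugs = novel)
      })
    }
  })
}

#' Assert that a split leaks no information
#'
#' Checks that test positives never appear among training positives and, for
#' S2/S3, that the novel-drug membership invariant holds exactly. Called
#' automatically by [run_experiment()]; errors on violation.
#'
#' @param split One element of the list returned by [split_dataset()].
#' @export
check_split_integrity <- function(split) {
  key <- function(df) paste(df$drugA, df$drugB, sep = "\r")
  if (length(intersect(key(split$train), key(split$test)))) {
    stop("split integrity: train/test positive overlap")
  }
  if (split$mode %in% c("S2", "S3")) {
    nov <- split$novel_drugs
    if (any(split$train$drugA %in% nov) || any(split$train$drugB %in% nov)) {
      stop("split integrity: novel drug appears in training pairs")
    }
    cnt <- (split$test$drugA %in% nov) + (split$test$drugB %in% nov)
    want <- if (split$mode == "S2") 1L else 2L
    if (nrow(split$test) && any(cnt != want)) {
      stop("split integrity: test pair novel-drug count violates ", split$mode)
    }
  }
  invisible(TRUE)
}

#' Write split manifests as JSON
#'
#' @param splits List returned by [split_dataset()].
#' @param path Output JSON file.
#' @export
write_split_manifest <- function(splits, path) {
  jsonlite::write_json(
    lapply(splits, function(s) list(
      mode = s$mode, fold = s$fold, seed = s$seed,
      train = s$train, test = s$test, novel_drugs = s$novel_drugs
    )),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
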