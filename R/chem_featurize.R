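## Substructure mining, multi-hot encoding and Tanimoto similarity profiles.

ATTRIBUTE_CATEGORIES <- c("substructure", "target", "enzyme", "pathway")

#' Mine frequent contiguous substructures from a SMILES corpus
#'
#' Enumerates every contiguous substring with length in `[min_len, max_len]`
#' and keeps those occurring in at least `min_support` distinct drugs. This is
#' a deterministic sequential-pattern realization of frequent-substructure
#' extraction: support is a document frequency (one count per drug, however
#' often the substring repeats inside a molecule).
#'
#' @param smiles_list Character vector of SMILES strings, one per drug.
#' @param min_support Minimum number of distinct drugs a substring must occur
#'   in. Defaults to 5% of the corpus size (at least 1).
#' @param min_len,max_len Substring length bounds (characters).
#' @return An object of class `substructure_vocab` with elements
#'   `substructures` (tokens ordered by descending support, ties broken
#'   lexicographically), `d` (vocabulary size) and `support` (named integer
#'   vector of document frequencies).
#' @export
mine_frequent_substructures <- function(smiles_list,
                                        min_support = NULL,
                                        min_len = 2L,
                                        max_len = 8L) {
  if (length(smiles_list) == 0L) {
    stop("mine_frequent_substructures: empty SMILES corpus")
  }
  if (!is.character(smiles_list) || anyNA(smiles_list)) {
    stop("mine_frequent_substructures: smiles_list must be character without NA")
  }
  if (is.null(min_support)) {
    min_support <- max(1L, ceiling(0.05 * length(smiles_list)))
  }
  if (min_support < 1L) stop("mine_frequent_substructures: min_support must be >= 1")
  if (min_len < 1L || min_len > max_len) {
    stop("mine_frequent_substructures: require 1 <= min_len <= max_len")
  }

  per_drug <- lapply(smiles_list, function(s) {
    nc <- nchar(s)
    if (nc < min_len) return(character(0))
    subs <- character(0)
    for (len in min_len:min(max_len, nc)) {
      starts <- seq_len(nc - len + 1L)
      subs <- c(subs, substring(s, starts, starts + len - 1L))
    }
    unique(subs)
  })
  tab <- table(unlist(per_drug))
  keep <- tab[tab >= min_support]
  toks <- names(keep)
  supp <- as.integer(keep)
  ## descending support, then lexicographic (byte order for determinism)
  ord <- order(-supp, toks, method = "radix")
  structure(
    list(substructures = toks[ord], d = length(toks), support = supp[ord]),
    class = "substructure_vocab"
  )
}

#' @export
print.substructure_vocab <- function(x, ...) {
  cat("substructure vocabulary: d =", x$d, "tokens\n")
  n <- min(8L, x$d)
  if (n > 0L) {
    cat("  top:", paste0(x$substructures[seq_len(n)], " (", x$support[seq_len(n)], ")",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a substructure vocabulary as ordered two-column TSV
#'
#' @param vocab A `substructure_vocab`.
#' @param path File path (`token<TAB>support`, no header, vocabulary order).
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "substructure_vocab"))
  utils::write.table(
    data.frame(token = vocab$substructures, support = vocab$support),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                          colClasses = c("character", "integer"))
  structure(
    list(substructures = df[[1]], d = nrow(df), support = df[[2]]),
    class = "substructure_vocab"
  )
}

#' Encode a drug's SMILES as a multi-hot substructure vector
#'
#' Position `h` of the result is 1 iff vocabulary token `h` occurs in the
#' SMILES as a contiguous substring.
#'
#' @param smiles A single SMILES string.
#' @param vocab A `substructure_vocab`.
#' @return Integer vector of length `vocab$d` with entries in \{0, 1\}.
#' @export
encode_multihot <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "substructure_vocab"))
  if (vocab$d == 0L) stop("encode_multihot: empty vocabulary")
  if (length(smiles) != 1L || is.na(smiles)) {
    stop("encode_multihot: smiles must be a single string")
  }
  as.integer(vapply(vocab$substructures,
                    function(tok) grepl(tok, smiles, fixed = TRUE),
                    logical(1), USE.NAMES = FALSE))
}

#' Tanimoto (Jaccard) similarity between two attribute sets
#'
#' `|intersection| / |union|`; two empty sets score 0 (a drug with no recorded
#' attributes shares no evidence).
#'
#' @param set_i,set_j Vectors treated as sets (duplicates ignored).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(set_i, set_j) {
  a <- unique(set_i); b <- unique(set_j)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

## Parse ";"-delimited attribute cells into character-vector sets.
.parse_attr_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character(0))
  unique(strsplit(cell, ";", fixed = TRUE)[[1]])
}

#' Read a drug table (CSV/TSV)
#'
#' Expected header: `drug_id,smiles,targets,enzymes,pathways`; attribute cells
#' are `;`-delimited lists. Missing attribute columns are tolerated (the
#' corresponding category is simply unavailable).
#'
#' @param path CSV (default) or TSV file; `.tsv`/`.tab` extensions use tabs.
#' @param drop_missing_smiles Drop rows with empty/NA SMILES (with a warning).
#' @param drop_single_atom Drop single-character SMILES (single-atom drugs).
#' @return `data.frame` with character columns.
#' @export
read_drug_table <- function(path, drop_missing_smiles = TRUE,
                            drop_single_atom = FALSE) {
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "")
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    stop("read_drug_table: need at least columns drug_id and smiles")
  }
  if (anyDuplicated(df$drug_id)) stop("read_drug_table: duplicated drug_id")
  if (drop_missing_smiles) {
    bad <- is.na(df$smiles) | !nzchar(df$smiles)
    if (any(bad)) {
      warning(sprintf("dropping %d drugs without SMILES", sum(bad)))
      df <- df[!bad, , drop = FALSE]
    }
  }
  if (drop_single_atom) {
    bad <- nchar(df$smiles) <= 1L
    if (any(bad)) {
      warning(sprintf("dropping %d single-atom drugs", sum(bad)))
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

## Collect per-drug attribute sets for one category from the drug table.
.category_sets <- function(drug_table, category, vocab = NULL,
                           multihot = NULL) {
  n <- nrow(drug_table)
  if (category == "substructure") {
    stopifnot(!is.null(vocab), !is.null(multihot))
    lapply(seq_len(n), function(i) vocab$substructures[multihot[i, ] == 1L])
  } else {
    col <- switch(category, target = "targets", enzyme = "enzymes",
                  pathway = "pathways",
                  stop("unknown attribute category: ", category))
    if (!col %in% names(drug_table)) {
      stop("drug table has no column '", col, "' for category '", category, "'")
    }
    lapply(drug_table[[col]], .parse_attr_cell)
  }
}

## Dense pairwise Tanimoto over a list of sets, via a binary incidence matrix.
.tanimoto_matrix <- function(sets) {
  n <- length(sets)
  toks <- unique(unlist(sets, use.names = FALSE))
  if (length(toks) == 0L) return(matrix(0, n, n))
  M <- matrix(0L, n, length(toks))
  idx <- lapply(sets, function(s) match(s, toks))
  for (i in seq_len(n)) if (length(idx[[i]])) M[i, idx[[i]]] <- 1L
  inter <- M %*% t(M)
  sizes <- rowSums(M)
  un <- outer(sizes, sizes, `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  out
}

#' Build per-category Tanimoto similarity profiles for a drug universe
#'
#' For every drug and every requested attribute category, computes the vector
#' of Tanimoto similarities against every drug in the universe (itself
#' included). Row `i` of a category matrix is drug `i`'s similarity profile for
#' that category.
#'
#' @param drug_table Drug table as returned by [read_drug_table()].
#' @param categories Subset of `c("substructure","target","enzyme","pathway")`,
#'   in profile order.
#' @param vocab Optional pre-mined `substructure_vocab`; mined from the table's
#'   SMILES with defaults when absent and "substructure" is requested.
#' @param ... Passed to [mine_frequent_substructures()] when mining.
#' @return Object of class `similarity_profiles`: `ids`, `categories`,
#'   `matrices` (named list of symmetric n x n matrices with entries in
#'   \[0, 1\]), `vocab`, `multihot` (n x d integer matrix).
#' @export
build_similarity_profiles <- function(drug_table,
                                      categories = c("substructure", "target",
                                                     "enzyme", "pathway"),
                                      vocab = NULL, ...) {
  if (nrow(drug_table) < 2L) stop("build_similarity_profiles: need >= 2 drugs")
  unknown <- setdiff(categories, ATTRIBUTE_CATEGORIES)
  if (length(unknown)) {
    stop("build_similarity_profiles: unknown categories: ",
         paste(unknown, collapse = ", "))
  }
  if (length(categories) == 0L) stop("build_similarity_profiles: no categories")

  multihot <- NULL
  if ("substructure" %in% categories || !is.null(vocab)) {
    if (is.null(vocab)) vocab <- mine_frequent_substructures(drug_table$smiles, ...)
    multihot <- t(vapply(drug_table$smiles,
                         function(s) encode_multihot(s, vocab),
                         integer(vocab$d), USE.NAMES = FALSE))
  }
  mats <- lapply(categories, function(cat) {
    sets <- .category_sets(drug_table, cat, vocab, multihot)
    m <- .tanimoto_matrix(sets)
    dimnames(m) <- list(drug_table$drug_id, drug_table$drug_id)
    m
  })
  names(mats) <- categories
  structure(
    list(ids = drug_table$drug_id, categories = categories, matrices = mats,
         vocab = vocab, multihot = multihot),
    class = "similarity_profiles"
  )
}

#' @export
print.similarity_profiles <- function(x, ...) {
  cat("similarity profiles:", length(x$ids), "drugs, categories:",
      paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Featurize a drug universe for model training
#'
#' Convenience bundle: mines the substructure vocabulary (unless given),
#' builds the multi-hot matrix and the per-category similarity profiles.
#'
#' @inheritParams build_similarity_profiles
#' @return Object of class `mmddi_features`: `ids`, `categories`, `profiles`
#'   (a `similarity_profiles`), `multihot` (n x d), `vocab`, `n`, `d`.
#' @export
featurize_drugs <- function(drug_table,
                            categories = c("substructure", "target",
                                           "enzyme", "pathway"),
                            vocab = NULL, ...) {
  profiles <- build_similarity_profiles(drug_table, categories, vocab, ...)
  multihot <- profiles$multihot
  if (is.null(multihot)) {
    if (is.null(vocab)) vocab <- mine_frequent_substructures(drug_table$smiles, ...)
    multihot <- t(vapply(drug_table$smiles,
                         function(s) encode_multihot(s, vocab),
                         integer(vocab$d), USE.NAMES = FALSE))
    profiles$vocab <- vocab
  }
  rownames(multihot) <- drug_table$drug_id
  structure(
    list(ids = profiles$ids, categories = categories, profiles = profiles,
         multihot = multihot, vocab = profiles$vocab,
         n = length(profiles$ids), d = ncol(multihot)),
    class = "mmddi_features"
  )
}

#' @export
print.mmddi_features <- function(x, ...) {
  cat("mmddi features:", x$n, "drugs, d =", x$d, "substructures, categories:",
      paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Concatenated similarity feature for an ordered drug pair
#'
#' Concatenates drug A's per-category similarity vectors (in profile category
#' order), followed by drug B's. Swapping the pair swaps the two halves; pairs
#' are ordered with the anchor (candidate perpetrator) first.
#'
#' @param drugA,drugB Drug identifiers present in `profiles`.
#' @param profiles A `similarity_profiles` object.
#' @return Numeric vector of length `2 * length(categories) * n`.
#' @export
build_pair_feature <- function(drugA, drugB, profiles) {
  stopifnot(inherits(profiles, "similarity_profiles"))
  ia <- match(drugA, profiles$ids)
  ib <- match(drugB, profiles$ids)
  if (is.na(ia) || is.na(ib)) {
    stop("build_pair_feature: unknown drug id: ",
         paste(c(drugA, drugB)[c(is.na(ia), is.na(ib))], collapse = ", "))
  }
  c(
    unlist(lapply(profiles$matrices, function(m) m[ia, ]), use.names = FALSE),
    unlist(lapply(profiles$matrices, function(m) m[ib, ]), use.names = FALSE)
  )
}
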