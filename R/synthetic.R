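## Synthetic drug universes with planted interaction mechanisms.
##
## The generator emulates the structure of curated DDI datasets: sparse
## binary substructure vectors driven by per-mechanism signature tokens,
## attribute categories whose token pools correlate with mechanisms (enzymes
## with metabolism, transporter-like targets with absorption), a
## short-head/long-tail interaction degree distribution, and a logistic
## interaction rule over mechanism compatibility.

.MECH_NAMES <- c("metabolism", "absorption")

#' Configuration of a synthetic drug universe
#'
#' @param n_drugs Number of drugs (>= 4).
#' @param d Substructure vocabulary size.
#' @param K_true Number of planted mechanisms (first two are named
#'   "metabolism" and "absorption").
#' @param signature_size Substructure signature tokens per mechanism.
#' @param signature_rate Inclusion probability of a signature token scaled by
#'   the drug's mechanism membership.
#' @param background_rate Inclusion probability of non-signature tokens.
#' @param attr_noise Noise rate on attribute-category token sampling.
#' @param strengths Per-mechanism interaction strength (length `K_true` or
#'   scalar).
#' @param sparsity Target fraction of non-interacting unordered pairs, in
#'   (0, 1). Default 0.8825 mirrors a curated reference dataset.
#' @param base Optional fixed intercept of the logistic interaction rule; when
#'   `NULL` (default) it is solved so the expected edge rate matches
#'   `1 - sparsity`.
#' @param degree_skew Coefficient on the per-drug activity latent; larger
#'   values give a heavier short-head/long-tail degree distribution.
#' @param tokens_per_pool Attribute tokens per (category, mechanism) pool.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(n_drugs = 300L, d = 200L, K_true = 2L,
                                   signature_size = 12L,
                                   signature_rate = 0.9,
                                   background_rate = 0.04,
                                   attr_noise = 0.1,
                                   strengths = 6,
                                   sparsity = 0.8825,
                                   base = NULL,
                                   degree_skew = 1,
                                   tokens_per_pool = 8L,
                                   seed = 1L) {
  stopifnot(n_drugs >= 4L, K_true >= 1L, d >= K_true * signature_size,
            sparsity > 0, sparsity < 1)
  if (length(strengths) == 1L) strengths <- rep(strengths, K_true)
  stopifnot(length(strengths) == K_true)
  structure(as.list(environment()), class = "synthetic_world_config")
}

.mech_names <- function(K) {
  c(.MECH_NAMES, if (K > 2L) paste0("mech", 3L:K))[seq_len(K)]
}

## Unique 3-letter substructure tokens (uppercase, so token boundaries in a
## concatenated "SMILES" string rarely alias another token).
.make_tokens <- function(d) {
  letters3 <- LETTERS[1:20]
  combos <- expand.grid(a = letters3, b = letters3, c = letters3,
                        stringsAsFactors = FALSE)
  paste0(combos$a, combos$b, combos$c)[seq_len(d)]
}

#' Generate a synthetic drug universe with planted mechanisms
#'
#' Each drug receives continuous mechanism memberships (one dominant
#' mechanism), a substructure set built from its mechanisms' signature
#' tokens plus background noise, and attribute tokens drawn from
#' mechanism-linked pools (enzyme tokens follow the metabolism membership,
#' transporter-like target tokens the absorption membership). An unordered
#' pair interacts with probability
#' `sigmoid(base + sum_k strength_k * u_ik * u_jk + degree_skew * (z_i + z_j))`
#' where `z` is a standard-normal activity latent; `base` is solved so the
#' expected sparsity matches the configured target. The dominant
#' (largest-contribution) mechanism of every positive pair is recorded as
#' ground truth.
#'
#' @param config A [synthetic_world_config()].
#' @return List of class `synthetic_world`: `drug_table` (loader dialect),
#'   `interactions` (`drugA,drugB` data.frame), `mechanisms` (per positive
#'   pair, one-hot dominant-mechanism indicators plus raw contributions),
#'   `vocab` (the planted `substructure_vocab`), `truth` (memberships `u`,
#'   activity `z`, mechanism names) and `config`.
#' @export
generate_world <- function(config = synthetic_world_config()) {
  stopifnot(inherits(config, "synthetic_world_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    n <- cfg$n_drugs; K <- cfg$K_true; d <- cfg$d
    mech <- .mech_names(K)
    ids <- sprintf("D%03d", seq_len(n))
    tokens <- .make_tokens(d)
    sig <- split(seq_len(K * cfg$signature_size),
                 rep(seq_len(K), each = cfg$signature_size))

    ## mechanism memberships: one dominant mechanism per drug
    primary <- sample.int(K, n, replace = TRUE)
    u <- matrix(stats::runif(n * K, 0, 0.3), n, K)
    u[cbind(seq_len(n), primary)] <- stats::runif(n, 0.7, 1)

    ## substructure sets and SMILES-like token strings
    sub_sets <- vector("list", n)
    for (i in seq_len(n)) {
      keep <- logical(d)
      for (k in seq_len(K)) {
        keep[sig[[k]]] <- stats::runif(cfg$signature_size) <
          cfg$signature_rate * u[i, k]
      }
      bg <- setdiff(which(stats::runif(d) < cfg$background_rate),
                    unlist(sig))
      keep[bg] <- TRUE
      if (!any(keep)) keep[sig[[primary[i]]][1L]] <- TRUE
      sub_sets[[i]] <- which(keep)
    }
    smiles <- vapply(sub_sets, function(ix) {
      paste(tokens[sample(ix)], collapse = "")
    }, character(1))

    ## attribute categories with mechanism-linked token pools;
    ## enzymes follow metabolism, targets (transporter-like) absorption,
    ## pathways all mechanisms equally.
    affinity <- function(cat, k) {
      switch(cat,
             enzyme = if (mech[k] == "metabolism") 1 else 0.2,
             target = if (mech[k] == "absorption") 1 else 0.2,
             pathway = 0.8)
    }
    attr_col <- function(cat) {
      pools <- lapply(seq_len(K), function(k)
        sprintf("%s_%s_%d", toupper(substr(cat, 1, 3)), mech[k],
                seq_len(cfg$tokens_per_pool)))
      shared <- sprintf("%s_shared_%d", toupper(substr(cat, 1, 3)),
                        seq_len(cfg$tokens_per_pool))
      vapply(seq_len(n), function(i) {
        toks <- character(0)
        for (k in seq_len(K)) {
          p <- pmin(1, affinity(cat, k) * u[i, k] * 0.8 + cfg$attr_noise * 0.2)
          toks <- c(toks, pools[[k]][stats::runif(cfg$tokens_per_pool) < p])
        }
        toks <- c(toks, shared[stats::runif(cfg$tokens_per_pool) < cfg$attr_noise])
        paste(unique(toks), collapse = ";")
      }, character(1))
    }
    drug_table <- data.frame(
      drug_id = ids, smiles = smiles,
      targets = attr_col("target"),
      enzymes = attr_col("enzyme"),
      pathways = attr_col("pathway"),
      stringsAsFactors = FALSE
    )

    ## logistic interaction rule; solve base for the target sparsity
    z <- stats::rnorm(n)
    pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ia <- pair_idx[, 1L]; ib <- pair_idx[, 2L]
    compat <- matrix(0, nrow(pair_idx), K)
    for (k in seq_len(K)) compat[, k] <- cfg$strengths[k] * u[ia, k] * u[ib, k]
    eta0 <- rowSums(compat) + cfg$degree_skew * (z[ia] + z[ib])
    if (is.null(cfg$base)) {
      target_rate <- 1 - cfg$sparsity
      f <- function(b) mean(stats::plogis(b + eta0)) - target_rate
      if (f(-40) > 0 || f(40) < 0) {
        stop("generate_world: target sparsity ", cfg$sparsity,
             " unattainable; attainable edge rate range [",
             signif(mean(stats::plogis(-40 + eta0)), 3), ", ",
             signif(mean(stats::plogis(40 + eta0)), 3), "]")
      }
      base <- stats::uniroot(f, c(-40, 40), tol = 1e-8)$root
    } else {
      base <- cfg$base
    }
    p_edge <- stats::plogis(base + eta0)
    edge <- stats::runif(length(p_edge)) < p_edge

    interactions <- data.frame(drugA = ids[ia[edge]], drugB = ids[ib[edge]],
                               stringsAsFactors = FALSE)
    contrib <- compat[edge, , drop = FALSE]
    dominant <- max.col(contrib, ties.method = "first")
    mech_ind <- matrix(0L, nrow(contrib), K,
                       dimnames = list(NULL, paste0("mech_", mech)))
    mech_ind[cbind(seq_len(nrow(contrib)), dominant)] <- 1L
    mechanisms <- cbind(interactions, as.data.frame(mech_ind),
                        stats::setNames(as.data.frame(contrib),
                                        paste0("contrib_", mech)))

    vocab <- structure(
      list(substructures = tokens, d = d,
           support = vapply(tokens, function(tk)
             sum(vapply(sub_sets, function(ix) tk %in% tokens[ix],
                        logical(1))), integer(1), USE.NAMES = FALSE)),
      class = "substructure_vocab")

    structure(
      list(drug_table = drug_table, interactions = interactions,
           mechanisms = mechanisms, vocab = vocab,
           truth = list(u = u, activity = z, mech_names = mech,
                        base = base, primary = primary),
           config = cfg),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  n <- nrow(x$drug_table)
  m <- nrow(x$interactions)
  cat("synthetic world:", n, "drugs,", m, "positive pairs (sparsity",
      round(1 - m / (n * (n - 1) / 2), 4), "),", x$config$K_true,
      "mechanisms\n")
  invisible(x)
}

#' Write a synthetic world in the loader CSV dialects
#'
#' Emits `drugs.csv`, `interactions.csv`, `mechanisms.csv` and a JSON echo of
#' the generating configuration for provenance.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$drug_table, file.path(dir, "drugs.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(world$interactions, file.path(dir, "interactions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(world$mechanisms, file.path(dir, "mechanisms.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(world$config),
                       file.path(dir, "world_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

## All permutations of 1..k (k is the small aspect count).
.perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in .perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
    }
  }
  out
}

#' Correlate aspect weights with ground-truth mechanism indicators
#'
#' Pearson correlation matrix between per-pair aspect contribution weights
#' and mechanism indicators, plus the label permutation (aspects are
#' exchangeable) maximizing the mean matched correlation.
#'
#' @param weights Matrix (pairs x K) of aspect weights.
#' @param indicators Matrix (pairs x K_true) of ground-truth indicators.
#' @return List with `correlations` (K x K_true), `matching` (for each of
#'   the first `min(K, K_true)` aspects, the matched mechanism column) and
#'   `matched_cor` (mean correlation under the best matching).
#' @export
mechanism_recovery_cor <- function(weights, indicators) {
  weights <- as.matrix(weights); indicators <- as.matrix(indicators)
  stopifnot(nrow(weights) == nrow(indicators))
  K <- ncol(weights); Kt <- ncol(indicators)
  cors <- matrix(NA_real_, K, Kt,
                 dimnames = list(paste0("aspect", seq_len(K)),
                                 colnames(indicators)))
  for (i in seq_len(K)) for (j in seq_len(Kt)) {
    if (stats::sd(weights[, i]) > 0 && stats::sd(indicators[, j]) > 0) {
      cors[i, j] <- stats::cor(weights[, i], indicators[, j])
    }
  }
  r <- min(K, Kt)
  best <- NULL; best_val <- -Inf
  for (pm in .perms(max(K, Kt))) {
    sel <- pm[seq_len(r)]
    if (K <= Kt) {
      vals <- cors[cbind(seq_len(r), sel)]
    } else {
      vals <- cors[cbind(sel, seq_len(r))]
    }
    v <- mean(vals, na.rm = TRUE)
    if (!is.nan(v) && v > best_val) {
      best_val <- v; best <- sel
    }
  }
  list(correlations = cors, matching = best, matched_cor = best_val)
}

#' Mechanism-recovery report for a trained model on a synthetic world
#'
#' Scores the world's positive pairs with the model, then correlates the
#' per-pair aspect contribution weights with the planted dominant-mechanism
#' indicators ([mechanism_recovery_cor()]).
#'
#' @param model Trained `mmddi_model`.
#' @param features `mmddi_features` built from the world's drug table.
#' @param world A `synthetic_world`.
#' @param max_pairs Cap on scored pairs (sampled under `seed`).
#' @param seed Integer seed for the subsample.
#' @return As [mechanism_recovery_cor()], plus `n_pairs`.
#' @export
mechanism_recovery_report <- function(model, features, world,
                                      max_pairs = 2000L, seed = 1L) {
  mech_cols <- grep("^mech_", names(world$mechanisms), value = TRUE)
  mechs <- world$mechanisms
  if (nrow(mechs) > max_pairs) {
    keep <- .with_seed(seed, sample.int(nrow(mechs), max_pairs))
    mechs <- mechs[keep, , drop = FALSE]
  }
  pr <- predict_risk(model, features,
                     mechs[, c("drugA", "drugB"), drop = FALSE])
  W <- as.matrix(pr[, grep("^aspect_w", names(pr)), drop = FALSE])
  out <- mechanism_recovery_cor(W, as.matrix(mechs[, mech_cols, drop = FALSE]))
  out$n_pairs <- nrow(mechs)
  out
}
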