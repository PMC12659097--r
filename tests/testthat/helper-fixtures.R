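# Small in-code fixtures shared across tests.

# Deterministic 6-drug table with hand-chosen attribute overlaps.
tiny_drug_table <- function() {
  data.frame(
    drug_id = c("d1", "d2", "d3", "d4", "d5", "d6"),
    smiles = c("CCO", "CCN", "CCC", "CNO", "OCCN", "NCCC"),
    targets = c("t1;t2", "t1", "t3", "t2;t3", "t1;t4", ""),
    enzymes = c("e1", "e1;e2", "e2", "e3", "e1", "e2;e3"),
    pathways = c("p1", "p1;p2", "p2", "p1", "p2", "p1;p2"),
    stringsAsFactors = FALSE
  )
}

tiny_interactions <- function() {
  data.frame(drugA = c("d1", "d1", "d2", "d3", "d4"),
             drugB = c("d2", "d3", "d4", "d5", "d6"),
             stringsAsFactors = FALSE)
}

# A small but trainable synthetic world + features; memoised per session.
small_world_env <- new.env()
small_world <- function() {
  if (is.null(small_world_env$world)) {
    small_world_env$world <- generate_world(
      synthetic_world_config(n_drugs = 60, d = 80, signature_size = 10,
                             seed = 42))
    small_world_env$features <- featurize_drugs(
      small_world_env$world$drug_table, vocab = small_world_env$world$vocab)
  }
  list(world = small_world_env$world, features = small_world_env$features)
}

# A tiny initialized (untrained) model over the small world.
small_model <- function(config = mmddi_config(), seed = 7L) {
  sw <- small_world()
  mmddi_model(2L * sw$features$d, sw$features$n,
              2L * length(sw$features$categories), config, seed = seed)
}

expect_prob_vector <- function(w, tol = 1e-6) {
  expect_true(all(w >= -tol))
  expect_equal(rowSums(as.matrix(w)), rep(1, nrow(as.matrix(w))),
               tolerance = 1e-5)
}
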