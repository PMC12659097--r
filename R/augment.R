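## Biologically motivated contrastive views of a binary substructure vector.
##
## flip: turn floor(n * alpha) randomly chosen zeros into ones -- emulates a
## drug pair acquiring new functional groups through interaction chemistry.
## shuffle: permute a random contiguous window of length floor(n * alpha) --
## emulates substructure rearrangement while conserving composition.

#' Flip augmentation: activate a random fraction of zero entries
#'
#' Exactly `floor(n * alpha)` zero positions (or every remaining zero if the
#' vector is denser than that) are set to 1; ones are never cleared, so the
#' output dominates the input elementwise.
#'
#' @param x Binary vector (entries in \{0, 1\}).
#' @param alpha Flip rate in \[0, 1\].
#' @param seed Optional integer seed for reproducible views.
#' @return Binary vector of the same length.
#' @export
aug_flip <- function(x, alpha, seed = NULL) {
  .check_binary(x)
  .check_rate(alpha)
  f <- floor(length(x) * alpha)
  zeros <- which(x == 0)
  if (f == 0L || length(zeros) == 0L) return(x)
  .with_seed(seed, {
    pick <- if (length(zeros) <= f) zeros else sample(zeros, f)
    x[pick] <- 1
    x
  })
}

#' Shuffle augmentation: permute a random contiguous window
#'
#' A start index is drawn uniformly over the valid range and the window of
#' length `floor(n * alpha)` is randomly permuted in place; entries outside
#' the window are untouched and the multiset of entries (hence the number of
#' ones) is conserved.
#'
#' @inheritParams aug_flip
#' @export
aug_shuffle <- function(x, alpha, seed = NULL) {
  .check_binary(x)
  .check_rate(alpha)
  n <- length(x)
  w <- floor(n * alpha)
  if (w <= 1L) return(x)
  .with_seed(seed, {
    k <- sample.int(n - w + 1L, 1L)
    idx <- k:(k + w - 1L)
    x[idx] <- x[sample(idx)]
    x
  })
}

.check_binary <- function(x) {
  if (!is.numeric(x) || any(!(x %in% c(0, 1)))) {
    stop("augmentation input must be a binary 0/1 vector")
  }
}

.check_rate <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("augmentation rate must be a scalar in [0, 1]")
  }
}

#' Generate two contrastive views of a binary vector
#'
#' The default pairing is maximally heterogeneous: one flip view and one
#' shuffle view of the same input. The two views form a positive pair; views
#' of other inputs in a batch act as negatives for InfoNCE.
#'
#' @param x Binary vector.
#' @param ops Character vector of length 2, each `"flip"` or `"shuffle"`.
#' @param rates Numeric length 2: the augmentation rate per view.
#' @param seed Optional integer seed (the two views consume successive draws
#'   from one stream, so a fixed seed reproduces the pair).
#' @return List with elements `view1`, `view2`.
#' @export
make_views <- function(x, ops = c("flip", "shuffle"), rates = c(0.1, 0.1),
                       seed = NULL) {
  stopifnot(length(ops) == 2L, length(rates) == 2L,
            all(ops %in% c("flip", "shuffle")))
  .with_seed(seed, {
    one <- function(op, rate) {
      if (op == "flip") aug_flip(x, rate) else aug_shuffle(x, rate)
    }
    list(view1 = one(ops[1L], rates[1L]), view2 = one(ops[2L], rates[2L]))
  })
}
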