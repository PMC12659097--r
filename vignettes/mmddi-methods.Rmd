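---
title: "Mechanism-disentangled DDI risk assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-disentangled DDI risk assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmddi)
```

## The problem

Co-administering two drugs can change the pharmacokinetics of one of them —
through shared metabolizing enzymes (CYP-mediated interactions), through
transporter competition during absorption, or through other pharmacological
routes. Given a drug universe $S$ with known interactions $I$ and the implicit
complement $F = (S \times S) \setminus I$, the package ranks, for an anchor
drug, candidate co-medications by an interaction risk coefficient in $(0, 1)$,
and attributes each prediction to $K$ disentangled mechanism *aspects* with
per-pair contribution weights.

Two properties distinguish the model from a plain link predictor:

* **Contrastive augmentation.** Two biologically motivated view generators
  perturb the pair's substructure vector — *flip* activates a fraction of
  zero entries (new functional groups appearing through interaction
  chemistry), *shuffle* permutes a contiguous window (substructure
  rearrangement, conserving composition). An InfoNCE loss aligns the two
  views of the same pair against in-batch negatives, which gives sparse,
  long-tail pairs more opportunities to shape the representation.
* **Mechanism disentanglement.** The fused pair representation is split into
  $K$ aspect vectors that a Kullback–Leibler independence regularizer keeps
  distinct; multi-head attention over the aspect set yields both the fused
  risk representation and interpretable per-aspect contribution weights.
  Without the regularizer, a nominal fusion weighting such as $(0.8, 0.2)$
  over aspects that each mix the true mechanisms 60/40 corresponds to
  effective weights $(0.56, 0.44)$ on the true mechanism bases —
  `effective_fusion_weights()` computes exactly this diagnostic.

## Featurization

Drugs enter as SMILES strings plus `;`-delimited attribute lists (targets,
enzymes, pathways). Two encodings are built:

* **Multi-hot substructure vectors.** `mine_frequent_substructures()`
  enumerates contiguous SMILES substrings of length `min_len`–`max_len`
  (defaults 2–8) kept at a document frequency of at least `min_support`
  (default 5% of the corpus), ordered by descending support then
  lexicographically — fully deterministic, no chemistry toolkit required.
  `encode_multihot()` marks which vocabulary tokens a drug contains. A pair is
  encoded as the concatenation of the two drugs' vectors (anchor first), so
  the input is ordered: the anchor is the candidate perpetrator.
* **Tanimoto similarity profiles.** For each attribute category $\omega$,
  drug $i$'s profile is the vector of
  $|S_i^{(\omega)} \cap S_j^{(\omega)}| / |S_i^{(\omega)} \cup S_j^{(\omega)}|$
  against every drug $j$. Two empty sets score 0 — a drug with no recorded
  targets shares no target evidence. Categories that a dataset lacks are
  simply omitted rather than zero-padded, which avoids fabricating similarity
  signal.

## Model

The model has two encoder branches and a disentangling head; every
differentiable piece runs on the package's reverse-mode autodiff tape
(`R/autodiff.R`), whose gradients are tested against central-difference
oracles.

**Drug-pair autoencoder.** The pair multi-hot vector $x$ passes through
$z = F(\mathrm{BN}(\sigma(W_e x)))$ and is reconstructed through
$\hat x = F(\mathrm{BN}(\sigma(W_d z)))$ with ReLU activations, batch
normalization (running statistics at inference) and a dense layer $F$ per
stage; the reconstruction loss is the mean squared error over dimensions. The
latent width defaults to $k = 64$, smaller than the input — the branch is a
compression that keeps the few informative functional substructures and
discards the rest.

**Contrastive projection.** A two-layer head with a final ReLU maps $z$ to
$h$; training aligns $h$ of the flip view with $h$ of the shuffle view of the
same pair (temperature $T = 0.05$, dot-product similarity, in-batch
negatives, max-subtraction stabilization).

**Association encoder.** The concatenated similarity feature is split into
one token per (drug-of-pair × category) block — $2 \times$ the number of
categories, each of length $n$ — and processed by two self-attention
sub-layers *without positional encodings*, each followed by a residual
position-wise feed-forward block, then mean-pooled. The encoder is therefore
permutation-invariant over tokens, which a test asserts to $10^{-5}$.
Internally the shared per-token projections run on row-stacked tokens so each
projection is a single matrix product.

**Disentanglement and risk.** The two branch outputs are fused by a dense
layer with dropout (rate 0.4 in training); $K$ bias-free linear + ReLU aspect
heads split the result. The aspect heads carry no bias by design: a biased
head could satisfy the independence regularizer with a constant,
input-independent aspect, detaching the risk score from the input — an
observed failure mode during development. Multi-head attention over the $K$
aspect tokens produces the fused vector; each aspect's contribution weight is
the attention mass it receives, averaged over heads and queries and
renormalized (with $K$ identical aspects the weights are uniform by symmetry,
a tested invariant). A sigmoid affine head maps the fused vector to the risk
coefficient.

## Objectives

The joint loss is
$L = \alpha L_{re} + \beta L_{InfoNCE} + \gamma L_{ind} + L_{bpr}$,
with the ranking term unweighted.

* $L_{bpr} = -\frac1m \sum \log \sigma(\hat r_{pos} - \hat r_{neg})$ over
  triples $\langle A, B^+, B^- \rangle$; the scores are the sigmoid risk
  values.
* $L_{ind}$ is **minus** the mean clamped symmetric KL divergence between the
  per-sample aspect distributions (clamp 5): raw KL is minimized by equal
  distributions, the opposite of independence, so minimizing the negated
  divergence pushes aspects apart. Distributions are per-sample softmaxes
  over aspect dimensions, taken over **L2-normalized** aspect vectors at a
  fixed logit scale (`ind_scale`, default 1): separation is rewarded in
  direction only, so the regularizer cannot be satisfied by inflating
  magnitudes, the second collapse route observed during development.
  Log-probabilities are computed as $a - \mathrm{logsumexp}(a)$, which stays
  finite where the softmax underflows.
* Loss weights default to $\alpha = \beta = 1$ and $\gamma = 0.1$. The
  regularizer weight is deliberately gentle: per-sample divergence
  maximization competes with the input-tracking of the attention masses, and
  a strong $\gamma$ froze the aspect directions into input-independent
  configurations in development experiments. All three are configurable.

## Training

Mini-batch Adam (default) at the reference recipe's settings: batch size 64
(of $\{32, 64, 128\}$), 15 epochs, dropout 0.4, $K = 2$ aspects, $T = 0.05$.
Triples are resampled every epoch with negatives drawn uniformly from each
anchor's non-interacting drugs, capped at `max_triples` (default 3000) per
epoch to keep epochs tractable on dense interaction sets. Early stopping
monitors a held-out validation BPR loss (10% of training positives, patience
3) and restores the best parameters. A global gradient-norm clip (default 5)
guards the temperature-scaled contrastive term against occasional exploding
steps. All randomness flows from one seed; identical seeds give identical
models, which a test asserts to $10^{-6}$.

The learning rate deserves a note. The reference recipe pairs $2 \times
10^{-5}$ with tens of thousands of interactions and roughly $10^4$ gradient
steps; that is the package default. The synthetic worlds used in examples,
tests and the acceptance script are two orders of magnitude smaller (a few
hundred drugs, $\sim 10^3$ steps), and there we use $10^{-3}$ — the standard
Adam magnitude for this problem size — chosen once up front and not tuned per
experiment.

Ablation variants map onto configuration toggles: `use_contrastive = FALSE`
removes the InfoNCE branch ("w/o Con"), `use_decoupling = FALSE` is the
$K = 1$ pipeline ("w/o De"), `use_association_encoder = FALSE` leaves the
multi-hot branch only.

## Evaluation protocols

* **Leave-one-out ranking.** For each test pair the anchor receives its
  held-out positive plus $N$ sampled negatives (default 100; the synthetic
  experiments use 50); candidates are ranked by risk, ties broken by
  ascending drug id. HIT@K is the top-$K$ hit fraction; NDCG@K contributes
  $1/\log_2(\mathrm{rank}_0 + 2)$ and MRR@K $1/(\mathrm{rank}_0 + 1)$ inside
  the top K and 0 outside, with $\mathrm{rank}_0$ the 0-based rank. For
  single-relevant-item lists MRR ≤ NDCG ≤ HIT pointwise, and a uniform random
  scorer attains $E[\mathrm{HIT@K}] = K/(N+1)$ — both are tested, the latter
  by Monte-Carlo calibration.
* **Threshold classification.** ACC/F1/Precision/Recall at the strict
  "exceeds 0.5" rule; AUC as the midrank statistic (ties get half credit);
  AUPR as the area under the precision–recall step curve. Single-class label
  sets report AUC/AUPR as `NA`.
* **Splits.** S1 partitions interactions into cross-validation folds
  (transductive); S2/S3 partition *drugs* 4:1 into known/novel and test on
  pairs with exactly one (S2) or two (S3) novel drugs, training pairs never
  containing a novel drug. `check_split_integrity()` asserts the
  no-leakage invariants and `run_experiment()` calls it before every fold.
  Negative sampling pools during cold-start training are restricted to known
  drugs.

## The synthetic world

`generate_world()` plants $K_{true}$ mechanisms (named metabolism and
absorption for the first two). Each drug gets a dominant mechanism (membership
$u \sim U(0.7, 1)$, off-mechanisms $U(0, 0.3)$), a substructure set built from
its mechanism's signature tokens (12 per mechanism, inclusion rate $0.9 u$)
plus background noise (rate 0.04), and attribute tokens from mechanism-linked
pools — enzyme tokens follow the metabolism membership, transporter-like
target tokens the absorption membership, pathways both. A pair interacts with
probability $\sigma(b + \sum_k s_k u_{ik} u_{jk} + \lambda (z_i + z_j))$
where $z$ is a standard-normal activity latent giving the short-head/long-tail
degree shape ($\lambda$ = 1) and $b$ is solved by root-finding so the expected
edge rate matches the target sparsity, 0.8825 by default — the sparsity of a
curated reference dataset of 572 drugs. Mechanism strengths default to 6,
which makes same-mechanism compatibility the dominant interaction driver
while leaving genuine label noise. The dominant contribution $s_k u_{ik}
u_{jk}$ of each positive pair is recorded as its ground-truth mechanism.

What the generator does *not* emulate: valid SMILES grammar (tokens are
synthetic 3-letter strings), real pharmacokinetics, correlated attribute
errors, and the multi-label event types of curated DDI corpora. Passing tests
on these worlds therefore demonstrate that the pipeline recovers planted
compatibility structure through the package's own featurization — not
clinical performance on real data.

`mechanism_recovery_report()` correlates per-pair aspect weights with the
planted mechanism indicators and resolves aspect/mechanism label switching by
maximizing the mean matched correlation over permutations.

## Numerical choices and degenerate inputs

* Empty-set Tanimoto is 0 by definition; KL inputs are $\varepsilon$-smoothed
  ($10^{-12}$) and renormalized; InfoNCE and the BPR softplus use
  max-subtraction / two-tail `log1p` forms.
* `floor(n * alpha)` for augmentation counts and window lengths; a flip
  request larger than the number of zeros flips every remaining zero rather
  than erroring, so dense vectors never abort training.
* Candidate lists for anchors with too few negatives shrink with a warning
  instead of erroring — long-tail drugs must not abort an evaluation run.
* Score ties in ranking break by ascending drug identifier, making reports
  byte-reproducible.
* Initialization is uniform fan-in scaling under an explicit seed; batch-norm
  running statistics start at (0, 1) with momentum 0.1.
* Problem sizes in the test-suite experiments: worlds of 60–300 drugs,
  $d \le 200$, candidate lists of $N = 50$, at most ~200 evaluated anchors
  per fold and 2000 scored pairs per recovery report. These sizes make the
  planted signal detectable while keeping each experiment to a couple of
  minutes of single-threaded CPU.

## Open design points and how they were resolved

* The concatenated similarity feature is read as per-drug similarity rows
  (length $n$ per category), the only dimensionally consistent reading; the
  attention tokenization (one token per drug × category block) follows from
  it.
* Augmentation operates on the joined pair vector — the module sits
  downstream of pair construction — with per-drug application available by
  building the pair from augmented halves.
* The latent is compressive ($k < d$) per the stated purpose of the branch.
* Aspect heads project from the shared representation rather than chunking
  the latent, so $K$ is independent of latent width.
* The fused vector is the weight-weighted sum of attended aspect outputs;
  the attention output projection alone is the natural alternative, and the
  weighted sum was chosen because it makes the reported contribution weights
  exactly the coefficients of the risk representation.
* Evaluation uses $N = 100$ negatives per anchor by default (a standard
  leave-one-out choice; configurable), since the headline protocol's $N$ is
  not fixed by the recipe.

## Known limitations

* Substring mining is not substructure chemistry: tokens are character
  n-grams, not molecular fragments; an RDKit-based canonicalizer/fragmenter
  could replace the miner where chemistry fidelity matters.
* The per-sample independence regularizer and the input-tracking of
  attention masses pull in opposite directions; with strong regularization
  the aspect directions can freeze. The gentle default mitigates but does not
  remove this tension (see the discussion above), and mechanism-recovery
  correlations vary across training seeds.
* Training is single-threaded dense linear algebra in R; universes beyond a
  few thousand drugs call for a compiled backend.
* Risk calibration is not studied: scores order candidates well before they
  are calibrated probabilities of clinical interaction.
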