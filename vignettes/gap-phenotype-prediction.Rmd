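---
title: "Predicting binary phenotypes from alignment gap patterns"
author: "gapnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binary phenotypes from alignment gap patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gene loss tracks phenotype loss. When a trait — say, the ability to
synthesize a metabolite — has been lost repeatedly across a clade, the
genes underlying it decay in exactly the lineages that lost the trait,
and that decay is visible in a multiple sequence alignment as gaps:
deleted exons, unalignable regions, or whole genes missing. `gapnet`
turns this signal into a supervised classifier. Given an alignment of one
genomic region across n species and a binary phenotype label per species
(`yes` / `no`, with `unknown` allowed), it learns to predict the
phenotype *from the gap pattern alone*, ignoring nucleotide identity
entirely. The fitted model answers three questions:

1. **Prediction** — which phenotype do the unknown-status species most
   likely have?
2. **Localization** — which alignment positions carry the predictive
   signal?
3. **Screening** — across many candidate regions, which ones are
   associated with the phenotype at all?

## The model

The alignment is one-hot encoded into a binary matrix x (n species × p
positions) with `x[i, j] = 0` for a gap and 1 for any nucleotide
(ambiguity codes and `N` count as "nucleotide present": the encoding
distinguishes only gap from non-gap). Invariant columns are removed and
the rest are centered; both statistics are computed over *all* supplied
species, labeled or not, so that unknown-status species can later be
projected consistently. Principal component analysis then reduces the
centered matrix to the smallest m components capturing at least 95% of
the variance (the threshold is exposed as `var_threshold`), giving the
feature matrix z. Optionally, a rooted species tree contributes binary
clade-membership features t: one column per non-root internal node, 1
for species inside the clade. The root clade contains every species and
is uninformative, so a tree with c internal nodes yields t = c − 1
features.

The classifier is a dense feed-forward network with L ∈ {0, 1, 2, 3}
hidden ReLU layers and a two-class softmax output, trained by Adam
(learning rate 10⁻², momentum decays 0.9/0.999, mini-batches of 33 rows
clipped to the training-set size, 500 epochs) on the mean binary
cross-entropy plus an elastic-net penalty on the connection weights,

λ · [ γ Σ|w| + (1 − γ)/2 Σw² ],

with biases unpenalized. With L = 0 the network reduces to softmax
(logistic) regression, and that case is the canonical one for
interpretation. Hyperparameters (L, λ, γ) are selected by
cross-validation — leave-one-out by default, which suits the small
species counts typical of this problem; k-fold is available — over a grid
of 100 λ values uniform in log₁₀ λ ∈ [−4, 3] and a 21-point γ grid
{0, 0.05, …, 1}. Among minimum-error cells the *simplest adequate model*
wins: fewest hidden layers first, then the most regularized (largest λ,
smallest γ). The chosen cell is refit on all labeled species. The
hidden-layer width k is not part of the search; it defaults to the
number of labeled species and is exposed in `gap_grid()`.

Cross-validation error is the number of misclassified species divided by
the number of labeled species; a region whose minimum CV error is at or
below 0.1 is called *associated* in screening mode (a minimum-error rule
is also provided for genome-wide scans).

## Position importance

For interpretation, the first-layer weights attached to the m PC inputs
are mapped back to alignment positions by premultiplying with the p × m
loading matrix; clade-feature weights have no alignment position and are
excluded. Each position then owns a coefficient vector, and positions
whose coefficients sit far from the bulk are the interesting ones:
`importance()` computes each position's squared Mahalanobis distance to
the mean coefficient (sample covariance across positions, denominator
p − 1), converts it to an F statistic by standard one-sample Hotelling
theory — F = (p − d)/(d(p − 1)) · T² with d and p − d degrees of
freedom — and adjusts the upper-tail p-values across positions with
Benjamini–Hochberg.

One identifiability point matters here. A softmax output layer is
invariant to adding a constant to both class logits, so for an L = 0
model only the *difference* of the two coefficient columns is
identifiable; their sum is pure optimization noise. Empirically the two
reconstructed columns are anti-correlated to five nines, and the
covariance eigendirection corresponding to the sum is orders of
magnitude smaller than the discriminant direction — small enough that a
naive d = 2 Mahalanobis distance amplifies that noise into spurious
significant positions. `importance()` therefore tests the yes-minus-no
contrast (d = 1) for L = 0 models; for deeper models the k first-layer
columns are identifiable and are tested jointly. The raw p × 2
reconstruction remains available via `reconstruct_position_weights()`.
A rank-deficient coefficient covariance falls back to the Moore–Penrose
pseudo-inverse with a warning, with the degrees of freedom reduced to
the rank; the F upper tail is one-sided by construction and no extra
doubling is applied.

## The simulator

`sim_config()` / `simulate_region()` generate benchmark data with the
statistical structure the method is meant to exploit:

* **Species tree.** A seeded pure-birth tree with 34 tips rescaled to a
  root-to-tip depth of 0.5 expected substitutions per site
  (`standin_species_tree()`). The tree is fixed by an internal seed so
  every session sees the same stand-in phylogeny; it is a synthetic
  stand-in, not an estimate of any published vertebrate phylogeny, and
  all benchmark numbers are approximate by design.
* **Gene trees.** One per region under a multispecies coalescent: one
  lineage per tip species, coalescing at rate C(k, 2)/θ per unit branch
  length within each ancestral population (θ = `coalescent_scale`,
  default 0.05). Smaller θ makes gene trees track the species tree.
* **Sequences.** A root sequence of Poisson-distributed length (mean
  1,575 nt) drawn from the equilibrium frequencies evolves along the
  gene tree under GTR+F (equal exchangeabilities and frequencies by
  default; both fully configurable when fitted values for a real
  dataset are available). Insertions and deletions
  arise as a Gillespie process at total rate 0.23 per site relative to
  the substitution rate, split evenly between insertions and deletions,
  with Zipf-distributed lengths (exponent 1.7, maximum 100). Homology is
  tracked exactly: every site ever created owns one global alignment
  column, so the emitted alignment is a true-homology alignment and
  ungapping any row recovers that tip's sequence.
* **Trait.** A symmetric two-state Markov chain on the region's *gene*
  tree (root state from the stationary distribution). The default rate
  gives about three expected flips across the tree — enough changes that
  both classes are usually populated, few enough that the trait stays
  phylogenetically clustered. Trait–gap association arises only through
  the shared gene tree; no direct gap–trait coupling is injected. Traits
  leaving fewer than two species in a class are redrawn (they cannot be
  cross-validated and carry no learnable signal).
* **Masking.** Each tip's sequence is independently replaced by all gaps
  with probability 0.05, emulating lineage-specific whole-gene deletion.

What the simulator does *not* emulate: among-site rate variation,
alignment error (columns are true homology), gene duplication,
empirically-calibrated GTR parameters, or any direct mechanistic link
between the trait and particular indels. Passing benchmarks therefore
show that the pipeline recovers tree-borne gap–trait association under
idealized alignments, not that it is robust to real-world alignment
artifacts.

## Benchmark protocol and problem sizes

`run_benchmark()` simulates regions and, per region, runs the full
selection pipeline four ways: alignment-only features and alignment +
clade features, each with the region's true trait and with random
Bernoulli(½) labels. Mean minimum CV error and the call rate at the
0.1 threshold under true traits give accuracy and the true positive
rate; the call rate under random labels gives the false positive rate.

The package's study size for this benchmark is 100 regions with a
reduced, clearly non-default grid (10 λ uniform in log₁₀ over [−4, 3] ×
5 γ {0, 0.25, …, 1} × L ∈ {0, 1}, k = 4 hidden units), leave-one-out
cross-validation throughout. The reduced profile keeps the full factorial
structure of the search while making the 100-region × 4-run protocol a
desk-scale computation; k = 4 reflects that with ~33 training rows a
narrow hidden layer is all the capacity the L = 1 cells need.
`scripts/acceptance.R` reruns exactly this protocol from scratch.

Two properties of this design are worth keeping in mind when reading its
numbers. First, the reported per-region error is a *minimum over grid
cells*, so it falls as the grid grows; a reduced grid is therefore
conservative about call rates at a fixed threshold relative to an
exhaustive search, and call-rate style metrics are only comparable
between runs that used the same grid. Second, with independent
Bernoulli(½) labels the false-positive side is extremely stringent at
these sizes: calling a region requires leave-one-out error ≤ 3/34 on
labels that carry no signal at all, a far tail of the per-cell error
distribution, so the measured false positive rate under iid labels is
expected to sit near zero.

## Numerical choices

* Cross-validation training runs in single precision with a fused code
  path that trains every (λ, γ) cell × fold simultaneously through
  shared BLAS calls; held-out rows contribute zero gradient. Final
  refits use the same trainer; forward passes for prediction run in
  double precision on the stored weights. CV errors are
  misclassification counts and are insensitive to the working precision.
* Weight initialization is uniform in ±1/√fan-in from a dedicated
  splitmix64 stream seeded per cell and fold; biases start at zero.
  Nothing consumes R's global RNG state, so fits are reproducible
  bit-for-bit for a given seed and never perturb the caller's RNG.
* Per-cell and per-region seeds are derived by hashing the master seed
  with the cell's hyperparameter values or the region id
  (`derive_seed()`), so grid results are independent of evaluation order
  and scanning regions one at a time equals scanning them in a batch.
* Prediction ties at probability exactly ½ resolve to `no`.
* PCA is a singular value decomposition of the centered matrix, no
  column rescaling; loading signs are fixed by making each column's
  largest-magnitude entry positive. m is capped at p − 1 and at the
  matrix rank.
* The 21-point γ grid {0, 0.05, …, 1} is used as written even though it
  is sometimes described as 20 values; the set has 21 elements.

## Known limitations

* All species in the label table must be present in the alignment;
  missing rows are an error, not imputed.
* An all-gap species is representable (and meaningful — whole-gene
  loss), but two species with identical gap patterns are
  indistinguishable to the model, whatever their labels.
* Leave-one-out CV on ~34 species has high variance per region; the
  benchmark averages over 100 regions for that reason.
* The Hotelling null treats positions as exchangeable draws from a
  common coefficient distribution; heavy linkage between nearby columns
  (shared indels) makes neighboring positions' statistics strongly
  dependent, so significant positions arrive in blocks, and the
  effective number of independent tests is smaller than p.
* The empirical route — UCSC multiz alignments of tens of thousands of
  genes — is out of scope here; the package reads one aligned FASTA per
  region and concatenating exons per gene is the caller's
  responsibility.
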