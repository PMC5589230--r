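---
title: "Scoring microbe-disease associations with a step-limited bi-random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microbe-disease associations with a step-limited bi-random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birw)
```

## The problem and the model

Curated microbe-disease association catalogs record which microbial genera
have been experimentally linked to which diseases. Such a catalog is a
sparse binary bipartite network: the one this package's defaults are shaped
around has 39 diseases, 292 genus-level microbes and 450 distinct
associations, i.e. each microbe touches 1.54 diseases and each disease
11.54 microbes on average. The prediction task is link prediction on this
bipartite graph: score every unobserved disease-microbe pair by how likely
it is to be a missing association.

`birw` does this in three stages.

**Similarity from interaction profiles.** The only input is the adjacency
matrix `A` (diseases on rows), so node similarity must come from the
network itself. Two microbes are similar when they associate with similar
disease sets; the Gaussian interaction-profile (GIP) kernel formalizes this
as `SM(i,j) = exp(-gamma ||m(i) - m(j)||^2)` over the binary column
profiles. The bandwidth is normalized by the mean squared profile norm
(`gip_bandwidth()`), so the kernel's scale adapts to network density; the
raw bandwidth `gamma'` defaults to 1 on both node sets. The same kernel
over row profiles gives the raw disease similarity `KSD`.

**Logistic regulation of disease similarity.** Kernel values below ~0.3
carry little evidence while values above ~0.6 are reliable, so `KSD` is
passed through `SD = 1/(1 + exp(c*KSD + d))` with slope `c = -15` and
offset `d = ln(9999)`. The offset is pinned by the anchor `SD = 1e-4`
exactly at `KSD = 0`; only the natural logarithm satisfies that anchor, so
`log(9999)` is read as `ln`. The transform is applied to every entry
including the diagonal (nothing exempts it), which leaves self-similarity
at ~0.997 instead of 1; this never matters because self-similarity does
not enter candidate ranking. The microbe side is deliberately left
unregulated.

**The walk.** Association evidence is propagated by a bi-random walk: up to
`l` steps through the microbe similarity network
(`Rm = alpha * MD %*% SM + (1 - alpha) * A`) and up to `r` steps through
the disease similarity network (`Rd = alpha * SD %*% MD + (1 - alpha) * A`),
run simultaneously and averaged while both sides are active, with the
longer side continuing alone afterwards. Conceptually each step extends
circular bigraphs -- a microbe path and a disease path closed by two known
associations -- and `alpha` geometrically down-weights evidence arriving
along longer paths. The walk stops after exactly `max(l, r)` steps; there
is no convergence threshold, because the step limits *are* the model's way
of accommodating the two networks' different topologies.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | decay per walk step, unitless in (0,1] | 0.4 | best cell of the published parameter sweep; larger values weight long paths more |
| `l`, `r` | step limits, microbe / disease side | 2, 2 | sweep optimum; performance degrades when `l != r` |
| `gamma_m`, `gamma_d` | raw GIP bandwidths | 1 | the field's convention; the effective bandwidth is density-normalized anyway |
| `c`, `d` | logistic slope / offset | -15, ln(9999) | slope from the cited cross-validation tuning; offset pinned by the `1e-4` anchor at `KSD = 0` |
| `normalize_similarity` | Laplacian-normalize SM, SD | `TRUE` | see below |
| `normalize_seed` | `MD0 = A / sum(A)` | `TRUE` | see below |

**The normalization question.** The update equations are printed without
any normalization, but the algorithm box they summarize is not available in
the extracted source, and the bi-random-walk literature they build on
Laplacian-normalizes both similarity matrices
(`D^{-1/2} S D^{-1/2}`) and scales the seed to unit mass. Rather than guess
silently, both modes are implemented: the canonical normalized mode is the
default, and `birw_params(normalize_similarity = FALSE, normalize_seed =
FALSE)` runs the printed equations verbatim. The acceptance tests run both
modes side by side. Normalization changes scores but, empirically on
synthetic networks, only mildly perturbs rankings.

A related design choice: when `t` exceeds `min(l, r)` the exhausted side
simply drops out of the average; the longer side's walk continues alone.
This follows the step-limited formulation in the cited literature.

## Evaluation protocol

`loocv()` hides each known association in turn, **recomputes both
similarity matrices from the reduced matrix** (the similarities are
association-derived, so leaving them fixed would leak the held-out link;
`recompute_similarity = FALSE` exists as a fast approximation for testing
only), reruns the walk, and compares the held-out pair's score with the
scores of all pairs that are zero in the full matrix. Each round
contributes its Mann-Whitney win fraction (ties count one half); since
every round faces the same candidate set size, the mean over rounds equals
the pooled probability that a held-out association outscores a random
unverified pair. The ROC curve is the empirical CDF of the per-round
false-positive fractions, emitted as a staircase so its trapezoidal area
equals the reported AUC exactly.

`kfold_cv()` extends this to repeated k-fold: one integer seed drives all
repeats, folds differ in size by at most one, a whole fold is zeroed at
once, and the per-repeat AUC is the mean over that repeat's held-out
associations. Entries held out in *other* folds are training positives for
the current fold and are not treated as candidates. Mean and standard
deviation over repeats are reported; published 5-fold numbers can only be
matched in distribution, never bitwise, because the original fold seeds are
unknown.

`rank_candidates()` ranks a disease's unverified microbes by descending
score with ties broken by index order (deterministic, reproducible).

## What the synthetic generator does and does not emulate

`block_model_spec()` / `generate_block_association()` implement a bipartite
stochastic block model: diseases and microbes are assigned round-robin to
`n_blocks` matched groups (deterministic block sizes, so
`expected_density()` is exact closed form), and each pair is drawn
independently with probability `p_in` within matched blocks and `p_out`
elsewhere. This gives tests a known ground truth: with `p_in >> p_out`,
similarity-driven ranking must recover withheld in-block links (LOOCV AUC
well above 0.5); with `p_in = p_out` there is nothing to recover and AUC
must hover near 0.5.

`synthetic_reference_records()` is a SYNTHETIC stand-in for the curated
reference export, which cannot be redistributed with this package. Its
stated world, fixed once: 39 diseases, 292 microbes, 5 matched block pairs
carrying ~75% of the association mass (`p_in ~ 0.15`, `p_out ~ 0.012`),
adjusted to exactly 450 distinct associations with every node covered, plus
33 duplicated rows for a 483-row table. It reproduces the reference's
*marginals* (counts, density, mean degrees 1.54 / 11.54) but not its actual
degree distribution or community structure. Consequently a green test on
the stand-in establishes that the pipeline is wired correctly at reference
scale -- and nothing about the published headline AUCs, which depend on the
real network's structure. The two acceptance tests that assert those
published values (LOOCV 0.8964, 5-fold 0.8808 +/- 0.0029) run the full
protocol on the stand-in and fail honestly, by design, rather than being
skipped or loosened.

## Numerical choices and degenerate inputs

- The GIP kernel's diagonal is set to exactly 1 (the distance computation
  would give `exp(-0)` anyway; the assignment guards against rounding).
- An all-zero profile *set* (no associations at all) makes the bandwidth
  undefined and errors; a single all-zero profile is fine and is handled
  by construction (kernel entries stay positive, so Laplacian
  normalization never divides by zero).
- AUC uses mid-rank tie handling, computed via the rank-sum identity in
  O(n log n) and verified against a brute-force pairwise oracle.
- Candidate ties in `rank_candidates()` break by microbe index order.
- At `l = r = 1`, scores of unverified pairs scale exactly by `alpha/2`,
  so their ranking is alpha-invariant -- the structural reason a published
  parameter sweep shows a constant column at `l = r = 1`. In floating
  point, rescaling is monotone but can merge near-ties into exact ties;
  the property tests assert "no strict inversion" rather than positional
  rank equality for this reason.
- `deduplicate()` is exact string match after whitespace trimming,
  case-sensitive by default (curated labels are assumed consistent); a
  case-insensitive switch exists because hand-curated catalogs vary.

## Known limitations

- Similarities derive solely from the association matrix, so predictions
  are biased toward well-studied nodes; nodes with no remaining links get
  uniform-ish profiles and weakly informative scores (the method still
  scores them -- nothing requires a disease to have known microbes).
- The generator matches mean density only; real catalogs have heavier-
  tailed degree distributions than a two-parameter block model.
- No ontology mapping or taxonomy normalization of names: "IBD" and
  "inflammatory bowel disease" are different diseases to this package.
- Published top-10 candidate tables are sensitive to the normalization
  mode and tie handling, which the original description leaves open; exact
  membership should be treated as mode-dependent.
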