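# birw — bi-random walk link prediction on microbe–disease networks

Curated microbe–disease association catalogs are small and sparse, yet most
microbe–disease pairs have simply never been studied. `birw` is for
researchers who want to prioritize which unstudied pairs to look at next:
given nothing but a two-column table of known associations (disease name,
microbe name), it scores **every** disease–microbe pair and ranks the
unverified candidates for each disease.

## The model

Let `A` be the binary `nd × nm` adjacency matrix of the bipartite
association network (diseases on rows). Three ingredients form a
heterogeneous network:

1. **Microbe similarity (SM)** — the Gaussian interaction-profile (GIP)
   kernel over the columns of `A`:
   `SM(i,j) = exp(−γ_m ‖m(i) − m(j)‖²)`, with the bandwidth normalized by
   the mean squared profile norm, `γ_m = γ′_m / (1/nm · Σ_k ‖m(k)‖²)`,
   `γ′_m = 1`.
2. **Disease similarity (SD)** — the same kernel over the rows of `A`
   (`KSD`), then regulated by a logistic transform
   `SD = 1 / (1 + exp(c·KSD + d))` with `c = −15`, `d = ln(9999)`, which
   suppresses the uninformative low-similarity range (`SD = 10⁻⁴` exactly
   at `KSD = 0`) and saturates the informative high range.
3. **Bi-random walk** — starting from the seed `MD₀ = A` (scaled to unit
   mass by default), up to `l` steps propagate scores through the microbe
   network, `Rm = α·MD·SM + (1−α)·A`, and up to `r` steps through the
   disease network, `Rd = α·SD·MD + (1−α)·A`; active sides are averaged
   each step and the walk stops after exactly `max(l, r)` steps. The decay
   `α ∈ (0,1]` down-weights evidence arriving along longer paths (longer
   circular bigraphs). Defaults: `α = 0.4`, `l = r = 2`.

The final matrix `MD` scores every pair; `rank_candidates()` turns a row of
it into a per-disease top-k table. Evaluation follows the field's standard
protocol: leave-one-out cross validation (similarities recomputed after
each removal) and 100× repeated 5-fold cross validation, with each held-out
association ranked against all unverified pairs (Mann–Whitney AUC, ties
counted ½).

## Worked example

```r
library(birw)

# a synthetic network with planted block structure: 10 diseases x 30
# microbes, two matched blocks, 90% in-block / 2% out-of-block association
rec <- deduplicate(generate_block_association(
  block_model_spec(n_diseases = 10, n_microbes = 30, n_blocks = 2,
                   p_in = 0.9, p_out = 0.02, seed = 7)))
nrow(rec)
#> [1] 137

fit <- predict_associations(rec, params = birw_params(alpha = 0.4, l = 2, r = 2))
rank_candidates(fit$MD, fit$A, "D1", top_k = 5)
#>   rank microbe        score
#> 1    1      M1 0.0020953162
#> 2    2     M19 0.0020953162
#> 3    3     M28 0.0002828062
#> 4    4      M8 0.0002802894
#> 5    5     M18 0.0002802894

loocv(rec)
#> Leave-one-out CV: AUC 0.9400 (137 positives vs 163 candidates)

kfold_cv(rec, k = 5, repeats = 10, seed = 1)
#> 5-fold CV, 10 repeats: mean AUC 0.9507 (sd 0.0035)
```

The top candidates for `D1` are exactly the in-block microbes whose
association went unobserved in this draw (e.g. `M1`, `M19` — same block as
`D1`, scored an order of magnitude above the out-of-block pairs), and the
cross-validation AUCs well above 0.5 confirm the walk recovers the planted
structure.

## Command line

A wrapper for scripted use is installed with the package:

```sh
birw=$(Rscript -e 'cat(system.file("exec", "birw", package = "birw"))')
Rscript $birw simulate --nd 10 --nm 30 --blocks 2 --p-in 0.9 --p-out 0.02 \
    --seed 7 --out net.tsv
Rscript $birw loocv --in net.tsv --alpha 0.4 --l 2 --r 2
Rscript $birw rank --in net.tsv --disease D1 --top 10
Rscript $birw sweep --in net.tsv --alpha 0.2,0.4 --l 1,2 --r 1,2
```

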