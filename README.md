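# multipletr

Model-based doublet/triplet detection for droplet-based single-cell data,
single- or multi-modality (RNA, ADT surface proteins, ATAC gene activity).

## The problem

Droplet platforms occasionally capture two or three cells in one droplet.
These multiplets masquerade as novel cell types, and in multiomics analyses
integrated clustering actively concentrates them into spurious clusters.
Most computational detectors rank droplets by similarity to simulated
doublets built from highly variable genes, then require the user to pick a
cutoff — and highly variable genes carry no signal for homotypic multiplets
(two cells of the same type).

## The model

multipletr fits, per modality, a compound Poisson mixture over **stable
features** — high-abundance, low-variability features (housekeeping genes,
ribosomal genes, broadly expressed surface markers) whose per-droplet totals
track the number of cells regardless of cell type:

- the number of extra cells per droplet is `K ~ Poisson(θ)`, right-truncated
  at `k_max = 2` (triplets);
- each of the `K + 1` cells contributes additively on the raw scale, with a
  Gamma contribution per feature for RNA/ATAC and a Gaussian one for ADT;
- a decline factor `f(d, k) = 1/(k+1) + (1 − 1/(k+1))·σ(d)` shrinks per-cell
  contributions in crowded droplets, so a doublet's conditional mean lies
  strictly between 1× and 2× the singlet mean:
  `X | K=k ~ Gamma(f(d,k)(k+1)α_i, β_i)` (and the Gaussian analogue with
  variance `(k+1)σ²_i`).

All parameters are estimated by maximum likelihood; Bayes' rule then gives
each droplet a posterior over {singlet, doublet, triplet}, and a droplet is
called a singlet iff `P(K = 0 | data) ≥ 0.5` — no tunable threshold.

Fit quality is scored per modality as `GOF = 1 / mean(KS)` (mean
Kolmogorov–Smirnov distance between empirical and fitted CDFs across stable
features; GOF > 3 indicates a reliable fit). With several modalities, the
final posterior is a per-droplet softmax-weighted combination, the weights
being `GOF × consistency` per modality (ATAC GOF halved by default), where
consistency is the fraction of stable features individually agreeing with
the modality's call for that droplet.

## Worked example

Simulate a 5000-droplet RNA well from the generative model (θ = 0.15,
decline d = 0.5, 50 gamma stable features) and run detection:

```r
library(multipletr)

set.seed(1)
truth <- cp_params("gamma", theta = 0.15, d = 0.5, k_max = 2,
                   alpha = runif(50, 50, 150), beta = rep(1, 50),
                   modality = "RNA")
sim <- simulate_droplets(list(RNA = truth), n = 5000, seed = 1)
res <- detect_multiplets(sim$matrices$RNA, n_stable_rna = 50, seed = 1,
                         verbose = TRUE)
#> aligned 5000 droplets across RNA
#> RNA: 50 stable features selected
#> RNA: fitted gamma model, -logLik = 1049472.40, theta = 0.1609, d = 0.492
#> RNA: GOF = 108.00 (mean KS = 0.0093)
#> called 14.9% of droplets multiplet

glance(res$fits$RNA)
#> # A tibble: 1 × 10
#>   modality family theta     d k_max n_droplets n_features    logLik converged
#> 1 RNA      gamma  0.161 0.492     2       5000         50 -1049472. TRUE

evaluate_calls(res$predictions$call, sim$labels$call,
               scores = 1 - res$predictions$combined_k0)
#> # A tibble: 1 × 8
#>      tp    fp    fn    tn precision recall    f1 auprc
#> 1   744     0     0  4256         1      1     1     1
```

The fitted rate (0.161) and decline (0.492) recover the simulation truth;
the implied multiplet fraction `1 − P_T(K=0)` matches the 14.9% of droplets
called multiplet, all of them correctly. `res$predictions` is a tibble with
per-modality posteriors, GOF, per-droplet weights, combined posteriors and
calls; `write_predictions()` serializes it as TSV. For real data, start from
`read_counts()` (10x-style MTX triplet or dense CSV/TSV) and, for multiple
modalities, pass a list of matrices — alignment, stable-feature selection,
fitting, GOF weighting and integration run in one call. A thin CLI with
`detect`, `simulate`, `evaluate` and `select-features` subcommands is in
`inst/scripts/multiplet-detect.R`.

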