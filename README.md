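# spotdecon

Cell-type deconvolution of spatial transcriptomics (ST) spots through
dropout-informed gene selection and a semi-supervised graph convolutional
network.

Spot-based ST platforms measure each capture spot as a pooled profile of
roughly 10–20 cells. `spotdecon` estimates the fractional cell-type
composition of every spot from an annotated scRNA-seq reference of the same
tissue. It is aimed at analysts who have a spots × genes count matrix with
spot coordinates, a cells × genes reference with cell-type labels, and want
per-spot proportions plus the diagnostics to trust them.

## Method

1. **Dropout-based gene selection.** Per gene, the dropout rate *P* (zero
   fraction) and mean expression *E* are tied by the Michaelis–Menten curve
   *P* = 1 − *E*/(*E* + *K*). A global *K<sub>M</sub>* is fitted by maximum
   likelihood (per-gene binomial zero counts); each gene's
   *K<sub>i</sub>* = *E·P*/(1 − *P*) is tested (right-tailed, on the log
   scale) against it. Genes with significant excess dropout — the signature
   of cell-type-specific expression — are ranked, the top-2000 sets from ST
   and reference are intersected, and the intersection becomes the feature
   panel.
2. **Pseudo-spots.** Mixtures of 10–20 annotated cells with exact fraction
   labels *m<sub>c</sub>/m* provide supervision; pseudo- and real spots are
   library-size normalized identically (×10,000).
3. **Embedding.** A three-layer autoencoder (200-unit bottleneck, 5 epochs,
   batch 300) embeds all spots; an SVD projection is the linear alternative.
4. **Graph.** Mutual *k*-nearest-neighbour edges (*k* = 100, Euclidean in
   the embedding) join pseudo- to real spots; lattice edges join each real
   spot to the four neighbours at (±*h*/2, ±*h*/2). The propagation operator
   is the symmetrically normalized adjacency with self-loops,
   Ã = D̂<sup>−1/2</sup>(A + I)D̂<sup>−1/2</sup>.
5. **GCN.** Three convolution layers H⁽ˡ⁺¹⁾ = ReLU(Ã H⁽ˡ⁾ W⁽ˡ⁾) with a
   softmax head output a composition per node; training minimizes
   soft-label cross-entropy on pseudo-nodes (80/10/10 split, Adam 0.005,
   early stopping patience 10). Real-spot rows are the answer; fractions
   under 5% are zeroed and rows renormalized.

A square-binning benchmark simulator (single-cell-resolution data →
ST-resolution spots with exact ground truth, scored by RMSE and base-2
Jensen–Shannon divergence) and a fully synthetic data generator make every
stage testable offline. See `vignette("methods")` for the full account.

## Worked example

```r
library(spotdecon)

cfg <- synthetic_config(seed = 42)          # 3 types, 500 genes, 8x8 lattice
ref <- simulate_reference(cfg)              # annotated scRNA-seq reference
tissue <- simulate_spatial_tissue(cfg, ref) # cells on a plane, blocked types
vis <- make_visium_like(cfg, tissue)        # spots + coordinates + truth

res <- run_pipeline(vis$expression, vis$coords,
                    ref$expression, ref$annotation,
                    pipeline_config(seed = 1), truth = vis$truth)
res$metrics
#> # A tibble: 3 × 2
#>   metric                 value
#>   <chr>                  <dbl>
#> 1 rmse                  0.106
#> 2 jsd                   0.0424
#> 3 rmse_uniform_baseline 0.367
```

The fitted compositions sit within RMSE ≈ 0.11 of the ground truth
(Jensen–Shannon divergence ≈ 0.04 per spot on average), far below the 0.367
a type-blind uniform prediction would score. `tidy(res)` returns the
proportions as a long tibble, `glance(res)` a one-row summary, and
`autoplot(res$proportions)` / `plot_spatial_proportions()` the standard
figures. A command-line front end with `simulate`, `bench`, `deconvolve`
and `ablate` subcommands is installed at `inst/cli/spotdecon.R`.

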