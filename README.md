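# micanet

Gene co-expression network analysis built on two ideas that correlation
pipelines miss: **non-linear association** and **fuzzy module membership**.

Strain panels and treated/control designs are full of gene pairs whose
relationship is strong but not linear — thresholded responses, saturating
curves, and gene-by-environment (GxE) interactions whose slope flips sign
with treatment, leaving the pooled Pearson correlation near zero. And many
genes genuinely act in more than one pathway, which hard clustering cannot
express. `micanet` is for transcriptome analysts who want modules that keep
those genes and those relationships.

## The method

1. **Association.** Every gene pair is scored with the maximal information
   coefficient (MIC): over all axis-aligned grids on the rank-ordered data
   with `x·y < n^0.6` cells, the maximum of
   `MI(grid in bits) / log2(min(x, y))`. MIC is 1 for any noiseless
   functional relationship, 0 for independence, and invariant to monotone
   transforms. A compiled search (exact dynamic programming over one axis
   given an equipartition of the other, both orientations; full enumeration
   at small n) makes the all-pairs matrix fast.
2. **Network.** The matrix is hard-thresholded at the lowest cutoff whose
   degree distribution passes the scale-free criterion (signed R² ≥ 0.9 of
   the log-log binned degree-frequency regression).
3. **Modules.** Network links are assigned to latent components by a
   collapsed Gibbs sampler (interaction component model, ICMg) with
   conditional
   `p(z|·) ∝ (n_z+α)/(N+Cα) · (q_zi+β)(q_zj+β) / ((2n_z+1+Mβ)(2n_z+Mβ))`,
   α = 10, β = 0.1. Accumulated component–gene co-occurrences give each
   gene a **membership vector** summing to 1 across modules.
4. **Summaries.** Modules are summarized by weighted-PCA eigengenes (first
   PC of standardized expression, membership-weighted), with stability
   profiles across membership cutoffs, hypergeometric enrichment,
   perplexity against ontology-derived gene classes, a usefulness score
   `U = Σ score_i/log2(N_i) − log10(unplaced)`, and a census of high-MIC /
   low-|r| pairs that quantifies the non-linear fraction of a network.

A simplified WGCNA-style baseline (|r|^power adjacency → topological
overlap → average-linkage clustering → eigengene merging) is included for
comparison, along with synthetic-data generators that plant overlapping
modules, the relationship archetypes above, and GxE mixtures with ground
truth.

## Worked example

Simulate a small panel with one linear module and one GxE module (treatment
shifts the latent activity and flips half the members' response sign), then
fit two components:

```r
library(micanet)
sim <- simulate_expression(simulation_design(
  n_samples = 100,
  modules = list(module_spec(15, "linear", noise_sd = 0.1),
                 module_spec(15, "gxe", noise_sd = 0.05)),
  n_background_genes = 6, seed = 7))
fit <- mica(sim$expr, n_modules = 2, hard_threshold = 0.5,
            burn_in = 2000, sampling_iters = 10000, seed = 7)
summary(fit)
#> MICA fit: 210 links at hard threshold 0.5
#> Hardened module sizes (6 unplaced):
#> M1 M2
#> 15 15
#> Mean max membership: 0.917
#> Eigengene variance explained:
#>    M1    M2
#> 0.828 0.447
```

Both planted modules are recovered intact — including the GxE module, whose
stable/sensitive gene pairs look unrelated to correlation but not to MIC:

```r
gp <- gxe_pairs(sim$truth)[1, ]
c(mic = mic_score(sim$expr[gp$gene1, ], sim$expr[gp$gene2, ])$mic,
  pearson_r = cor(sim$expr[gp$gene1, ], sim$expr[gp$gene2, ]))
#>       mic pearson_r
#>     0.972     0.012
```

The six background genes are unplaced, and membership rows (`coef(fit)`)
show the fuzziness directly: module genes sit near (1, 0) or (0, 1), while
a background gene sits near (0.5, 0.5). The eigengene variance explained is
high for the linear module (0.83) and lower for the GxE module (0.45),
as expected: a single linear summary cannot capture a sign-flipping module,
which is precisely why the membership matrix, not the eigengene, is the
primary module description.

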