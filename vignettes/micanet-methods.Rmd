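---
title: "Maximal information component analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximal information component analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micanet)
```

# The problem

Co-expression network analysis groups genes whose transcript levels covary
across a panel of conditions or genetic backgrounds into modules. Two
assumptions of correlation-based pipelines conflict with how transcriptional
systems actually behave. First, Pearson correlation only scores linear
dependence, yet real gene pairs show threshold, saturating, and
condition-dependent relationships; in a panel that pools treated and control
samples, a pair whose slope flips sign with treatment (a gene-by-environment,
GxE, interaction) has pooled correlation near zero while being tightly
coupled in each condition. Second, hard clustering puts each gene in exactly
one module, though multi-functional genes genuinely belong to several.

`micanet` addresses both: associations are scored with the maximal
information coefficient (MIC), which detects any strong functional
relationship; and modules are inferred with a link-community Gibbs sampler
(the interaction component model, ICMg) whose output is a fuzzy membership
matrix — each gene has a proportional affiliation to every component. The
`mica()` function runs the full pipeline and returns a fitted object; a
correlation/TOM baseline (`run_baseline()`) and a set of network-quality
statistics (`perplexity()`, `usefulness()`, `module_stability()`,
`nonlinearity_census()`) support method comparison.

# The association measure

For a pair of vectors of length $n$, MIC searches axis-aligned grids on the
rank-ordered data. A grid with $x$ columns and $y$ rows is admissible when
$x \cdot y < n^{0.6}$ (exponent configurable); for each grid the mutual
information of the empirical cell frequencies is computed in bits and divided
by $\log_2 \min(x, y)$, its maximum attainable value at that resolution; MIC
is the maximum normalized value over the search. It lies in $[0, 1]$, equals
1 for any noiseless monotone relationship, 0 for constants, and is invariant
under strictly increasing transforms of either variable because grids act on
ranks.

Numerical choices that matter:

* **Base-2 logs throughout.** The normalizer only cancels the MI's base if
  both use the same base; bits are fixed for both.
* **Strict resolution bound, minimum 2x2.** The bound $x y < n^{0.6}$ is
  strict; the 2x2 family is always admitted so the statistic stays defined
  at very small $n$.
* **Ties.** Cut points are restricted to boundaries between distinct values,
  so tied observations are never split across a cell boundary; grids that
  cannot realize a cut are skipped. No jitter is added.
* **Search modes.** `mode = "exhaustive"` enumerates every admissible grid
  and is the reference; `mode = "heuristic"` equipartitions one axis into
  $q$ rows and finds the exactly optimal column partition by dynamic
  programming over clump boundaries (cutting between two points in the same
  row cannot help, so the restriction is lossless given the rows), run in
  both orientations, with a superclump cap of 15 candidate boundaries per
  allowed column. For $n \le 25$ the admissible grid space is tiny, so the
  heuristic simply enumerates it; the two modes are identical there by
  construction, and the heuristic is bounded above by the exhaustive value
  wherever both run.
* **Purity.** `mic_matrix()` computes pairs independently in a fixed order;
  the result is bit-identical under any evaluation order and permutes with
  the genes.

What MIC can and cannot resolve at panel scale is worth stating plainly: at
$n = 100$ the resolution bound admits at most $\sim 15$ cells, so a
noiseless X-shaped pattern (two crossing lines with the *same* support)
cannot exceed MIC $\approx 0.6$ — each column of any admissible grid still
sees both branches. Condition-dependent pairs become high-MIC when the
condition also displaces the regulator's activity range, which separates the
branches into a V/parabola-like curve (a function, hence MIC $\to$ 1). The
synthetic generator plants exactly this geometry (below).

# Network construction and the sampler

ICMg operates on an unweighted link set, so the association matrix is hard
thresholded: `pick_hard_threshold()` scans cutoffs in steps of 0.05 and
returns the lowest one whose binarized degree distribution passes the
scale-free criterion, signed $R^2 \ge 0.9$. The signed fit regresses
$\log_{10}$ relative frequency on $\log_{10}$ mean connectivity over 10
equal-width degree bins (empty bins dropped) and carries the sign
$-\mathrm{sign}(\mathrm{slope}) R^2$, so only decreasing, power-law-like
distributions score high. Equal-width binning in $k$ and the bin count are
conventions, both configurable. When no cutoff passes — planted-module
simulations, for instance, are deliberately not scale-free — `mica()` falls
back to the best-fitting scanned cutoff and says so.

Each link $l$ carries a latent component label $z_l \in \{1..C\}$. The
collapsed conditional for relabeling one link with endpoints $i_0, j_0$ is

$$p(z_0 \mid \cdot) \propto \frac{n_{z_0}' + \alpha}{N' + C\alpha} \cdot
\frac{(q_{z_0 i_0}' + \beta)(q_{z_0 j_0}' + \beta)}
{(2 n_{z_0}' + 1 + M\beta)(2 n_{z_0}' + M\beta)},$$

where $n_z$ counts links in component $z$, $q_{zi}$ counts component-node
co-occurrences, $M$ is the node count, and primes mean the interrogated link
has been removed. This conditional is exactly the ratio of the collapsed
joint $\prod_z (\alpha)_{n_z} \prod_{z,i} (\beta)_{q_{zi}} /
(M\beta)_{2n_z}$ (rising factorials), which is what the test suite
enumerates on tiny graphs to validate the sampler.

Sampler conventions:

* $\alpha = 10$, $\beta = 0.1$: the method's published defaults, governing
  component-size balance and per-node membership spread.
* A *sweep* is one pass over all links in fixed input order (determinism;
  random visit order would need a second RNG stream for no measurable
  benefit at these sizes). Defaults: 40,000 burn-in sweeps, then 10,000
  sweeps sampled every 10. Tests and the desk-scale studies use 2,000 /
  10,000, which the planted-graph checks show is ample at a few thousand
  links.
* Initialization draws a single global component distribution from
  Dirichlet($\alpha$) and assigns links multinomially.
* Membership accumulates the co-occurrence table $q$ over retained samples;
  gene $i$'s membership in component $z$ is its normalized accumulated
  co-occurrence. Genes with no links get uniform rows and are flagged
  `unsupported`; `harden()` sends them to the unplaced bucket.
* Empty components persist (no respawning); label switching between modes
  is possible in principle but is glacial on graphs of hundreds of links,
  and all reported statistics (co-placement, ARI, stability) are
  label-invariant.

# Eigengenes

A module summary is the first principal component of its (gene-wise
standardized) expression. The weighted variant eigendecomposes
$C = X^\top W X / \sum w$ with $W = \mathrm{diag}(w)$, the one weighted-PCA
convention that reduces exactly to the unweighted case at uniform weights;
membership columns serve as $w$, so every gene contributes in proportion to
its affiliation. Signs are fixed by orienting each eigengene to correlate
non-negatively with the weighted mean module profile, making outputs
deterministic; stability statistics use $|{\rm cor}|$ anyway, so a sign flip
can never depress them. Genes constant across samples carry no direction and
are zero-weighted with a warning.

`stability_profile()` recomputes unweighted eigengenes for the gene sets
passing each membership cutoff (default 0.10–0.90 by 0.05) and reports mean
absolute correlations between cutoffs and to the weighted eigengene. A flat,
near-1 profile over a range of cutoffs means any binary partition in that
range represents the fuzzy decomposition faithfully;
`optimal_cutoff_scan()` then picks the usefulness-maximizing cutoff among
the stable ones (ties to the lowest, favoring inclusiveness).

# The comparison baseline

The baseline follows the classical correlation pipeline: $|r|$ (unsigned —
the historical default, consistent with the high powers the soft-thresholding
step selects), raised to the first power passing the scale-free criterion;
topological overlap
$\mathrm{TOM}_{ij} = (\sum_{u \notin \{i,j\}} A_{iu}A_{uj} + A_{ij}) /
(\min(k_i, k_j) + 1 - A_{ij})$; average-linkage clustering of
$1 - \mathrm{TOM}$; a static cut to a requested module count with groups
below `min_size` (default 20) unplaced; and iterative merging of modules
whose eigengenes correlate above 0.8. The static cut replaces dynamic tree
cutting, whose reimplementation is out of scope here; the practical
consequence is outlier sensitivity — background genes occupy the top slices
of an average-linkage tree, so the cut count must exceed the expected module
count by roughly the number of stray genes. On the 200-gene studies a cut of
20 with `min_size = 20` behaves like a practitioner's configuration; cutting
at the planted count merges real modules and should not be used when
background genes are present.

# Module-quality statistics

*Standard gene classes.* The perplexity reference classes are derived from a
gene-annotation DAG by walking from the root toward the leaves, counting
only network genes: descent stops where a child falls below 30 genes and the
parent is emitted unless it exceeds 300 (too broad); adequately sized leaves
are emitted directly. A minimal OBO reader (`read_obo()`) and a two-column
annotation table loader are provided; a synthetic ontology generator stands
in when no ontology is available.

*Perplexity* is $2^{-\sum_l \log_2 \hat P(c_l \mid r_l) / N}$ over the
module-by-class confusion matrix with row-normalized $\hat P$. Events are
gene-level by default — every placed gene contributes one event per
(module, class) it occupies, so multi-assigned genes count once per module —
with a cell-level variant behind a flag; both give 1 on a diagonal confusion
matrix and $k$ on one uniform over $k$ classes, which pins the log base.
The normalized value multiplies by the fraction of dataset genes the method
placed, making methods with different coverage comparable; comparisons
should use it.

*Enrichment and usefulness.* Per-module enrichment is the maximum
$-\log_{10}$ one-sided hypergeometric over-representation p-value over
terms — the negative-log reading of a DAVID-style score, computable offline.
Usefulness is $U = \sum_i \mathrm{score}_i / \log_2 N_i - \log_{10} M$ with
$N_i$ the module size and $M$ the unplaced count: small, strongly enriched
modules are worth more, and abandoning genes costs. Singleton modules are
excluded ($\log_2 1 = 0$); $M = 0$ is treated as $M = 1$.

*Stability* between two partitions is the one-sided Fisher exact p-value of
each module-pair overlap against the shared universe.

*The non-linearity census* collects all pairs with MIC above a cutoff
(default 0.9) and histograms their $|r|$: mass below 0.6 indicates
relationships only the information-theoretic score sees; mass above 0.9,
near-perfect linear pairs. $|r|$ rather than signed $r$ is used since the
unsigned network treats them alike. An optional seeded subsample equalizes
census sizes across datasets.

# What the synthetic data emulates — and what it does not

`simulate_expression()` plants modules driven by independent standard-normal
latent factors across samples, with member genes following one of five
response archetypes: linear, high-threshold (logistic step at the factor
median, sharpness 0.1), logarithmic, quadratic, and gxe. Noise is additive
Gaussian on a unit-variance signal (default sd 0.1, i.e. 10% of signal);
overlap genes mix the first two factors equally and are the planted
multi-module cases; background genes are pure noise.

The gxe archetype encodes the condition-dependent geometry discussed above:
treatment shifts the module's latent activity by `condition_shift` (default
1.2 sd — a strong but ordinary treatment effect) and flips the response sign
of the *sensitive* half of the members in condition B. A sensitive/stable
pair pooled over conditions then traces a parabola-like curve: pooled
$|r| \approx 0.1$, MIC near 1 at $n = 100$. These mixed pairs are what
`gxe_pairs()` returns and what the census should flag. A pure opposite-slope
X without the activity shift is *not* used, deliberately: its MIC ceiling at
panel sizes (~0.6) sits below any sensible hard threshold's comfort zone,
and the displaced-support geometry is the one that matches observed
treated-vs-control scatter plots.

The generator is a pure function of design and seed. It does **not**
emulate: microarray probe effects or batch structure, heteroscedastic or
heavy-tailed noise, correlated latent factors, genetic relatedness between
panel strains, or realistic scale-free co-expression degree distributions
(planted blocks are deliberately modular, which is exactly why the
scale-free scan fails on them and the fallback threshold path runs). Passing
tests on this data therefore demonstrates the machinery — estimator
correctness, sampler correctness, the discriminative advantage on
condition-dependent signal — not performance on any real tissue panel.

# Study conditions used by the tests and acceptance script

Desk-scale sizes were chosen so the full pipeline exercises every code path
in minutes: 200 genes x 100 samples (42/42/42-gene linear, linear,
threshold modules; a 34-gene gxe module at noise 0.05; 10 overlap and 30
background genes); a 200-node, 4-block planted graph (within/between edge
probabilities 0.2/0.005) for sampler recovery; 500-node
preferential-attachment graphs for the scale-free fit; reduced sampler
schedule (2,000 burn-in, 10,000 sampling sweeps, thin 10). Co-placement of a
gene set is reported as the fraction of its pairs sharing a module
(`pair_coplacement()`), which is 1 for an intact module, just under 0.5 for
a clean two-way split, and 0 for scattered or unplaced genes — a
label-invariant statistic that distinguishes those three outcomes where a
max-share count cannot.

# Known limitations

* The number of components $C$ must be supplied; the model cannot infer it.
* MIC is $O(p^2)$ pairs with a nontrivial per-pair search; the compiled
  estimator handles desk-scale inputs in seconds and thousands of genes in
  hours, not the millions of pairs of a full transcriptome.
* No p-values accompany MIC scores (the published lookup tables are
  external) and enrichment p-values are reported raw, per the usefulness
  definition.
* The static baseline cut is not dynamic tree cutting; module counts from it
  are configuration-dependent and are not comparable to published counts
  from the dynamic algorithm.
* The hard-threshold fallback (best-fitting cutoff when none passes 0.9) is
  a pragmatic default for non-scale-free inputs and should be reviewed when
  it triggers.
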