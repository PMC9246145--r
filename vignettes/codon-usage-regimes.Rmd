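---
title: "Separating mutation-bias regimes from selection on synonymous codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating mutation-bias regimes from selection on synonymous codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonregimes)
```

## The problem

Synonymous codons are used non-uniformly. Two forces shape the pattern:
non-adaptive nucleotide biases (mutation bias, biased gene conversion,
replication-timing effects — anything that does not covary with expression)
and natural selection for translational efficiency, which is strongest in
highly expressed genes. Most codon models assume the non-adaptive component
is uniform across the genome. When it is not — long GC-rich or GC-poor
chromosomal tracts are common in yeasts and other eukaryotes — the variation
in codon usage that a model attributes to expression-correlated selection is
partly mutational, and estimates of selection (and of which codon is
"optimal") can be badly wrong.

`codonregimes` implements a pipeline to detect and absorb such intragenomic
heterogeneity using coding sequences alone:

1. **Regime clustering** (`cluster_genes()`): correspondence analysis (CA) of
   per-gene codon frequencies, CLARA k-medoids on the first four principal
   coordinates, clusters labelled `lower_gc3` / `higher_gc3` by median GC3.
2. **Model fitting** (`fit_roc_semppr()`): a Bayesian
   selection–mutation–drift multinomial model in which the probability of
   codon $i$ in gene $g$ within a synonymous family is
   $$p_{i,g} = \frac{e^{-\Delta M_i - \Delta\eta_i \phi_g}}
     {\sum_j e^{-\Delta M_j - \Delta\eta_j \phi_g}},$$
   with codon-specific mutation bias $\Delta M$ and selection $\Delta\eta$
   measured against each family's alphabetically last codon, and latent
   per-gene expression $\phi_g$ following a lognormal with mean fixed at 1.
   The *ConstMut* variant fits one genome-wide $\Delta M$ set; *VarMut* gives
   each cluster its own $\Delta M$ while sharing $\Delta\eta$ (all genes use
   one tRNA pool, so translational selection is common).
3. **Comparison and landscape statistics** (`compare_models()`,
   `window_profile()`): Spearman correlation of predicted expression against
   empirical abundances, DIC, optimal-codon identity, AT-partner re-scaled
   coefficients, and GC3 / cluster-composition profiles in 20-gene windows
   along chromosomes.

Serine is split into TCN and AGY families (exchanging them requires a
non-serine intermediate under weak mutation); for CTG-clade yeasts
(`genetic_code("ctg_ser")`) CTG is a synonym-less serine group of its own.

## Model, priors and sampler

The per-gene codon counts are multinomial within each family with the
probabilities above (the normalizing constant is dropped everywhere — it is
constant in the parameters, so likelihood ratios and DIC differences are
unaffected). Priors: free coefficients $\Delta M, \Delta\eta \sim
\mathcal N(0, 10^2)$ (near-flat over the plausible range; halving or
widening this prior moves toy-fit posteriors negligibly), and
$\log\phi_g \sim \mathcal N(-s_\phi^2/2, s_\phi^2)$ so $E[\phi] = 1$.
The spread $s_\phi$ is a *fixed* constant of the configuration
(default 1.5, a typical spread for yeast expression); the gauge section
below explains why it is part of the prior specification rather than an
estimated parameter.

Sampling is adaptive Metropolis-within-Gibbs, with the likelihood kernels in
C++: a joint random-walk on all $\log\phi_g$ accepted per gene (genes are
conditionally independent), per-family blocks for $\Delta M$ (per regime)
and $\Delta\eta$. Proposal scales adapt
toward 30% acceptance during burn-in only, preserving detailed balance
afterwards. The desk-scale default is 20,000 iterations, 5,000 burn-in,
keeping every 10th sample, two chains; `mcmc_config(preset = "reference")`
switches to the long-chain setting (200,000 / 50,000 / 10) appropriate for
whole genomes. Predicted expression is the posterior mean of $\phi$.

Two structural features of this posterior deserve explanation, because the
package handles both explicitly rather than hoping chains behave.

**The mirror mode.** Negating every $\Delta\eta$ while inverting the ranks
of $\phi$ produces a second, locally stable mode (low-expression genes play
the role of high-expression ones). Random-walk chains fall into either mode
at random and never leave. `fit_roc_semppr()` therefore runs a short
*orientation pilot*: one pilot chain from a standard start, a second from
the mirror image of the first one's final state; the orientation with the
lower mean deviance anchors the production chains (odd chains continue from
the anchor, even chains jitter the coefficients and redraw $\phi$ from the
prior, so starting points remain dispersed). A reflection move proposed
every 100 iterations additionally lets a chain cross between modes if the
data prefer the other one.

**The expression gauge.** The likelihood is exactly invariant under
$\phi \to (\phi - \kappa)/\lambda$, $\Delta\eta \to \lambda\Delta\eta$,
$\Delta M \to \Delta M + \kappa\Delta\eta$: the location and scale of
$\phi$ are conventions, not estimable quantities, and the lognormal spread
is identified only through third-and-higher moments of the expression
configuration — far too weakly to restrain an MCMC chain. Left
unconstrained, the prior slowly drags chains along this ridge into a
degenerate funnel (expression compressed, selection coefficients inflated);
we measured drifts that corrupt $\Delta M$ estimates while leaving
expression *ranks* untouched, and a sampled $s_\phi$ diffuses with them.
The sampler therefore (i) treats $s_\phi$ as a fixed prior constant and
(ii) pins the gauge every iteration by the exact invariance transform,
projecting onto the orbit point that matches the prior's first two moments
in the model's own scale: $\overline{\phi} = 1$ and
$\mathrm{var}(\log\phi) = s_\phi^2$. The spread condition is strictly
monotone in the shift, so the projection is unique for any shape of the
expression configuration (warm-started Newton with a bisection fallback).
Reported $\Delta M$, $\Delta\eta$ and $\phi$ are all in this gauge, which
is also the gauge of the generative convention. Misspecifying $s_\phi$
re-scales coefficients smoothly but leaves expression ranks, optimal-codon
calls and model contrasts unchanged.

Convergence is assessed across chains: Gelman–Rubin potential scale
reduction for every free coefficient, plus the Spearman
correlation of the chains' posterior-mean expression vectors
(`convergence_check()`). DIC uses $p_D = \bar D - D(\bar\theta)$ with
$D(\bar\theta)$ evaluated at the posterior means of all parameters
(expression included).

## Clustering choices

CA rows are per-gene *frequencies* (rows sum to one), so gene length does
not set row mass; RSCU is deliberately not used as CA input because it is
known to introduce artifacts. Zero-mass codon columns are dropped with a
warning. Clustering uses the first four row principal coordinates
(coordinates scaled by the singular values; `scale = "standard"` is
available). CLARA draws 5 subsets of half the genes — the subset fraction
follows the original analysis, the subset count is the classic CLARA
default — runs PAM (BUILD+SWAP, Euclidean distance, ties broken by lowest
index) on each, assigns all genes to the nearest candidate medoids, and
keeps the medoid set with the smallest mean dissimilarity. `k = 2` is the
default; `k = 3` is supported and, as expected, usually dilutes the
expression signal by splitting the high-expression genes.

## The synthetic-genome generator

All validation runs on genomes from `simulate_genome()`, which emulates the
data structure the analysis assumes: lognormal expression
($s_\phi = 1.5$), gene lengths discretized-lognormal with median 400 codons
(a typical yeast CDS scale), codon counts multinomial per family under the
equilibrium probabilities with regime-specific $\Delta M$ and shared
$\Delta\eta$, regimes laid out in geometric blocks along chromosomes, and
observed expression equal to truth times lognormal noise
($\sigma_{obs} = 0.5$) — the simplest noise model producing the
rank-correlation validation structure the analysis relies on. Amino-acid
family usage is uniform across families (no biological frequency data is
assumed).

Presets define the study conditions: `single_regime` (1,500 genes,
$\Delta M \sim U(-2,2)$, $\Delta\eta \sim U(-0.5,0.5)$);
`two_regime_strong` (2,000 genes, GC3 shifts of $\mp 0.5$ applied to the
mutation bias of GC-ending codons, chosen so the realized median-GC3 gap
between regimes exceeds 0.1 — the separation above which regime-aware fits
clearly pay off); `two_regime_weak` (shifts $\mp 0.1$, gap near 0.03); and
`null_blocks` (identical coefficients in both nominal regimes, block length
1, so labels are independent of GC3 by construction).

What the generator does *not* emulate: real amino-acid composition,
length–expression correlations, GC-content gradients within genes,
ambiguous bases, annotation errors, or phylogenetic structure. Passing
recovery tests therefore demonstrates the estimator's correctness under the
model's own assumptions, not robustness to their violation.

## What recovery is possible at desk scale

With $\Delta\eta$ uniform on $[-0.5, 0.5]$, ~400 codons per gene spread over
19 multi-codon families, and $s_\phi = 1.5$, the per-gene Fisher information
about $\phi$ is modest, and low-expression genes (the majority, since the
median of a mean-one lognormal with $s = 1.5$ is 0.32) are barely ranked by
their codon counts. Maximizing each gene's likelihood *under the true
coefficients* — the information ceiling no estimator can beat — yields
Spearman($\hat\phi_{MLE}, \phi$) $\approx 0.76$ on this scenario, and the
MCMC posterior means reach that ceiling. Rank recovery of expression at
these settings is therefore bounded near 0.76; the codon-level coefficients
are a different matter — $\Delta\eta$ and $\Delta M$ pool information across
all genes and are recovered with Pearson correlations above 0.95. On
two-regime genomes the contrast of interest (VarMut recovering regime
structure that ConstMut smears) concerns exactly these pooled quantities
and the *relative* ranking improvements, both of which the tests exercise.

## Numerical and policy choices

* Codon counting excludes the initiator ATG (initiation is constrained
  independently of synonymous choice) and the terminal stop; a
  `count_start_codon` switch restores the initiator for compatibility
  checks. Sequences with ambiguity codes are rejected outright so
  multinomial totals stay exact.
* GC3 is computed over all counted sense codons, including 1- and 2-fold
  families.
* Windows: moving windows are centered with truncation at chromosome ends;
  non-overlapping windows keep a trailing partial bin only when it holds at
  least half a window (flagged). Window correlations pool windows across
  chromosomes into one test.
* CAI: reference RSCU values of zero are floored at 0.01 before weights are
  formed; synonym-less families are excluded from CAI and RSCU. The
  CA-based automatic reference set takes the top 5% of genes on the first
  CA axis after orienting it against an expression proxy (total codon count
  when no proxy is given).
* Tie-breaks are deterministic everywhere: PAM swaps by lowest point index,
  optimal codons alphabetically, expression extremes by gene id.
* All randomness flows from explicit seeds; simulation, clustering, fitting
  and the full pipeline are bit-reproducible given the same seed.

## Limitations

The gauge and orientation handling make desk-scale fits reproducible and
interpretable, but the model remains misspecified for real genomes in all
the ways the generator section lists, and DIC — computed from a model fit
without empirical grounding — tends to favor the more flexible VarMut
variant even when added flexibility does not improve expression prediction.
Empirical-expression correlations are the more conservative comparison, and
both are reported. Clustering k is not chosen automatically; over-clustering
demonstrably dilutes the selection signal.
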