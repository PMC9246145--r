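# codonregimes

Quantifying natural selection on synonymous codon usage when non-adaptive
nucleotide biases vary *within* a genome.

## The problem

Codon usage bias reflects both mutation-like forces (mutation bias, biased
gene conversion — anything independent of expression) and translational
selection, which is strongest in highly expressed genes. Models that assume
one genome-wide mutational background misattribute regional nucleotide bias
(GC-rich and GC-poor chromosomal tracts are common in yeasts) to selection,
weakening or inverting the inferred selection on codons and misidentifying
"optimal" codons.

`codonregimes` addresses this with coding sequences alone:

1. **Find candidate mutation regimes** — correspondence analysis of per-gene
   codon frequencies, CLARA k-medoids clustering on the first four principal
   coordinates, clusters labelled by median GC3 (`cluster_genes()`).
2. **Fit a selection–mutation–drift codon model by MCMC** — within each
   synonymous family the probability of codon *i* in gene *g* is

   $$p_{i,g} = \frac{e^{-\Delta M_i - \Delta\eta_i\,\phi_g}}{\sum_j e^{-\Delta M_j - \Delta\eta_j\,\phi_g}}$$

   with codon-specific mutation bias ΔM and selection Δη relative to each
   family's reference codon, and latent lognormal gene expression φ (mean
   1). *ConstMut* fits one ΔM set; *VarMut* fits one ΔM set per regime with
   Δη shared across regimes (`fit_roc_semppr()`).
3. **Compare and localize** — Spearman correlation of predicted expression
   against empirical abundances, DIC, optimal-codon identity, AT- vs
   GC-ending re-scaled coefficients, and GC3 landscapes in 20-gene windows
   along chromosomes (`compare_models()`, `window_profile()`).

A synthetic-genome generator with known ground truth (`simulate_genome()`,
`build_preset()`) backs every stage's validation; no external data are
needed. Intended users: molecular-evolution researchers analysing codon
usage in (non-model) species with annotated coding sequences.

## Worked example

```r
library(codonregimes)

# a two-regime genome: 600 genes, regime-specific GC3 bias in ~50-gene
# blocks, shared selection, lognormal expression (sd of log = 1.5)
sim <- simulate_genome(build_preset("two_regime_strong", n_genes = 600, seed = 8),
                       emit_sequences = FALSE)
sim
#> <synthetic_genome> 'two_regime_strong': 600 genes, 2 regime(s), realized delta median GC3 = 0.1721

# cluster genes into candidate regimes from codon frequencies alone
ra <- cluster_genes(sim$count_table, k = 2, seed = 8)
ra
#> <regime_assignment> k = 2; sizes: higher_gc3=216, lower_gc3=384; delta median GC3 = 0.1724
mean((unname(ra$labels) == "higher_gc3") + 1 == sim$truth$genes$regime)
#> [1] 0.9966667

# fit both model variants and compare against (noisy) observed expression
cfg <- mcmc_config(iterations = 8000, burn_in = 2000, seed = 8)
fit_c <- fit_roc_semppr(sim$count_table, NULL, cfg)            # ConstMut
fit_v <- fit_roc_semppr(sim$count_table, ra, cfg)              # VarMut
emp <- setNames(sim$truth$genes$observed_expression, sim$count_table$gene_ids)
compare_models(fit_c, fit_v, emp)
#> <model_comparison>
#>   Spearman(phi, empirical): ConstMut -0.103, VarMut 0.747 (delta +0.851, 600 genes)
#>   delta DIC (VarMut - ConstMut): -6161.7 (lower DIC is better)
#>   optimal-codon agreement: 26% of families
```

Reading the numbers: with one genome-wide mutation background the
predicted expression actually *anti*-correlates with the observed
abundances (rho = -0.10) — the regime structure masquerades as expression
variation and masks selection; giving each regime its own mutation-bias
coefficients restores a strong rank correlation (rho = 0.75), and DIC
prefers the regime-aware model by thousands of units. The low
optimal-codon agreement between the two fits is itself the finding: the
one-background model identifies a different "optimal" codon in roughly
three quarters of the families.

The end-to-end pipeline (simulate/read → filter → cluster → both fits →
comparison → windows → TSV/JSON reports) is `run_full_analysis()`, and a
thin command-line wrapper with `simulate`, `cluster` and `run-all`
subcommands is installed at `inst/scripts/codonregimes-cli.R`.

## Package layout

- `R/genetic_code.R`, `R/genome_io.R` — codon families (Ser4/Ser2 split,
  CTG-Ser variant), FASTA reading, gene filters, codon counting, GC3.
- `R/ca.R`, `R/kmedoids.R`, `R/regimes.R` — correspondence analysis,
  PAM/CLARA, regime assignment, KS contrast.
- `R/roc_model.R`, `R/mcmc.R`, `src/roc_mcmc.cpp` — the codon model,
  priors, adaptive MCMC (C++ core), DIC, convergence diagnostics,
  AT-partner rescaling, optimal codons.
- `R/simulate.R` — scenarios, presets, the genome generator.
- `R/analysis.R`, `R/pipeline.R`, `R/compare.R` — Spearman/RSCU/CAI,
  window landscapes, model comparison, orchestration.
- `vignettes/codon-usage-regimes.Rmd` — model, priors, sampler design
  (mirror-mode handling, expression gauge fixing), generator assumptions,
  and what desk-scale recovery can and cannot show.
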