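#' Draw codon-model coefficients for a simulation scenario
#'
#' Non-reference mutation-bias coefficients are drawn uniformly on
#' `dm_range` and selection coefficients on `deta_range` (reference codons
#' stay at 0). When several regimes are requested they share the same base
#' draw but differ by a GC3 shift: regime `r` subtracts `gc_shift[r]` from
#' the mutation-bias of every codon whose third base is G or C (relative to
#' its family reference), so positive shifts favor GC-ending codons. This is
#' the knob that creates regimes of different non-adaptive GC bias while
#' selection stays shared.
#'
#' @param genetic_code A [genetic_code()] object.
#' @param n_regimes Number of mutation regimes.
#' @param dm_range,deta_range Uniform ranges for the base draws.
#' @param gc_shift Numeric vector, one GC3 shift per regime (default all 0).
#' @param seed Optional seed.
#' @return An [roc_params()] object with `n_regimes` mutation-bias columns.
#' @export
sample_roc_parameters <- function(genetic_code = codonregimes::genetic_code(),
                                  n_regimes = 1L, dm_range = c(-2, 2),
                                  deta_range = c(-0.5, 0.5),
                                  gc_shift = rep(0, n_regimes), seed = NULL) {
  stopifnot(length(gc_shift) == n_regimes)
  with_seed(seed, {
    codons <- genetic_code$codons
    is_gc3 <- stats::setNames(substr(codons, 3, 3) %in% c("G", "C"), codons)
    dm <- matrix(0, length(codons), n_regimes,
                 dimnames = list(codons, NULL))
    eta <- stats::setNames(rep(0, length(codons)), codons)
    for (fam in multi_codon_families(genetic_code)) {
      nonref <- setdiff(fam$codons, fam$reference)
      base <- runif(length(nonref), dm_range[1], dm_range[2])
      for (r in seq_len(n_regimes)) {
        dm[nonref, r] <- base -
          gc_shift[r] * (is_gc3[nonref] - is_gc3[fam$reference])
      }
      eta[nonref] <- runif(length(nonref), deta_range[1], deta_range[2])
    }
    roc_params(genetic_code, delta_m = dm, delta_eta = eta,
               regime_names = paste0("regime", seq_len(n_regimes)))
  })
}

#' Define a synthetic-genome scenario
#'
#' Collects everything the generator needs: the true codon-model
#' coefficients per regime, the lognormal expression spread, how genes are
#' laid out in regime blocks along chromosomes, gene lengths, and the
#' multiplicative observation noise on expression.
#'
#' @param n_genes Number of genes.
#' @param params True coefficients, an [roc_params()] (its number of
#'   mutation-bias columns sets the number of regimes).
#' @param s_phi Lognormal scale of true expression (location is fixed at
#'   \eqn{-s_\phi^2/2} so expression has mean 1).
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param gene_length_meanlog,gene_length_sdlog Discretized-lognormal gene
#'   length (in codons; defaults give a median of 400 codons, a typical
#'   yeast CDS scale).
#' @param family_weights Named amino-acid-family usage weights (default
#'   uniform over the code's families).
#' @param block_length_mean Mean regime block length in genes (geometric
#'   block lengths; 1 means every gene draws its regime independently).
#' @param regime_proportions Probability of each regime per block.
#' @param sigma_obs Lognormal scale of the multiplicative observation noise
#'   on expression (0 = noise-free).
#' @param seed Default seed for [simulate_genome()].
#' @param name Scenario label.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_genes, params, s_phi = 1.5,
                                n_chromosomes = 8L,
                                gene_length_meanlog = log(400),
                                gene_length_sdlog = 0.3,
                                family_weights = NULL,
                                block_length_mean = 50,
                                regime_proportions = NULL,
                                sigma_obs = 0.5, seed = 1L,
                                name = "custom") {
  stopifnot(inherits(params, "roc_params"), n_genes >= 1L, s_phi > 0,
            block_length_mean >= 1, sigma_obs >= 0)
  n_regimes <- ncol(params$delta_m)
  if (is.null(regime_proportions)) {
    regime_proportions <- rep(1 / n_regimes, n_regimes)
  }
  stopifnot(length(regime_proportions) == n_regimes,
            abs(sum(regime_proportions) - 1) < 1e-8)
  fam_ids <- names(params$genetic_code$families)
  if (is.null(family_weights)) {
    family_weights <- stats::setNames(rep(1 / length(fam_ids), length(fam_ids)),
                                      fam_ids)
  }
  stopifnot(all(names(family_weights) %in% fam_ids),
            abs(sum(family_weights) - 1) < 1e-8, all(family_weights >= 0))
  structure(
    list(
      n_genes = as.integer(n_genes), params = params, s_phi = s_phi,
      n_chromosomes = as.integer(n_chromosomes),
      gene_length_meanlog = gene_length_meanlog,
      gene_length_sdlog = gene_length_sdlog,
      family_weights = family_weights,
      block_length_mean = block_length_mean,
      regime_proportions = regime_proportions,
      sigma_obs = sigma_obs, seed = as.integer(seed), name = name
    ),
    class = "simulation_scenario"
  )
}

#' Named simulation presets
#'
#' Four study conditions used throughout the package's validation:
#' \describe{
#'   \item{single_regime}{1,500 genes under one mutation regime; coefficients
#'     from `U(-2, 2)` (mutation) and `U(-0.5, 0.5)` (selection),
#'     `s_phi = 1.5`.}
#'   \item{two_regime_strong}{2,000 genes in two regimes laid out in ~50-gene
#'     blocks; regime GC3 shifts of -0.5/+0.5 give a realized
#'     median-GC3 separation above 0.1 between regimes.}
#'   \item{two_regime_weak}{As above with shifts -0.1/+0.1, targeting a
#'     median-GC3 separation near 0.03.}
#'   \item{null_blocks}{2,000 genes with two *nominal* regimes whose
#'     coefficients are identical and whose blocks have length 1: regime
#'     labels are independent of GC3 by construction.}
#' }
#'
#' @param name Preset name.
#' @param n_genes Optional override of the preset's gene count.
#' @param seed Seed used both for the coefficient draw and as the scenario's
#'   default simulation seed.
#' @return A [simulation_scenario()].
#' @export
build_preset <- function(name = c("single_regime", "two_regime_strong",
                                  "two_regime_weak", "null_blocks"),
                         n_genes = NULL, seed = 1L) {
  name <- match.arg(name)
  gcode <- genetic_code()
  par_seed <- seed + 77003L
  sc <- switch(name,
    single_regime = simulation_scenario(
      n_genes = n_genes %||% 1500L,
      params = sample_roc_parameters(gcode, 1L, seed = par_seed),
      s_phi = 1.5, seed = seed, name = name
    ),
    two_regime_strong = simulation_scenario(
      n_genes = n_genes %||% 2000L,
      params = sample_roc_parameters(gcode, 2L, gc_shift = c(-0.5, 0.5),
                                     seed = par_seed),
      s_phi = 1.5, block_length_mean = 50, seed = seed, name = name
    ),
    two_regime_weak = simulation_scenario(
      n_genes = n_genes %||% 2000L,
      params = sample_roc_parameters(gcode, 2L, gc_shift = c(-0.1, 0.1),
                                     seed = par_seed),
      s_phi = 1.5, block_length_mean = 50, seed = seed, name = name
    ),
    null_blocks = simulation_scenario(
      n_genes = n_genes %||% 2000L,
      params = sample_roc_parameters(gcode, 2L, gc_shift = c(0, 0),
                                     seed = par_seed),
      s_phi = 1.5, block_length_mean = 1, seed = seed, name = name
    )
  )
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample true gene expression
#'
#' Lognormal with location \eqn{-s_\phi^2/2}, so the expectation is exactly 1
#' regardless of `s_phi` (the model's evolutionary-average convention).
#'
#' @param n Number of genes.
#' @param s_phi Lognormal scale, `> 0`.
#' @param seed Optional seed.
#' @return Positive numeric vector of length `n`.
#' @export
sample_expression <- function(n, s_phi, seed = NULL) {
  if (!is.numeric(s_phi) || s_phi <= 0) stop("'s_phi' must be > 0")
  with_seed(seed, rlnorm(n, meanlog = -s_phi^2 / 2, sdlog = s_phi))
}

#' Lay out genes in regime blocks along chromosomes
#'
#' Genes are split evenly across chromosomes in order; each chromosome is
#' filled with contiguous blocks whose lengths are geometric with mean
#' `block_length_mean` and whose regimes are drawn from
#' `regime_proportions`. Block length 1 yields independent per-gene regimes
#' (no physical clustering).
#'
#' @param n_genes,n_chromosomes Genome layout.
#' @param block_length_mean Mean block length in genes (`>= 1`).
#' @param regime_proportions Per-regime probability (sums to 1).
#' @param seed Optional seed.
#' @return Data.frame `chromosome`, `position` (1-based ordinal per
#'   chromosome), `regime` (integer).
#' @export
sample_regime_blocks <- function(n_genes, n_chromosomes, block_length_mean,
                                 regime_proportions, seed = NULL) {
  stopifnot(block_length_mean >= 1)
  with_seed(seed, {
    chrom_sizes <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1L)))
    n_regimes <- length(regime_proportions)
    out <- vector("list", n_chromosomes)
    for (ch in seq_len(n_chromosomes)) {
      size <- chrom_sizes[ch]
      regs <- integer(0)
      while (length(regs) < size) {
        len <- if (block_length_mean == 1) 1L else
          1L + rgeom(1L, 1 / block_length_mean)
        reg <- sample.int(n_regimes, 1L, prob = regime_proportions)
        regs <- c(regs, rep(reg, len))
      }
      out[[ch]] <- data.frame(
        chromosome = sprintf("chr%02d", ch),
        position = seq_len(size),
        regime = regs[seq_len(size)]
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate one gene's codon counts
#'
#' Codons are allocated to amino-acid families by a multinomial draw over the
#' scenario's family weights; within each synonymous family the member counts
#' are multinomial with the equilibrium probabilities of
#' [codon_probabilities()] under the gene's regime-specific mutation bias and
#' the shared selection coefficients.
#'
#' @param scenario A [simulation_scenario()].
#' @param phi True expression of the gene.
#' @param regime Integer regime of the gene.
#' @param length_codons Number of (sense) codons to draw.
#' @param seed Optional seed.
#' @return Named integer count vector over the 61 sense codons.
#' @export
simulate_gene_counts <- function(scenario, phi, regime, length_codons,
                                 seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  with_seed(seed, {
    gcode <- scenario$params$genetic_code
    counts <- stats::setNames(rep(0L, length(gcode$codons)), gcode$codons)
    w <- scenario$family_weights
    alloc <- stats::rmultinom(1L, length_codons, w)[, 1L]
    for (fid in names(w)[alloc > 0L]) {
      fam <- gcode$families[[fid]]
      if (fam$size == 1L) {
        counts[fam$codons] <- counts[fam$codons] + alloc[fid]
      } else {
        p <- codon_probabilities(scenario$params, fid, phi, regime)
        counts[fam$codons] <- counts[fam$codons] +
          stats::rmultinom(1L, alloc[fid], p)[, 1L]
      }
    }
    counts
  })
}

#' Add multiplicative observation noise to expression
#'
#' Stands in for measured mRNA abundances (TPM-like): the true expression is
#' multiplied by lognormal noise of scale `sigma_obs`. With `sigma_obs = 0`
#' the observation equals the truth.
#'
#' @param phi True expression vector.
#' @param sigma_obs Noise scale, `>= 0`.
#' @param seed Optional seed.
#' @return Noisy abundance vector of the same length.
#' @export
simulate_observed_expression <- function(phi, sigma_obs, seed = NULL) {
  if (sigma_obs < 0) stop("'sigma_obs' must be >= 0")
  if (sigma_obs == 0) return(phi)
  with_seed(seed, phi * rlnorm(length(phi), 0, sigma_obs))
}

#' Simulate a whole synthetic genome with known truth
#'
#' Draws expression, regime block structure, gene lengths and codon counts
#' for every gene, optionally back-translates each gene into a CDS (ATG
#' prepended, TAA appended, codon order shuffled) for FASTA round-trip use,
#' and records the full ground truth alongside.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Seed (default: the scenario's); the whole genome is a
#'   deterministic function of scenario + seed.
#' @param emit_sequences Build CDS strings (set `FALSE` to skip the string
#'   assembly when only counts are needed).
#' @return Object of class `synthetic_genome`: `scenario`, `count_table` (a
#'   `codon_count_table` with coordinates), `records` (data.frame `gene_id`,
#'   `sequence` when emitted, `chromosome`, `position`), `truth` (list with
#'   per-gene data.frame `genes` — regime, phi, observed expression, gc3 —
#'   the true `params`, `s_phi`, and `delta_median_gc3`, the realized
#'   between-regime difference of median GC3).
#' @export
simulate_genome <- function(scenario, seed = scenario$seed,
                            emit_sequences = TRUE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  with_seed(seed, {
    gcode <- scenario$params$genetic_code
    n <- scenario$n_genes
    n_regimes <- ncol(scenario$params$delta_m)

    layout <- sample_regime_blocks(n, scenario$n_chromosomes,
                                   scenario$block_length_mean,
                                   scenario$regime_proportions)
    phi <- sample_expression(n, scenario$s_phi)
    lengths <- pmax(30L, as.integer(round(rlnorm(n, scenario$gene_length_meanlog,
                                                 scenario$gene_length_sdlog))))
    gene_ids <- sprintf("g%05d", seq_len(n))

    counts <- matrix(0L, n, length(gcode$codons),
                     dimnames = list(gene_ids, gcode$codons))
    for (g in seq_len(n)) {
      counts[g, ] <- simulate_gene_counts(scenario, phi[g], layout$regime[g],
                                          lengths[g])
    }
    observed <- simulate_observed_expression(phi, scenario$sigma_obs)

    sequences <- NULL
    if (emit_sequences) {
      sequences <- vapply(seq_len(n), function(g) {
        cods <- rep(gcode$codons, counts[g, ])
        paste0("ATG", paste(sample(cods), collapse = ""), "TAA")
      }, character(1))
    }

    gc3 <- gc3_percent(counts)
    med_by_regime <- vapply(seq_len(n_regimes), function(r) {
      stats::median(gc3[layout$regime == r])
    }, numeric(1))

    records <- data.frame(
      gene_id = gene_ids,
      chromosome = layout$chromosome,
      position = layout$position,
      stringsAsFactors = FALSE
    )
    if (emit_sequences) records$sequence <- sequences

    count_table <- structure(
      list(
        gene_ids = gene_ids, counts = counts,
        gc3 = stats::setNames(gc3, gene_ids),
        coords = records[, c("gene_id", "chromosome", "position")],
        genetic_code = gcode
      ),
      class = "codon_count_table"
    )

    truth_genes <- data.frame(
      gene_id = gene_ids,
      chromosome = layout$chromosome,
      position = layout$position,
      regime = layout$regime,
      phi = phi,
      observed_expression = observed,
      length_codons = lengths,
      gc3 = gc3,
      stringsAsFactors = FALSE
    )

    structure(
      list(
        scenario = scenario,
        count_table = count_table,
        records = records,
        truth = list(
          genes = truth_genes,
          params = scenario$params,
          s_phi = scenario$s_phi,
          delta_median_gc3 = max(med_by_regime) - min(med_by_regime)
        )
      ),
      class = "synthetic_genome"
    )
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> '", x$scenario$name, "': ", x$scenario$n_genes,
      " genes, ", ncol(x$scenario$params$delta_m), " regime(s), realized ",
      "delta median GC3 = ", sprintf("%.4f", x$truth$delta_median_gc3), "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic genome to disk
#'
#' Emits the CDS FASTA, gene metadata TSV (`gene_id`, `chromosome`,
#' `position`), observed-expression TSV, per-gene truth TSV, true
#' coefficient TSV and a scenario JSON, so recovery analyses never need the
#' generator's internals.
#'
#' @param genome A [simulate_genome()] result (with sequences emitted).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(genome$records$sequence)) {
    stop("genome was simulated with emit_sequences = FALSE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "cds.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_params = file.path(dir, "truth_params.tsv"),
    scenario = file.path(dir, "scenario.json")
  )
  write_cds_fasta(genome$records, paths["fasta"])
  write.table(genome$records[, c("gene_id", "chromosome", "position")],
              paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(gene_id = genome$truth$genes$gene_id,
               expression = genome$truth$genes$observed_expression),
    paths["expression"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(genome$truth$genes, paths["truth_genes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  pars <- genome$truth$params
  par_df <- data.frame(
    codon = rownames(pars$delta_m),
    family = unname(pars$genetic_code$codon_to_family[rownames(pars$delta_m)]),
    pars$delta_m,
    delta_eta = unname(pars$delta_eta),
    check.names = FALSE
  )
  write.table(par_df, paths["truth_params"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  sc <- genome$scenario
  jsonlite::write_json(
    list(
      name = sc$name, n_genes = sc$n_genes, s_phi = sc$s_phi,
      n_chromosomes = sc$n_chromosomes,
      gene_length_meanlog = sc$gene_length_meanlog,
      gene_length_sdlog = sc$gene_length_sdlog,
      block_length_mean = sc$block_length_mean,
      regime_proportions = sc$regime_proportions,
      sigma_obs = sc$sigma_obs, seed = sc$seed,
      delta_median_gc3 = genome$truth$delta_median_gc3
    ),
    paths["scenario"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
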