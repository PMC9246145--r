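test_that("sampled expression has mean one and is seed-reproducible", {
  phi <- sample_expression(1e5, s_phi = 1.5, seed = 1)
  se <- sd(phi) / sqrt(length(phi))
  expect_lt(abs(mean(phi) - 1), 3 * se)
  expect_identical(phi, sample_expression(1e5, 1.5, seed = 1))
  # s_phi -> 0 concentrates at 1
  expect_lt(max(abs(sample_expression(100, 1e-4, seed = 2) - 1)), 1e-3)
  expect_error(sample_expression(10, 0), "s_phi")
})

test_that("regime blocks respect layout and block-length extremes", {
  # one huge block per chromosome
  lay <- sample_regime_blocks(200, 4, block_length_mean = 1e6,
                              regime_proportions = c(0.5, 0.5), seed = 3)
  per_chrom <- tapply(lay$regime, lay$chromosome, function(r) length(unique(r)))
  expect_true(all(per_chrom == 1))
  expect_equal(nrow(lay), 200L)
  expect_true(all(tapply(lay$position, lay$chromosome, function(p)
    identical(p, seq_along(p)))))

  # block length 1: regimes i.i.d., runs are short
  lay1 <- sample_regime_blocks(2000, 4, 1, c(0.5, 0.5), seed = 4)
  runs <- rle(lay1$regime)$lengths
  expect_lt(mean(runs), 2.5)

  # mean block 50: long runs dominate
  lay50 <- sample_regime_blocks(2000, 4, 50, c(0.5, 0.5), seed = 5)
  expect_gt(mean(rle(lay50$regime)$lengths), 10)
})

test_that("pooled simulated codon frequencies match the model probabilities", {
  gc <- genetic_code()
  pars <- sample_roc_parameters(gc, 1, seed = 40)
  sc <- simulation_scenario(1, pars, s_phi = 1.5, name = "freqcheck")
  phi <- 2.3
  total <- 0
  acc <- setNames(rep(0, 61), gc$codons)
  for (s in 1:20) {
    cnt <- simulate_gene_counts(sc, phi, 1, 5000, seed = s)
    acc <- acc + cnt
    total <- total + 5000
  }
  for (fid in c("Ala", "Leu", "Lys", "Ser4")) {
    fam <- gc$families[[fid]]
    p <- codon_probabilities(pars, fid, phi)
    n_f <- sum(acc[fam$codons])
    obs <- acc[fam$codons] / n_f
    se <- sqrt(p * (1 - p) / n_f)
    expect_true(all(abs(obs - p) < 4 * se + 1e-9))
  }
})

test_that("strong selection saturates the favored codon", {
  gc <- genetic_code()
  pars <- roc_params(gc, delta_eta = c(AGC = -10))
  sc <- simulation_scenario(1, pars, name = "sat")
  cnt <- simulate_gene_counts(sc, 5, 1, 4000, seed = 1)
  expect_equal(unname(cnt[["AGT"]]), 0)
})

test_that("emitted FASTA re-read through the counting path matches exactly", {
  sim <- simulate_genome(build_preset("two_regime_weak", n_genes = 30,
                                      seed = 21))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(sim$records, path)
  rec <- read_cds_fasta(path)
  flt <- filter_genes(rec)
  expect_identical(nrow(flt$retained), 30L) # all simulated genes are canonical
  tab <- build_count_table(flt$retained)
  expect_identical(tab$counts, sim$count_table$counts)
  expect_equal(tab$gc3, sim$count_table$gc3)
})

test_that("genomes are byte-identical under the same scenario and seed", {
  a <- simulate_genome(build_preset("two_regime_strong", n_genes = 40,
                                    seed = 17))
  b <- simulate_genome(build_preset("two_regime_strong", n_genes = 40,
                                    seed = 17))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("observation noise behaves at its limits", {
  phi <- sample_expression(500, 1.5, seed = 6)
  expect_identical(simulate_observed_expression(phi, 0), phi)
  obs <- simulate_observed_expression(phi, 0.5, seed = 7)
  rho <- cor(phi, obs, method = "spearman")
  expect_gt(rho, 0.8)
  expect_lt(rho, 1)
  # ranks invariant under monotone transforms
  expect_equal(cor(phi, log(obs), method = "spearman"), rho)
})

test_that("GC3 in the strong preset separates regimes stochastically", {
  sim <- simulate_genome(build_preset("two_regime_strong", n_genes = 500,
                                      seed = 23),
                         emit_sequences = FALSE)
  g <- sim$truth$genes
  expect_gte(sim$truth$delta_median_gc3, 0.1)
  q <- quantile(g$gc3[g$regime == 2], c(0.25, 0.5, 0.75))
  p <- quantile(g$gc3[g$regime == 1], c(0.25, 0.5, 0.75))
  expect_true(all(q > p))
})

test_that("written genomes carry a consistent truth bundle", {
  sim <- simulate_genome(build_preset("single_regime", n_genes = 12, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_genome(sim, dir)
  expect_true(all(file.exists(paths)))
  tg <- read.delim(paths[["truth_genes"]])
  expect_identical(tg$gene_id, sim$truth$genes$gene_id)
  meta <- jsonlite::read_json(paths[["scenario"]])
  expect_equal(meta$n_genes, 12L)
})
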