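test_that("Spearman correlation matches Pearson on ranks", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  set.seed(50)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(spearman_cor(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_warning(res <- spearman_cor(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("RSCU follows its defining ratio", {
  gc <- genetic_code()
  counts <- setNames(rep(0L, 61), gc$codons)
  counts[c("GCA", "GCC", "GCG", "GCT")] <- c(3L, 1L, 0L, 0L)
  counts[c("AGC", "AGT")] <- c(0L, 5L)
  counts[c("TCA", "TCC", "TCG", "TCT")] <- 2L
  r <- rscu(counts, gc)
  expect_equal(r$rscu[match(c("GCA", "GCC", "GCG", "GCT"), r$codon)],
               c(3, 1, 0, 0), tolerance = 1e-12)
  expect_equal(r$rscu[match(c("AGC", "AGT"), r$codon)], c(0, 2),
               tolerance = 1e-12)
  expect_equal(r$rscu[match("TCA", r$codon)], 1, tolerance = 1e-12)
  # empty family flagged as NA; singletons excluded entirely
  expect_true(all(is.na(r$rscu[r$family == "Lys"])))
  expect_false(any(r$family %in% c("Met", "Trp")))
  # scaling all counts leaves RSCU unchanged
  expect_equal(rscu(counts * 7L, gc)$rscu, r$rscu, tolerance = 1e-12)
})

test_that("expression extremes are deterministic, id-breaking ties", {
  expr <- setNames(c(5, 1, 4, 2, 3, 10, 0, 7, 6, 9,
                     8, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5, 0.5),
                   sprintf("g%02d", 1:20))
  ext <- expression_extremes(expr, 0.1)
  expect_length(ext$high, 2L)
  expect_identical(ext$high, names(sort(expr, decreasing = TRUE))[1:2])
  expect_identical(ext$low, names(sort(expr))[1:2])
  expect_error(expression_extremes(expr, 0.6), "fraction")
  expect_error(expression_extremes(expr[1:5], 0.05), "too few")
  tied <- setNames(rep(1, 20), sprintf("g%02d", 1:20))
  expect_warning(et <- expression_extremes(tied, 0.1), "equal")
  expect_identical(et$high, c("g01", "g02"))
})

test_that("CAI reproduces the hand-computed geometric mean", {
  gc <- genetic_code()
  # reference gene: Ser2 counts (3, 1) -> RSCU (1.5, 0.5) -> weights (1, 1/3)
  counts <- matrix(0L, 2, 61, dimnames = list(c("ref", "gene"), gc$codons))
  counts["ref", c("AGC", "AGT")] <- c(3L, 1L)
  counts["gene", c("AGC", "AGT")] <- c(1L, 1L)
  tab <- table_from_counts(counts, gc)
  got <- cai(tab, "ref")
  expect_equal(unname(got["gene"]), sqrt(1 / 3), tolerance = 1e-12)
  # a gene using only family-maximal codons scores exactly 1
  expect_equal(unname(cai(tab, "ref")["ref"]), 1 ^ (3 / 4) * (1 / 3)^(1 / 4),
               tolerance = 1e-12)

  only_max <- matrix(0L, 2, 61, dimnames = list(c("r2", "g2"), gc$codons))
  only_max["r2", c("AGC", "AGT")] <- c(3L, 1L)
  only_max["g2", "AGC"] <- 5L
  tab2 <- table_from_counts(only_max, gc)
  expect_equal(unname(cai(tab2, "r2")["g2"]), 1, tolerance = 1e-12)
  # CAI is invariant to gene length at fixed codon frequencies
  long <- only_max
  long["g2", "AGC"] <- 50L
  expect_equal(unname(cai(table_from_counts(long, gc), "r2")["g2"]), 1,
               tolerance = 1e-12)
  expect_error(cai(tab, character(0)), "empty")
})

test_that("CA reference set is enriched in high-expression genes", {
  sim <- simulate_genome(build_preset("single_regime", n_genes = 400,
                                      seed = 33),
                         emit_sequences = FALSE)
  tab <- sim$count_table
  phi <- setNames(sim$truth$genes$phi, tab$gene_ids)
  ref <- ca_reference_set(tab, fraction = 0.1, expression_proxy = phi)
  expect_gt(mean(phi[ref]), mean(phi))
  expect_identical(sort(ca_reference_set(tab, fraction = 1)), sort(tab$gene_ids))
})

test_that("window profiles match brute-force window means", {
  set.seed(51)
  n <- 60
  counts <- matrix(rpois(n * 61, 3) + 1L, n, 61,
                   dimnames = list(sprintf("g%03d", 1:n),
                                   genetic_code()$codons))
  coords <- data.frame(gene_id = rownames(counts),
                       chromosome = "chr1", position = sample(n))
  tab <- table_from_counts(counts, coords = coords)
  labels <- setNames(sample(c("lower_gc3", "higher_gc3"), n, replace = TRUE),
                     rownames(counts))

  prof <- window_profile(tab, labels, window_size = 20, mode = "moving")
  ord <- coords$gene_id[order(coords$position)]
  g_sorted <- tab$gc3[ord]
  i <- 30 # interior: full window of 20 genes, 9 before and 10 after
  expect_equal(prof$mean_gc3[prof$window_index == i],
               mean(g_sorted[(i - 9):(i + 10)]), tolerance = 1e-12)
  expect_true(all(prof$n_genes <= 20))

  npf <- window_profile(tab, labels, window_size = 20, mode = "nonoverlapping")
  expect_equal(sum(npf$n_genes), n)
  expect_equal(npf$mean_gc3[1], mean(g_sorted[1:20]), tolerance = 1e-12)
  expect_equal(npf$frac_higher[2],
               mean(labels[ord[21:40]] == "higher_gc3"), tolerance = 1e-12)

  # all-higher labels give fraction one everywhere; alternating give 0.5
  all_high <- setNames(rep("higher_gc3", n), rownames(counts))
  expect_true(all(window_profile(tab, all_high, 20, "moving")$frac_higher == 1))
  alt <- setNames(rep(c("lower_gc3", "higher_gc3"), n / 2), ord)
  expect_true(all(window_profile(tab, alt, 20,
                                 "nonoverlapping")$frac_higher == 0.5))
})

test_that("partial trailing bins are kept only when at least half-full", {
  set.seed(53)
  counts <- matrix(rpois(52 * 61, 3) + 1L, 52, 61,
                   dimnames = list(sprintf("g%03d", 1:52),
                                   genetic_code()$codons))
  coords <- data.frame(gene_id = rownames(counts), chromosome = "chr1",
                       position = 1:52)
  labels <- setNames(rep("lower_gc3", 52), rownames(counts))
  tab48 <- table_from_counts(counts[1:48, ], coords = coords[1:48, ])
  npf <- window_profile(tab48, labels[1:48], 20, "nonoverlapping")
  expect_equal(nrow(npf), 2L) # trailing 8 genes < half window: dropped
  tab50 <- table_from_counts(counts[1:50, ], coords = coords[1:50, ])
  npf2 <- window_profile(tab50, labels[1:50], 20, "nonoverlapping")
  expect_equal(nrow(npf2), 3L) # trailing 10 genes = half window: kept
  expect_true(npf2$partial[3])
})

test_that("window correlation tracks the regime landscape", {
  sim <- simulate_genome(build_preset("two_regime_strong", n_genes = 800,
                                      seed = 29),
                         emit_sequences = FALSE)
  tab <- sim$count_table
  truth_labels <- setNames(
    c("lower_gc3", "higher_gc3")[sim$truth$genes$regime],
    tab$gene_ids
  )
  npf <- window_profile(tab, truth_labels, 20, "nonoverlapping")
  wc <- window_correlation(npf)
  expect_gt(wc$rho, 0.8)

  # labels drawn independently of GC3: correlation near zero
  set.seed(52)
  null_labels <- setNames(sample(unname(truth_labels)), tab$gene_ids)
  wc0 <- window_correlation(window_profile(tab, null_labels, 20,
                                           "nonoverlapping"))
  expect_lt(abs(wc0$rho), 0.35)
  expect_error(window_correlation(window_profile(tab, truth_labels, 20,
                                                 "moving")),
               "non-overlapping")
})
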