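test_that("equilibrium codon probabilities obey the closed forms", {
  gc <- genetic_code()
  p0 <- roc_params(gc)
  # all coefficients zero: uniform within every family
  for (fid in c("Ala", "Leu", "Ser2")) {
    fam <- gc$families[[fid]]
    expect_equal(unname(codon_probabilities(p0, fid, 2)),
                 rep(1 / fam$size, fam$size))
  }
  # 2-codon family, non-reference dM = ln 2, dEta = 0: p = (1/3, 2/3)
  p1 <- roc_params(gc, delta_m = c(AGC = log(2)))
  pr <- codon_probabilities(p1, "Ser2", 1)
  expect_equal(unname(pr["AGC"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(pr["AGT"]), 2 / 3, tolerance = 1e-12)
  # phi = 0 removes selection entirely
  p2 <- roc_params(gc, delta_m = c(AGC = log(2)), delta_eta = c(AGC = 5))
  expect_equal(codon_probabilities(p2, "Ser2", 0), pr)
})

test_that("probabilities sum to one and shifts of dM cancel", {
  gc <- genetic_code()
  set.seed(30)
  for (rep in 1:50) {
    fid <- sample(names(gc$families), 1)
    fam <- gc$families[[fid]]
    dm <- setNames(runif(fam$size, -3, 3), fam$codons)
    eta <- setNames(runif(fam$size, -1, 1), fam$codons)
    phi <- rlnorm(1, 0, 1.5)
    pars <- roc_params(gc, delta_m = dm, delta_eta = eta)
    pr <- codon_probabilities(pars, fid, phi)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    # adding a constant to every member's dM (brute-force renormalization)
    v <- pars$delta_m[fam$codons, 1]
    ev <- pars$delta_eta[fam$codons]
    z <- exp(-(v + 7 + ev * phi))
    expect_equal(unname(pr), unname(z / sum(z)), tolerance = 1e-12)
  }
})

test_that("non-reference probability decreases with expression when disfavored", {
  pars <- roc_params(genetic_code(), delta_eta = c(AGC = 0.4))
  phis <- seq(0, 8, by = 0.5)
  p_nonref <- vapply(phis, function(ph) {
    codon_probabilities(pars, "Ser2", ph)[["AGC"]]
  }, numeric(1))
  expect_true(all(diff(p_nonref) < 0))
})

test_that("gene log-likelihood equals direct summation over families", {
  gc <- genetic_code()
  set.seed(31)
  dm <- setNames(runif(61, -1, 1), gc$codons)
  eta <- setNames(runif(61, -0.5, 0.5), gc$codons)
  pars <- roc_params(gc, delta_m = dm, delta_eta = eta)
  counts <- setNames(rpois(61, 3), gc$codons)
  phi <- 1.7

  brute <- 0
  for (fam in gc$families) {
    if (fam$size < 2) next
    p <- codon_probabilities(pars, fam$family_id, phi)
    brute <- brute + sum(counts[fam$codons] * log(p))
  }
  expect_equal(gene_log_likelihood(counts, pars, phi), brute, tolerance = 1e-10)
  expect_equal(gene_log_likelihood(counts * 0L, pars, phi), 0)

  uniform <- roc_params(gc)
  two <- setNames(rep(0L, 61), gc$codons)
  two[c("AGC", "AGT")] <- 1L
  expect_equal(gene_log_likelihood(two, uniform, 1), 2 * log(1 / 2))
})

test_that("the C++ likelihood kernel agrees with the R implementation", {
  sim <- simulate_genome(build_preset("two_regime_strong", n_genes = 20,
                                      seed = 5),
                         emit_sequences = FALSE)
  tab <- sim$count_table
  pars <- sim$truth$params
  phi <- sim$truth$genes$phi
  reg <- sim$truth$genes$regime
  dev <- roc_deviance(tab, pars, phi, reg)
  brute <- -2 * sum(vapply(seq_along(phi), function(g) {
    gene_log_likelihood(tab$counts[g, ], pars, phi[g], reg[g])
  }, numeric(1)))
  expect_equal(dev, brute, tolerance = 1e-8)
  # deviance is linear in the counts
  tab2 <- tab
  tab2$counts <- tab$counts * 2L
  expect_equal(roc_deviance(tab2, pars, phi, reg), 2 * dev, tolerance = 1e-8)
})

test_that("regime-specific likelihood collapses to shared when dM is equal", {
  sim <- simulate_genome(build_preset("two_regime_strong", n_genes = 15,
                                      seed = 6),
                         emit_sequences = FALSE)
  tab <- sim$count_table
  phi <- sim$truth$genes$phi
  gc <- genetic_code()
  set.seed(32)
  dm1 <- setNames(runif(61, -1, 1), gc$codons)
  eta <- setNames(runif(61, -0.5, 0.5), gc$codons)
  shared <- roc_params(gc, delta_m = dm1, delta_eta = eta)
  twin <- roc_params(gc, delta_m = cbind(shared$delta_m[, 1],
                                         shared$delta_m[, 1]),
                     delta_eta = eta,
                     regime_names = c("a", "b"))
  reg <- sim$truth$genes$regime
  expect_equal(roc_deviance(tab, twin, phi, reg),
               roc_deviance(tab, shared, phi, rep(1L, length(phi))),
               tolerance = 1e-9)
})

test_that("scale transformations leave the likelihood invariant", {
  sim <- simulate_genome(build_preset("single_regime", n_genes = 12, seed = 7),
                         emit_sequences = FALSE)
  tab <- sim$count_table
  pars <- sim$truth$params
  phi <- sim$truth$genes$phi
  scaled <- roc_params(pars$genetic_code, delta_m = pars$delta_m,
                       delta_eta = pars$delta_eta * 2)
  expect_equal(roc_deviance(tab, pars, phi),
               roc_deviance(tab, scaled, phi / 2), tolerance = 1e-8)
  # but the prior on phi moves, pinning the scale
  lp1 <- roc_log_prior(pars, phi, s_phi = 1.5)
  lp2 <- roc_log_prior(scaled, phi / 2, s_phi = 1.5)
  expect_false(isTRUE(all.equal(lp1, lp2)))
})

test_that("log prior behaves at its boundaries", {
  pars <- roc_params(genetic_code())
  phi <- rep(1, 5)
  expect_equal(roc_log_prior(pars, phi, s_phi = -1), -Inf)
  expect_equal(roc_log_prior(pars, c(phi, -1), s_phi = 1), -Inf)
  expect_true(is.finite(roc_log_prior(pars, exp(rep(-0.5, 5)), s_phi = 1)))
  # near-flat prior: widening tau barely moves the density differences
  p_a <- roc_log_prior(pars, phi, 1, tau = 10)
  p_b <- roc_log_prior(pars, phi, 1, tau = 1e6)
  d1 <- roc_log_prior(roc_params(genetic_code(), delta_m = c(AGC = 1)),
                      phi, 1, tau = 1e6) - p_b
  expect_lt(abs(d1), 1e-9)
  expect_true(is.finite(p_a))
})

test_that("AT-partner rescaling follows the subtraction rule", {
  gc <- genetic_code()
  pars <- roc_params(gc, delta_eta = c(GCG = 0.4, GCA = 0.1, GCC = 0.25))
  res <- rescale_to_at_reference(pars)
  sel <- res[res$type == "selection", ]
  expect_equal(sel$value[sel$codon == "GCG"], 0.3, tolerance = 1e-12)
  # reference codon GCT carries 0, so GCC is unchanged
  expect_equal(sel$value[sel$codon == "GCC"], 0.25, tolerance = 1e-12)
  expect_identical(sel$partner[sel$codon == "GCC"], "GCT")
  # equal coefficients rescale to zero
  pars0 <- roc_params(gc, delta_eta = c(GCG = 0.2, GCA = 0.2))
  res0 <- rescale_to_at_reference(pars0)
  expect_equal(res0$value[res0$type == "selection" & res0$codon == "GCG"], 0,
               tolerance = 1e-12)
})

test_that("optimal codons minimize the selection coefficient", {
  gc <- genetic_code()
  pars <- roc_params(gc, delta_eta = c(GCA = -0.5, GCC = 0.2))
  expect_identical(unname(identify_optimal_codons(pars)["Ala"]), "GCA")
  # all zero: alphabetically first member wins the tie
  zero <- identify_optimal_codons(roc_params(gc))
  expect_identical(unname(zero["Ala"]), "GCA")
  expect_identical(unname(zero["Ser2"]), "AGC")
})
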