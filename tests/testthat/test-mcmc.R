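# Small-scale sampler checks. Heavier parameter-recovery runs live in the
# acceptance suite.

test_that("configurations are validated", {
  expect_error(mcmc_config(iterations = 1000, burn_in = 1000), "burn_in")
  expect_error(mcmc_config(iterations = 100, burn_in = 99, thin = 10),
               "retains no")
  expect_error(mcmc_config(thin = 0), "thin")
  ref <- mcmc_config(preset = "reference")
  expect_identical(ref$iterations, 200000L)
  expect_identical(ref$burn_in, 50000L)
  expect_identical(ref$thin, 10L)
})

test_that("with expression fixed, a 2-codon family recovers the binomial logit", {
  gc <- genetic_code()
  # all counts in Ser2 (AGC vs reference AGT), phi pinned at 1: only the sum
  # dM + dEta is identified and its MLE is -log(c_nonref / c_ref)
  n <- 40
  counts <- matrix(0L, n, 61, dimnames = list(sprintf("g%02d", 1:n),
                                              gc$codons))
  counts[, "AGC"] <- 120L
  counts[, "AGT"] <- 360L
  tab <- table_from_counts(counts, gc)
  cfg <- mcmc_config(iterations = 4000, burn_in = 1000, thin = 5,
                     n_chains = 2, seed = 3, fix_phi = TRUE)
  fit <- fit_roc_semppr(tab, NULL, cfg)

  samples_sum <- do.call(rbind, lapply(fit$trace, function(ch) {
    ch$dm + ch$deta
  }))
  free_names <- names(codonregimes:::free_coefficients(fit$params)$delta_eta)
  j <- which(free_names == "AGC")
  est <- mean(samples_sum[, j])
  sd_est <- sd(samples_sum[, j])
  mle <- -log(120 / 360)
  expect_lt(abs(est - mle), 2 * sd_est + 0.02)
  expect_gt(sd_est, 0)
})

test_that("DIC arithmetic is exact on a hand-computed trace", {
  fake <- structure(
    list(trace = list(list(deviance = c(10, 14))), deviance_at_mean = 11),
    class = "roc_fit"
  )
  got <- dic(fake)
  expect_equal(got$mean_deviance, 12)
  expect_equal(got$p_d, 1)
  expect_equal(got$dic, 13)

  degenerate <- structure(
    list(trace = list(list(deviance = rep(42, 5))), deviance_at_mean = 42),
    class = "roc_fit"
  )
  expect_equal(dic(degenerate)$p_d, 0)
  expect_equal(dic(degenerate)$dic, 42)

  empty <- structure(list(trace = list(list(deviance = numeric(0))),
                          deviance_at_mean = 1), class = "roc_fit")
  expect_error(dic(empty), "empty trace")
})

test_that("convergence diagnostics separate agreement from disagreement", {
  # identical chains: scale reduction factors at one
  ch <- list(dm = matrix(rnorm(50), 25), deta = matrix(rnorm(25), 25),
             s_phi = exp(rnorm(25, 0, 0.1)), phi = matrix(rlnorm(250), 25),
             deviance = rnorm(25, 100))
  sim <- simulate_genome(build_preset("single_regime", n_genes = 10, seed = 1),
                         emit_sequences = FALSE)
  base <- structure(
    list(trace = list(ch, ch),
         params = roc_params(genetic_code()),
         config = mcmc_config(seed = 1)),
    class = "roc_fit"
  )
  conv <- convergence_check(base)
  expect_true(conv$available)
  expect_equal(conv$max_psrf, 1, tolerance = 0.05)
  expect_equal(conv$phi_cross_chain_spearman, 1)
  expect_true(conv$converged)

  # opposite-ranked expression across chains must fail the check
  ch2 <- ch
  ch2$phi <- -ch$phi + max(ch$phi) + 1
  bad <- base
  bad$trace <- list(ch, ch2)
  expect_false(convergence_check(bad)$converged)

  single <- base
  single$trace <- list(ch)
  expect_false(isTRUE(convergence_check(single)$available))
})

test_that("a deliberately short run reports non-convergence risk honestly", {
  sim <- simulate_genome(build_preset("single_regime", n_genes = 40, seed = 13),
                         emit_sequences = FALSE)
  cfg <- mcmc_config(iterations = 60, burn_in = 10, thin = 1, n_chains = 2,
                     seed = 2)
  fit <- fit_roc_semppr(sim$count_table, NULL, cfg)
  expect_true(is.finite(fit$dic))
  expect_false(is.na(fit$convergence$converged))
  # diagnostics exist for every free coefficient plus the spread parameter
  expect_length(fit$convergence$psrf, 2L * 40L + 1L)
})

test_that("fits are reproducible for a fixed seed", {
  sim <- simulate_genome(build_preset("single_regime", n_genes = 30, seed = 5),
                         emit_sequences = FALSE)
  cfg <- mcmc_config(iterations = 800, burn_in = 300, thin = 5, n_chains = 1,
                     seed = 11)
  f1 <- fit_roc_semppr(sim$count_table, NULL, cfg)
  f2 <- fit_roc_semppr(sim$count_table, NULL, cfg)
  expect_identical(f1$phi_mean, f2$phi_mean)
  expect_identical(f1$dic, f2$dic)

  trace_path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_trace(f1, trace_path)
  tr <- read.delim(trace_path, check.names = FALSE)
  expect_identical(nrow(tr), nrow(f1$trace[[1]]$dm))
  expect_true(all(c("chain", "s_phi", "deviance", "AGC.genome", "eta.AGC")
                  %in% colnames(tr)))
})
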