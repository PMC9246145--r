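#' MCMC configuration for the codon model fit
#'
#' The default is a desk-scale configuration (20,000 iterations, thin 10,
#' burn-in 5,000, two chains) suitable for simulation studies; the
#' `"reference"` preset (200,000 / 10 / 50,000, two chains) matches the
#' long-chain settings used for whole-genome analyses.
#'
#' @param iterations Total MCMC iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param burn_in Iterations discarded (and during which proposal scales
#'   adapt); must be `< iterations`.
#' @param n_chains Number of independent chains started from different points.
#' @param seed Integer master seed; chain `c` runs on `seed + 1000 * c`.
#' @param target_acceptance Adaptation target for all proposal scales.
#' @param adapt_interval Iterations between adaptation steps during burn-in.
#' @param tau Prior SD for the codon coefficients.
#' @param s_phi Lognormal scale of the expression prior (a fixed constant:
#'   the likelihood is affine-invariant in expression, so the spread is only
#'   weakly identified and is treated as part of the prior specification;
#'   see the package vignette).
#' @param fix_phi Keep all gene expression values fixed at 1 (diagnostic use).
#' @param preset `"desk"` or `"reference"`; overrides the iteration counts.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 20000L, thin = 10L, burn_in = 5000L,
                        n_chains = 2L, seed = 1L, target_acceptance = 0.3,
                        adapt_interval = 50L, tau = 10, s_phi = 1.5,
                        fix_phi = FALSE, preset = c("desk", "reference")) {
  preset <- match.arg(preset)
  if (preset == "reference") {
    iterations <- 200000L
    thin <- 10L
    burn_in <- 50000L
  }
  cfg <- list(
    iterations = as.integer(iterations), thin = as.integer(thin),
    burn_in = as.integer(burn_in), n_chains = as.integer(n_chains),
    seed = as.integer(seed), target_acceptance = target_acceptance,
    adapt_interval = as.integer(adapt_interval), tau = tau,
    s_phi = s_phi, fix_phi = isTRUE(fix_phi), preset = preset
  )
  if (cfg$thin < 1L) stop("'thin' must be >= 1")
  if (cfg$burn_in < 0L || cfg$burn_in >= cfg$iterations) {
    stop("'burn_in' must be >= 0 and < 'iterations'")
  }
  if ((cfg$iterations - cfg$burn_in) %/% cfg$thin < 1L) {
    stop("configuration retains no post-burn-in samples")
  }
  if (cfg$n_chains < 1L) stop("'n_chains' must be >= 1")
  if (cfg$s_phi <= 0) stop("'s_phi' must be > 0")
  structure(cfg, class = "mcmc_config")
}

#' Fit the selection-mutation-drift codon model by MCMC
#'
#' Bayesian estimation of codon-specific mutation bias and selection together
#' with latent per-gene expression, from codon counts alone. With `regimes =
#' NULL` a single genome-wide set of mutation-bias coefficients is fit
#' (the ConstMut model); with a [cluster_genes()] assignment (or an integer
#' vector of per-gene regime indices) each regime receives its own
#' mutation-bias coefficients while selection coefficients remain shared
#' (the VarMut model) — regimes share one cytoplasm and tRNA pool, so
#' translational selection is common to all of them. Every gene keeps a
#' single expression value regardless of regime.
#'
#' The sampler is an adaptive Metropolis-within-Gibbs scheme: a joint
#' random-walk proposal on all log expression values with per-gene
#' acceptance, and per-family block random walks on the mutation-bias (per
#' regime) and selection coefficients. Proposal scales adapt toward the
#' target acceptance during burn-in only. The expression scale and location
#' (a likelihood-invariant gauge) are pinned each iteration to the prior
#' convention, and the prior's lognormal spread `s_phi` is a fixed constant
#' of the configuration; see the vignette for why the spread is not
#' estimated.
#'
#' The posterior of this model has a mirror mode in which every selection
#' coefficient is negated and expression ranks are inverted; random-walk
#' chains started blindly fall into either mode with roughly equal
#' probability and never leave. The fit therefore begins with a short
#' orientation pilot: one pilot chain runs from a standard start (pooled
#' log-frequency mutation bias, prior-drawn expression), a second pilot runs
#' from the mirror image of the first one's final state, and the orientation
#' with the lower mean deviance anchors the production chains. Chains still
#' start from dispersed points — odd chains continue from the anchor state,
#' even chains jitter the anchored coefficients and redraw expression from
#' the prior — and an occasional reflection move lets a chain jump across
#' modes if the data favor the other one.
#'
#' @param count_table A [build_count_table()] result.
#' @param regimes `NULL`, a `regime_assignment`, or an integer vector of
#'   per-gene regime indices aligned with the table's genes.
#' @param config An [mcmc_config()].
#' @return Object of class `roc_fit`: posterior means (`params`, an
#'   [roc_params()]; `phi_mean`, `phi_sd`, `s_phi_mean`), `dic`, `p_d`,
#'   `mean_deviance`, `deviance_at_mean`, per-chain `trace`, `convergence`
#'   (see [convergence_check()]), `acceptance`, plus the inputs needed to
#'   recompute everything (`gene_ids`, `regime_index`, `regime_names`,
#'   `model`, `config`).
#' @export
fit_roc_semppr <- function(count_table, regimes = NULL,
                           config = mcmc_config()) {
  stopifnot(inherits(count_table, "codon_count_table"),
            inherits(config, "mcmc_config"))
  gcode <- count_table$genetic_code
  n <- length(count_table$gene_ids)

  if (is.null(regimes)) {
    regime_index <- rep(1L, n)
    regime_names <- "genome"
  } else if (inherits(regimes, "regime_assignment")) {
    stopifnot(identical(regimes$gene_ids, count_table$gene_ids))
    regime_names <- names(regimes$median_gc3_per_cluster)
    regime_index <- match(unname(regimes$labels), regime_names)
  } else {
    regime_index <- as.integer(regimes)
    stopifnot(length(regime_index) == n, all(regime_index >= 1L))
    regime_names <- paste0("regime", seq_len(max(regime_index)))
  }
  n_regimes <- length(regime_names)
  model <- if (n_regimes == 1L) "ConstMut" else "VarMut"

  idx <- family_index(gcode)
  members0 <- lapply(idx, function(f) f$cols - 1L)
  dm_pooled <- init_delta_m(count_table, regime_index, n_regimes, idx)
  zero61 <- rep(0, length(gcode$codons))

  run_chain <- function(chain_seed, dm0, deta0, phi0,
                        iterations = config$iterations,
                        burn_in = config$burn_in, thin = config$thin) {
    with_seed(chain_seed, roc_mcmc_chain(
      counts = count_table$counts, members = members0,
      regime = regime_index, n_regimes = n_regimes,
      dm_init = dm0, deta_init = deta0, phi_init = phi0,
      s_phi = config$s_phi,
      iterations = iterations, burn_in = burn_in, thin = thin,
      tau = config$tau, target_accept = config$target_acceptance,
      adapt_interval = config$adapt_interval, fix_phi = config$fix_phi
    ))
  }

  # --- orientation pilot -------------------------------------------------
  # The posterior has a mirror mode (selection negated, expression ranks
  # inverted) that short random-walk chains cannot leave. A short pilot
  # chain is run from the standard start, a second pilot from the mirror
  # image of its final state, and the orientation with the lower mean
  # deviance anchors the initialization of the production chains.
  anchor <- NULL
  if (!config$fix_phi) {
    pilot_iters <- max(1000L, min(config$burn_in, 5000L))
    pilot_burn <- as.integer(0.7 * pilot_iters)
    pilot_thin <- max(1L, (pilot_iters - pilot_burn) %/% 20L)
    s0 <- config$s_phi
    p1 <- run_chain(config$seed + 101L, dm_pooled, zero61,
                    with_seed(config$seed + 11L, rlnorm(n, -s0^2 / 2, s0)),
                    iterations = pilot_iters, burn_in = pilot_burn,
                    thin = pilot_thin)
    f1 <- p1$final
    mu0 <- -s0^2 / 2
    cc <- exp(mu0)
    dm_ref <- f1$dm + 2 * outer(f1$deta, rep(1, n_regimes)) * cc
    p2 <- run_chain(config$seed + 102L, dm_ref, -f1$deta,
                    exp(2 * mu0 - log(f1$phi)),
                    iterations = pilot_iters, burn_in = pilot_burn,
                    thin = pilot_thin)
    anchor <- if (mean(p2$deviance) < mean(p1$deviance)) p2$final else p1$final
  }

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    seed_ch <- config$seed + 1000L * ch
    if (config$fix_phi) {
      dm0 <- if (ch %% 2L == 1L) dm_pooled else
        matrix(0, length(gcode$codons), n_regimes)
      chains[[ch]] <- run_chain(seed_ch, dm0, zero61, rep(1, n))
    } else if (ch %% 2L == 1L) {
      # odd chains continue from the pilot's winning state
      chains[[ch]] <- run_chain(seed_ch, anchor$dm, anchor$deta, anchor$phi)
    } else {
      # even chains disperse around the anchored mode: jittered coefficients
      # and a fresh prior draw of expression
      start <- with_seed(seed_ch + 7L, {
        dm0 <- anchor$dm
        dm0[dm0 != 0] <- dm0[dm0 != 0] + rnorm(sum(dm0 != 0), 0, 0.3)
        deta0 <- anchor$deta
        deta0[deta0 != 0] <- deta0[deta0 != 0] + rnorm(sum(deta0 != 0), 0, 0.1)
        list(dm0 = dm0, deta0 = deta0,
             phi0 = rlnorm(n, -config$s_phi^2 / 2, config$s_phi))
      })
      chains[[ch]] <- run_chain(seed_ch, start$dm0, start$deta0, start$phi0)
    }
  }

  # pooled posterior means
  dm_mean <- colMeans(do.call(rbind, lapply(chains, `[[`, "dm")))
  deta_mean <- colMeans(do.call(rbind, lapply(chains, `[[`, "deta")))
  params <- unpack_free(dm_mean, deta_mean, gcode, n_regimes, regime_names)
  if (config$fix_phi) {
    phi_mean <- rep(1, n)
    phi_sd <- rep(0, n)
  } else {
    phi_all <- do.call(rbind, lapply(chains, `[[`, "phi"))
    phi_mean <- colMeans(phi_all)
    phi_sd <- apply(phi_all, 2L, stats::sd)
  }
  s_phi_mean <- config$s_phi
  names(phi_mean) <- names(phi_sd) <- count_table$gene_ids

  dev_samples <- unlist(lapply(chains, `[[`, "deviance"))
  dev_at_mean <- roc_deviance(count_table, params, phi_mean, regime_index)
  mean_dev <- mean(dev_samples)
  p_d <- mean_dev - dev_at_mean
  dic <- dev_at_mean + 2 * p_d

  fit <- structure(
    list(
      params = params, phi_mean = phi_mean, phi_sd = phi_sd,
      s_phi_mean = s_phi_mean, dic = dic, p_d = p_d,
      mean_deviance = mean_dev, deviance_at_mean = dev_at_mean,
      trace = chains, gene_ids = count_table$gene_ids,
      regime_index = regime_index, regime_names = regime_names,
      model = model, config = config,
      acceptance = list(
        phi = lapply(chains, `[[`, "accept_phi"),
        blocks = lapply(chains, `[[`, "accept_block")
      )
    ),
    class = "roc_fit"
  )
  fit$convergence <- convergence_check(fit)
  fit
}

# Mutation-bias initialization from pooled codon frequencies: with phi near
# zero the model reduces to p proportional to exp(-dM), so log frequency
# ratios to the reference codon are a natural starting point.
init_delta_m <- function(count_table, regime_index, n_regimes, idx) {
  dm <- matrix(0, ncol(count_table$counts), n_regimes)
  for (r in seq_len(n_regimes)) {
    pooled <- colSums(count_table$counts[regime_index == r, , drop = FALSE]) + 0.5
    for (f in idx) {
      dm[f$nonref_cols, r] <- log(pooled[f$ref_col]) - log(pooled[f$nonref_cols])
    }
  }
  dm
}

# inverse of the sampler's free-parameter packing
unpack_free <- function(dm_free, deta_free, gcode, n_regimes, regime_names) {
  idx <- family_index(gcode)
  dm <- matrix(0, length(gcode$codons), n_regimes,
               dimnames = list(gcode$codons, regime_names))
  eta <- stats::setNames(rep(0, length(gcode$codons)), gcode$codons)
  pos_m <- 0L
  pos_e <- 0L
  for (f in idx) {
    k <- length(f$nonref_cols)
    for (r in seq_len(n_regimes)) {
      dm[f$nonref_cols, r] <- dm_free[pos_m + seq_len(k)]
      pos_m <- pos_m + k
    }
    eta[f$nonref_cols] <- deta_free[pos_e + seq_len(k)]
    pos_e <- pos_e + k
  }
  roc_params(gcode, delta_m = dm, delta_eta = eta, regime_names = regime_names)
}

#' @export
print.roc_fit <- function(x, ...) {
  cat("<roc_fit> ", x$model, ": ", length(x$gene_ids), " genes, ",
      length(x$regime_names), " regime(s), ", length(x$trace), " chain(s)\n",
      "  DIC = ", sprintf("%.1f", x$dic), " (p_D = ", sprintf("%.1f", x$p_d),
      "); s_phi = ", sprintf("%.3f", x$s_phi_mean),
      "; converged: ", x$convergence$converged, "\n", sep = "")
  invisible(x)
}

#' Deviance Information Criterion of a fit
#'
#' \eqn{\bar D} is the mean deviance over retained samples, \eqn{D(\bar\theta)}
#' the deviance at the posterior means of all parameters,
#' \eqn{p_D = \bar D - D(\bar\theta)} the effective number of parameters, and
#' \eqn{\mathrm{DIC} = D(\bar\theta) + 2 p_D}. Lower DIC is better.
#'
#' @param fit An [fit_roc_semppr()] result.
#' @param count_table Optional: recompute \eqn{D(\bar\theta)} against this
#'   table instead of using the value cached in the fit.
#' @return List with `dic`, `p_d`, `mean_deviance`, `deviance_at_mean`.
#' @export
dic <- function(fit, count_table = NULL) {
  stopifnot(inherits(fit, "roc_fit"))
  dev_samples <- unlist(lapply(fit$trace, `[[`, "deviance"))
  if (length(dev_samples) == 0L) stop("fit has an empty trace")
  d_at_mean <- if (is.null(count_table)) {
    fit$deviance_at_mean
  } else {
    roc_deviance(count_table, fit$params, fit$phi_mean, fit$regime_index)
  }
  d_bar <- mean(dev_samples)
  p_d <- d_bar - d_at_mean
  list(dic = d_at_mean + 2 * p_d, p_d = p_d, mean_deviance = d_bar,
       deviance_at_mean = d_at_mean)
}

#' Cross-chain convergence diagnostics
#'
#' Gelman-Rubin potential scale reduction factors for every free codon
#' coefficient, plus the Spearman
#' correlation between the chains' posterior-mean expression vectors. The fit
#' is flagged `converged` when all PSRFs are below `psrf_threshold` and the
#' minimum cross-chain expression correlation reaches `phi_spearman_threshold`.
#' With a single chain the diagnostics are flagged unavailable.
#'
#' @param fit An [fit_roc_semppr()] result.
#' @param psrf_threshold PSRF cut-off (default 1.1).
#' @param phi_spearman_threshold Cross-chain expression-rank cut-off
#'   (default 0.95).
#' @return List with `available`, `psrf` (named vector), `max_psrf`,
#'   `phi_cross_chain_spearman`, `converged`.
#' @export
convergence_check <- function(fit, psrf_threshold = 1.1,
                              phi_spearman_threshold = 0.95) {
  stopifnot(inherits(fit, "roc_fit"))
  if (length(fit$trace) < 2L) {
    return(list(available = FALSE, psrf = NULL, max_psrf = NA_real_,
                phi_cross_chain_spearman = NA_real_, converged = NA))
  }
  param_mats <- lapply(fit$trace, function(ch) {
    cbind(ch$dm, ch$deta, log_s_phi = log(ch$s_phi))
  })
  nms <- c(names(free_coefficients(fit$params)$delta_m),
           paste0("eta.", names(free_coefficients(fit$params)$delta_eta)),
           "log_s_phi")
  psrf <- vapply(seq_len(ncol(param_mats[[1]])), function(j) {
    gelman_psrf(lapply(param_mats, function(m) m[, j]))
  }, numeric(1))
  names(psrf) <- nms[seq_along(psrf)]

  phi_rho <- NA_real_
  if (!fit$config$fix_phi) {
    means <- lapply(fit$trace, function(ch) colMeans(ch$phi))
    combs <- utils::combn(length(means), 2L)
    phi_rho <- min(apply(combs, 2L, function(pr) {
      stats::cor(means[[pr[1]]], means[[pr[2]]], method = "spearman")
    }))
  }
  max_psrf <- max(psrf, na.rm = TRUE)
  converged <- max_psrf < psrf_threshold &&
    (is.na(phi_rho) || phi_rho >= phi_spearman_threshold)
  list(available = TRUE, psrf = psrf, max_psrf = max_psrf,
       phi_cross_chain_spearman = phi_rho, converged = converged)
}

# Potential scale reduction factor across chains (one scalar parameter).
# Degenerate (zero-variance) traces are reported as 1.
gelman_psrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  w <- mean(vapply(chains, stats::var, numeric(1)))
  b_over_n <- stats::var(vapply(chains, mean, numeric(1)))
  if (!is.finite(w) || w <= .Machine$double.eps) return(1)
  sqrt((n - 1) / n + b_over_n / w)
}

#' Write the retained MCMC samples to TSV
#'
#' One row per retained iteration: chain, sample index, every free
#' mutation-bias and selection coefficient, the expression spread and the
#' deviance. Per-gene expression samples are omitted (a `genes x samples`
#' table rarely serves downstream tools; use `fit$trace[[chain]]$phi`).
#'
#' @param fit An [fit_roc_semppr()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fit_trace <- function(fit, path) {
  stopifnot(inherits(fit, "roc_fit"))
  free <- free_coefficients(fit$params)
  rows <- lapply(seq_along(fit$trace), function(ch) {
    tr <- fit$trace[[ch]]
    dm <- tr$dm
    colnames(dm) <- names(free$delta_m)
    deta <- tr$deta
    colnames(deta) <- paste0("eta.", names(free$delta_eta))
    data.frame(chain = ch, sample = seq_len(nrow(dm)), dm, deta,
               s_phi = tr$s_phi, deviance = tr$deviance,
               check.names = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write posterior summaries of a fit to TSV
#'
#' Two files: per-coefficient estimates (posterior mean and SD of mutation
#' bias per regime and selection per codon, the optimal-codon flag and the
#' AT-partner re-scaled values) and per-gene expression estimates.
#'
#' @param fit An [fit_roc_semppr()] result.
#' @param params_path,genes_path Output TSV paths.
#' @return Invisibly, a list of the two data frames.
#' @export
write_fit_summaries <- function(fit, params_path, genes_path) {
  gcode <- fit$params$genetic_code
  idx <- family_index(gcode)
  dm_sd <- apply(do.call(rbind, lapply(fit$trace, `[[`, "dm")), 2L, stats::sd)
  deta_sd <- apply(do.call(rbind, lapply(fit$trace, `[[`, "deta")), 2L, stats::sd)
  sd_params <- unpack_free(dm_sd, deta_sd, gcode, length(fit$regime_names),
                           fit$regime_names)
  optimal <- identify_optimal_codons(fit$params)
  rows <- list()
  for (f in idx) {
    for (cod in f$codons) {
      for (r in fit$regime_names) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = f$family_id, codon = cod, regime = r,
          delta_m_mean = fit$params$delta_m[cod, r],
          delta_m_sd = sd_params$delta_m[cod, r],
          delta_eta_mean = fit$params$delta_eta[cod],
          delta_eta_sd = sd_params$delta_eta[cod],
          optimal = unname(optimal[f$family_id]) == cod,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  params_df <- do.call(rbind, rows)
  write.table(params_df, params_path, sep = "\t", quote = FALSE, row.names = FALSE)

  genes_df <- data.frame(
    gene_id = fit$gene_ids,
    phi_mean = unname(fit$phi_mean),
    phi_sd = unname(fit$phi_sd),
    regime = fit$regime_names[fit$regime_index],
    stringsAsFactors = FALSE
  )
  write.table(genes_df, genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(params = params_df, genes = genes_df))
}
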