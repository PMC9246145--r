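#' Construct a set of codon-model coefficients
#'
#' Holds the codon-specific mutation-bias coefficients (\eqn{\Delta M}, one
#' column per mutation regime) and selection coefficients (\eqn{\Delta\eta},
#' shared across regimes), both measured relative to each family's reference
#' codon (the alphabetically last member, pinned at 0 and never sampled).
#'
#' @param genetic_code A [genetic_code()] object.
#' @param delta_m Numeric 61 x n_regimes matrix (rownames = codons) or a
#'   single named vector; missing entries default to 0. Reference entries are
#'   forced to 0.
#' @param delta_eta Named numeric vector over (a subset of) the 61 sense
#'   codons; missing entries default to 0. Reference entries are forced to 0.
#' @param regime_names Optional names for the regimes.
#' @return Object of class `roc_params` with elements `delta_m` (61 x R),
#'   `delta_eta` (length 61), `genetic_code`, `regime_names`.
#' @export
roc_params <- function(genetic_code = codonregimes::genetic_code(),
                       delta_m = NULL, delta_eta = NULL,
                       regime_names = NULL) {
  codons <- genetic_code$codons
  if (is.null(delta_m)) delta_m <- matrix(0, length(codons), 1L)
  if (!is.matrix(delta_m)) {
    v <- rep(0, length(codons))
    names(v) <- codons
    v[names(delta_m)] <- delta_m
    delta_m <- matrix(v, ncol = 1L)
  } else if (!is.null(rownames(delta_m))) {
    m <- matrix(0, length(codons), ncol(delta_m))
    m[match(rownames(delta_m), codons), ] <- delta_m
    delta_m <- m
  }
  stopifnot(nrow(delta_m) == length(codons))
  rownames(delta_m) <- codons

  eta <- rep(0, length(codons))
  names(eta) <- codons
  if (!is.null(delta_eta)) eta[names(delta_eta)] <- delta_eta

  # pin reference codons at zero
  for (f in genetic_code$families) {
    delta_m[f$reference, ] <- 0
    eta[f$reference] <- 0
  }
  if (is.null(regime_names)) {
    regime_names <- if (ncol(delta_m) == 1L) "genome" else
      regime_label_names(ncol(delta_m))
  }
  colnames(delta_m) <- regime_names
  structure(
    list(delta_m = delta_m, delta_eta = eta, genetic_code = genetic_code,
         regime_names = regime_names),
    class = "roc_params"
  )
}

#' @export
print.roc_params <- function(x, ...) {
  cat("<roc_params> ", ncol(x$delta_m), " regime(s), ",
      x$genetic_code$n_free, " free coefficients per type (",
      x$genetic_code$code_name, " code)\n", sep = "")
  invisible(x)
}

#' Codon probabilities within a synonymous family
#'
#' The selection-mutation-drift equilibrium probability of codon \eqn{i} in a
#' gene with expression \eqn{\phi}:
#' \deqn{p_i = \frac{e^{-\Delta M_i - \Delta\eta_i \phi}}
#'   {\sum_j e^{-\Delta M_j - \Delta\eta_j \phi}}}
#' evaluated with max-subtraction for overflow safety. At \eqn{\phi = 0}
#' probabilities depend only on mutation bias; as \eqn{\phi} grows, codons
#' with smaller \eqn{\Delta\eta} are increasingly favored.
#'
#' @param params An [roc_params()] object.
#' @param family_id Family identifier (e.g. `"Ala"`, `"Ser2"`).
#' @param phi Gene expression value, `>= 0`.
#' @param regime Regime column of `params$delta_m` to use (index or name).
#' @return Named probability vector over the family members (sums to 1).
#' @export
codon_probabilities <- function(params, family_id, phi, regime = 1L) {
  stopifnot(inherits(params, "roc_params"))
  fam <- params$genetic_code$families[[family_id]]
  if (is.null(fam)) stop("unknown family: ", family_id)
  if (!is.finite(phi) || phi < 0) stop("'phi' must be finite and >= 0")
  softmax_neg(params$delta_m[fam$codons, regime] +
                params$delta_eta[fam$codons] * phi)
}

# softmax of -x with max-subtraction
softmax_neg <- function(x) {
  if (any(!is.finite(x))) stop("non-finite model coefficients")
  z <- -x
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Log-likelihood of one gene's codon counts
#'
#' Multinomial log-likelihood (normalizing constant dropped) summed over
#' synonymous families: \eqn{\sum_f \sum_i c_i \log p_i} with \eqn{p} from
#' [codon_probabilities()]. Families with zero counts contribute 0.
#'
#' @param counts Named count vector over the 61 sense codons.
#' @param params An [roc_params()] object.
#' @param phi Gene expression value.
#' @param regime Mutation regime of the gene.
#' @return Scalar log-likelihood.
#' @export
gene_log_likelihood <- function(counts, params, phi, regime = 1L) {
  stopifnot(inherits(params, "roc_params"))
  ll <- 0
  for (fam in multi_codon_families(params$genetic_code)) {
    c_f <- counts[fam$codons]
    if (sum(c_f) == 0) next
    x <- params$delta_m[fam$codons, regime] + params$delta_eta[fam$codons] * phi
    z <- -x
    zmax <- max(z)
    ll <- ll + sum(c_f * z) - sum(c_f) * (zmax + log(sum(exp(z - zmax))))
  }
  unname(ll)
}

#' Log prior density of the model state
#'
#' Lognormal prior on gene expression with location \eqn{-s_\phi^2/2} (so
#' that the prior mean of \eqn{\phi} is 1, pinning the scale left free by the
#' likelihood), independent Normal(0, tau^2) priors on every free
#' mutation-bias and selection coefficient, and a half-Normal(0,
#' `s_phi_scale`^2) prior on \eqn{s_\phi}.
#'
#' @param params An [roc_params()] object.
#' @param phi Per-gene expression vector (all `> 0`).
#' @param s_phi Lognormal scale; `<= 0` yields `-Inf`.
#' @param tau Prior SD of the codon coefficients (default 10).
#' @param s_phi_scale Half-normal scale for `s_phi` (default 2).
#' @return Scalar log prior density (additive constants included).
#' @export
roc_log_prior <- function(params, phi, s_phi, tau = 10, s_phi_scale = 2) {
  if (s_phi <= 0) return(-Inf)
  if (any(phi <= 0)) return(-Inf)
  lp <- sum(stats::dlnorm(phi, meanlog = -s_phi^2 / 2, sdlog = s_phi, log = TRUE))
  free <- free_coefficients(params)
  lp <- lp + sum(stats::dnorm(c(free$delta_m, free$delta_eta), 0, tau, log = TRUE))
  lp + stats::dnorm(s_phi, 0, s_phi_scale, log = TRUE) + log(2)
}

# Free (non-reference) coefficient values in the sampler's storage layout:
# family-major, regime-major within family, member within regime.
free_coefficients <- function(params) {
  idx <- family_index(params$genetic_code)
  regs <- colnames(params$delta_m)
  dm <- unlist(unname(lapply(idx, function(f) {
    unlist(lapply(seq_along(regs), function(r) {
      stats::setNames(params$delta_m[f$nonref_cols, r],
                      paste0(f$nonref_codons, ".", regs[r]))
    }))
  })))
  eta <- unlist(unname(lapply(idx, function(f) {
    stats::setNames(params$delta_eta[f$nonref_cols], f$nonref_codons)
  })))
  list(delta_m = dm, delta_eta = eta)
}

#' Model deviance of a codon count table
#'
#' \eqn{-2 \sum_g \log L_g} with the per-gene multinomial log-likelihood of
#' [gene_log_likelihood()] (normalizing constant dropped).
#'
#' @param count_table A [build_count_table()] result.
#' @param params An [roc_params()] object.
#' @param phi Per-gene expression vector, aligned with the table's genes.
#' @param regimes Optional integer vector of per-gene regime indices
#'   (default: all genes in regime 1).
#' @return Scalar deviance.
#' @export
roc_deviance <- function(count_table, params, phi, regimes = NULL) {
  stopifnot(inherits(count_table, "codon_count_table"))
  n <- length(count_table$gene_ids)
  if (is.null(regimes)) regimes <- rep(1L, n)
  stopifnot(length(phi) == n, length(regimes) == n)
  idx <- family_index(params$genetic_code)
  members0 <- lapply(idx, function(f) f$cols - 1L)
  ll <- roc_loglik_matrix(count_table$counts, params$delta_m,
                          params$delta_eta, as.numeric(phi),
                          as.integer(regimes), members0)
  -2 * sum(ll)
}

#' Re-express coefficients relative to the AT-ending partner codon
#'
#' The fitted coefficients are relative to each family's alphabetically last
#' codon. To read off GC-versus-AT preference directly, every GC-ending codon
#' is re-expressed relative to its AT partner: `value(NNG) = value(NNG) -
#' value(NNA)` and `value(NNC) = value(NNC) - value(NNT)` (a codon's own
#' value being 0 when it is the reference). A positive re-scaled selection
#' coefficient means the GC-ending codon is disfavored relative to the
#' AT-ending partner; negative means favored. If the direct partner is not a
#' family member, the family's other AT-ending member is used (noted);
#' families with no AT/GC pairing are skipped with a note.
#'
#' @param params An [roc_params()] object (e.g. posterior means from a fit).
#' @return Data.frame with columns `family`, `codon`, `partner`, `type`
#'   (`mutation` per regime or `selection`), `regime`, `value`, `note`.
#' @export
rescale_to_at_reference <- function(params) {
  stopifnot(inherits(params, "roc_params"))
  out <- list()
  regs <- colnames(params$delta_m)
  for (fam in multi_codon_families(params$genetic_code)) {
    gc_members <- fam$codons[substr(fam$codons, 3, 3) %in% c("G", "C")]
    for (cod in gc_members) {
      third <- substr(cod, 3, 3)
      partner <- paste0(substr(cod, 1, 2), if (third == "G") "A" else "T")
      note <- ""
      if (!partner %in% fam$codons) {
        alt_end <- if (third == "G") "A" else "T"
        alt <- fam$codons[substr(fam$codons, 3, 3) == alt_end]
        if (length(alt) == 0L) {
          alt <- fam$codons[substr(fam$codons, 3, 3) %in% c("A", "T")]
        }
        if (length(alt) == 0L) {
          out[[length(out) + 1L]] <- data.frame(
            family = fam$family_id, codon = cod, partner = NA_character_,
            type = "skipped", regime = NA_character_, value = NA_real_,
            note = "no AT-ending member in family", stringsAsFactors = FALSE
          )
          next
        }
        partner <- alt[length(alt)]
        note <- "direct AT partner absent; nearest AT-ending member used"
      }
      for (r in regs) {
        out[[length(out) + 1L]] <- data.frame(
          family = fam$family_id, codon = cod, partner = partner,
          type = "mutation", regime = r,
          value = params$delta_m[cod, r] - params$delta_m[partner, r],
          note = note, stringsAsFactors = FALSE
        )
      }
      out[[length(out) + 1L]] <- data.frame(
        family = fam$family_id, codon = cod, partner = partner,
        type = "selection", regime = NA_character_,
        value = params$delta_eta[cod] - params$delta_eta[partner],
        note = note, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Identify the optimal codon of each synonymous family
#'
#' The optimal (preferred) codon is the member with the minimal selection
#' coefficient (the reference codon counting as 0): by the model's form,
#' smaller \eqn{\Delta\eta} means higher probability as expression grows.
#' Exact ties are broken alphabetically.
#'
#' @param params An [roc_params()] object.
#' @return Named character vector, family id to optimal codon (multi-codon
#'   families only).
#' @export
identify_optimal_codons <- function(params) {
  stopifnot(inherits(params, "roc_params"))
  fams <- multi_codon_families(params$genetic_code)
  out <- vapply(fams, function(fam) {
    eta <- params$delta_eta[fam$codons] # codons already sorted alphabetically
    fam$codons[which.min(eta)]
  }, character(1))
  stats::setNames(out, vapply(fams, `[[`, character(1), "family_id"))
}
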