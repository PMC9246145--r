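#' Compare ConstMut and VarMut model fits
#'
#' Summarises what allowing regime-specific mutation bias changes: the rank
#' correlation between predicted (posterior-mean) and empirical expression
#' under each model, their difference, the DIC difference (VarMut minus
#' ConstMut; negative favors VarMut), per-family optimal-codon calls and
#' their agreement, and the change in the AT-partner re-scaled selection
#' coefficients between models.
#'
#' @param fit_const,fit_var [fit_roc_semppr()] results on the same gene set
#'   (typically one-regime and regime-specific fits).
#' @param empirical_expression Optional named vector of empirical abundances
#'   (e.g. TPM); genes are matched by name and the intersection used.
#' @return Object of class `model_comparison`: `spearman_const`,
#'   `spearman_var` (each a list `rho`, `p`, or `NULL` without empirical
#'   data), `delta_spearman`, `delta_dic`, `optimal_codons` (data.frame per
#'   family), `optimal_agreement`, `selection_shift` (data.frame of re-scaled
#'   selection coefficients under both models with log fold changes),
#'   `n_genes_compared`.
#' @export
compare_models <- function(fit_const, fit_var, empirical_expression = NULL) {
  stopifnot(inherits(fit_const, "roc_fit"), inherits(fit_var, "roc_fit"))
  if (!identical(fit_const$gene_ids, fit_var$gene_ids)) {
    stop("fits were made on different gene sets")
  }

  sp_const <- sp_var <- NULL
  delta_sp <- NA_real_
  n_common <- NA_integer_
  if (!is.null(empirical_expression)) {
    common <- intersect(fit_const$gene_ids, names(empirical_expression))
    if (length(common) < 3L) stop("fewer than 3 genes shared with empirical expression")
    n_common <- length(common)
    emp <- empirical_expression[common]
    sp_const <- spearman_cor(fit_const$phi_mean[common], emp)
    sp_var <- spearman_cor(fit_var$phi_mean[common], emp)
    delta_sp <- sp_var$rho - sp_const$rho
  }

  opt_const <- identify_optimal_codons(fit_const$params)
  opt_var <- identify_optimal_codons(fit_var$params)
  opt <- data.frame(
    family = names(opt_const),
    constmut = unname(opt_const),
    varmut = unname(opt_var[names(opt_const)]),
    stringsAsFactors = FALSE
  )
  opt$agree <- opt$constmut == opt$varmut

  res_const <- rescale_to_at_reference(fit_const$params)
  res_var <- rescale_to_at_reference(fit_var$params)
  sc <- res_const[res_const$type == "selection", c("family", "codon", "partner", "value")]
  sv <- res_var[res_var$type == "selection", c("codon", "value")]
  shift <- merge(sc, sv, by = "codon", suffixes = c("_const", "_var"))
  shift$sign_change <- sign(shift$value_const) != sign(shift$value_var)
  shift$log_fold_change <- log(abs(shift$value_var) / abs(shift$value_const))

  structure(
    list(
      spearman_const = sp_const, spearman_var = sp_var,
      delta_spearman = delta_sp,
      delta_dic = fit_var$dic - fit_const$dic,
      optimal_codons = opt,
      optimal_agreement = mean(opt$agree),
      selection_shift = shift,
      n_genes_compared = n_common
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  if (!is.null(x$spearman_const)) {
    cat(sprintf("  Spearman(phi, empirical): ConstMut %.3f, VarMut %.3f (delta %+.3f, %d genes)\n",
                x$spearman_const$rho, x$spearman_var$rho, x$delta_spearman,
                x$n_genes_compared))
  }
  cat(sprintf("  delta DIC (VarMut - ConstMut): %.1f (lower DIC is better)\n", x$delta_dic))
  cat(sprintf("  optimal-codon agreement: %.0f%% of families\n", 100 * x$optimal_agreement))
  invisible(x)
}
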