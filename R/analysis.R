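#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the asymptotic
#' t-approximation p-value. Constant input yields an `NA` correlation with a
#' warning rather than an error.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{i} in a family of \eqn{n_{aa}} synonyms with pooled counts
#' \eqn{c}, \eqn{\mathrm{RSCU}_i = c_i / (\sum_j c_j / n_{aa})}: the observed
#' count relative to the expectation under unbiased synonymous usage.
#' Synonym-less families (ATG, TGG, and CTG under the `ctg_ser` code) are
#' excluded; families with zero pooled counts yield `NA` values.
#'
#' @param pooled_counts Named count vector over the 61 sense codons, pooled
#'   over a gene set.
#' @param genetic_code A [genetic_code()] object.
#' @return Data.frame `codon`, `family`, `rscu`.
#' @export
rscu <- function(pooled_counts, genetic_code = codonregimes::genetic_code()) {
  rows <- lapply(multi_codon_families(genetic_code), function(fam) {
    c_f <- as.numeric(pooled_counts[fam$codons])
    tot <- sum(c_f)
    data.frame(
      codon = fam$codons,
      family = fam$family_id,
      rscu = if (tot > 0) c_f / (tot / fam$size) else rep(NA_real_, fam$size),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' High- and low-expression gene sets
#'
#' The top and bottom `fraction` of genes by expression; ties are broken by
#' gene id so the split is deterministic.
#'
#' @param expression Named numeric vector (names = gene ids).
#' @param fraction Tail fraction in (0, 0.5).
#' @return List with `high` and `low` character vectors of gene ids (each of
#'   size `floor(n * fraction)`).
#' @export
expression_extremes <- function(expression, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5) stop("'fraction' must be in (0, 0.5)")
  n <- length(expression)
  n_ext <- floor(n * fraction)
  if (n_ext < 1L) stop("too few genes for a non-empty extreme set")
  if (stats::sd(expression) == 0) {
    warning("all expression values equal; extremes are id-ordered")
  }
  ids <- names(expression)
  ord_low <- order(expression, ids)
  ord_high <- order(-expression, ids)
  list(high = ids[ord_high[seq_len(n_ext)]],
       low = ids[ord_low[seq_len(n_ext)]])
}

#' Codon adaptation index
#'
#' Per-gene CAI: the geometric mean of relative adaptiveness weights
#' \eqn{w_i = \mathrm{RSCU}_i / \max_{j \in \mathrm{family}} \mathrm{RSCU}_j}
#' computed from a high-expression reference set, taken over the gene's
#' codons in families with at least two members. Reference RSCU values of 0
#' are floored at 0.01 before the weights are formed, so codons absent from
#' the reference set do not force a CAI of zero.
#'
#' @param count_table A [build_count_table()] result.
#' @param reference_gene_ids Gene ids of the reference set (non-empty).
#' @param rscu_floor Floor applied to zero reference RSCU values.
#' @return Named numeric vector of per-gene CAI values in (0, 1].
#' @export
cai <- function(count_table, reference_gene_ids, rscu_floor = 0.01) {
  stopifnot(inherits(count_table, "codon_count_table"))
  if (length(reference_gene_ids) == 0L) stop("empty reference gene set")
  if (!all(reference_gene_ids %in% count_table$gene_ids)) {
    stop("reference gene ids not all present in the count table")
  }
  gcode <- count_table$genetic_code
  pooled <- colSums(count_table$counts[reference_gene_ids, , drop = FALSE])
  ref_rscu <- rscu(pooled, gcode)
  ref_rscu$rscu[is.na(ref_rscu$rscu) | ref_rscu$rscu == 0] <- rscu_floor
  w <- unlist(lapply(split(ref_rscu, ref_rscu$family), function(d) {
    stats::setNames(d$rscu / max(d$rscu), d$codon)
  }))
  names(w) <- sub("^[^.]+\\.", "", names(w))

  cods <- intersect(colnames(count_table$counts), names(w))
  logw <- log(w[cods])
  cmat <- count_table$counts[, cods, drop = FALSE]
  tot <- rowSums(cmat)
  stats::setNames(exp(as.vector(cmat %*% logw) / tot), count_table$gene_ids)
}

#' Data-driven CAI reference set from correspondence analysis
#'
#' Emulates the automatic reference-set detection of classic codon-usage
#' tools: the first CA axis of the per-gene codon frequencies is oriented to
#' correlate positively with an expression proxy (given, or total gene codon
#' count otherwise) and the top `fraction` of genes along the oriented axis
#' form the reference set.
#'
#' @param count_table A [build_count_table()] result.
#' @param fraction Fraction of genes to select (default 0.05; 1 selects all).
#' @param expression_proxy Optional named numeric proxy for expression.
#' @return Character vector of reference gene ids.
#' @export
ca_reference_set <- function(count_table, fraction = 0.05,
                             expression_proxy = NULL) {
  stopifnot(inherits(count_table, "codon_count_table"))
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  freq <- count_table$counts / rowSums(count_table$counts)
  axis1 <- correspondence_analysis(freq, n_components = 1L)$row_coordinates[, 1L]
  proxy <- if (is.null(expression_proxy)) {
    rowSums(count_table$counts)
  } else {
    as.numeric(expression_proxy[count_table$gene_ids])
  }
  if (stats::cor(axis1, proxy, method = "spearman") < 0) axis1 <- -axis1
  n_ref <- max(1L, floor(length(axis1) * fraction))
  ids <- count_table$gene_ids
  ids[order(-axis1, ids)][seq_len(n_ref)]
}

#' GC3 landscape along chromosomes
#'
#' Summarises GC3 and regime-label composition in 20-gene windows along each
#' chromosome (genes ordered by their ordinal position). `"moving"` windows
#' are centered on each gene and truncated at chromosome ends;
#' `"nonoverlapping"` windows partition the gene order into consecutive
#' bins, keeping a final partial bin only when it holds at least half a
#' window (flagged in the output).
#'
#' @param count_table A [build_count_table()] result with coordinates.
#' @param labels Named character vector of cluster labels per gene (from
#'   [cluster_genes()]); the fraction reported is of genes labelled
#'   `"higher_gc3"`.
#' @param window_size Window size in genes (default 20).
#' @param mode `"moving"` or `"nonoverlapping"`.
#' @return Object of class `window_profile`: data.frame `chromosome`,
#'   `window_index`, `center_position`, `mean_gc3`, `frac_higher`, `n_genes`,
#'   `partial`, with attributes `mode` and `window_size`.
#' @export
window_profile <- function(count_table, labels, window_size = 20L,
                           mode = c("moving", "nonoverlapping")) {
  mode <- match.arg(mode)
  stopifnot(inherits(count_table, "codon_count_table"))
  if (is.null(count_table$coords)) stop("count table has no coordinates")
  coords <- count_table$coords
  if (anyNA(coords$chromosome) || anyNA(coords$position)) {
    stop("coordinates contain missing values")
  }
  gc3 <- count_table$gc3[coords$gene_id]
  higher <- as.numeric(unname(labels[coords$gene_id]) == "higher_gc3")
  if (anyNA(higher)) stop("labels missing for some genes")

  rows <- list()
  for (chrom in unique(coords$chromosome)) {
    sel <- which(coords$chromosome == chrom)
    sel <- sel[order(coords$position[sel])]
    m <- length(sel)
    g <- gc3[sel]
    h <- higher[sel]
    if (mode == "moving") {
      if (m < window_size) {
        warning("chromosome ", chrom, " has fewer than ", window_size,
                " genes; skipped in moving profile")
        next
      }
      before <- (window_size - 1L) %/% 2L
      after <- window_size - 1L - before
      for (i in seq_len(m)) {
        win <- max(1L, i - before):min(m, i + after)
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, window_index = i,
          center_position = coords$position[sel[i]],
          mean_gc3 = mean(g[win]), frac_higher = mean(h[win]),
          n_genes = length(win), partial = length(win) < window_size,
          stringsAsFactors = FALSE
        )
      }
    } else {
      n_bins <- m %/% window_size
      rem <- m %% window_size
      keep_partial <- rem >= window_size / 2
      for (b in seq_len(n_bins + as.integer(keep_partial && rem > 0L))) {
        win <- ((b - 1L) * window_size + 1L):min(b * window_size, m)
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, window_index = b,
          center_position = coords$position[sel[win[ceiling(length(win) / 2)]]],
          mean_gc3 = mean(g[win]), frac_higher = mean(h[win]),
          n_genes = length(win), partial = length(win) < window_size,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) stop("no windows could be formed")
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "window_size") <- window_size
  class(out) <- c("window_profile", class(out))
  out
}

#' Correlation between window GC3 and regime composition
#'
#' Spearman correlation, pooled across chromosomes, between the mean GC3 of
#' non-overlapping windows and the fraction of their genes assigned to the
#' higher-GC3 regime. Non-overlapping windows are required so that the rank
#' test's independence assumption is reasonable.
#'
#' @param profile A non-overlapping [window_profile()].
#' @return List with `rho`, `p` and `n_windows`.
#' @export
window_correlation <- function(profile) {
  stopifnot(inherits(profile, "window_profile"))
  if (attr(profile, "mode") != "nonoverlapping") {
    stop("window_correlation requires a non-overlapping profile")
  }
  if (nrow(profile) < 3L) stop("need at least 3 windows")
  sp <- spearman_cor(profile$mean_gc3, profile$frac_higher)
  c(sp, list(n_windows = nrow(profile)))
}
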