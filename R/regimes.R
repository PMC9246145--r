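#' Cluster genes into candidate mutation regimes
#'
#' Hypothesizes sets of genes evolving under different non-adaptive
#' nucleotide biases without any a priori annotation: per-gene codon
#' frequencies (rows scaled to sum to 1, so long genes do not dominate) are
#' decomposed by correspondence analysis, the leading `n_components` row
#' principal coordinates are clustered with CLARA k-medoids, and clusters are
#' labelled by ascending median GC3 — `lower_gc3` / `higher_gc3` for `k = 2`,
#' with `middle_gc3` inserted for `k = 3`.
#'
#' @param count_table A [build_count_table()] result.
#' @param k Number of clusters (default 2; 3 supported).
#' @param seed Optional integer seed for the CLARA subset draws.
#' @param n_components Leading CA dimensions fed to the clustering (default 4).
#' @param n_subsets,subset_fraction CLARA controls; defaults 5 subsets of half
#'   the genes.
#' @param scale CA coordinate scaling handed to [correspondence_analysis()].
#' @return Object of class `regime_assignment`: `gene_ids`, `labels` (named
#'   character, one of the GC3-ordered labels per gene), `cluster_index`
#'   (internal medoid slot per gene), `medoid_gene_ids`, `k`,
#'   `median_gc3_per_cluster` (named by label, ascending),
#'   `delta_median_gc3` (highest minus lowest median), `ca_coordinates`.
#' @export
cluster_genes <- function(count_table, k = 2L, seed = NULL, n_components = 4L,
                          n_subsets = 5L, subset_fraction = 0.5,
                          scale = c("principal", "standard")) {
  stopifnot(inherits(count_table, "codon_count_table"))
  n <- length(count_table$gene_ids)
  if (n < 2L * k) stop("need at least 2k genes to cluster")
  freq <- count_table$counts / rowSums(count_table$counts)
  ca <- correspondence_analysis(freq, n_components = n_components,
                                scale = match.arg(scale))
  cl <- clara_medoids(ca$row_coordinates, k, n_subsets = n_subsets,
                      subset_fraction = subset_fraction, seed = seed)

  med_gc3 <- vapply(seq_len(k), function(j) {
    stats::median(count_table$gc3[cl$labels == j])
  }, numeric(1))
  ord <- order(med_gc3)
  label_names <- regime_label_names(k)
  # map internal medoid slots onto GC3-ordered labels
  slot_to_label <- character(k)
  slot_to_label[ord] <- label_names
  labels <- stats::setNames(slot_to_label[cl$labels], count_table$gene_ids)

  structure(
    list(
      gene_ids = count_table$gene_ids,
      labels = labels,
      cluster_index = cl$labels,
      medoid_gene_ids = count_table$gene_ids[cl$medoids],
      k = k,
      median_gc3_per_cluster = stats::setNames(med_gc3[ord], label_names),
      delta_median_gc3 = max(med_gc3) - min(med_gc3),
      ca_coordinates = ca$row_coordinates
    ),
    class = "regime_assignment"
  )
}

regime_label_names <- function(k) {
  if (k == 1L) return("single")
  if (k == 2L) return(c("lower_gc3", "higher_gc3"))
  if (k == 3L) return(c("lower_gc3", "middle_gc3", "higher_gc3"))
  c("lower_gc3", paste0("gc3_rank", seq_len(k - 2L) + 1L), "higher_gc3")
}

#' @export
print.regime_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat("<regime_assignment> k = ", x$k, "; sizes: ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "; delta median GC3 = ", sprintf("%.4f", x$delta_median_gc3), "\n",
      sep = "")
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of cluster GC3 distributions
#'
#' Two-sided two-sample KS test (asymptotic p-value) between the per-gene GC3
#' values of two regime clusters.
#'
#' @param gc3_lower,gc3_higher Numeric GC3 vectors for the two clusters.
#' @return List with `D` (sup of the ECDF difference) and `p`.
#' @export
ks_compare_gc3 <- function(gc3_lower, gc3_higher) {
  if (length(gc3_lower) == 0L || length(gc3_higher) == 0L) {
    stop("both GC3 samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(gc3_lower, gc3_higher, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Write a regime assignment to TSV
#'
#' One row per gene: id, cluster label, CA coordinates and GC3.
#'
#' @param assignment A [cluster_genes()] result.
#' @param count_table The matching count table (source of GC3).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_regime_assignment <- function(assignment, count_table, path) {
  df <- data.frame(
    gene_id = assignment$gene_ids,
    cluster_label = unname(assignment$labels),
    assignment$ca_coordinates,
    gc3 = unname(count_table$gc3[assignment$gene_ids]),
    check.names = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
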