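# Shared fixtures: everything is generated in code at test time.

# A tiny deterministic codon count table built from hand-written CDS strings.
toy_records <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    sequence = c(
      "ATGGCCGCCGCAAAAAAGTAA", # Ala x3, Lys x2
      "ATGTTTTTCGGTGGCGGATAA", # Phe x2, Gly x3
      "ATGGCGGCGAAAAAATAA"     # Ala x2, Lys x2
    ),
    stringsAsFactors = FALSE
  )
}

toy_table <- function(metadata = NULL) {
  build_count_table(toy_records(), genetic_code(), metadata = metadata)
}

# Assemble a codon_count_table directly from a count matrix (no sequences).
table_from_counts <- function(counts, gcode = genetic_code(), coords = NULL) {
  structure(
    list(
      gene_ids = rownames(counts),
      counts = counts,
      gc3 = stats::setNames(gc3_percent(counts), rownames(counts)),
      coords = coords,
      genetic_code = gcode
    ),
    class = "codon_count_table"
  )
}

# Best-mapping accuracy of a 2-way clustering against true integer labels.
label_accuracy <- function(assignment, true_regime) {
  pred <- as.integer(factor(unname(assignment$labels),
                            levels = c("lower_gc3", "higher_gc3")))
  max(mean(pred == true_regime), mean(pred == 3L - true_regime))
}

# Adjusted Rand index (brute force over the pair-count contingency table).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Small two-blob planar point set with known membership.
two_blob_points <- function(n_per = 4, d = 2, sep = 10, seed = 1) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(seed, {
    pts <- rbind(
      matrix(rnorm(n_per * d, 0, 0.3), ncol = d),
      matrix(rnorm(n_per * d, sep, 0.3), ncol = d)
    )
    list(points = pts, truth = rep(1:2, each = n_per))
  })
}

# Exhaustive k-medoids minimization (oracle for PAM on tiny point sets).
exhaustive_medoids <- function(points, k) {
  d <- as.matrix(dist(points))
  n <- nrow(points)
  best <- NULL
  for (set in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, set, drop = FALSE], 1, min))
    if (is.null(best) || cost < best$cost) best <- list(medoids = set, cost = cost)
  }
  best
}
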