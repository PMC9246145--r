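#' PAM k-medoids clustering
#'
#' Classic BUILD + SWAP partitioning around medoids with Euclidean distance.
#' BUILD greedily seeds the medoid set; SWAP exchanges a (medoid, non-medoid)
#' pair whenever the exchange lowers the total cost
#' \eqn{\sum_p d(p, \mathrm{medoid}(p))}, running to a local optimum. The
#' procedure is fully deterministic: all ties are broken by the lowest point
#' index.
#'
#' @param points Numeric matrix, one row per observation.
#' @param k Number of medoids, `1 <= k <= nrow(points)`.
#' @return List with `medoids` (row indices, in the order chosen), `labels`
#'   (per-point medoid slot, 1..k) and `total_cost`.
#' @export
pam_medoids <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L || k > n) stop("'k' must be between 1 and the number of points")
  d <- as.matrix(stats::dist(points))

  # BUILD: first medoid is the 1-median; then add the point with the largest
  # reduction in total cost
  medoids <- unname(which.min(colSums(d)))
  dnear <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    reduction <- colSums(pmax(dnear - d[, cand, drop = FALSE], 0))
    best <- cand[which.max(reduction)]
    medoids <- c(medoids, best)
    dnear <- pmin(dnear, d[, best])
  }

  # SWAP: steepest-descent exchanges until no swap improves the cost
  cost <- sum(dnear)
  repeat {
    best_delta <- -1e-12
    best_m <- NA_integer_
    best_h <- NA_integer_
    cand <- setdiff(seq_len(n), medoids)
    if (length(cand) == 0L) break
    for (mi in seq_along(medoids)) {
      others <- medoids[-mi]
      dexcl <- if (length(others) > 0L) {
        do.call(pmin, lapply(others, function(j) d[, j]))
      } else {
        rep(Inf, n)
      }
      new_cost <- colSums(pmin(d[, cand, drop = FALSE], dexcl))
      delta <- new_cost - cost
      j <- which.min(delta)
      if (delta[j] < best_delta ||
          (delta[j] == best_delta && !is.na(best_h) && cand[j] < best_h)) {
        best_delta <- delta[j]
        best_m <- mi
        best_h <- cand[j]
      }
    }
    if (is.na(best_m)) break
    medoids[best_m] <- best_h
    dmat <- d[, medoids, drop = FALSE]
    dnear <- do.call(pmin, asplit(dmat, 2L))
    cost <- sum(dnear)
  }

  dmat <- d[, medoids, drop = FALSE]
  labels <- max.col(-dmat, ties.method = "first")
  list(medoids = unname(medoids), labels = labels, total_cost = sum(dnear))
}

#' CLARA: k-medoids for large point sets via subsampling
#'
#' Draws `n_subsets` random subsets (each a fraction `subset_fraction` of the
#' points, without replacement), runs [pam_medoids()] on each subset, assigns
#' every point to its nearest candidate medoid by Euclidean distance, and
#' keeps the medoid set with the smallest mean dissimilarity over all points.
#' With `subset_fraction = 1` and `n_subsets = 1` the result is exactly PAM
#' on the full data.
#'
#' @param points Numeric matrix, one row per observation.
#' @param k Number of medoids.
#' @param n_subsets Number of random subsets to evaluate.
#' @param subset_fraction Fraction of points per subset (0, 1].
#' @param seed Optional integer; makes the subset draws (and hence the whole
#'   result) reproducible.
#' @return List with `medoids` (row indices into `points`), `labels`
#'   (per-point medoid slot, 1..k) and `mean_dissimilarity`.
#' @export
clara_medoids <- function(points, k, n_subsets = 5L, subset_fraction = 0.5,
                          seed = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n_subsets < 1L) stop("'n_subsets' must be >= 1")
  if (subset_fraction <= 0 || subset_fraction > 1) {
    stop("'subset_fraction' must be in (0, 1]")
  }
  size <- min(n, max(1L, round(subset_fraction * n)))
  if (size < k) stop("subset size (", size, ") smaller than k (", k, ")")

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_subsets)) {
      idx <- sort(sample.int(n, size))
      fit <- pam_medoids(points[idx, , drop = FALSE], k)
      medoids <- idx[fit$medoids]
      dmed <- medoid_distances(points, medoids)
      labels <- max.col(-dmed, ties.method = "first")
      score <- mean(dmed[cbind(seq_len(n), labels)])
      if (is.null(best) || score < best$mean_dissimilarity) {
        best <- list(medoids = medoids, labels = labels,
                     mean_dissimilarity = score)
      }
    }
    best
  })
}

# n x k matrix of Euclidean distances from every point to each medoid row
medoid_distances <- function(points, medoids) {
  vapply(medoids, function(m) {
    sqrt(rowSums(sweep(points, 2L, points[m, ], `-`)^2))
  }, numeric(nrow(points)))
}
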