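#' Correspondence analysis of a non-negative table
#'
#' Standard (chi-square metric) correspondence analysis: the matrix of
#' standardized residuals of the correspondence table,
#' \eqn{S = D_r^{-1/2} (P - r c^\top) D_c^{-1/2}} with \eqn{P} the table
#' divided by its grand total and \eqn{r, c} its margins, is decomposed by
#' SVD. Row principal coordinates are \eqn{D_r^{-1/2} U \Sigma}; total
#' inertia is \eqn{\sum_k \sigma_k^2}, which equals the Pearson chi-square
#' statistic of the table divided by its grand total.
#'
#' Columns with zero total mass are undefined under the chi-square metric and
#' are dropped first (with a warning).
#'
#' @param x Non-negative matrix (e.g. genes by codon frequencies); every row
#'   must have positive sum.
#' @param n_components Number of leading dimensions to return (default 4).
#' @param scale `"principal"` (coordinates scaled by singular values; the
#'   default, used downstream for clustering) or `"standard"`.
#' @return Object of class `ca_result`: `row_coordinates` (rows x d),
#'   `singular_values` (all positive singular values), `total_inertia`,
#'   `dropped_columns`, `scale`.
#' @export
correspondence_analysis <- function(x, n_components = 4L,
                                    scale = c("principal", "standard")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (any(x < 0)) stop("input matrix must be non-negative")
  if (nrow(x) < 2L) stop("correspondence analysis needs at least 2 rows")
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("every row must have a positive sum")
  cs <- colSums(x)
  dropped <- colnames(x)[cs == 0]
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped), " zero-mass column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, cs > 0, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("correspondence analysis needs at least 2 usable columns")

  total <- sum(x)
  p <- x / total
  r <- rowSums(p)
  c_ <- colSums(p)
  s <- (p - tcrossprod(r, c_)) / sqrt(tcrossprod(r, c_))
  dec <- svd(s)
  # numerical rank: singular values at machine-noise level are not dimensions
  pos <- dec$d > max(dec$d[1], 0) * 1e-12
  d_all <- dec$d[pos]
  d <- min(n_components, length(d_all), ncol(x) - 1L, nrow(x) - 1L)

  if (d < 1L) {
    # degenerate table (identical row profiles): zero inertia, zero coordinates
    coords <- matrix(0, nrow(x), max(1L, min(n_components, ncol(x) - 1L)))
  } else {
    u <- dec$u[, seq_len(d), drop = FALSE]
    coords <- u / sqrt(r)
    if (scale == "principal") {
      coords <- sweep(coords, 2L, d_all[seq_len(d)], `*`)
    }
  }
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("ca", seq_len(ncol(coords)))

  structure(
    list(
      row_coordinates = coords,
      singular_values = d_all,
      total_inertia = sum(d_all^2),
      dropped_columns = dropped,
      scale = scale
    ),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat("<ca_result> ", nrow(x$row_coordinates), " rows, ",
      ncol(x$row_coordinates), " components (", x$scale, "), total inertia ",
      sprintf("%.4g", x$total_inertia), "\n", sep = "")
  invisible(x)
}
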