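# Standardization, correlation-matrix PCA with retention rules, Ward
# clustering. The deterministic PC sign convention lives here because the
# downstream membership functions are not sign-invariant.

#' Column standardization (z-scores)
#'
#' Centers each column to mean 0 and scales to sample SD 1. Missing cells are
#' mean-imputed first (their count is attached as attribute
#' `"n_imputed"`), so every accession stays scoreable downstream.
#'
#' @param x Numeric matrix (rows = accessions, cols = traits).
#' @return Standardized matrix with attribute `n_imputed`.
#' @export
standardize_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows to standardize")
  n_imp <- 0L
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (all(miss)) stop("column ", colnames(x)[j], " is all-missing")
    if (any(miss)) {
      x[miss, j] <- mean(x[!miss, j])
      n_imp <- n_imp + sum(miss)
    }
  }
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = s)
  attr(out, "scaled:center") <- NULL; attr(out, "scaled:scale") <- NULL
  attr(out, "n_imputed") <- n_imp
  out
}

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the sample correlation matrix of the (standardized)
#' input. Components are ordered by descending eigenvalue and each is flipped,
#' deterministically, so that its largest-|loading| entry is positive — the
#' membership-function scoring downstream depends on this convention, so the
#' applied flips are reported.
#'
#' @param xs Standardized matrix from [standardize_matrix()].
#' @return A `pca_result`: eigenvalues, proportion (`pv`) and cumulative
#'   proportion of variance, loadings (trait x component), scores
#'   (accession x component), and the sign flips applied.
#' @export
pca_corr <- function(xs) {
  xs <- as.matrix(xs)
  if (any(!is.finite(xs))) stop("non-finite entries in PCA input")
  R <- stats::cor(xs)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vec <- eig$vectors
  flips <- vapply(seq_len(ncol(vec)), function(j) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) -1 else 1
  }, numeric(1))
  vec <- sweep(vec, 2, flips, `*`)
  dimnames(vec) <- list(colnames(xs), paste0("PC", seq_len(ncol(vec))))
  scores <- xs %*% vec
  structure(list(eigenvalues = vals,
                 pv = vals / sum(vals),
                 cum_pv = cumsum(vals) / sum(vals),
                 loadings = vec,
                 scores = scores,
                 sign_flips = flips),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("correlation PCA:", length(x$eigenvalues), "components\n")
  print(round(rbind(eigenvalue = x$eigenvalues, pv = x$pv, cum_pv = x$cum_pv), 4))
  invisible(x)
}

#' Component-retention rules
#'
#' `eigenvalue_gt` keeps components with eigenvalue > `threshold` (Kaiser rule
#' at the default 1); `cumulative_ge` keeps the smallest leading set whose
#' cumulative proportion of variance reaches `threshold`; `fixed` keeps
#' exactly `threshold` components.
#'
#' @param pca A [pca_corr()] result.
#' @param rule One of `"eigenvalue_gt"`, `"cumulative_ge"`, `"fixed"`.
#' @param threshold Rule parameter (see above).
#' @return Number of components to retain (smallest count satisfying the rule).
#' @export
retain_components <- function(pca, rule = c("eigenvalue_gt", "cumulative_ge", "fixed"),
                              threshold = 1) {
  rule <- match.arg(rule)
  k <- switch(rule,
    eigenvalue_gt = sum(pca$eigenvalues > threshold),
    cumulative_ge = {
      i <- which(pca$cum_pv >= threshold - 1e-12)
      if (length(i) == 0) 0L else min(i)
    },
    fixed = as.integer(threshold))
  if (k < 1 || k > length(pca$eigenvalues))
    stop("retention rule '", rule, "' (threshold ", threshold, ") unsatisfiable")
  k
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering of accessions with Euclidean distance and the
#' Ward minimum-variance criterion (Ward.D2, squared-distance updates), cut to
#' `k` clusters. Deterministic given input order; labels follow order of first
#' appearance.
#'
#' @param xs Standardized matrix.
#' @param k Number of clusters, `1 <= k <= nrow(xs)`.
#' @return List with `labels` (named 1..k), `merge` and `height` from the
#'   dendrogram.
#' @export
ward_cluster <- function(xs, k) {
  n <- nrow(xs)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  hc <- stats::hclust(stats::dist(xs), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, merge = hc$merge, height = hc$height, hclust = hc)
}
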