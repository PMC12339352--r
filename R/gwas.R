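# Mixed-linear-model association scan of the comprehensive tolerance score:
# VanRaden kinship, EMMA-style REML of the variance ratio under the null
# model only (P3D), per-marker generalized-least-squares Wald tests,
# Bonferroni thresholding and Manhattan/QQ data export.

#' Marker quality filters
#'
#' Removes markers below a minor-allele-frequency floor or above a
#' missing-call ceiling, reporting the counts removed.
#'
#' @param genotypes A `genotype_matrix`.
#' @param maf_min MAF floor in \[0, 0.5\] (default 0.05).
#' @param missing_max Missing-fraction ceiling in \[0, 1\] (default 0.2).
#' @return Filtered `genotype_matrix` with attribute `filter_report`.
#' @export
filter_markers <- function(genotypes, maf_min = 0.05, missing_max = 0.2) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1) stop("missing_max must be in [0, 1]")
  d <- genotypes$dosage
  miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min & miss <= missing_max
  if (!any(keep)) stop("no markers pass the filters")
  out <- new_genotype_matrix(d[, keep, drop = FALSE],
                             genotypes$map[keep, , drop = FALSE])
  rownames(out$map) <- NULL
  attr(out, "filter_report") <- c(n_input = ncol(d),
                                  n_removed_maf = sum(maf < maf_min),
                                  n_removed_missing = sum(miss > missing_max & maf >= maf_min),
                                  n_kept = sum(keep))
  out
}

#' VanRaden genomic relationship matrix
#'
#' `K = Z Z' / (2 * sum(p_k (1 - p_k)))` with `Z = dosage - 2p` (VanRaden
#' method 1). Missing dosages are mean-imputed per marker. The diagonal
#' averages about 1 in an unstructured population.
#'
#' @param genotypes A `genotype_matrix` (>= 2 markers).
#' @return Symmetric accession x accession matrix.
#' @export
kinship <- function(genotypes) {
  d <- genotypes$dosage
  if (ncol(d) < 2) stop("need >= 2 markers for kinship")
  p <- colMeans(d, na.rm = TRUE) / 2
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centering
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers monomorphic: kinship undefined")
  K <- tcrossprod(Z) / denom
  (K + t(K)) / 2
}

# REML profile log-likelihood of delta = s2e/s2g on the eigenbasis of K,
# null model only (EMMA). s = eigenvalues of K, ys/Xs = rotated data.
reml_loglik_delta <- function(log_delta, s, ys, Xs) {
  delta <- exp(log_delta)
  w <- 1 / (s + delta)
  n <- length(ys); p <- ncol(Xs)
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% b
  rss <- sum(w * r^2)
  -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(s + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

#' Mixed-linear-model association scan
#'
#' Fits the null model `y = X b + u + e` with `u ~ N(0, s2g K)` once by REML
#' on the eigenbasis of K, then fixes the variance ratio (P3D) and tests each
#' marker by generalized least squares with a two-sided Wald t test. `n_pcs`
#' leading genotype principal components can be included as fixed covariates.
#' With `K = I` the scan collapses exactly to per-marker ordinary least
#' squares.
#'
#' The genomic inflation factor `lambda = median(chi2) / 0.4549` is always
#' reported; no genomic-control correction is applied.
#'
#' @param y Named numeric vector of phenotypes (the D score), names =
#'   accessions.
#' @param genotypes A `genotype_matrix` covering the same accessions.
#' @param K Kinship matrix from [kinship()] (or identity).
#' @param n_pcs Number of genotype PCs as fixed covariates (default 0).
#' @param threshold_neglog10 Significance threshold on the -log10(p) scale;
#'   default the Bonferroni threshold [bonferroni_threshold()] at the scanned
#'   marker count.
#' @return A `gwas_result`: `scan` data.frame (marker, chrom, pos, beta, se,
#'   p, neglog10p, significant), `threshold`, `lambda`, `delta` (REML variance
#'   ratio), `significant` marker ids.
#' @export
mlm_scan <- function(y, genotypes, K, n_pcs = 0, threshold_neglog10 = NULL) {
  d <- genotypes$dosage
  acc <- intersect(names(y), rownames(d))
  if (length(acc) < 10) stop("fewer than 10 accessions shared between phenotype and genotypes")
  y <- y[acc]; d <- d[acc, , drop = FALSE]; K <- K[acc, acc]
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  n <- length(y); m <- ncol(d)

  # per-marker mean imputation
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }

  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values)))
    stop("K is not positive semidefinite; consider adding a small diagonal jitter")
  s <- pmax(eK$values, 0)
  U <- eK$vectors

  X0 <- matrix(1, n, 1)
  if (n_pcs > 0) {
    Zc <- scale(d, center = TRUE, scale = FALSE)
    pcs <- svd(Zc, nu = n_pcs, nv = 0)$u[, seq_len(n_pcs), drop = FALSE]
    X0 <- cbind(X0, pcs)
  }
  ys <- crossprod(U, y)
  X0s <- crossprod(U, X0)

  opt <- stats::optimize(reml_loglik_delta, interval = c(-10, 10),
                         s = s, ys = ys, Xs = X0s, maximum = TRUE)
  log_delta <- opt$maximum
  if (log_delta < -9.9 || log_delta > 9.9)
    warning("variance ratio estimate at the search boundary (delta = ",
            signif(exp(log_delta), 3), ")")
  delta <- exp(log_delta)
  w <- 1 / (s + delta)
  sw <- sqrt(w)

  Gs <- crossprod(U, d) * sw          # rotated, weighted markers
  X0w <- X0s * sw
  yw <- ys * sw
  p0 <- ncol(X0w)
  df <- n - p0 - 1L

  beta <- se <- pval <- numeric(m)
  A0 <- crossprod(X0w)
  a0y <- crossprod(X0w, yw)
  yy <- sum(yw^2)
  for (j in seq_len(m)) {
    g <- Gs[, j]
    Xg <- crossprod(X0w, g)
    gg <- sum(g^2)
    gy <- sum(g * yw)
    XtX <- rbind(cbind(A0, Xg), c(Xg, gg))
    Xty <- c(a0y, gy)
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch)) { beta[j] <- NA; se[j] <- NA; pval[j] <- NA; next }
    b <- backsolve(ch, forwardsolve(t(ch), Xty))
    rss <- yy - sum(b * Xty)
    sigma2 <- max(rss, 0) / df
    # (X'X)^{-1}[k,k] for the last column is 1/R[k,k]^2 (R upper triangular)
    inv_last <- 1 / ch[p0 + 1L, p0 + 1L]^2
    beta[j] <- b[p0 + 1L]
    se[j] <- sqrt(sigma2 * inv_last)
    tt <- beta[j] / se[j]
    pval[j] <- 2 * stats::pt(-abs(tt), df = df)
  }
  pval <- pmax(pval, 1e-300)

  thr <- if (is.null(threshold_neglog10)) bonferroni_threshold(m) else threshold_neglog10
  neglog10p <- -log10(pval)
  chisq <- stats::qchisq(pval, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)

  scan <- data.frame(marker = genotypes$map$id, chrom = genotypes$map$chrom,
                     pos = genotypes$map$pos, beta = beta, se = se, p = pval,
                     neglog10p = neglog10p,
                     significant = neglog10p >= thr,
                     stringsAsFactors = FALSE)
  structure(list(scan = scan, threshold = thr, lambda = lambda, delta = delta,
                 n = n, n_markers = m,
                 significant = scan$marker[scan$significant]),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("MLM scan: %d accessions x %d markers; threshold -log10(p) >= %.2f; lambda = %.3f\n",
              x$n, x$n_markers, x$threshold, x$lambda))
  cat(length(x$significant), "significant marker(s)\n")
  top <- x$scan[order(x$scan$p), ][1:min(5, nrow(x$scan)), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' `-log10(1/m) = log10(m)` for `m` tested markers: the cutoff on the
#' -log10(p) scale for a family-wise error rate of 1.
#'
#' @param n_markers Number of tested markers (>= 1).
#' @return Threshold on the -log10(p) scale.
#' @export
bonferroni_threshold <- function(n_markers) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  log10(n_markers)
}

#' Manhattan and QQ plot data export
#'
#' Manhattan table: marker, chromosome, position, -log10(p) and a cumulative
#' genome coordinate (strictly increasing genome-wide). QQ table: observed
#' -log10(p) in ascending p order against expected `-log10((i - 0.5) / m)`.
#'
#' @param result A [mlm_scan()] result.
#' @return List of data.frames `manhattan` and `qq`.
#' @export
export_manhattan_qq <- function(result) {
  sc <- result$scan[order(result$scan$chrom, result$scan$pos), , drop = FALSE]
  offsets <- c(0, cumsum(tapply(sc$pos, sc$chrom, max)))
  names(offsets) <- NULL
  chrom_index <- match(sc$chrom, unique(sc$chrom))
  manhattan <- data.frame(marker = sc$marker, chrom = sc$chrom, pos = sc$pos,
                          neglog10p = sc$neglog10p,
                          cum_pos = sc$pos + offsets[chrom_index],
                          stringsAsFactors = FALSE)
  m <- nrow(sc)
  obs <- sort(sc$neglog10p, decreasing = TRUE)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m), observed = obs)
  list(manhattan = manhattan, qq = qq)
}
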