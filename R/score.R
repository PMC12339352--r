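# The comprehensive saline-alkali tolerance evaluation: stress/control
# tolerance index, PCA on the index matrix, fuzzy membership functions,
# variance-contribution weights, the comprehensive score D and its ranking.

#' Salt-tolerance index matrix for one year
#'
#' `Si = 100 * V_AK / V_CK` per accession and trait: each trait's stress value
#' as a percentage of its control value. An index of 100 means the accession
#' is unaffected by stress in that trait. Missing or zero control values leave
#' the cell missing (flagged); accessions absent from either treatment are
#' excluded with a warning.
#'
#' @param table Long phenotype data.frame with both CK and AK records.
#' @param year Trial year.
#' @param traits Trait subset; default all observed traits. See `drop_sr` in
#'   [score_pipeline()] for the conventional 8-trait variant.
#' @return A `tolerance_index` matrix (accession x trait, percent) with
#'   attributes `year` and `n_flagged`.
#' @export
tolerance_index <- function(table, year, traits = NULL) {
  ck <- pheno_wide(table, year, "CK")
  ak <- pheno_wide(table, year, "AK")
  common <- intersect(rownames(ck), rownames(ak))
  dropped <- setdiff(union(rownames(ck), rownames(ak)), common)
  if (length(dropped))
    warning(length(dropped), " accession(s) missing in one treatment, excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (is.null(traits)) traits <- intersect(colnames(ck), colnames(ak))
  ck <- ck[common, traits, drop = FALSE]
  ak <- ak[common, traits, drop = FALSE]
  bad_ck <- is.na(ck) | ck == 0
  s <- 100 * ak / ck
  s[bad_ck] <- NA_real_
  structure(s, year = year, n_flagged = sum(bad_ck | is.na(ak)),
            class = c("tolerance_index", class(s)))
}

#' PCA of the tolerance-index matrix
#'
#' Standardizes the index matrix (mean-imputing missing cells, logged) and
#' runs correlation-matrix PCA, retaining the smallest leading component set
#' whose cumulative variance contribution reaches `retain_threshold`
#' (default 0.80).
#'
#' @param index A [tolerance_index()] matrix.
#' @param retain_threshold Cumulative proportion of variance to reach.
#' @return A `pca_result` with `n_retained` and `n_imputed` fields set.
#' @export
index_pca_scores <- function(index, retain_threshold = 0.80) {
  if (nrow(index) < 2 || ncol(index) < 2)
    stop("need >= 2 accessions and >= 2 traits")
  xs <- standardize_matrix(unclass(index))
  p <- pca_corr(xs)
  p$n_retained <- retain_components(p, "cumulative_ge", retain_threshold)
  p$n_imputed <- attr(xs, "n_imputed")
  p
}

#' Fuzzy membership function for one component's scores
#'
#' Min-max normalization `Ui = (Si - Smin) / (Smax - Smin)` across accessions:
#' maps the component scores onto \[0, 1\], order-preserving, with at least
#' one accession at 0 and one at 1. A degenerate component (Smax = Smin) maps
#' everyone to 0.5 with a warning.
#'
#' @param scores Numeric vector of one component's scores.
#' @return Membership values in \[0, 1\].
#' @export
membership <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 accessions")
  smin <- min(scores); smax <- max(scores)
  if (smax == smin) {
    warning("degenerate component: all scores equal, membership set to 0.5")
    return(rep(0.5, length(scores)))
  }
  (scores - smin) / (smax - smin)
}

#' Variance-contribution weights over retained components
#'
#' `Wi = PVi / sum(PVi)` over the retained components only, so the weights sum
#' to one.
#'
#' @param pv Variance contributions of the retained components (> 0).
#' @return Weights summing to 1.
#' @export
component_weights <- function(pv) {
  if (length(pv) == 0) stop("empty retained component set")
  if (any(pv <= 0)) stop("variance contributions must be > 0")
  pv / sum(pv)
}

#' Comprehensive tolerance score D and ranking
#'
#' `D = sum_i Ui * Wi` over retained components: a weighted fuzzy-membership
#' aggregate in \[0, 1\], larger meaning more saline-alkali tolerant. Ranking
#' is descending by D with dense ranks (ties share a rank), stable by
#' accession id.
#'
#' @param U Accession x component membership matrix.
#' @param W Component weights (same length as `ncol(U)`, summing to 1).
#' @return data.frame: accession, D, rank — ordered by rank.
#' @export
comprehensive_score <- function(U, W) {
  U <- as.matrix(U)
  if (ncol(U) != length(W)) stop("dimension mismatch between U and W")
  D <- drop(U %*% W)
  acc <- rownames(U)
  if (is.null(acc)) acc <- as.character(seq_len(nrow(U)))
  out <- data.frame(accession = acc, D = D, stringsAsFactors = FALSE)
  out <- out[order(-out$D, out$accession), , drop = FALSE]
  out$rank <- dense_rank_desc(out$D)
  rownames(out) <- NULL
  out
}

#' Full comprehensive-evaluation pipeline for one year
#'
#' Composes [tolerance_index()], [index_pca_scores()], [membership()],
#' [component_weights()] and [comprehensive_score()], and reports full
#' provenance: retained component count, eigenvalues, variance contributions,
#' weights and the PC sign flips applied (D is not invariant to the sign
#' convention, so it is logged).
#'
#' @param table Long phenotype data.frame.
#' @param year Trial year.
#' @param drop_sr Drop seed-setting rate from the index (the one trait
#'   typically unaffected by the stress treatment), scoring 8 traits instead
#'   of 9.
#' @param retain_threshold Cumulative variance contribution to retain
#'   (default 0.80).
#' @return A `score_result`: `scores` data.frame (accession, PC scores, Ui, D,
#'   rank), `U`, `W`, `pv`, `eigenvalues`, `n_retained`, `sign_flips`,
#'   `year`, `traits`.
#' @export
score_pipeline <- function(table, year, drop_sr = FALSE, retain_threshold = 0.80) {
  traits <- sort(unique(table$trait))
  if (drop_sr) traits <- setdiff(traits, "SR")
  s <- tolerance_index(table, year, traits = traits)
  p <- index_pca_scores(s, retain_threshold = retain_threshold)
  k <- p$n_retained
  sc <- p$scores[, seq_len(k), drop = FALSE]
  U <- apply(sc, 2, membership)
  rownames(U) <- rownames(sc)
  W <- component_weights(p$pv[seq_len(k)])
  res <- comprehensive_score(U, W)
  ord <- match(res$accession, rownames(sc))
  scores <- cbind(res["accession"],
                  as.data.frame(sc[ord, , drop = FALSE], optional = TRUE),
                  stats::setNames(as.data.frame(U[ord, , drop = FALSE], optional = TRUE),
                                  paste0("U", seq_len(k))),
                  res[c("D", "rank")])
  rownames(scores) <- NULL
  structure(list(scores = scores, U = U, W = W,
                 pv = p$pv[seq_len(k)], eigenvalues = p$eigenvalues,
                 n_retained = k, sign_flips = p$sign_flips[seq_len(k)],
                 n_imputed = p$n_imputed, year = year, traits = traits),
            class = "score_result")
}

#' @export
print.score_result <- function(x, n = 10, ...) {
  cat(sprintf("comprehensive tolerance scores, year %s: %d accessions, %d traits, %d PCs (weights %s)\n",
              x$year, nrow(x$scores), length(x$traits), x$n_retained,
              paste(round(x$W, 3), collapse = "/")))
  print(utils::head(x$scores, n))
  invisible(x)
}
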