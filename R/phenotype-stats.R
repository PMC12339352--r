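# Descriptive statistics, coefficient of variation, Shannon-Weaver diversity
# and per-group Pearson correlation matrices for the trait panel.

#' Seed-setting rate
#'
#' SR = GN / (GN + UG): filled grains over total spikelets. Vectorised; a zero
#' total yields a missing value with a warning.
#'
#' @param GN Filled grain number (>= 0).
#' @param UG Unfilled grain number (>= 0).
#' @return Proportion in \[0, 1\].
#' @export
seed_setting_rate <- function(GN, UG) {
  if (any(GN < 0, na.rm = TRUE) || any(UG < 0, na.rm = TRUE))
    stop("grain counts must be non-negative")
  tot <- GN + UG
  out <- GN / tot
  if (any(tot == 0, na.rm = TRUE)) {
    warning("GN + UG = 0: seed-setting rate undefined, returning NA")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Shannon-Weaver diversity index H' (nats)
#'
#' `H' = -sum(Pi * ln(Pi))` with `Pi = Ni/N` over non-missing observations.
#' In `"distinct"` mode every distinct observed value is a group. In
#' `"binned"` mode values are cut into `k` classes: class 1 below
#' `mean - 2*SD`, class `k` at or above `mean + 2*SD`, and `k - 2` interior
#' classes of equal width `4*SD/(k-2)` — the germplasm-survey convention.
#'
#' @param values Numeric observations (NAs dropped).
#' @param mode `"distinct"` (default) or `"binned"`.
#' @param k Number of classes for binned mode (default 10).
#' @return H' in nats; 0 when all values are identical; at most `ln(N)`.
#' @export
shannon_diversity <- function(values, mode = c("distinct", "binned"), k = 10) {
  mode <- match.arg(mode)
  x <- values[!is.na(values)]
  if (length(x) == 0) stop("all values missing: H' undefined")
  if (mode == "distinct") {
    ni <- table(x)
  } else {
    if (k < 3) stop("binned mode needs k >= 3")
    mu <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(0)
    breaks <- c(-Inf, mu - 2 * s + 4 * s / (k - 2) * (0:(k - 2)), Inf)
    ni <- table(cut(x, breaks = breaks, right = FALSE))
  }
  p <- ni[ni > 0] / length(x)
  -sum(p * log(p))
}

#' Per-group trait summaries
#'
#' For each (year, treatment, trait) cell: n (non-missing), mean, sample SD,
#' CV = 100 * SD / mean, min, max and Shannon-Weaver H'. A zero mean leaves CV
#' missing and flags the row.
#'
#' @param table Long phenotype data.frame.
#' @param shannon_mode Grouping rule passed to [shannon_diversity()].
#' @param k Classes for binned Shannon mode.
#' @return data.frame keyed by (year, treatment, trait).
#' @export
trait_summary <- function(table, shannon_mode = "distinct", k = 10) {
  groups <- unique(table[c("year", "treatment", "trait")])
  groups <- groups[order(groups$year, groups$treatment, groups$trait), , drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    v <- table$value[table$year == g$year & table$treatment == g$treatment &
                     table$trait == g$trait]
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("need >= 2 non-missing values for ", g$trait,
                            " in ", g$year, " ", g$treatment)
    m <- mean(v); s <- stats::sd(v)
    cv <- if (m == 0) NA_real_ else 100 * s / m
    data.frame(year = g$year, treatment = g$treatment, trait = g$trait,
               n = length(v), mean = m, sd = s, cv = cv,
               cv_undefined = m == 0, min = min(v), max = max(v),
               shannon = shannon_diversity(v, mode = shannon_mode, k = k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise-complete Pearson correlation matrix for one trial group
#'
#' Computes the trait-by-trait Pearson correlation within one (year,
#' treatment) group, with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df, `n` being the
#' pairwise-complete count. A zero-variance trait leaves its row/column
#' missing with a warning.
#'
#' @param table Long phenotype data.frame.
#' @param year,treatment Group selectors.
#' @return List with `r`, `p` and `n` (trait x trait matrices) plus the group
#'   label.
#' @export
correlation_matrix <- function(table, year, treatment) {
  w <- pheno_wide(table, year, treatment)
  k <- ncol(w)
  zero_var <- apply(w, 2, function(x) stats::var(x, na.rm = TRUE) == 0)
  if (any(zero_var))
    warning("zero-variance trait(s): ", paste(colnames(w)[zero_var], collapse = ", "))
  r <- suppressWarnings(stats::cor(w, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(w))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { p[i, j] <- 0; next }
    n <- nmat[i, j]
    if (n < 3 || is.na(r[i, j])) next
    if (abs(r[i, j]) >= 1) { p[i, j] <- 0; next }
    tt <- r[i, j] * sqrt((n - 2) / (1 - r[i, j]^2))
    p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  diag(r) <- 1
  list(r = r, p = p, n = nmat, year = year, treatment = treatment)
}
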