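#!/usr/bin/env Rscript
# Multivariate structure of the phenotypes per year x treatment: correlation
# PCA (eigenvalues, variance contributions, loadings, scores) with the
# Kaiser eigenvalue > 1 retention rule, and Ward (minimum variance)
# hierarchical clustering of the standardized data cut at k = 3.

suppressMessages(library(satol))

pheno <- read_phenotypes("results/fixtures/phenotypes.csv")

for (yr in unique(pheno$year)) for (tr in c("CK", "AK")) {
  w <- satol:::pheno_wide(pheno, yr, tr)
  xs <- standardize_matrix(w)
  p <- pca_corr(xs)
  k <- retain_components(p, "eigenvalue_gt", 1)
  tag <- sprintf("%s_%s", yr, tr)
  write.table(data.frame(component = seq_along(p$eigenvalues),
                         eigenvalue = p$eigenvalues, pv = p$pv,
                         cum_pv = p$cum_pv),
              sprintf("results/pca_eigen_%s.tsv", tag), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(round(p$loadings, 4), sprintf("results/pca_loadings_%s.tsv", tag),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(round(p$scores, 4), sprintf("results/pca_scores_%s.tsv", tag),
              sep = "\t", quote = FALSE, col.names = NA)

  cl <- ward_cluster(xs, 3)
  write.table(data.frame(accession = rownames(xs), cluster = cl$labels),
              sprintf("results/clusters_%s.tsv", tag), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("%s: %d PCs with eigenvalue > 1 (cum PV %.1f%%); Ward k=3 sizes: %s\n",
              tag, k, 100 * p$cum_pv[k],
              paste(table(cl$labels), collapse = "/")))
}
cat("PCA tables -> results/pca_*_<group>.tsv; clusters -> results/clusters_<group>.tsv\n")
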