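# Shared fixture builders; everything is generated in code at test time.

small_config <- function(seed = 1, ...) {
  args <- list(n_accessions = 40, n_markers = 120, n_chromosomes = 3,
               chrom_length_bp = 1e6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# noiseless configuration: every variance 0, fixed tolerance ratio
noiseless_config <- function(base = 0.85, seed = 1, ...) {
  small_config(seed = seed, var_genotype = 0, var_year = 0, var_gxy = 0,
               var_gxl = 0, var_residual = 0, n_causal = 0,
               tolerance_ratio_base = base, tolerance_ratio_sd = 0, ...)
}

# long-format phenotype table from an accession x trait matrix, one
# (year, treatment) group per call
long_table <- function(mat, year = 2016, treatment = "CK") {
  data.frame(accession = rep(rownames(mat), ncol(mat)),
             year = year, treatment = treatment,
             trait = rep(colnames(mat), each = nrow(mat)),
             value = as.vector(mat), stringsAsFactors = FALSE)
}

# frozen from the first verified run of the seed-2024 30-accession pipeline
GOLDEN_TOP3 <- data.frame(
  accession = c("S14", "S16", "S25"),
  D = c(1.000000000000000, 0.949737763865055, 0.866076732786571),
  stringsAsFactors = FALSE)

pheno_long_sort <- function(d) {
  d <- d[order(d$accession, d$year, d$treatment, d$trait), ]
  rownames(d) <- NULL
  d
}

# hand-built gene models: genes (gene_id, chrom, start, end, strand) and an
# exon layout; introns are the gaps between consecutive exons
make_gene_models <- function(genes, exons) {
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# one gene spanning [start, end] with a single whole-span exon
single_exon_gene <- function(gene_id = "GX", chrom = 1, start = 1000, end = 2000) {
  make_gene_models(
    genes = data.frame(gene_id = gene_id, chrom = chrom, start = start,
                       end = end, strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(gene_id = gene_id, chrom = chrom, start = start,
                       end = end, exon_number = 1L, stringsAsFactors = FALSE))
}
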