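# Candidate-region annotation around associated markers: genes within a
# +/- window (default 150 kb per side, the LD-decay scale of temperate
# japonica), nearest-gene distance with exon/intron context, and
# region-level variant classification.

#' Candidate region around an associated marker
#'
#' Collects the genes whose span intersects `[pos - window, pos + window]`
#' (1-based inclusive, clipped at 1). Distance to each gene is 0 when the
#' marker lies inside the gene span, else the gap to the nearest span edge.
#' The nearest gene is the minimum-distance gene, ties broken by lower start
#' coordinate; when the marker is inside it, the context is `"exon"` or
#' `"intron"` by the gene's exon intervals.
#'
#' @param marker List or one-row data.frame with `chrom` and `pos` (and
#'   optionally `id`).
#' @param models A `gene_models` list.
#' @param window Half-window in bp (default 150000).
#' @return A `candidate_region`: marker, window bounds, `genes` data.frame
#'   with distances, `nearest_gene`, `nearest_distance`, `context`.
#' @export
candidate_region <- function(marker, models, window = 150000) {
  chrom <- marker$chrom; pos <- marker$pos
  g <- models$genes
  if (!chrom %in% g$chrom)
    stop("chromosome ", chrom, " absent from the gene models")
  lo <- max(1, pos - window); hi <- pos + window
  gc <- g[g$chrom == chrom, , drop = FALSE]
  win <- IRanges::IRanges(lo, hi)
  spans <- IRanges::IRanges(gc$start, gc$end)
  hit <- IRanges::overlapsAny(spans, win)
  genes <- gc[hit, , drop = FALSE]
  if (nrow(genes) == 0) {
    return(structure(list(marker = marker, window = c(lo, hi), genes = genes,
                          nearest_gene = NA_character_,
                          nearest_distance = NA_real_, context = "intergenic"),
                     class = "candidate_region"))
  }
  genes$distance <- ifelse(pos >= genes$start & pos <= genes$end, 0,
                           pmin(abs(pos - genes$start), abs(pos - genes$end)))
  genes <- genes[order(genes$distance, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  nearest <- genes[1, ]
  context <- if (nearest$distance > 0) "upstream/downstream" else {
    ex <- models$exons[models$exons$gene_id == nearest$gene_id, , drop = FALSE]
    if (any(pos >= ex$start & pos <= ex$end)) "exon" else "intron"
  }
  structure(list(marker = marker, window = c(lo, hi), genes = genes,
                 nearest_gene = nearest$gene_id,
                 nearest_distance = nearest$distance, context = context),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  id <- if (!is.null(x$marker$id)) x$marker$id else
    paste0("chr", x$marker$chrom, ":", x$marker$pos)
  cat(sprintf("candidate region %s [%d, %d]: %d gene(s); nearest %s (%s)\n",
              id, x$window[1], x$window[2], nrow(x$genes),
              x$nearest_gene,
              if (identical(x$nearest_distance, 0)) x$context
              else paste0(x$nearest_distance, " bp")))
  invisible(x)
}

#' Region-level variant classification
#'
#' Labels each variant exonic, intronic or intergenic by interval overlap
#' with the gene models (priority exon > intron > intergenic), and SNP vs
#' InDel by allele length (any allele of length != 1 makes an InDel). Returns
#' the labelled table and class counts.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param models A `gene_models` list.
#' @return List: `variants` (with `region` and `type` columns) and `counts`
#'   (named vector: exonic, intronic, intergenic, SNP, InDel).
#' @export
classify_variants <- function(variants, models) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  vr <- GenomicRanges::GRanges(as.character(v$chrom),
                               IRanges::IRanges(v$pos, v$pos))
  ex <- models$exons; g <- models$genes
  exr <- GenomicRanges::GRanges(as.character(ex$chrom),
                                IRanges::IRanges(ex$start, ex$end))
  gr <- GenomicRanges::GRanges(as.character(g$chrom),
                               IRanges::IRanges(g$start, g$end))
  in_exon <- IRanges::overlapsAny(vr, exr)
  in_gene <- IRanges::overlapsAny(vr, gr)
  v$region <- ifelse(in_exon, "exonic", ifelse(in_gene, "intronic", "intergenic"))
  v$type <- ifelse(nchar(v$ref) == 1 & nchar(v$alt) == 1, "SNP", "InDel")
  counts <- c(exonic = sum(v$region == "exonic"),
              intronic = sum(v$region == "intronic"),
              intergenic = sum(v$region == "intergenic"),
              SNP = sum(v$type == "SNP"),
              InDel = sum(v$type == "InDel"))
  list(variants = v, counts = counts)
}
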