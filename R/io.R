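# File formats: phenotype CSV (wide), genotype VCF 4.2 / dosage TSV,
# gene models GFF3 (1-based inclusive).

#' Write / read the phenotype table
#'
#' The CSV schema is wide: `accession, year, treatment` then one column per
#' trait. Internally the pipeline uses the long form (accession, year,
#' treatment, trait, value).
#'
#' @param table Long-format phenotype data.frame.
#' @param path Output CSV path.
#' @export
write_phenotypes <- function(table, path) {
  traits <- unique(table$trait)
  keys <- unique(table[c("accession", "year", "treatment")])
  keys <- keys[order(keys$year, keys$treatment, keys$accession), , drop = FALSE]
  wide <- keys
  for (tr in traits) {
    sub <- table[table$trait == tr, , drop = FALSE]
    i <- match(paste(keys$accession, keys$year, keys$treatment),
               paste(sub$accession, sub$year, sub$treatment))
    wide[[tr]] <- sub$value[i]
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @return `read_phenotypes()` returns the long-format phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "year", "treatment")
  if (!all(need %in% names(wide)))
    stop("parse error: phenotype CSV must have columns ", paste(need, collapse = ", "))
  traits <- setdiff(names(wide), need)
  long <- do.call(rbind, lapply(traits, function(tr)
    data.frame(accession = wide$accession, year = wide$year,
               treatment = wide$treatment, trait = tr, value = wide[[tr]],
               stringsAsFactors = FALSE)))
  bad <- long$trait == "SR" & !is.na(long$value) & (long$value < 0 | long$value > 1)
  if (any(bad)) stop("invalid phenotype table: SR outside [0, 1]")
  rownames(long) <- NULL
  long
}

# minimal VCF 4.2 emitter for the simulated biallelic SNPs (GT only)
write_vcf <- function(genotypes, path) {
  map <- genotypes$map
  d <- genotypes$dosage
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste0("##contig=<ID=", unique(map$chrom), ">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  body <- paste(map$chrom, map$pos, map$id, map$ref, map$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(accession = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  map_path <- sub("\\.tsv$", ".map.tsv", path)
  utils::write.table(genotypes$map, map_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or a dosage TSV mirror
#'
#' VCF: biallelic SNP sites only (multiallelic sites are skipped with a
#' warning); dosage is the alternate-allele count from the GT field, `./.`
#' becomes missing. TSV mirror: first column `accession`, remaining columns
#' one marker each with values 0/1/2; a sibling `*.map.tsv` provides the
#' marker map if present.
#'
#' @param path Path to a `.vcf` or `.tsv` file.
#' @return A `genotype_matrix` (see [simulate_genotypes()]); minor-allele
#'   frequency is computed on non-missing calls.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(z) {
      if (any(z == "." | is.na(z))) return(NA_real_)
      sum(z != "0")
    }, numeric(1))
  }
  dosage <- apply(gt, 2, alt_count)
  dosage <- t(dosage)  # accession x marker
  colnames(dosage) <- rownames(gt)
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("S", fix$CHROM, "_", fix$POS)[is.na(id) | id == "."]
  map <- data.frame(id = id, chrom = type.convert(fix$CHROM, as.is = TRUE),
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  new_genotype_matrix(dosage, map)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "accession")
    stop("parse error: dosage TSV must start with an 'accession' column")
  dosage <- as.matrix(df[, -1, drop = FALSE])
  rownames(dosage) <- df$accession
  storage.mode(dosage) <- "double"
  map_path <- sub("\\.tsv$", ".map.tsv", path)
  map <- if (file.exists(map_path))
    utils::read.table(map_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else {
    # fall back to parsing ids of the form S<chrom>_<pos>
    ids <- colnames(dosage)
    chrom <- suppressWarnings(as.integer(sub("^S([0-9]+)_([0-9]+)$", "\\1", ids)))
    pos <- suppressWarnings(as.integer(sub("^S([0-9]+)_([0-9]+)$", "\\2", ids)))
    data.frame(id = ids, chrom = chrom, pos = pos, ref = NA_character_,
               alt = NA_character_, stringsAsFactors = FALSE)
  }
  new_genotype_matrix(dosage, map)
}

#' Write / read gene models as GFF3
#'
#' Gene and exon features, 1-based inclusive coordinates, exons carrying a
#' `Parent` attribute pointing at their gene.
#'
#' @param models A `gene_models` list (see [simulate_gene_models()]).
#' @param path GFF3 path.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes; e <- models$exons
  gr_g <- GenomicRanges::GRanges(
    seqnames = as.character(g$chrom),
    ranges = IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  strand_e <- g$strand[match(e$gene_id, g$gene_id)]
  gr_e <- GenomicRanges::GRanges(
    seqnames = as.character(e$chrom),
    ranges = IRanges::IRanges(e$start, e$end), strand = strand_e,
    type = "exon", ID = paste0(e$gene_id, ".exon", e$exon_number))
  gr_e$Parent <- as(as.list(e$gene_id), "CharacterList")
  gr_g$Parent <- as(rep(list(character(0)), length(gr_g)), "CharacterList")
  rtracklayer::export(c(gr_g, gr_e), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @return `read_gene_models()` returns a `gene_models` list.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  g <- data.frame(gene_id = as.character(gr$ID[is_gene]),
                  chrom = type.convert(as.character(GenomicRanges::seqnames(gr[is_gene])), as.is = TRUE),
                  start = GenomicRanges::start(gr[is_gene]),
                  end = GenomicRanges::end(gr[is_gene]),
                  strand = as.character(GenomicRanges::strand(gr[is_gene])),
                  stringsAsFactors = FALSE)
  is_exon <- gr$type == "exon"
  parent <- vapply(gr$Parent[is_exon], function(p) p[1], character(1))
  e <- data.frame(gene_id = parent,
                  chrom = type.convert(as.character(GenomicRanges::seqnames(gr[is_exon])), as.is = TRUE),
                  start = GenomicRanges::start(gr[is_exon]),
                  end = GenomicRanges::end(gr[is_exon]),
                  stringsAsFactors = FALSE)
  e <- e[order(e$gene_id, e$start), , drop = FALSE]
  e$exon_number <- stats::ave(e$start, e$gene_id, FUN = seq_along)
  rownames(e) <- NULL
  o <- order(g$chrom, g$start)
  g <- g[o, , drop = FALSE]; rownames(g) <- NULL
  structure(list(genes = g, exons = e), class = "gene_models")
}
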