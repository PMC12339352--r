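#' Configuration for the synthetic saline-alkali field trial
#'
#' Bundles every knob of the synthetic trial: dimensions (accessions, years,
#' treatments, traits, markers, chromosomes), per-trait variance components of
#' the phenotype model, and the genetics of the stress response (number of
#' causal markers, their effects on the per-accession tolerance ratio, the
#' baseline stress/control ratio and its residual spread).
#'
#' The phenotype model is multiplicative in the stress treatment: control (CK)
#' values follow an additive genotype + year + genotype-by-year + residual
#' model, and stress (AK) values are the CK values scaled by a per-accession
#' tolerance ratio plus a genotype-by-treatment deviation and fresh residual
#' noise. Causal markers act on the tolerance ratio, not on the raw traits, so
#' the stress/control index is the natural estimand downstream.
#'
#' `var_treatment` is accepted for completeness but defaults to 0: the
#' treatment main effect is governed by `tolerance_ratio_base` in the
#' multiplicative model.
#'
#' @param n_accessions Number of accessions (default 450, the trial size).
#' @param n_years Number of years (default 2).
#' @param n_treatments Number of treatments; fixed at 2 (CK control, AK stress).
#' @param n_traits Number of traits (default 9; the standard trait panel).
#' @param n_markers Number of biallelic SNP markers.
#' @param n_chromosomes Number of chromosomes (default 12, the rice karyotype).
#' @param chrom_length_bp Chromosome length in bp (default 30 Mb).
#' @param maf_range Range the per-marker minor-allele frequency is drawn from,
#'   within (0, 0.5].
#' @param var_genotype,var_year,var_treatment,var_gxy,var_gxl,var_residual
#'   Per-trait variances (length 1 or `n_traits`). Defaults scale with the
#'   squared trait mean so every trait has a realistic coefficient of
#'   variation.
#' @param n_causal Number of causal markers acting on the tolerance ratio.
#' @param causal_effect_sizes Effect of each causal marker on the tolerance
#'   ratio per alternate-allele dosage unit (length `n_causal`).
#' @param tolerance_ratio_base Mean AK/CK ratio in (0, 1]; values below 1 make
#'   stress depress growth.
#' @param tolerance_ratio_sd Residual SD of the per-accession ratio.
#' @param ld_block_size Markers per linkage block; 1 (default) simulates
#'   unlinked markers, larger values copy a block template with mutation.
#' @param seed Master seed; component sub-streams are derived from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_accessions = 450, n_years = 2, n_treatments = 2,
                       n_traits = 9, n_markers = 3000, n_chromosomes = 12,
                       chrom_length_bp = 3e7, maf_range = c(0.05, 0.5),
                       var_genotype = NULL, var_year = NULL,
                       var_treatment = 0, var_gxy = NULL, var_gxl = NULL,
                       var_residual = NULL,
                       n_causal = 3, causal_effect_sizes = c(0.15, 0.12, 0.10),
                       tolerance_ratio_base = 0.85, tolerance_ratio_sd = 0.05,
                       ld_block_size = 1, seed = 1) {
  if (n_accessions < 2 || n_markers < 1 || n_chromosomes < 1 ||
      n_years < 1 || n_traits < 1 || chrom_length_bp < 1)
    stop("configuration error: non-positive or degenerate dimensions")
  if (n_treatments != 2)
    stop("configuration error: the trial design has exactly 2 treatments (CK, AK)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("configuration error: maf_range must lie within (0, 0.5]")
  if (n_causal > n_markers)
    stop("configuration error: n_causal exceeds n_markers")
  if (tolerance_ratio_base <= 0)
    stop("configuration error: tolerance_ratio_base must be positive")

  traits <- if (n_traits == nrow(TRAIT_INFO)) TRAIT_INFO$trait else
    paste0("T", seq_len(n_traits))
  mu <- if (n_traits == nrow(TRAIT_INFO)) TRAIT_INFO$mean else
    rep(10, n_traits)

  per_trait <- function(x, default) {
    v <- if (is.null(x)) default else rep_len(x, n_traits)
    if (any(v < 0)) stop("configuration error: variances must be >= 0")
    stats::setNames(v, traits)
  }
  cfg <- list(
    n_accessions = as.integer(n_accessions), n_years = as.integer(n_years),
    n_treatments = 2L, n_traits = as.integer(n_traits),
    n_markers = as.integer(n_markers), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp), maf_range = maf_range,
    traits = traits, trait_means = stats::setNames(mu, traits),
    var_genotype  = per_trait(var_genotype,  (0.10 * mu)^2),
    var_year      = per_trait(var_year,      (0.05 * mu)^2),
    var_treatment = per_trait(var_treatment, rep(0, n_traits)),
    var_gxy       = per_trait(var_gxy,       (0.04 * mu)^2),
    var_gxl       = per_trait(var_gxl,       (0.03 * mu)^2),
    var_residual  = per_trait(var_residual,  (0.08 * mu)^2),
    n_causal = as.integer(n_causal),
    causal_effect_sizes = rep_len(causal_effect_sizes, max(n_causal, 1L))[seq_len(n_causal)],
    tolerance_ratio_base = tolerance_ratio_base,
    tolerance_ratio_sd = tolerance_ratio_sd,
    ld_block_size = as.integer(ld_block_size),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genotype matrix of biallelic SNP dosages
#'
#' Draws a per-marker alternate-allele frequency uniformly from
#' `config$maf_range` and samples dosages from Binomial(2, p) per accession,
#' i.e. an unstructured panmictic population. Markers are spread over
#' `n_chromosomes` chromosomes at strictly increasing positions. With
#' `ld_block_size > 1`, consecutive markers within a block are copies of the
#' block template with 5% per-genotype mutation, giving local LD for
#' region-level tests.
#'
#' @param config A [sim_config()] object.
#' @return A `genotype_matrix`: list with `dosage` (accession x marker matrix
#'   of 0/1/2), `map` (data.frame: id, chrom, pos, ref, alt) and `maf`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[1])
  n <- config$n_accessions; m <- config$n_markers
  acc <- paste0("S", seq_len(n))

  # chromosome assignment: contiguous, nearly even
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    if (length(idx) > config$chrom_length_bp)
      stop("configuration error: more markers than base pairs on chromosome ", c)
    pos[idx] <- sort(sample.int(config$chrom_length_bp, length(idx)))
  }

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  if (config$ld_block_size > 1L) {
    block <- (seq_len(m) - 1L) %/% config$ld_block_size
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) < 2L) next
      template <- dosage[, idx[1]]
      for (j in idx[-1]) {
        mut <- stats::runif(n) < 0.05
        dosage[, j] <- ifelse(mut, stats::rbinom(n, 2L, p[j]), template)
      }
    }
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  map <- data.frame(id = paste0("S", chrom, "_", pos), chrom = chrom, pos = pos,
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  dimnames(dosage) <- list(acc, map$id)
  new_genotype_matrix(dosage, map)
}

new_genotype_matrix <- function(dosage, map) {
  af <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, map = map, maf = pmin(af, 1 - af)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "accessions x", ncol(x$dosage),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Simulate the two-treatment multi-year phenotype trial
#'
#' For each trait the control (CK) observation is
#' `mu + g_i + y_j + gy_ij + e` with independent normal effects at the
#' configured variances; the stress (AK) observation is
#' `CK * r_i + gl_i + e'`, where the per-accession tolerance ratio is
#' `r_i = base + sum_k beta_k (x_ik - mean_k) + N(0, sd)`, floored at 1e-3.
#' Causal markers therefore shift tolerance, not raw growth. Seed-setting rate
#' is clamped to \[0, 1\] and all traits to non-negative values.
#'
#' @param config A [sim_config()].
#' @param genotypes The matching [simulate_genotypes()] output.
#' @return List with `phenotypes` (long data.frame: accession, year, treatment,
#'   trait, value) and `truth` (causal marker ids and effects, per-accession
#'   true ratio, per-trait variance components, true tolerance ranking).
#' @export
simulate_phenotypes <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  acc <- rownames(genotypes$dosage)
  if (length(acc) != config$n_accessions)
    stop("consistency error: genotype accessions do not match the configuration")
  seeds <- derive_seeds(config$seed)

  # causal architecture of the tolerance ratio (own sub-stream)
  set.seed(seeds[2])
  n <- config$n_accessions
  causal_idx <- if (config$n_causal > 0)
    sort(sample.int(config$n_markers, config$n_causal)) else integer(0)
  r <- rep(config$tolerance_ratio_base, n)
  if (length(causal_idx)) {
    X <- genotypes$dosage[, causal_idx, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    r <- r + drop(Xc %*% config$causal_effect_sizes)
  }
  r <- r + stats::rnorm(n, 0, config$tolerance_ratio_sd)
  r <- pmax(r, 1e-3)
  names(r) <- acc

  set.seed(seeds[3])
  years <- 2016L + seq_len(config$n_years) - 1L
  out <- vector("list", config$n_traits)
  for (t in seq_len(config$n_traits)) {
    trait <- config$traits[t]
    mu <- config$trait_means[t]
    g  <- stats::rnorm(n, 0, sqrt(config$var_genotype[t]))
    yj <- stats::rnorm(config$n_years, 0, sqrt(config$var_year[t]))
    gl <- stats::rnorm(n, 0, sqrt(config$var_gxl[t]))
    rows <- vector("list", config$n_years)
    for (j in seq_len(config$n_years)) {
      gy <- stats::rnorm(n, 0, sqrt(config$var_gxy[t]))
      e_ck <- stats::rnorm(n, 0, sqrt(config$var_residual[t]))
      e_ak <- stats::rnorm(n, 0, sqrt(config$var_residual[t]))
      ck <- mu + g + yj[j] + gy + e_ck
      ak <- ck * r + gl + e_ak
      rows[[j]] <- data.frame(
        accession = rep(acc, 2L), year = years[j],
        treatment = rep(c("CK", "AK"), each = n),
        trait = trait, value = c(ck, ak), stringsAsFactors = FALSE)
    }
    out[[t]] <- do.call(rbind, rows)
  }
  pheno <- do.call(rbind, out)
  # physical clamps
  pheno$value <- pmax(pheno$value, 0)
  if ("SR" %in% config$traits)
    pheno$value[pheno$trait == "SR"] <- pmin(pheno$value[pheno$trait == "SR"], 1)

  ranking <- acc[order(-r, acc)]
  truth <- list(
    causal_marker_ids = genotypes$map$id[causal_idx],
    causal_effect_sizes = config$causal_effect_sizes,
    tolerance_ratio = r,
    variance_components = lapply(stats::setNames(seq_len(config$n_traits), config$traits),
      function(t) list(VA = config$var_genotype[[t]], VAY = config$var_gxy[[t]],
                       VAL = config$var_gxl[[t]], Ve = config$var_residual[[t]])),
    ranking = ranking
  )
  list(phenotypes = pheno, truth = truth)
}

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` non-overlapping genes across the configured chromosomes,
#' each with 1-5 exons inside the gene span (the first exon starts at the gene
#' start and the last ends at the gene end). Coordinates are 1-based inclusive.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes (> 0).
#' @return A `gene_models` list with `genes` (gene_id, chrom, start, end,
#'   strand) and `exons` (gene_id, chrom, start, end, exon_number).
#' @export
simulate_gene_models <- function(config, n_genes = 60) {
  stopifnot(inherits(config, "sim_config"))
  if (n_genes <= 0) stop("configuration error: n_genes must be > 0")
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[4])
  chrom_of <- rep_len(seq_len(config$n_chromosomes), n_genes)
  genes <- NULL; exons <- NULL; gid <- 0L
  for (c in seq_len(config$n_chromosomes)) {
    k <- sum(chrom_of == c)
    if (k == 0) next
    len <- sample(2000:6000, k, replace = TRUE)
    if (sum(len) + k > config$chrom_length_bp)
      stop("configuration error: genes cannot fit on chromosome ", c)
    slack <- config$chrom_length_bp - sum(len)
    gaps <- diff(c(0, sort(sample.int(slack, k))))
    start <- cumsum(gaps) + cumsum(c(0, len[-k])) + 1L
    end <- start + len - 1L
    for (i in seq_len(k)) {
      gid <- gid + 1L
      id <- sprintf("G%02dg%04d", c, gid)
      genes <- rbind(genes, data.frame(
        gene_id = id, chrom = c, start = start[i], end = end[i],
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE))
      ne <- sample.int(5L, 1L)
      # alternate exon/intron segments spanning the whole gene
      cuts <- if (ne > 1L)
        sort(sample(seq.int(start[i] + 1L, end[i] - 1L), 2L * (ne - 1L))) else integer(0)
      bounds <- c(start[i], cuts, end[i])
      es <- bounds[seq(1, length(bounds), by = 2)]
      ee <- bounds[seq(2, length(bounds), by = 2)]
      exons <- rbind(exons, data.frame(
        gene_id = id, chrom = c, start = es, end = ee,
        exon_number = seq_along(es), stringsAsFactors = FALSE))
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write a complete fixture set for the pipeline
#'
#' Simulates genotypes, phenotypes and gene models under one configuration and
#' writes: the phenotype CSV, the genotype VCF and its TSV dosage mirror, the
#' GFF3 gene models, the ground-truth JSON, and a manifest recording the seed,
#' an md5 hash of the configuration and every file written.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @param n_genes Number of genes to simulate.
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_fixture_set <- function(config, out_dir, n_genes = 60) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  geno <- simulate_genotypes(config)
  sim <- simulate_phenotypes(config, geno)
  genes <- simulate_gene_models(config, n_genes = n_genes)

  paths <- c(
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    dosage_tsv = file.path(out_dir, "genotypes_dosage.tsv"),
    gff3 = file.path(out_dir, "genes.gff3"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_phenotypes(sim$phenotypes, paths[["phenotypes"]])
  write_vcf(geno, paths[["vcf"]])
  write_dosage_tsv(geno, paths[["dosage_tsv"]])
  write_gene_models(genes, paths[["gff3"]])
  truth <- sim$truth
  truth$variance_components <- lapply(truth$variance_components, as.list)
  truth$tolerance_ratio <- as.list(truth$tolerance_ratio)  # keep accession names
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)

  cfg_file <- tempfile(); on.exit(unlink(cfg_file))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), cfg_file)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   files = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
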