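test_that("the VCF reader applies the dosage coding and skips bad sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "1\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tm2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t0/0",
    "1\t300\tm3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",
    "1\t400\tm4\tT\tC\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1"), path)
  expect_warning(g <- read_genotypes(path), "multiallelic")
  expect_equal(colnames(g$dosage), c("m1", "m2", "m4"))
  expect_equal(unname(g$dosage[, "m1"]), c(0, 1, 2))
  expect_true(is.na(g$dosage["S1", "m2"]))
  expect_equal(unname(g$dosage[, "m4"]), c(2, 0, 1))  # phased GT accepted
  expect_equal(g$map$pos, c(100L, 200L, 400L))
  # MAF on non-missing calls: m2 has one alt in four called alleles
  expect_equal(unname(g$maf["m2"]), 0.25)
})

test_that("marker filters remove what a brute-force recount says they should", {
  cfg <- small_config(seed = 13, maf_range = c(0.02, 0.5))
  g <- simulate_genotypes(cfg)
  g$dosage[1:10, 5] <- NA  # 25% missing at marker 5

  ident <- filter_markers(g, maf_min = 0, missing_max = 1)
  expect_equal(ncol(ident$dosage), ncol(g$dosage))

  f <- filter_markers(g, maf_min = 0.05, missing_max = 0.2)
  af <- colMeans(g$dosage, na.rm = TRUE) / 2
  keep_oracle <- pmin(af, 1 - af) >= 0.05 & colMeans(is.na(g$dosage)) <= 0.2
  expect_equal(colnames(f$dosage), colnames(g$dosage)[keep_oracle])
  rep <- attr(f, "filter_report")
  expect_equal(unname(rep["n_kept"]), sum(keep_oracle))
  expect_equal(unname(rep["n_input"]), ncol(g$dosage))

  # a monomorphic marker never survives a positive MAF floor
  g$dosage[, 3] <- 0
  f2 <- filter_markers(g, maf_min = 0.01, missing_max = 1)
  expect_false(colnames(g$dosage)[3] %in% colnames(f2$dosage))
})

test_that("VanRaden kinship matches the hand formula and its identities", {
  set.seed(19)
  d <- matrix(rbinom(40, 2, 0.4), 5, 8,
              dimnames = list(paste0("S", 1:5), paste0("m", 1:8)))
  g <- satol:::new_genotype_matrix(d, data.frame(id = paste0("m", 1:8),
                                                 chrom = 1, pos = 1:8,
                                                 ref = "A", alt = "C"))
  K <- kinship(g)
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  K_hand <- Z %*% t(Z) / (2 * sum(p * (1 - p)))
  expect_equal(K, K_hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(K - t(K))), 1e-12)

  # duplicated accessions are identical by state
  d2 <- rbind(d, S6 = d["S1", ])
  g2 <- satol:::new_genotype_matrix(d2, g$map)
  K2 <- kinship(g2)
  expect_equal(K2["S1", "S6"], K2["S1", "S1"], tolerance = 1e-12)

  # unstructured population: mean diagonal near 1
  cfg <- sim_config(n_accessions = 200, n_markers = 500, seed = 3)
  Kbig <- kinship(simulate_genotypes(cfg))
  expect_lt(abs(mean(diag(Kbig)) - 1), 0.1)
  expect_error(kinship(satol:::new_genotype_matrix(d[, 1, drop = FALSE],
                                                   g$map[1, ])), ">= 2 markers")
})

test_that("the mixed-model scan collapses to OLS at K = identity", {
  cfg <- small_config(seed = 29, n_accessions = 50)
  g <- simulate_genotypes(cfg)
  set.seed(30)
  y <- setNames(rnorm(50), rownames(g$dosage))
  K <- diag(50); dimnames(K) <- list(names(y), names(y))
  gw <- suppressWarnings(mlm_scan(y, g, K))
  p_ols <- vapply(seq_len(ncol(g$dosage)), function(j) {
    x <- g$dosage[, j]
    if (var(x) == 0) return(NA_real_)
    summary(lm(y ~ x))$coefficients[2, 4]
  }, numeric(1))
  ok <- !is.na(p_ols)
  expect_lt(max(abs(gw$scan$p[ok] - p_ols[ok])), 1e-6)
})

test_that("the scan is invariant to consistent accession reordering", {
  cfg <- small_config(seed = 37, n_accessions = 40)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(cfg, g)
  res <- score_pipeline(sim$phenotypes, 2016)
  y <- setNames(res$scores$D, res$scores$accession)
  K <- kinship(g)
  gw1 <- suppressWarnings(mlm_scan(y, g, K))

  perm <- sample(names(y))
  g2 <- g; g2$dosage <- g$dosage[perm, ]
  gw2 <- suppressWarnings(mlm_scan(y[perm], g2, K[perm, perm]))
  expect_equal(gw2$scan$p, gw1$scan$p, tolerance = 1e-8)

  # non-PSD K is refused with advice
  Kbad <- K; Kbad[1, 2] <- Kbad[2, 1] <- 1e4
  expect_error(suppressWarnings(mlm_scan(y, g, Kbad)), "jitter")
})

test_that("significance flags agree with the threshold and a recount", {
  cfg <- sim_config(n_accessions = 120, n_markers = 400, n_causal = 1,
                    causal_effect_sizes = 0.3, tolerance_ratio_sd = 0.02,
                    seed = 41)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(cfg, g)
  res <- score_pipeline(sim$phenotypes, 2016)
  y <- setNames(res$scores$D, res$scores$accession)
  gw <- suppressWarnings(mlm_scan(y, g, kinship(g)))
  expect_equal(gw$threshold, log10(400))
  expect_equal(gw$scan$significant, gw$scan$neglog10p >= gw$threshold)
  expect_setequal(gw$significant,
                  gw$scan$marker[-log10(gw$scan$p) >= log10(400)])
  expect_true(all(gw$scan$p > 0 & gw$scan$p <= 1))
})

test_that("Bonferroni thresholds follow log10(m)", {
  expect_equal(bonferroni_threshold(10), 1)
  expect_equal(bonferroni_threshold(1), 0)
  expect_equal(bonferroni_threshold(1e6), 6)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("Manhattan/QQ exports are well-formed and calibrated on uniform p", {
  cfg <- small_config(seed = 43, n_accessions = 40)
  g <- simulate_genotypes(cfg)
  set.seed(44)
  y <- setNames(rnorm(40), rownames(g$dosage))
  K <- diag(40); dimnames(K) <- list(names(y), names(y))
  gw <- suppressWarnings(mlm_scan(y, g, K))
  ex <- export_manhattan_qq(gw)
  expect_equal(nrow(ex$qq), nrow(gw$scan))
  expect_true(all(diff(ex$manhattan$cum_pos) > 0))
  expect_equal(ex$qq$expected, sort(ex$qq$expected, decreasing = TRUE))

  # DKW envelope on the p-value ECDF across 20 fixed seeds, m = 2000
  m <- 2000
  eps <- sqrt(log(2 / 1e-4) / (2 * m))
  for (s in 1:20) {
    set.seed(s)
    fake <- gw
    fake$scan <- data.frame(marker = paste0("m", 1:m), chrom = 1L,
                            pos = seq_len(m), neglog10p = -log10(runif(m)))
    fake$scan$p <- 10^(-fake$scan$neglog10p)
    ex2 <- export_manhattan_qq(fake)
    p_sorted <- sort(10^(-ex2$qq$observed))
    expect_lt(max(abs(p_sorted - (seq_len(m) - 0.5) / m)), eps + 0.5 / m)
  }
})
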