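test_that("genotype generation is deterministic and respects dosage/MAF bounds", {
  cfg <- cohort_config(n_accessions = 60, n_snps_per_chrom = 40, n_pairs = 5,
                       seed = 11)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1$dosages %in% 0:2))
  expect_true(all(g1$snp_meta$maf >= cfg$maf_range[1]))
  expect_false(identical(
    g1$dosages,
    generate_genotypes(cohort_config(n_accessions = 60, n_snps_per_chrom = 40,
                                     n_pairs = 5, seed = 12))$dosages))
})

test_that("forced maf_range pins allele frequencies near 0.5", {
  # sampling error has two layers: the founder pool (binomial with
  # n_founders draws) and the accession draws; a large pool isolates the
  # forced frequency
  cfg <- cohort_config(n_accessions = 1000, n_snps_per_chrom = 30, n_pairs = 2,
                       maf_range = c(0.5, 0.5), n_founders = 200L, seed = 2)
  g <- generate_genotypes(cfg)
  f <- colMeans(g$dosages) / 2
  # block-shared founder draws correlate SNPs within a block, inflating the
  # extreme deviation relative to independent sampling
  expect_true(all(abs(f - 0.5) < 0.2))
  expect_lt(abs(mean(f) - 0.5), 0.02)
})

test_that("within-block LD exceeds cross-block LD; two-founder blocks give r2 = 1", {
  cfg <- cohort_config(n_accessions = 300, n_snps_per_chrom = 40, n_pairs = 2,
                       ld_block_len = 2e6, seed = 5)
  g <- generate_genotypes(cfg)
  sm <- g$snp_meta[g$snp_meta$chrom == "A01", ]
  block <- floor((sm$pos - 1) / cfg$ld_block_len)
  r2 <- cor(g$dosages[, sm$snp])^2
  same <- outer(block, block, "==") & upper.tri(r2)
  diff <- outer(block, block, "!=") & upper.tri(r2)
  expect_gt(mean(r2[same]), mean(r2[diff]))

  # with only two founder haplotypes per block, any two polymorphic SNPs in
  # one block are copies up to allele relabeling: pairwise r2 = 1
  cfg2 <- cohort_config(n_accessions = 200, n_snps_per_chrom = 10, n_pairs = 2,
                        ld_block_len = 1e8, n_founders = 2, seed = 9)
  g2 <- generate_genotypes(cfg2)
  sm2 <- g2$snp_meta[g2$snp_meta$chrom == "A01", ]
  if (nrow(sm2) >= 2) {
    r2b <- cor(g2$dosages[, sm2$snp])^2
    expect_true(all(abs(r2b[upper.tri(r2b)] - 1) < 1e-12))
  }
})

test_that("expression model collapses to its deterministic parts", {
  cfg <- cohort_config(n_accessions = 30, n_snps_per_chrom = 30, n_pairs = 6,
                       noise_sd = 0, seed = 3)
  g <- generate_genotypes(cfg)
  ann <- generate_gene_annotation(cfg)
  # no effects, no offsets: At and Dt copies identical everywhere
  ge0 <- generate_expression(g, truth_set(), cfg, ann)
  expect_equal(ge0$expr$values[ann$pairs$gene_At, , ],
               ge0$expr$values[ann$pairs$gene_Dt, , ],
               ignore_attr = TRUE)
  expect_true(all(ge0$expr$values >= 0))

  # one cis effect beta = 1: log2(expr+1) gap between dosage-2 and dosage-0
  # homozygotes is exactly 2
  snp <- g$snp_meta$snp[1]
  tr <- truth_set(cis_effects = data.frame(
    snp = snp, gene = ann$pairs$gene_At[1], beta = 1, timepoints = "all",
    stringsAsFactors = FALSE))
  ge1 <- generate_expression(g, tr, cfg, ann)
  d <- g$dosages[, snp]
  if (any(d == 2) && any(d == 0)) {
    v <- log2(ge1$expr$values[ann$pairs$gene_At[1], , 1] + 1)
    expect_equal(mean(v[d == 2]) - mean(v[d == 0]), 2, tolerance = 1e-10)
  }

  # +1 log2 bias offset: score approaches (2x - x)/(2x + x) = 1/3, the
  # linear-scale pseudocount shifts it slightly upward
  tr2 <- truth_set(bias_offsets = data.frame(
    pair = ann$pairs$pair[1], timepoint = "all", offset = 1,
    stringsAsFactors = FALSE))
  ge2 <- generate_expression(g, tr2, cfg, ann)
  sc <- bias_score(ge2$expr$values[ann$pairs$gene_At[1], , ],
                   ge2$expr$values[ann$pairs$gene_Dt[1], , ])
  expect_true(all(sc >= 1 / 3 - 1e-12 & sc < 1 / 3 + 0.04))
})

test_that("effects referencing an absent timepoint error", {
  cfg <- cohort_config(n_accessions = 20, n_snps_per_chrom = 10, n_pairs = 2,
                       seed = 4)
  g <- generate_genotypes(cfg)
  ann <- generate_gene_annotation(cfg)
  tr <- truth_set(cis_effects = data.frame(
    snp = g$snp_meta$snp[1], gene = ann$pairs$gene_At[1], beta = 1,
    timepoints = "99DPA", stringsAsFactors = FALSE))
  expect_error(generate_expression(g, tr, cfg, ann), "timepoint")
})

test_that("noise changes only the residual, not the genetic signal", {
  cfg0 <- cohort_config(n_accessions = 40, n_snps_per_chrom = 20, n_pairs = 4,
                        noise_sd = 0, seed = 6)
  g <- generate_genotypes(cfg0)
  ann <- generate_gene_annotation(cfg0)
  snp <- g$snp_meta$snp[3]
  tr <- truth_set(cis_effects = data.frame(
    snp = snp, gene = ann$pairs$gene_At[2], beta = 0.8, timepoints = "all",
    stringsAsFactors = FALSE))
  e0 <- generate_expression(g, tr, cfg0, ann)
  cfg1 <- cfg0; cfg1$noise_sd <- 0.3
  e1 <- generate_expression(g, tr, cfg1, ann)
  resid <- log2(e1$expr$values + 1) - log2(e0$expr$values + 1)
  expect_equal(mean(resid), 0, tolerance = 0.02)
  expect_equal(sd(resid), 0.3, tolerance = 0.02)
})

test_that("phenotype generation hits the target heritability", {
  cfg <- cohort_config(n_accessions = 2000, n_snps_per_chrom = 15, n_pairs = 2,
                       seed = 8)
  g <- generate_genotypes(cfg)
  loci <- data.frame(snp = g$snp_meta$snp[1:8], trait = "FL", effect = 0.5,
                     favorable = "alt", stringsAsFactors = FALSE)
  mk <- function(h2) truth_set(causal_phenotype_loci = loci,
                               target_h2 = c(FL = h2))
  p1 <- generate_phenotypes(g, mk(1), seed = 1)
  expect_equal(p1$phenotypes$FL, p1$genetic_values$FL)
  p0 <- generate_phenotypes(g, mk(0), seed = 1)
  expect_lt(abs(cor(p0$phenotypes$FL, p0$genetic_values$FL)), 0.08)
  p5 <- generate_phenotypes(g, mk(0.5), seed = 1)
  r2 <- summary(lm(p5$phenotypes$FL ~ p5$genetic_values$FL))$r.squared
  expect_lt(abs(r2 - 0.5), 0.05)
  expect_error(truth_set(causal_phenotype_loci = loci, target_h2 = c(FL = 1.5)),
               "0, 1")
})

test_that("population split recovers the planted frequency shift", {
  cfg <- cohort_config(n_accessions = 1200, n_snps_per_chrom = 20, n_pairs = 2,
                       maf_range = c(0.08, 0.12), seed = 10)
  g <- generate_genotypes(cfg)
  fav_sel <- g$snp_meta$snp[1]
  fav_pur <- g$snp_meta$snp[2]
  tr <- truth_set(causal_phenotype_loci = data.frame(
    snp = c(fav_sel, fav_pur), trait = "FL", effect = 0.5,
    favorable = c("alt", "ref"), stringsAsFactors = FALSE),
    target_h2 = c(FL = 0.5))
  freq_fav <- function(dos, snp, sel, fav) {
    f <- mean(dos[sel, snp]) / 2
    if (fav == "ref") 1 - f else f
  }
  # shift = 0: groups match within sampling error
  pp0 <- generate_populations(g, tr, shift = 0, seed = 21)
  cult <- pp0$groups$group == "cultivar"
  d0 <- freq_fav(pp0$genotypes$dosages, fav_sel, cult, "alt") -
    freq_fav(pp0$genotypes$dosages, fav_sel, !cult, "alt")
  expect_lt(abs(d0), 0.06)
  # shift = 0.7 recovered by counting; purifying locus shifted oppositely
  pp <- generate_populations(g, tr, shift = 0.7, purifying = fav_pur, seed = 22)
  cult <- pp$groups$group == "cultivar"
  d_sel <- freq_fav(pp$genotypes$dosages, fav_sel, cult, "alt") -
    freq_fav(pp$genotypes$dosages, fav_sel, !cult, "alt")
  expect_equal(d_sel, 0.7, tolerance = 0.07)
  d_pur <- freq_fav(pp$genotypes$dosages, fav_pur, !cult, "ref") -
    freq_fav(pp$genotypes$dosages, fav_pur, cult, "ref")
  expect_equal(d_pur, 0.7, tolerance = 0.07)
  expect_error(generate_populations(g, tr, shift = 1.5), "shift")
})
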