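test_that("inverse normal transform maps ranks to normal quantiles", {
  got <- inverse_normal_transform(c(3, 1, 2))
  expect_equal(got, qnorm(c(5 / 6, 1 / 6, 3 / 6)))
  expect_equal(got[3], 0)  # the median maps to zero
  set.seed(1)
  x <- rexp(1000)
  z <- inverse_normal_transform(x)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(sd(z), 1, tolerance = 0.02)
  # rank-based: a monotone relabeling permutes the output identically
  perm <- sample(1000)
  expect_equal(inverse_normal_transform(x[perm]), z[perm])
  expect_warning(z0 <- inverse_normal_transform(c(2, 2, 2)), "identical")
  expect_equal(z0, c(0, 0, 0))
  expect_error(inverse_normal_transform(c(1, NA)), "non-missing")
})

test_that("gene filter keeps genes expressed in at least 5% of samples", {
  n <- 340
  v <- array(0, dim = c(3, n, 1),
             dimnames = list(c("zero", "at5pct", "at4pct"),
                             sprintf("S%03d", 1:n), "t1"))
  v["at5pct", 1:17, 1] <- 1     # 17/340 = exactly 5%
  v["at4pct", 1:13, 1] <- 1     # 13/340 ~ 3.8%
  keep <- filter_genes(make_expression_cube(v))
  expect_false(keep["zero", 1])
  expect_true(keep["at5pct", 1])
  expect_false(keep["at4pct", 1])
})

test_that("scan_linear matches the normal-equations oracle and handles edge cases", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(40:80, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    C <- if (i %% 2) matrix(rnorm(n * 2), n) else NULL
    y <- 0.3 * g + rnorm(n) + if (is.null(C)) 0 else C %*% c(0.5, -0.2)
    got <- scan_linear(as.numeric(y), matrix(g, ncol = 1,
                                             dimnames = list(NULL, "s")), C)
    want <- ols_oracle(as.numeric(y), g, C)
    expect_equal(got$beta, want$beta, tolerance = 1e-8)
    expect_equal(got$se, want$se, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
  # perfect fit: beta = 1, p underflows toward zero
  g <- rep(0:2, each = 20)
  r <- scan_linear(1.0 * g, matrix(g, ncol = 1, dimnames = list(NULL, "s")))
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-100)
  expect_error(scan_linear(rep(1, 60), matrix(g, ncol = 1)), "constant")
})

test_that("null p-values are uniform", {
  set.seed(42)
  n <- 150
  G <- matrix(rbinom(n * 500, 2, 0.3), n)
  colnames(G) <- paste0("s", 1:500)
  y <- rnorm(n)
  r <- scan_linear(y, G)
  ks <- suppressWarnings(stats::ks.test(r$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the genome-wide threshold is 1/n", {
  expect_equal(signif(significance_threshold(2658921), 3), 3.76e-7)
  expect_equal(significance_threshold(1e6), 1e-6)
  expect_error(significance_threshold(0), ">= 1")
})

test_that("BH correction matches the hand-derived step-up rule", {
  # by hand: q_i = min over j >= i of p_(j) * m / j
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(bh_fdr(p) <= 0.05))
  expect_true(all(bh_fdr(c(0.5, 0.6)) > 0.05))
  set.seed(1)
  p2 <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p2)[perm], bh_fdr(p2[perm]))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("LD r2 is the squared dosage correlation, sign-free", {
  a <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  expect_true(is.na(ld_r2(a, rep(1, 8))))
  set.seed(5)
  r2 <- replicate(200, ld_r2(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.3)))
  expect_gt(mean(r2 < 0.02), 0.97)
})

test_that("SNP clustering reproduces the gap and size rules", {
  rec <- data.frame(snp = paste0("s", 1:4), chrom = "A01",
                    pos = c(100, 4000, 9000, 13000), p = c(1e-8, 1e-9, 1e-7, 1e-8),
                    stringsAsFactors = FALSE)
  loci <- cluster_snps(rec, "trans")
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_snps, 4)
  expect_equal(loci$lead_snp, "s2")
  # a 3-SNP cluster is discarded ("more than three SNPs")
  expect_equal(nrow(cluster_snps(rec[1:3, ], "trans")), 0)
  # a gap > 10 kb splits the chain, leaving two sub-threshold clusters
  rec2 <- rec
  rec2$pos[3:4] <- c(20000, 24000)
  expect_equal(nrow(cluster_snps(rec2, "trans")), 0)
})

test_that("GWAS loci merge on lead-lead LD", {
  set.seed(3)
  base <- rbinom(200, 2, 0.4)
  # leads of the two loci: identical dosages (r2 = 1) or independent
  mk_geno <- function(linked) {
    d <- cbind(l1 = base,
               l2 = if (linked) base else rbinom(200, 2, 0.4))
    make_genotype_matrix(d, pos = c(1000, 31000))
  }
  rec <- data.frame(snp = c("A01_1000", "A01_31000"), chrom = "A01",
                    pos = c(1000, 31000), p = c(1e-9, 1e-8),
                    stringsAsFactors = FALSE)
  merged <- cluster_snps(rec, "gwas", genotypes = mk_geno(TRUE))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$lead_snp, "A01_1000")
  split <- cluster_snps(rec, "gwas", genotypes = mk_geno(FALSE))
  expect_equal(nrow(split), 2)
})

test_that("cross-stage eQTL merging needs both LD and distance; idempotent", {
  set.seed(4)
  base <- rbinom(300, 2, 0.4)
  dos <- cbind(a = base, b = base, c = rbinom(300, 2, 0.4))
  g <- make_genotype_matrix(dos, pos = c(1e5, 1.5e5, 3e5))
  snp <- g$snp_meta$snp
  mk_locus <- function(id, lead, stage, p) {
    data.frame(locus = id, chrom = "A01",
               start = g$snp_meta$pos[g$snp_meta$snp == lead],
               end = g$snp_meta$pos[g$snp_meta$snp == lead],
               n_snps = 1L, lead_snp = lead, lead_p = p, snps = lead,
               stage = stage, stringsAsFactors = FALSE)
  }
  # same lead at two stages: one merged eQTL active at both
  two <- rbind(mk_locus("L1", snp[1], "0DPA", 1e-8),
               mk_locus("L2", snp[1], "4DPA", 1e-9))
  m <- merge_eqtls_across_stages(two, g)
  expect_equal(nrow(m), 1)
  expect_equal(m$stages, "0DPA,4DPA")
  expect_equal(m$lead_snp, snp[1])
  # r2 = 1 but distance 200 kb > 100 kb: not merged
  far <- rbind(mk_locus("L1", snp[1], "0DPA", 1e-8),
               mk_locus("L2", snp[2], "4DPA", 1e-9))
  far$start[2] <- far$end[2] <- 3e5
  g2 <- g; g2$snp_meta$pos[2] <- 3e5
  expect_equal(nrow(merge_eqtls_across_stages(far, g2)), 2)
  # within distance, r2 = 1: merged; merging is idempotent
  near <- rbind(mk_locus("L1", snp[1], "0DPA", 1e-8),
                mk_locus("L2", snp[2], "4DPA", 1e-9))
  m1 <- merge_eqtls_across_stages(near, g)
  expect_equal(nrow(m1), 1)
  m2 <- merge_eqtls_across_stages(m1, g)
  expect_equal(m2[, c("chrom", "start", "end", "lead_snp")],
               m1[, c("chrom", "start", "end", "lead_snp")])
  # independent leads stay apart regardless of distance
  uncor <- rbind(mk_locus("L1", snp[1], "0DPA", 1e-8),
                 mk_locus("L2", snp[3], "4DPA", 1e-9))
  g3 <- g; g3$snp_meta$pos[3] <- 1.2e5
  uncor$start[2] <- uncor$end[2] <- 1.2e5
  expect_equal(nrow(merge_eqtls_across_stages(uncor, g3)), 2)
})

test_that("hotspot detection applies the >3-gene and <20-kb merge rules", {
  mk_loci <- function(pos, genes, stage = "0DPA") {
    data.frame(chrom = "A01", lead_snp = NA, lead_pos = pos, target = genes,
               stage = stage, stringsAsFactors = FALSE)
  }
  # one region trans-regulating 10 genes -> one hotspot with all 10
  h <- detect_hotspots(mk_loci(seq(1e5, 1.9e5, by = 1e4), paste0("g", 1:10)))
  expect_equal(nrow(h), 1)
  expect_equal(h$n_genes, 10)
  # exactly 3 genes -> no hotspot ("more than three genes")
  h3 <- detect_hotspots(mk_loci(c(1e5, 1.1e5, 1.2e5), paste0("g", 1:3)))
  expect_equal(nrow(h3), 0)
  # two hotspots 10 kb apart -> merged into one
  loci <- rbind(mk_loci(seq(1e5, 1.6e5, by = 2e4), paste0("a", 1:4)),
                mk_loci(seq(1.7e5, 2.3e5, by = 2e4), paste0("b", 1:4)))
  hm <- detect_hotspots(loci)
  expect_equal(nrow(hm), 1)
  expect_equal(hm$n_genes, 8)
  # 30 kb apart -> stays two hotspots
  loci2 <- rbind(mk_loci(seq(1e5, 1.6e5, by = 2e4), paste0("a", 1:4)),
                 mk_loci(seq(1.9e5, 2.5e5, by = 2e4), paste0("b", 1:4)))
  expect_equal(nrow(detect_hotspots(loci2, window = 6e4)), 2)
})

test_that("cis scan respects the window and detects a planted effect", {
  set.seed(11)
  n <- 200
  dos <- sapply(1:30, function(i) rbinom(n, 2, 0.3))
  g <- make_genotype_matrix(dos, pos = seq(5e5, by = 5e4, length.out = 30))
  causal <- g$snp_meta$snp[10]
  tss <- g$snp_meta$pos[10]
  y <- g$dosages[, causal] * 1.0 + rnorm(n)
  sc <- scan_cis(inverse_normal_transform(y), tss, "A01", g,
                 n_perm = 200, seed = 1)
  expect_equal(sc$lead$snp, causal)
  expect_lt(sc$p_gene, 0.05)
  expect_gte(sc$p_gene, 1 / 201)  # permutation floor
  # window = 0: only the SNP exactly at the TSS is tested
  sc0 <- scan_cis(inverse_normal_transform(y), tss, "A01", g, window = 0,
                  n_perm = 50, seed = 1)
  expect_equal(sc0$records$snp, causal)
  expect_null(scan_cis(y, 1, "Z99", g, n_perm = 10))
})

test_that("bias-eQTL scan is invariant to joint scaling and applies the 5-95% filter", {
  co <- small_cohort()
  calls <- call_bias_cube(co$expr, co$pairs)
  scores <- bias_score_cube(co$expr, co$pairs)
  be1 <- scan_bias_eqtl(scores, calls, co$genotypes, pairs = co$pairs)
  # scaling both homoeologs by c > 0 leaves the bias score, hence the scan,
  # unchanged
  scaled <- co$expr
  scaled$values <- scaled$values * 3
  calls2 <- call_bias_cube(scaled, co$pairs)
  scores2 <- bias_score_cube(scaled, co$pairs)
  expect_equal(scores2, scores, ignore_attr = TRUE)
  be2 <- scan_bias_eqtl(scores2, calls2, co$genotypes, pairs = co$pairs)
  expect_equal(be1$records$p, be2$records$p)
  # a pair biased in ~100% of accessions is excluded by the 95% filter
  n_acc <- dim(co$expr$values)[2]
  v <- array(1, dim = c(2, n_acc, 1),
             dimnames = list(c("gA", "gD"), dimnames(co$expr$values)[[2]], "t1"))
  v["gA", , 1] <- 10
  e97 <- make_expression_cube(v)
  p1 <- data.frame(pair = "P1", gene_At = "gA", gene_Dt = "gD",
                   stringsAsFactors = FALSE)
  be3 <- scan_bias_eqtl(bias_score_cube(e97, p1), call_bias_cube(e97, p1),
                        co$genotypes, pairs = p1)
  expect_equal(nrow(be3$records), 0)
  expect_equal(be3$skipped$biased_frac, 1)
})

test_that("Dt-side effects are sign-flipped for comparison", {
  expect_equal(dt_sign_flip(c(0.5, 0.5), c("At", "Dt")), c(0.5, -0.5))
})

test_that("conditional rounds peel off independent signals", {
  set.seed(13)
  n <- 300
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  G <- cbind(s1 = g1, s2 = g2, s3 = rbinom(n, 2, 0.4))
  y <- g1 + 0.8 * g2 + rnorm(n, 0, 0.5)
  hits <- scan_conditional(y, G, threshold = 1e-4)
  expect_setequal(hits$snp[1:2], c("s1", "s2"))
  expect_false("s3" %in% hits$snp)
})
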