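# shared fixtures, built in code

# wrap a plain dosage matrix as a genotype_matrix with evenly spaced SNPs
make_genotype_matrix <- function(dosages, chrom = "A01", pos = NULL,
                                 acc = NULL) {
  n_snp <- ncol(dosages)
  if (is.null(pos)) pos <- seq(1e4, by = 1e4, length.out = n_snp)
  if (is.null(acc)) acc <- sprintf("S%03d", seq_len(nrow(dosages)))
  snp <- sprintf("%s_%d", chrom, pos)
  dimnames(dosages) <- list(acc, snp)
  structure(list(
    dosages = dosages,
    snp_meta = data.frame(snp = snp, chrom = chrom, pos = pos,
                          ref = "A", alt = "G",
                          maf = pmin(colMeans(dosages) / 2,
                                     1 - colMeans(dosages) / 2),
                          stringsAsFactors = FALSE),
    accession_ids = acc
  ), class = "genotype_matrix")
}

# wrap a genes x accessions x timepoints array as an expression_cube
make_expression_cube <- function(values, gene_meta = NULL) {
  genes <- dimnames(values)[[1]]
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene = genes, chrom = "A01",
                            tss = seq(1e5, by = 1e5, length.out = length(genes)),
                            strand = "+", subgenome = "At",
                            stringsAsFactors = FALSE)
  }
  structure(list(values = values, gene_meta = gene_meta,
                 timepoints = dimnames(values)[[3]]),
            class = "expression_cube")
}

# small cohort reused across files (built once per test run)
.fixtures <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixtures$co)) {
    cfg <- cohort_config(n_accessions = 100, n_snps_per_chrom = 60,
                         n_pairs = 12, seed = 42)
    .fixtures$co <- simulate_cohort(cfg)
  }
  .fixtures$co
}

# independent normal-equations OLS oracle (explicit design-matrix inversion)
ols_oracle <- function(y, g, C = NULL) {
  X <- cbind(1, g, C)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtX_inv))
  tt <- beta / se
  list(beta = unname(beta[2]), se = unname(se[2]),
       p = unname(2 * pt(-abs(tt[2]), df)))
}

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
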