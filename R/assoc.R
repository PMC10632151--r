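#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles at probabilities
#' `(rank - 0.5) / n` with mid-ranked ties, preserving order. Used to
#' normalize per-gene expression before eQTL scans.
#'
#' @param x numeric vector (NA tolerated and preserved).
#' @return transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(x))
  if (length(unique(x[ok])) == 1L) {
    warning("all values identical; transform returns zeros")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

#' Expression-based gene filter
#'
#' Keeps a gene at a timepoint when it is expressed (value > `min_fpkm`)
#' in at least `min_frac` of the accessions with data at that timepoint —
#' i.e., drops genes lowly expressed in more than `1 - min_frac` of
#' samples.
#'
#' @param expr an `expression_cube`.
#' @param min_fpkm expression threshold (default 0.1).
#' @param min_frac minimum expressed fraction (default 0.05).
#' @return logical matrix genes x timepoints (`TRUE` = keep).
#' @export
filter_genes <- function(expr, min_fpkm = 0.1, min_frac = 0.05) {
  v <- expr$values
  keep <- sapply(seq_along(expr$timepoints), function(t) {
    m <- v[, , t, drop = FALSE]
    n_obs <- rowSums(!is.na(m))
    n_expr <- rowSums(m > min_fpkm, na.rm = TRUE)
    n_obs > 0 & n_expr / pmax(n_obs, 1) >= min_frac
  })
  if (is.null(dim(keep))) keep <- matrix(keep, nrow = dim(v)[1])
  dimnames(keep) <- list(dimnames(v)[[1]], expr$timepoints)
  keep
}

# residualize columns of m on covariates (with intercept); qr-based
residualize <- function(m, covariates = NULL) {
  n <- nrow(m)
  X <- cbind(rep(1, n), covariates)
  qr_x <- qr(X)
  m - qr.fitted(qr_x, m)
}

#' Fixed-effect linear association scan
#'
#' Ordinary least squares of a target on each SNP dosage plus covariates
#' (Frisch-Waugh residualization, identical to the full OLS fit). Returns
#' per-SNP effect, standard error and two-sided t-test p-value. Rows with
#' missing target or covariates are dropped; SNPs with missing dosages are
#' handled pairwise.
#'
#' @param y numeric target vector (expression, bias score or trait).
#' @param G dosage matrix, accessions x SNPs (columns named).
#' @param covariates optional numeric matrix of covariates (no intercept).
#' @return data.frame with columns `snp`, `beta`, `se`, `t`, `p`, `n`.
#' @export
scan_linear <- function(y, G, covariates = NULL) {
  if (is.null(dim(G))) G <- matrix(G, ncol = 1, dimnames = list(NULL, "snp1"))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  keep <- !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]
  G <- G[keep, , drop = FALSE]
  C <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  n <- length(y)
  k <- if (is.null(C)) 0L else ncol(C)
  if (n - k - 2 <= 0) stop("not enough observations for the model")
  if (sd(y) == 0) stop("target is constant")
  scan_one <- function(g, yy, cc) {
    ok <- !is.na(g)
    nn <- sum(ok)
    if (nn - k - 2 <= 0) return(c(NA, NA, NA, NA, nn))
    ry <- residualize(cbind(yy[ok]), cc[ok, , drop = FALSE])
    rg <- residualize(cbind(g[ok]), cc[ok, , drop = FALSE])
    ssg <- sum(rg^2)
    if (ssg < .Machine$double.eps * nn) return(c(NA, NA, NA, NA, nn))
    beta <- sum(rg * ry) / ssg
    rss <- sum(ry^2) - beta^2 * ssg
    df <- nn - k - 2
    se <- sqrt(max(rss, 0) / df / ssg)
    tt <- beta / se
    c(beta, se, tt, 2 * pt(-abs(tt), df), nn)
  }
  if (!anyNA(G)) {
    ry <- residualize(cbind(y), C)
    RG <- residualize(G, C)
    ssg <- colSums(RG^2)
    ok <- ssg > .Machine$double.eps * n
    beta <- as.vector(crossprod(RG, ry)) / ssg
    rss <- sum(ry^2) - beta^2 * ssg
    df <- n - k - 2
    se <- sqrt(pmax(rss, 0) / df / ssg)
    tt <- beta / se
    p <- 2 * pt(-abs(tt), df)
    beta[!ok] <- se[!ok] <- tt[!ok] <- p[!ok] <- NA
    res <- cbind(beta, se, tt, p, n)
  } else {
    res <- t(apply(G, 2, scan_one, yy = y, cc = C))
  }
  data.frame(snp = colnames(G), beta = res[, 1], se = res[, 2], t = res[, 3],
             p = res[, 4], n = as.integer(res[, 5]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genome-wide significance threshold
#'
#' The Bonferroni-motivated `1 / n` threshold on the total number of
#' genomic SNPs (e.g. 2,658,921 SNPs give 3.76e-7).
#'
#' @param n_snps total number of SNPs tested (>= 1).
#' @return the p-value threshold `1 / n_snps`.
#' @export
significance_threshold <- function(n_snps) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || is.na(n_snps) || n_snps < 1) {
    stop("`n_snps` must be a single number >= 1")
  }
  1 / n_snps
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper over `p.adjust(..., "BH")`; q-values are
#' monotone non-decreasing in p rank and invariant to input order.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' accessions; undefined (NA) when either SNP is monomorphic in the
#' overlap.
#'
#' @param a,b dosage vectors.
#' @return r-squared in \[0, 1\] or NA.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need at least 2 jointly observed accessions")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])^2
}

#' Principal-component covariates
#'
#' `genotype_pcs()` returns the top genotype principal components (the
#' population-structure covariates of the association scans);
#' `expression_pcs()` returns the top expression PCs at one timepoint (the
#' hidden-factor surrogates).
#'
#' @param genotypes a `genotype_matrix`.
#' @param n_pcs number of components.
#' @return numeric matrix accessions x components.
#' @export
genotype_pcs <- function(genotypes, n_pcs = 3L) {
  d <- genotypes$dosages
  d <- scale(d, center = TRUE, scale = FALSE)
  d[is.na(d)] <- 0
  pc <- prcomp(d, center = FALSE, rank. = n_pcs)
  m <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  rownames(m) <- genotypes$accession_ids
  m
}

#' @rdname genotype_pcs
#' @param expr_matrix genes x accessions expression matrix (one timepoint).
#' @export
expression_pcs <- function(expr_matrix, n_pcs = 5L) {
  m <- t(expr_matrix)
  keep <- colSums(is.na(m)) == 0 & apply(m, 2, sd, na.rm = TRUE) > 0
  m <- scale(m[, keep, drop = FALSE])
  pc <- prcomp(m, center = FALSE, rank. = min(n_pcs, ncol(m), nrow(m) - 1))
  pc$x
}

#' Gene-level cis-eQTL scan with permutation p-value
#'
#' Scans all SNPs within `window` bp of the gene's transcription start
#' site, then computes a gene-level empirical p-value by comparing the
#' observed minimum nominal p against `n_perm` phenotype permutations
#' (min-p scheme, floor `1 / (n_perm + 1)`).
#'
#' @param y numeric expression vector for the gene (accession order of
#'   `genotypes`), typically inverse-normal transformed.
#' @param tss,chrom transcription start site and chromosome of the gene.
#' @param genotypes a `genotype_matrix`.
#' @param covariates optional covariate matrix.
#' @param window cis window half-width in bp (default 1 Mb).
#' @param n_perm number of permutations (default 1000).
#' @param seed permutation seed.
#' @return list with `records` (per-SNP scan), `lead` (lead SNP row),
#'   `p_gene` (empirical gene-level p), `nominal_alpha` (the 5% quantile of
#'   the permutation min-p distribution, usable as a nominal significance
#'   cutoff for member SNPs), or NULL when no SNP lies in the window.
#' @export
scan_cis <- function(y, tss, chrom, genotypes, covariates = NULL,
                     window = 1e6, n_perm = 1000L, seed = 1L) {
  sm <- genotypes$snp_meta
  in_win <- sm$chrom == chrom & abs(sm$pos - tss) <= window
  if (!any(in_win)) return(NULL)
  G <- genotypes$dosages[, sm$snp[in_win], drop = FALSE]
  keep <- !is.na(y) & rowSums(is.na(G)) == 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    C <- covariates[keep, , drop = FALSE]
  } else C <- NULL
  y <- y[keep]
  G <- G[keep, , drop = FALSE]
  records <- scan_linear(y, G, C)
  obs_min <- suppressWarnings(min(records$p, na.rm = TRUE))
  if (!is.finite(obs_min)) return(NULL)
  # permutations: max |correlation| between residualized y permutations and
  # residualized SNPs is equivalent to min nominal p (common df)
  n <- length(y)
  k <- if (is.null(C)) 0L else ncol(C)
  df <- n - k - 2
  RG <- residualize(G, C)
  sg <- sqrt(colSums(RG^2))
  usable <- sg > .Machine$double.eps * n
  RGn <- sweep(RG[, usable, drop = FALSE], 2, sg[usable], "/")
  perm_max <- with_seed(seed, {
    P <- replicate(n_perm, sample.int(n))
    YP <- matrix(y[P], nrow = n)
    RYP <- residualize(YP, C)
    RYP <- sweep(RYP, 2, sqrt(colSums(RYP^2)), "/")
    apply(abs(crossprod(RGn, RYP)), 2, max)
  })
  # observed max |r| on the same normalized scale
  ry <- residualize(cbind(y), C)
  ry <- ry / sqrt(sum(ry^2))
  obs_max_r <- max(abs(crossprod(RGn, ry)))
  p_gene <- (1 + sum(perm_max >= obs_max_r)) / (n_perm + 1)
  # nominal alpha: |r| quantile 95% of perm max-|r| converted to p scale
  r_alpha <- quantile(perm_max, 0.95, names = FALSE)
  t_alpha <- r_alpha * sqrt(df) / sqrt(max(1 - r_alpha^2, .Machine$double.eps))
  nominal_alpha <- 2 * pt(-abs(t_alpha), df)
  lead <- records[which.min(records$p), , drop = FALSE]
  list(records = records, lead = lead, p_gene = p_gene,
       nominal_alpha = nominal_alpha)
}

#' Cis-eQTL mapping over all genes at one timepoint
#'
#' Applies [inverse_normal_transform()] per gene, runs [scan_cis()] for
#' every gene passing the expression filter, and calls eGenes at
#' Benjamini-Hochberg FDR < `fdr` on the gene-level permutation p-values.
#'
#' @param expr an `expression_cube`.
#' @param timepoint stage label to map.
#' @param genotypes a `genotype_matrix`.
#' @param covariates optional covariates (accessions x k).
#' @param genes optional subset of gene ids (default: all passing
#'   [filter_genes()]).
#' @inheritParams scan_cis
#' @param fdr eGene FDR threshold.
#' @return data.frame with one row per scanned gene: `gene`, `lead_snp`,
#'   `beta`, `se`, `p_nominal`, `p_gene`, `q_gene`, `significant`,
#'   `nominal_alpha`.
#' @export
map_cis_eqtl <- function(expr, timepoint, genotypes, covariates = NULL,
                         genes = NULL, window = 1e6, n_perm = 1000L,
                         fdr = 0.05, seed = 1L) {
  t_idx <- match(timepoint, expr$timepoints)
  if (is.na(t_idx)) stop("unknown timepoint: ", timepoint)
  keep <- filter_genes(expr)[, t_idx]
  if (is.null(genes)) genes <- rownames(expr$values)[keep]
  genes <- intersect(genes, rownames(expr$values)[keep])
  rows <- list()
  for (g in genes) {
    gm <- expr$gene_meta[expr$gene_meta$gene == g, ]
    y <- expr$values[g, , t_idx]
    acc <- match(genotypes$accession_ids, dimnames(expr$values)[[2]])
    y <- log2(y[acc] + 1)
    if (sum(!is.na(y)) < 10 || sd(y, na.rm = TRUE) == 0) next
    y <- inverse_normal_transform(y)
    sc <- scan_cis(y, gm$tss, gm$chrom, genotypes, covariates,
                   window = window, n_perm = n_perm,
                   seed = seed + match(g, genes))
    if (is.null(sc)) next
    rows[[g]] <- data.frame(gene = g, lead_snp = sc$lead$snp,
                            beta = sc$lead$beta, se = sc$lead$se,
                            p_nominal = sc$lead$p, p_gene = sc$p_gene,
                            nominal_alpha = sc$nominal_alpha,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), lead_snp = character(0),
                      beta = numeric(0), se = numeric(0),
                      p_nominal = numeric(0), p_gene = numeric(0),
                      nominal_alpha = numeric(0), q_gene = numeric(0),
                      significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_gene <- bh_fdr(out$p_gene)
  out$significant <- out$q_gene < fdr
  out
}

#' Cluster significant SNPs into loci
#'
#' In `trans` mode, significant SNPs on one chromosome are chained when
#' consecutive SNPs lie within `gap` bp (default 10 kb) and only clusters
#' with more than three SNPs (>= 4) are kept. In `gwas` mode the chain gap
#' is 20 kb, any cluster size is kept, and consecutive loci are merged when
#' their lead SNPs are in LD (r2 >= `r2_min`).
#'
#' @param records data.frame with columns `snp`, `chrom`, `pos`, `p` (and
#'   optionally `target`).
#' @param mode `"trans"` or `"gwas"`.
#' @param gap chain gap in bp; defaults 10 kb (trans) / 20 kb (gwas).
#' @param min_snps minimum cluster size kept in trans mode (default 4,
#'   i.e. "more than three SNPs").
#' @param genotypes `genotype_matrix`, required in gwas mode for lead-lead
#'   LD.
#' @param r2_min LD threshold for gwas locus merging.
#' @return data.frame of loci: `locus`, `chrom`, `start`, `end`, `n_snps`,
#'   `lead_snp`, `lead_p`, `snps` (comma-separated).
#' @export
cluster_snps <- function(records, mode = c("trans", "gwas"), gap = NULL,
                         min_snps = 4L, genotypes = NULL, r2_min = 0.6) {
  mode <- match.arg(mode)
  if (is.null(gap)) gap <- if (mode == "trans") 1e4 else 2e4
  empty <- data.frame(locus = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), n_snps = integer(0),
                      lead_snp = character(0), lead_p = numeric(0),
                      snps = character(0), stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  loci <- list()
  for (ch in unique(records$chrom)) {
    r <- records[records$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(r$pos) > gap))
    for (g in unique(grp)) {
      s <- r[grp == g, , drop = FALSE]
      if (mode == "trans" && nrow(s) < min_snps) next
      lead <- s[which.min(s$p), ]
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, start = min(s$pos), end = max(s$pos),
        n_snps = nrow(s), lead_snp = lead$snp, lead_p = lead$p,
        snps = paste(s$snp, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(loci)) return(empty)
  out <- do.call(rbind, loci)
  if (mode == "gwas" && nrow(out) > 1) {
    if (is.null(genotypes)) stop("gwas mode needs `genotypes` for LD merging")
    merged <- list()
    cur <- out[1, ]
    for (i in seq_len(nrow(out))[-1]) {
      nxt <- out[i, ]
      r2 <- if (cur$chrom == nxt$chrom) {
        ld_r2(genotypes$dosages[, cur$lead_snp], genotypes$dosages[, nxt$lead_snp])
      } else NA_real_
      if (!is.na(r2) && r2 >= r2_min) {
        cur$end <- max(cur$end, nxt$end)
        cur$start <- min(cur$start, nxt$start)
        cur$n_snps <- cur$n_snps + nxt$n_snps
        cur$snps <- paste(cur$snps, nxt$snps, sep = ",")
        if (nxt$lead_p < cur$lead_p) {
          cur$lead_snp <- nxt$lead_snp; cur$lead_p <- nxt$lead_p
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nxt
      }
    }
    merged[[length(merged) + 1L]] <- cur
    out <- do.call(rbind, merged)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$locus <- sprintf("L%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus", "chrom", "start", "end", "n_snps", "lead_snp", "lead_p", "snps")]
}

#' Merge stage-wise eQTL loci for one target
#'
#' Single-linkage merging of loci (for the same target gene or pair) whose
#' lead SNPs satisfy both r2 >= `r2_min` and distance <= `max_dist`. The
#' merged lead is the overall minimum-p lead; the stage activity vector is
#' retained. Idempotent.
#'
#' @param loci data.frame of loci with columns of [cluster_snps()] plus
#'   `stage`.
#' @param genotypes a `genotype_matrix`.
#' @param r2_min LD threshold (default 0.6).
#' @param max_dist maximum lead-lead distance in bp (default 100 kb).
#' @return data.frame of merged loci with a comma-separated `stages`
#'   column.
#' @export
merge_eqtls_across_stages <- function(loci, genotypes, r2_min = 0.6,
                                      max_dist = 1e5) {
  if (!nrow(loci)) {
    return(cbind(loci[, setdiff(names(loci), "stage"), drop = FALSE],
                 data.frame(stages = character(0))))
  }
  if (!"stage" %in% names(loci)) loci$stage <- "all"
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pos <- genotypes$snp_meta$pos[match(loci$lead_snp, genotypes$snp_meta$snp)]
  chrom <- genotypes$snp_meta$chrom[match(loci$lead_snp, genotypes$snp_meta$snp)]
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (chrom[i] != chrom[j]) next
      if (abs(pos[i] - pos[j]) > max_dist) next
      r2 <- ld_r2(genotypes$dosages[, loci$lead_snp[i]],
                  genotypes$dosages[, loci$lead_snp[j]])
      if (!is.na(r2) && r2 >= r2_min) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  rows <- lapply(unique(comp), function(cmp) {
    s <- loci[comp == cmp, , drop = FALSE]
    lead <- s[which.min(s$lead_p), ]
    data.frame(locus = lead$locus, chrom = lead$chrom,
               start = min(s$start), end = max(s$end),
               n_snps = sum(s$n_snps), lead_snp = lead$lead_snp,
               lead_p = lead$lead_p,
               snps = paste(unique(unlist(strsplit(s$snps, ","))), collapse = ","),
               stages = paste(sort(unique(s$stage)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect trans-eQTL hotspots
#'
#' Scans lead-SNP positions of trans loci with a fixed window, counting the
#' distinct regulated eGenes per window; windows regulating more than
#' `min_genes - 1` genes (default: more than three, i.e. >= 4) seed
#' hotspots, and adjacent hotspots closer than `merge_gap` are merged.
#' Per-timepoint gene counts are recorded.
#'
#' @param loci data.frame of trans loci with columns `chrom`, `lead_snp`,
#'   `target` and optionally `stage`; lead positions are taken from
#'   `genotypes` or from a `lead_pos` column.
#' @param genotypes a `genotype_matrix` (for lead positions).
#' @param window scan window width in bp (default 100 kb).
#' @param min_genes minimum distinct regulated genes (default 4).
#' @param merge_gap merge distance between adjacent hotspots (default
#'   20 kb).
#' @return data.frame of hotspots: `hotspot`, `chrom`, `start`, `end`,
#'   `n_genes`, `genes` (comma-separated), `stage_counts`.
#' @export
detect_hotspots <- function(loci, genotypes = NULL, window = 1e5,
                            min_genes = 4L, merge_gap = 2e4) {
  empty <- data.frame(hotspot = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_genes = integer(0), genes = character(0),
                      stage_counts = character(0), stringsAsFactors = FALSE)
  if (!nrow(loci)) return(empty)
  if (!"lead_pos" %in% names(loci)) {
    if (is.null(genotypes)) stop("need `genotypes` or a lead_pos column")
    loci$lead_pos <- genotypes$snp_meta$pos[match(loci$lead_snp,
                                                  genotypes$snp_meta$snp)]
  }
  if (!"stage" %in% names(loci)) loci$stage <- "all"
  hits <- list()
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, , drop = FALSE]
    l <- l[order(l$lead_pos), , drop = FALSE]
    # candidate windows anchored at each lead
    wins <- lapply(seq_len(nrow(l)), function(i) {
      sel <- l$lead_pos >= l$lead_pos[i] & l$lead_pos <= l$lead_pos[i] + window
      genes <- unique(l$target[sel])
      if (length(genes) < min_genes) return(NULL)
      list(start = min(l$lead_pos[sel]), end = max(l$lead_pos[sel]),
           rows = which(sel))
    })
    wins <- Filter(Negate(is.null), wins)
    if (!length(wins)) next
    # merge overlapping or nearby candidate windows
    wins <- wins[order(vapply(wins, `[[`, 0, "start"))]
    cur <- wins[[1]]
    flush <- function(w) {
      rows <- l[w$rows, , drop = FALSE]
      genes <- sort(unique(rows$target))
      tab <- table(rows$stage[!duplicated(paste(rows$stage, rows$target))])
      hits[[length(hits) + 1L]] <<- data.frame(
        chrom = ch, start = w$start, end = w$end,
        n_genes = length(genes), genes = paste(genes, collapse = ","),
        stage_counts = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                             collapse = ","),
        stringsAsFactors = FALSE)
    }
    for (w in wins[-1]) {
      if (w$start - cur$end < merge_gap) {
        cur$end <- max(cur$end, w$end)
        cur$rows <- union(cur$rows, w$rows)
      } else {
        flush(cur); cur <- w
      }
    }
    flush(cur)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$hotspot <- sprintf("H%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("hotspot", "chrom", "start", "end", "n_genes", "genes", "stage_counts")]
}

#' Trait GWAS scan with locus clumping
#'
#' Linear-model association of a trait on every SNP (MAF > `maf_min`) with
#' covariates, thresholded at [significance_threshold()] and clumped into
#' loci with [cluster_snps()] in gwas mode.
#'
#' @param genotypes a `genotype_matrix`.
#' @param phenotypes data.frame with `accession` and trait columns.
#' @param trait trait column name.
#' @param covariates optional covariates (default: top 3 genotype PCs).
#' @param maf_min MAF filter (default 0.05).
#' @param gap,r2_min clumping parameters (20 kb, 0.6).
#' @return list with `records` (significant SNPs), `loci`, `threshold`.
#' @export
run_gwas <- function(genotypes, phenotypes, trait, covariates = NULL,
                     maf_min = 0.05, gap = 2e4, r2_min = 0.6) {
  y <- phenotypes[[trait]][match(genotypes$accession_ids, phenotypes$accession)]
  if (is.null(covariates)) covariates <- genotype_pcs(genotypes, 3L)
  sm <- genotypes$snp_meta
  use <- sm$maf > maf_min
  rec <- scan_linear(y, genotypes$dosages[, sm$snp[use], drop = FALSE], covariates)
  rec$chrom <- sm$chrom[use]
  rec$pos <- sm$pos[use]
  thr <- significance_threshold(sum(use))
  sig <- rec[!is.na(rec$p) & rec$p < thr, , drop = FALSE]
  loci <- cluster_snps(sig, mode = "gwas", gap = gap, genotypes = genotypes,
                       r2_min = r2_min)
  list(records = sig, loci = loci, threshold = thr)
}

#' Bias-eQTL scan for homoeolog pairs
#'
#' For every pair and timepoint whose biased-accession fraction lies in
#' \[`min_frac`, `max_frac`\], associates SNP dosages with the pair's bias
#' score by [scan_linear()]. SNPs passing [significance_threshold()] are
#' clustered (trans rules: 10-kb chains, more than three SNPs) and merged
#' across stages by lead-SNP LD and distance. Effects reported against the
#' Dt member's eQTL scale must be sign-flipped (`dt_sign_flip()`), because
#' a dosage effect that raises Dt expression lowers the bias score.
#'
#' @param scores result of [bias_score_cube()].
#' @param calls result of [call_bias_cube()].
#' @param genotypes a `genotype_matrix`.
#' @param covariates optional covariates.
#' @param pairs pair map (rows matching `scores`).
#' @param min_frac,max_frac biased-fraction filter (defaults 5% and 95%).
#' @param maf_min MAF filter.
#' @param gap,min_snps,r2_min,max_dist locus clustering/merging parameters.
#' @return list with `records` (significant SNP associations, with `pair`
#'   and `stage`), `loci` (merged bias-eQTL loci per pair), `skipped`
#'   (pair/timepoint log of filter exclusions), `threshold`.
#' @export
scan_bias_eqtl <- function(scores, calls, genotypes, covariates = NULL,
                           pairs = NULL, min_frac = 0.05, max_frac = 0.95,
                           maf_min = 0.05, gap = 1e4, min_snps = 4L,
                           r2_min = 0.6, max_dist = 1e5) {
  tps <- dimnames(scores)[[3]]
  pr_ids <- dimnames(scores)[[1]]
  sm <- genotypes$snp_meta
  use <- sm$maf > maf_min
  G <- genotypes$dosages[, sm$snp[use], drop = FALSE]
  thr <- significance_threshold(sum(use))
  recs <- list(); skipped <- list()
  for (i in seq_along(pr_ids)) {
    for (t in seq_along(tps)) {
      cl <- calls[i, , t]
      obs <- !is.na(cl)
      if (!any(obs)) next
      frac <- mean(cl[obs] %in% c("BiasA", "BiasD"))
      if (frac < min_frac || frac > max_frac) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          pair = pr_ids[i], timepoint = tps[t], biased_frac = frac,
          stringsAsFactors = FALSE)
        next
      }
      y <- scores[i, , t]
      if (sd(y, na.rm = TRUE) == 0 || sum(!is.na(y)) < 10) next
      r <- scan_linear(y, G, covariates)
      r <- r[!is.na(r$p) & r$p < thr, , drop = FALSE]
      if (!nrow(r)) next
      r$chrom <- sm$chrom[use][match(r$snp, sm$snp[use])]
      r$pos <- sm$pos[use][match(r$snp, sm$snp[use])]
      r$pair <- pr_ids[i]
      r$stage <- tps[t]
      recs[[length(recs) + 1L]] <- r
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(snp = character(0), beta = numeric(0), se = numeric(0),
               t = numeric(0), p = numeric(0), n = integer(0),
               chrom = character(0), pos = integer(0), pair = character(0),
               stage = character(0), stringsAsFactors = FALSE)
  loci <- list()
  if (nrow(records)) {
    for (pr in unique(records$pair)) {
      for (st in unique(records$stage[records$pair == pr])) {
        sub <- records[records$pair == pr & records$stage == st, , drop = FALSE]
        cl <- cluster_snps(sub, mode = "trans", gap = gap, min_snps = min_snps)
        if (nrow(cl)) { cl$pair <- pr; cl$stage <- st; loci[[length(loci) + 1L]] <- cl }
      }
    }
  }
  loci_merged <- if (length(loci)) {
    all_loci <- do.call(rbind, loci)
    out <- lapply(unique(all_loci$pair), function(pr) {
      m <- merge_eqtls_across_stages(all_loci[all_loci$pair == pr, , drop = FALSE],
                                     genotypes, r2_min = r2_min,
                                     max_dist = max_dist)
      m$pair <- pr
      m
    })
    do.call(rbind, out)
  } else {
    data.frame(locus = character(0), chrom = character(0), start = integer(0),
               end = integer(0), n_snps = integer(0), lead_snp = character(0),
               lead_p = numeric(0), snps = character(0), stages = character(0),
               pair = character(0), stringsAsFactors = FALSE)
  }
  list(records = records, loci = loci_merged,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       threshold = thr)
}

#' Sign convention for Dt-side bias-eQTL effect comparison
#'
#' A bias-eQTL effect is reported on the bias-score scale (positive =
#' toward At). When comparing it with the eQTL effect on the Dt member's
#' expression, the effect is multiplied by -1 so the two are on a common
#' scale.
#'
#' @param beta numeric effect(s).
#' @param subgenome `"At"` or `"Dt"` (vectorized).
#' @return sign-adjusted effects.
#' @export
dt_sign_flip <- function(beta, subgenome) {
  ifelse(subgenome == "Dt", -beta, beta)
}

#' Flag colocalization of bias-eQTL loci with member eQTL loci
#'
#' A bias-eQTL locus colocalizes with an eQTL of either pair member when
#' its lead SNP falls inside the eQTL locus interval or the two leads are
#' in LD (r2 >= `r2_min`).
#'
#' @param bias_loci merged bias-eQTL loci (with `pair`, `lead_snp`).
#' @param eqtl_loci merged eQTL loci with a `target` gene column.
#' @param pairs pair map.
#' @param genotypes a `genotype_matrix`.
#' @param r2_min LD threshold.
#' @return `bias_loci` with a logical `colocalized` column.
#' @export
flag_bias_colocalization <- function(bias_loci, eqtl_loci, pairs, genotypes,
                                     r2_min = 0.6) {
  if (!nrow(bias_loci)) {
    bias_loci$colocalized <- logical(0)
    return(bias_loci)
  }
  sm <- genotypes$snp_meta
  bias_loci$colocalized <- vapply(seq_len(nrow(bias_loci)), function(i) {
    pr <- pairs[pairs$pair == bias_loci$pair[i], ]
    members <- c(pr$gene_At, pr$gene_Dt)
    el <- eqtl_loci[eqtl_loci$target %in% members, , drop = FALSE]
    if (!nrow(el)) return(FALSE)
    lead_pos <- sm$pos[sm$snp == bias_loci$lead_snp[i]]
    lead_chrom <- sm$chrom[sm$snp == bias_loci$lead_snp[i]]
    inside <- any(el$chrom == lead_chrom & el$start <= lead_pos &
                    el$end >= lead_pos)
    if (inside) return(TRUE)
    any(vapply(el$lead_snp, function(s) {
      r2 <- ld_r2(genotypes$dosages[, s], genotypes$dosages[, bias_loci$lead_snp[i]])
      !is.na(r2) && r2 >= r2_min
    }, TRUE))
  }, TRUE)
  bias_loci
}

#' Stepwise conditional association rounds
#'
#' After each round the lead SNP is regressed out of the target and the
#' scan repeated, up to `rounds` rounds, stopping when no SNP passes
#' `threshold`. A lightweight forward pass for detecting independent
#' signals at one locus.
#'
#' @inheritParams scan_linear
#' @param threshold nominal p threshold per round.
#' @param rounds maximum rounds (default 3).
#' @return data.frame of independent lead SNPs with a `round` column.
#' @export
scan_conditional <- function(y, G, covariates = NULL, threshold = 1e-5,
                             rounds = 3L) {
  out <- list()
  C <- covariates
  for (r in seq_len(rounds)) {
    rec <- scan_linear(y, G, C)
    rec <- rec[!is.na(rec$p), , drop = FALSE]
    if (!nrow(rec) || min(rec$p) >= threshold) break
    lead <- rec[which.min(rec$p), , drop = FALSE]
    lead$round <- r
    out[[r]] <- lead
    C <- cbind(C, G[, lead$snp])
  }
  if (!length(out)) {
    return(data.frame(snp = character(0), beta = numeric(0), se = numeric(0),
                      t = numeric(0), p = numeric(0), n = integer(0),
                      round = integer(0)))
  }
  do.call(rbind, out)
}
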