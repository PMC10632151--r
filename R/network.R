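#' Build the bipartite locus-gene regulatory network
#'
#' Nodes are regulatory loci (merged eQTLs or hotspots) and candidate
#' genes; edges connect a locus to a gene it regulates. Loci whose lead SNP
#' falls inside a hotspot interval are absorbed into the hotspot node
#' (edges are inherited). The graph is bipartite: locus-locus and gene-gene
#' edges never occur.
#'
#' @param eqtls data.frame of merged eQTL loci with columns `locus`,
#'   `chrom`, `start`, `end`, `lead_snp`, `target` and optionally `stages`.
#' @param hotspots data.frame from [detect_hotspots()] (may be empty).
#' @param candidates character vector of candidate gene ids (non-empty);
#'   only edges to candidate genes enter the network.
#' @param genotypes optional `genotype_matrix` for lead positions (else a
#'   `lead_pos` column is required on `eqtls`).
#' @return an igraph graph with vertex attributes `type`
#'   (`"locus"`/`"hotspot"`/`"gene"`) and edge attribute `stages`.
#' @export
build_network <- function(eqtls, hotspots = NULL, candidates, genotypes = NULL) {
  if (!length(candidates)) stop("candidate gene set is empty")
  if (!nrow(eqtls)) stop("no eQTL loci supplied")
  if (!"lead_pos" %in% names(eqtls)) {
    if (is.null(genotypes)) stop("need `genotypes` or a lead_pos column")
    eqtls$lead_pos <- genotypes$snp_meta$pos[match(eqtls$lead_snp,
                                                   genotypes$snp_meta$snp)]
  }
  if (anyNA(eqtls$lead_pos) || anyNA(eqtls$target)) {
    stop("dangling references: every locus needs a resolvable lead and target")
  }
  eqtls$node <- eqtls$locus
  eqtls$node_type <- "locus"
  if (!is.null(hotspots) && nrow(hotspots)) {
    for (i in seq_len(nrow(hotspots))) {
      hit <- eqtls$chrom == hotspots$chrom[i] &
        eqtls$lead_pos >= hotspots$start[i] &
        eqtls$lead_pos <= hotspots$end[i]
      eqtls$node[hit] <- hotspots$hotspot[i]
      eqtls$node_type[hit] <- "hotspot"
    }
  }
  edges <- eqtls[eqtls$target %in% candidates, , drop = FALSE]
  if (!nrow(edges)) stop("no locus regulates a candidate gene")
  edge_df <- unique(data.frame(from = edges$node, to = edges$target,
                               stages = edges$stages %||% "all",
                               stringsAsFactors = FALSE))
  node_types <- unique(rbind(
    data.frame(name = edges$node, type = edges$node_type,
               stringsAsFactors = FALSE),
    data.frame(name = unique(edge_df$to), type = "gene",
               stringsAsFactors = FALSE)
  ))
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = node_types)
  g
}

#' Detect network modules by modularity maximization
#'
#' Partitions the (undirected, unweighted) locus-gene network into modules
#' by Louvain multi-level modularity maximization, seeded for
#' reproducibility.
#'
#' @param network an igraph graph from [build_network()].
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed for the (order-dependent) greedy passes.
#' @return list with `membership` (named integer vector) and `Q` (the
#'   Newman modularity of the returned partition, recomputable via
#'   `igraph::modularity`).
#' @export
detect_modules <- function(network, resolution = 1.0, seed = 1L) {
  if (igraph::vcount(network) == 0) stop("empty graph")
  comm <- with_seed(seed, igraph::cluster_louvain(network,
                                                  resolution = resolution))
  membership <- igraph::membership(comm)
  Q <- igraph::modularity(network, membership)
  list(membership = membership, Q = Q)
}

#' Log-log linear fit of the gene in-degree distribution
#'
#' Fits `log10(count) ~ log10(degree)` over the distinct positive
#' in-degrees of the gene nodes; a near-linear trend (high r2) is the
#' scale-free signature.
#'
#' @param network an igraph graph with a `type` vertex attribute.
#' @return list with `slope`, `r2`, `p` (regression F-test) and the
#'   underlying `degrees` table, or NULL when fewer than 3 distinct
#'   degrees exist.
#' @export
degree_powerlaw_fit <- function(network) {
  genes <- igraph::V(network)[igraph::V(network)$type == "gene"]
  deg <- igraph::degree(network, v = genes)
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3) {
    warning("fewer than 3 distinct in-degree values; fit undefined")
    return(NULL)
  }
  d <- data.frame(log_deg = log10(as.numeric(names(tab))),
                  log_count = log10(as.numeric(tab)))
  fit <- lm(log_count ~ log_deg, data = d)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  fstat <- sm$fstatistic
  list(slope = unname(coef(fit)[2]), r2 = sm$r.squared,
       p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       degrees = d)
}

#' Module-trait regression profile across timepoints
#'
#' For each timepoint, regresses the trait on the expression of the
#' module's genes and records the multiple-regression r2; the normalized
#' r2 (share of the summed r2 across timepoints) localizes the stage at
#' which the module tracks the trait. When the number of genes reaches the
#' sample size, a small ridge penalty replaces OLS and the row is flagged.
#' Profiles with total r2 below `min_total_r2` are reported unnormalized
#' (NA shares) and flagged unstable.
#'
#' @param module_genes character vector of gene ids (>= `min_genes`).
#' @param expr an `expression_cube`.
#' @param phenotypes data.frame with `accession` and the trait column.
#' @param trait trait name.
#' @param min_genes module size filter (default 5).
#' @param min_total_r2 stability floor for normalization (default 0.01).
#' @return data.frame with one row per timepoint: `timepoint`, `r2`,
#'   `normalized_r2`, `ridge`, `unstable`.
#' @export
module_trait_r2 <- function(module_genes, expr, phenotypes, trait,
                            min_genes = 5L, min_total_r2 = 0.01) {
  if (length(module_genes) < min_genes) {
    stop("module has fewer than ", min_genes, " genes")
  }
  acc <- dimnames(expr$values)[[2]]
  y_all <- phenotypes[[trait]][match(acc, phenotypes$accession)]
  rows <- lapply(seq_along(expr$timepoints), function(t) {
    X <- t(expr$values[module_genes, , t, drop = TRUE])
    if (is.null(dim(X))) X <- matrix(X, ncol = length(module_genes))
    X <- log2(X + 1)
    ok <- !is.na(y_all) & rowSums(is.na(X)) == 0
    X <- X[ok, , drop = FALSE]; y <- y_all[ok]
    keep_col <- apply(X, 2, sd) > 0
    X <- X[, keep_col, drop = FALSE]
    ridge <- ncol(X) >= nrow(X)
    if (!ncol(X)) return(data.frame(timepoint = expr$timepoints[t], r2 = 0,
                                    ridge = FALSE))
    if (!ridge) {
      fit <- lm(y ~ X)
      r2 <- summary(fit)$r.squared
    } else {
      # ridge fallback when p >= n
      Xs <- scale(X); ys <- y - mean(y)
      lam <- 1e-2 * nrow(X)
      b <- solve(crossprod(Xs) + diag(lam, ncol(Xs)), crossprod(Xs, ys))
      yhat <- Xs %*% b
      r2 <- 1 - sum((ys - yhat)^2) / sum(ys^2)
    }
    data.frame(timepoint = expr$timepoints[t], r2 = max(r2, 0), ridge = ridge,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- sum(out$r2)
  out$unstable <- total < min_total_r2
  out$normalized_r2 <- if (total >= min_total_r2) out$r2 / total else NA_real_
  out
}

#' Haseman-Elston SNP heritability
#'
#' Estimates the fraction of phenotypic variance captured by a SNP set by
#' regressing the off-diagonal phenotypic cross-products of the centered
#' trait on the corresponding entries of the genomic relationship matrix
#' (GRM) built from standardized dosages; the slope estimates the genetic
#' variance and `h2 = slope / var(y)`, clamped to \[0, 1\].
#'
#' @param genotypes a `genotype_matrix` or a plain dosage matrix.
#' @param y phenotype vector in accession order.
#' @param snps optional SNP id subset (e.g. the cis or trans partition of
#'   a gene's SNPs, or a module's SNPs).
#' @return list with `h2`, `h2_unclamped`, `slope`, `n_snps`.
#' @export
module_heritability <- function(genotypes, y, snps = NULL) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else genotypes
  if (!is.null(snps)) dos <- dos[, snps, drop = FALSE]
  if (ncol(dos) < 2) stop("need at least 2 SNPs")
  if (length(y) != nrow(dos)) stop("phenotype length must match accessions")
  ok <- !is.na(y) & rowSums(is.na(dos)) == 0
  y <- y[ok]; dos <- dos[ok, , drop = FALSE]
  n <- length(y)
  if (n < 50) stop("need at least 50 accessions")
  poly <- apply(dos, 2, sd) > 0
  dos <- dos[, poly, drop = FALSE]
  if (ncol(dos) < 2) stop("fewer than 2 polymorphic SNPs")
  Z <- scale(dos)
  K <- tcrossprod(Z) / ncol(Z)
  yc <- y - mean(y)
  cp <- tcrossprod(yc)
  lower <- lower.tri(K)
  kij <- K[lower]
  if (sd(kij) == 0) stop("GRM is degenerate (constant off-diagonals)")
  slope <- cov(kij, cp[lower]) / var(kij)
  h2_raw <- slope / var(y)
  list(h2 = min(max(h2_raw, 0), 1), h2_unclamped = h2_raw, slope = slope,
       n_snps = ncol(dos))
}

#' One-sided Fisher enrichment of a locus subset across modules
#'
#' For each module, tests whether loci from `subset` are over-represented
#' among the module's locus nodes (one-sided Fisher exact test, greater),
#' with Benjamini-Hochberg correction across modules.
#'
#' @param subset character vector of locus node names (e.g. loci with a
#'   favorable-allele frequency shift).
#' @param membership named module assignment from [detect_modules()].
#' @param locus_nodes names of all locus/hotspot nodes in the network; by
#'   default every assigned node not in `genes`.
#' @param genes optional gene node names excluded from the universe.
#' @return data.frame per module: counts, odds ratio, `p`, `q`.
#' @export
enrich_loci_in_modules <- function(subset, membership, locus_nodes = NULL,
                                   genes = character(0)) {
  if (!length(subset)) stop("empty locus subset")
  if (is.null(locus_nodes)) locus_nodes <- setdiff(names(membership), genes)
  subset <- intersect(subset, locus_nodes)
  if (!length(subset)) stop("subset has no overlap with the network's loci")
  mods <- sort(unique(membership[locus_nodes]))
  rows <- lapply(mods, function(m) {
    in_mod <- names(membership)[membership == m]
    in_mod <- intersect(in_mod, locus_nodes)
    a <- length(intersect(subset, in_mod))
    b <- length(setdiff(subset, in_mod))
    c_ <- length(setdiff(in_mod, subset))
    d <- length(setdiff(locus_nodes, union(subset, in_mod)))
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(module = m, n_subset_in = a, n_subset_out = b,
               n_module = length(in_mod), odds_ratio = unname(ft$estimate),
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out
}

#' Heritability accumulation over nested SNP subsets
#'
#' Estimates [module_heritability()] on nested random subsets of
#' increasing size, reproducing the growth curve of explained variance as
#' more trait-related variants are considered.
#'
#' @param genotypes a `genotype_matrix`.
#' @param y phenotype vector in accession order.
#' @param sizes increasing subset sizes.
#' @param seed seed for the nested sampling.
#' @return data.frame with `n_snps` and `h2`.
#' @export
heritability_accumulation <- function(genotypes, y, sizes, seed = 1L) {
  snps <- genotypes$snp_meta$snp
  sizes <- sort(pmin(sizes, length(snps)))
  ordering <- with_seed(seed, sample(snps))
  rows <- lapply(sizes, function(s) {
    est <- module_heritability(genotypes, y, snps = ordering[seq_len(s)])
    data.frame(n_snps = s, h2 = est$h2)
  })
  do.call(rbind, rows)
}
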