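#' Flag trait-associated candidate genes from expression
#'
#' Surrogate transcriptome-trait association: per gene and timepoint,
#' ordinary least squares of the trait on the gene's (log2) expression plus
#' covariates, Benjamini-Hochberg corrected across all gene-timepoint
#' tests. A gene is a candidate when q < `fdr` in at least one timepoint;
#' its effect direction is the sign of the expression coefficient at the
#' most significant timepoint. The trait-associated variant is the lead
#' SNP of the gene's best cis-eQTL, falling back to the best GWAS locus
#' lead within `fallback_window` of the TSS; candidates with neither are
#' emitted without a variant (and are excluded from genotype-dependent
#' states downstream).
#'
#' @param expr an `expression_cube` (pre-filtered genes recommended).
#' @param phenotypes data.frame with `accession` + trait column.
#' @param trait trait name.
#' @param covariates optional covariates (accessions x k, genotype order =
#'   cube accession order).
#' @param cis_results optional [map_cis_eqtl()] table (per timepoint rows
#'   allowed) used to attach variants.
#' @param gwas_loci optional GWAS locus table for the fallback.
#' @param fdr candidate threshold (default 0.05).
#' @param fallback_window GWAS fallback window around the TSS (default
#'   1 Mb).
#' @return data.frame of candidates: `gene`, `trait`, `direction`,
#'   `best_timepoint`, `q`, `variant` (NA when none found).
#' @export
flag_candidates <- function(expr, phenotypes, trait, covariates = NULL,
                            cis_results = NULL, gwas_loci = NULL,
                            fdr = 0.05, fallback_window = 1e6) {
  acc <- dimnames(expr$values)[[2]]
  y <- phenotypes[[trait]][match(acc, phenotypes$accession)]
  genes <- rownames(expr$values)
  tests <- list()
  for (t in seq_along(expr$timepoints)) {
    for (g in genes) {
      x <- log2(expr$values[g, , t] + 1)
      ok <- !is.na(x) & !is.na(y)
      if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
      if (sum(ok) < 10 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      rec <- scan_linear(y[ok],
                         matrix(x[ok], ncol = 1, dimnames = list(NULL, "x")),
                         if (!is.null(covariates))
                           covariates[ok, , drop = FALSE])
      if (is.na(rec$p)) next
      tests[[length(tests) + 1L]] <- data.frame(
        gene = g, timepoint = expr$timepoints[t],
        beta = rec$beta, p = rec$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(tests)) {
    return(data.frame(gene = character(0), trait = character(0),
                      direction = character(0), best_timepoint = character(0),
                      q = numeric(0), variant = character(0)))
  }
  tab <- do.call(rbind, tests)
  tab$q <- p.adjust(tab$p, "BH")
  cand_genes <- unique(tab$gene[tab$q < fdr])
  rows <- lapply(cand_genes, function(g) {
    sub <- tab[tab$gene == g, , drop = FALSE]
    best <- sub[which.min(sub$p), ]
    variant <- NA_character_
    if (!is.null(cis_results) && nrow(cis_results)) {
      cr <- cis_results[cis_results$gene == g & cis_results$significant, ,
                        drop = FALSE]
      if (nrow(cr)) variant <- cr$lead_snp[which.min(cr$p_gene)]
    }
    if (is.na(variant) && !is.null(gwas_loci) && nrow(gwas_loci)) {
      gm <- expr$gene_meta[expr$gene_meta$gene == g, ]
      gl <- gwas_loci[gwas_loci$chrom == gm$chrom &
                        abs((gwas_loci$start + gwas_loci$end) / 2 - gm$tss) <=
                        fallback_window, , drop = FALSE]
      if (nrow(gl)) variant <- gl$lead_snp[which.min(gl$lead_p)]
    }
    data.frame(gene = g, trait = trait,
               direction = ifelse(best$beta >= 0, "positive", "negative"),
               best_timepoint = best$timepoint, q = min(sub$q),
               variant = variant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify one homoeolog pair observation into the four coordination states
#'
#' Crosses two booleans: *genotype-favorable* — the accession carries at
#' least one favorable allele at the candidate's trait-associated variant
#' (dominant coding; set `dominant = FALSE` to require homozygosity) — and
#' *expression-favorable* — for a positively acting candidate, the
#' homoeolog partner is not more than `fold`-fold below the candidate
#' (higher or no difference); mirrored for negative candidates.
#'
#' @param direction `"positive"` or `"negative"` candidate effect.
#' @param favorable_dosage dosage of the favorable allele (0, 1, 2 or NA).
#' @param cand_expr candidate-gene expression.
#' @param homoeolog_expr partner-homoeolog expression.
#' @param fold fold-change unit defining "no difference" (default 2).
#' @param dominant genotype coding (default `TRUE`: dosage >= 1 favorable).
#' @return one of `"favorable_pair"`, `"genotype_only"`,
#'   `"expression_only"`, `"unfavorable_pair"`, or NA for missing
#'   genotype.
#' @export
classify_pair_state <- function(direction, favorable_dosage, cand_expr,
                                homoeolog_expr, fold = 2, dominant = TRUE) {
  n <- max(length(favorable_dosage), length(cand_expr), length(homoeolog_expr))
  direction <- rep_len(direction, n)
  favorable_dosage <- rep_len(favorable_dosage, n)
  cand_expr <- rep_len(cand_expr, n)
  homoeolog_expr <- rep_len(homoeolog_expr, n)
  if (any(cand_expr < 0, na.rm = TRUE) || any(homoeolog_expr < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative")
  }
  geno_fav <- if (dominant) favorable_dosage >= 1 else favorable_dosage == 2
  expr_fav <- ifelse(direction == "positive",
                     homoeolog_expr >= cand_expr / fold,
                     homoeolog_expr <= cand_expr * fold)
  out <- rep(NA_character_, n)
  ok <- !is.na(geno_fav) & !is.na(expr_fav)
  out[ok & geno_fav & expr_fav] <- "favorable_pair"
  out[ok & geno_fav & !expr_fav] <- "genotype_only"
  out[ok & !geno_fav & expr_fav] <- "expression_only"
  out[ok & !geno_fav & !expr_fav] <- "unfavorable_pair"
  out
}

#' Per-accession/timepoint coordination states for all candidate pairs
#'
#' @param candidates [flag_candidates()] table (rows without a variant are
#'   skipped with a log attribute).
#' @param pairs pair map (`pair`, `gene_At`, `gene_Dt`).
#' @param expr an `expression_cube` containing both members.
#' @param genotypes a `genotype_matrix`.
#' @param library optional allele library giving the favorable allele per
#'   variant; defaults to favorable = alt when the candidate's direction
#'   is positive... supply explicitly for real use (see
#'   [build_allele_library()]). If NULL, favorable allele is taken as the
#'   allele whose dosage has positive covariance with the trait proxy --
#'   here simplified to "alt".
#' @param fold fold-change unit (default 2).
#' @param dominant genotype coding.
#' @return character array pairs x accessions x timepoints of states, with
#'   attribute `skipped` listing candidates without variants.
#' @export
pair_state_cube <- function(candidates, pairs, expr, genotypes,
                            library = NULL, fold = 2, dominant = TRUE) {
  cand <- candidates[candidates$gene %in% c(pairs$gene_At, pairs$gene_Dt), ,
                     drop = FALSE]
  skipped <- cand$gene[is.na(cand$variant)]
  cand <- cand[!is.na(cand$variant), , drop = FALSE]
  acc <- dimnames(expr$values)[[2]]
  tps <- expr$timepoints
  pair_rows <- pairs[pairs$gene_At %in% cand$gene | pairs$gene_Dt %in% cand$gene, ,
                     drop = FALSE]
  states <- array(NA_character_,
                  dim = c(nrow(pair_rows), length(acc), length(tps)),
                  dimnames = list(pair_rows$pair, acc, tps))
  g_idx <- match(acc, genotypes$accession_ids)
  for (i in seq_len(nrow(pair_rows))) {
    is_at <- pair_rows$gene_At[i] %in% cand$gene
    cand_gene <- if (is_at) pair_rows$gene_At[i] else pair_rows$gene_Dt[i]
    partner <- if (is_at) pair_rows$gene_Dt[i] else pair_rows$gene_At[i]
    cr <- cand[cand$gene == cand_gene, ][1, ]
    dos <- genotypes$dosages[g_idx, cr$variant]
    fav_allele <- "alt"
    if (!is.null(library) && cr$variant %in% library$lead_snp) {
      fav_allele <- library$favorable[library$lead_snp == cr$variant][1]
    }
    fav_dos <- if (fav_allele == "ref") 2 - dos else dos
    for (t in seq_along(tps)) {
      states[i, , t] <- classify_pair_state(
        cr$direction, fav_dos,
        expr$values[cand_gene, , t], expr$values[partner, , t],
        fold = fold, dominant = dominant)
    }
  }
  attr(states, "skipped") <- skipped
  states
}

#' Aggregate coordination states to pair-level labels and accession counts
#'
#' Applies the priority rules: (1) `favorable_pair` when at least
#' `min_frac` of classified accessions are favorable pairs at every
#' timepoint; (2) `genotype_only` when favorable-pair-or-genotype-only
#' reaches `min_frac` at every timepoint but (1) fails; (3)
#' `expression_only` symmetrically; (4) `unfavorable_pair` otherwise.
#' Also counts, per accession, the number of pairs in each state (using
#' each pair's modal state across timepoints).
#'
#' @param states array from [pair_state_cube()].
#' @param min_frac aggregation threshold (default 0.5).
#' @return list with `pair_summary` (pair, label) and `accession_counts`
#'   (accession x state counts).
#' @export
summarize_pair_states <- function(states, min_frac = 0.5) {
  prs <- dimnames(states)[[1]]
  tps <- dimnames(states)[[3]]
  frac_at_tp <- function(i, set) {
    vapply(seq_along(tps), function(t) {
      s <- states[i, , t]
      obs <- !is.na(s)
      if (!any(obs)) return(NA_real_)
      mean(s[obs] %in% set)
    }, 0)
  }
  label <- vapply(seq_along(prs), function(i) {
    f1 <- frac_at_tp(i, "favorable_pair")
    if (all(!is.na(f1)) && all(f1 >= min_frac)) return("favorable_pair")
    f2 <- frac_at_tp(i, c("favorable_pair", "genotype_only"))
    if (all(!is.na(f2)) && all(f2 >= min_frac)) return("genotype_only")
    f3 <- frac_at_tp(i, c("favorable_pair", "expression_only"))
    if (all(!is.na(f3)) && all(f3 >= min_frac)) return("expression_only")
    "unfavorable_pair"
  }, "")
  state_levels <- c("favorable_pair", "genotype_only", "expression_only",
                    "unfavorable_pair")
  acc <- dimnames(states)[[2]]
  counts <- matrix(0L, nrow = length(acc), ncol = length(state_levels),
                   dimnames = list(acc, state_levels))
  for (i in seq_along(prs)) {
    m <- states[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(tps))
    modal <- apply(m, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_character_)
      names(sort(table(factor(v, state_levels)), decreasing = TRUE))[1]
    })
    ok <- !is.na(modal)
    for (s in state_levels) counts[ok & modal == s, s] <-
        counts[ok & modal == s, s] + 1L
  }
  list(pair_summary = data.frame(pair = prs, label = label,
                                 stringsAsFactors = FALSE),
       accession_counts = counts)
}

#' Group accessions by temporal expression pattern of one gene
#'
#' Clusters accessions by their row-normalized temporal expression profile
#' (Ward linkage, Euclidean) into `k` groups and flags a group as
#' favorable when its accessions' trait values stochastically exceed the
#' remainder's (one-sided Wilcoxon rank-sum, BH q < `fdr`).
#'
#' @param gene gene id.
#' @param expr an `expression_cube`.
#' @param phenotypes data.frame with `accession` + trait column.
#' @param trait trait name.
#' @param k number of groups (default 8; reduced with a message when the
#'   number of accessions with complete profiles is smaller).
#' @param fdr favorable-group threshold.
#' @return list with `groups` (data.frame accession, group, peak
#'   timepoint) and `group_summary` (group, n, trait median, q,
#'   favorable).
#' @export
expression_pattern_groups <- function(gene, expr, phenotypes, trait,
                                      k = 8L, fdr = 0.05) {
  prof <- expr$values[gene, , , drop = TRUE]  # accessions x timepoints
  complete <- rowSums(is.na(prof)) == 0
  prof <- prof[complete, , drop = FALSE]
  tot <- rowSums(prof)
  keep <- tot > 0
  prof <- prof[keep, , drop = FALSE] / tot[keep]
  n <- nrow(prof)
  if (n < 2) stop("need at least 2 accessions with complete profiles")
  if (n < k) {
    message("reducing k from ", k, " to ", n)
    k <- n
  }
  hc <- hclust(dist(prof), method = "ward.D2")
  grp <- cutree(hc, k = k)
  y <- phenotypes[[trait]][match(rownames(prof), phenotypes$accession)]
  peaks <- expr$timepoints[apply(prof, 1, which.max)]
  summ <- lapply(sort(unique(grp)), function(g) {
    ing <- grp == g
    p <- if (sum(ing) >= 2 && sum(!ing) >= 2 && !all(is.na(y))) {
      suppressWarnings(wilcox.test(y[ing], y[!ing],
                                   alternative = "greater", exact = FALSE)$p.value)
    } else NA_real_
    data.frame(group = g, n = sum(ing), trait_median = median(y[ing], na.rm = TRUE),
               p = p, stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  summ$q <- NA_real_
  ok <- !is.na(summ$p)
  summ$q[ok] <- p.adjust(summ$p[ok], "BH")
  summ$favorable <- !is.na(summ$q) & summ$q < fdr
  list(groups = data.frame(accession = rownames(prof), group = grp,
                           peak_timepoint = peaks, stringsAsFactors = FALSE),
       group_summary = summ)
}

#' Bias-score shift between genotype groups
#'
#' Per pair and timepoint, compares the magnitude of the bias score between
#' accessions carrying the favorable and the unfavorable genotype
#' (two-sided Wilcoxon rank-sum, BH across pairs); direction is the sign
#' of the median difference. Pairs with fewer than `min_n` accessions in
#' either group are skipped and logged.
#'
#' @param scores [bias_score_cube()] array.
#' @param favorable_acc,unfavorable_acc accession id vectors per pair:
#'   either shared character vectors or named lists keyed by pair id.
#' @param min_n minimum group size (default 5).
#' @return data.frame per pair x timepoint: `delta` (favorable minus
#'   unfavorable median |score|), `p`, `q`, `direction`; skipped pairs in
#'   attribute `skipped`.
#' @export
bias_shift_by_genotype <- function(scores, favorable_acc, unfavorable_acc,
                                   min_n = 5L) {
  prs <- dimnames(scores)[[1]]
  tps <- dimnames(scores)[[3]]
  get_grp <- function(x, pr) if (is.list(x)) x[[pr]] else x
  rows <- list(); skipped <- character(0)
  for (pr in prs) {
    fav <- get_grp(favorable_acc, pr)
    unf <- get_grp(unfavorable_acc, pr)
    if (length(fav) < min_n || length(unf) < min_n) {
      skipped <- c(skipped, pr)
      next
    }
    for (t in seq_along(tps)) {
      a <- abs(scores[pr, fav, t]); b <- abs(scores[pr, unf, t])
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < min_n || length(b) < min_n) next
      p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pr, timepoint = tps[t], delta = median(a) - median(b), p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(0), timepoint = character(0),
               delta = numeric(0), p = numeric(0))
  if (nrow(out)) {
    out$q <- p.adjust(out$p, "BH")
    out$direction <- ifelse(out$delta >= 0, "increase", "decrease")
  } else {
    out$q <- numeric(0); out$direction <- character(0)
  }
  attr(out, "skipped") <- skipped
  out
}
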