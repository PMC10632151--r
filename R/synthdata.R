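#' Configure a synthetic allotetraploid cohort
#'
#' Defines the shape of a simulated cohort: accessions, SNPs laid out in
#' linkage-disequilibrium (LD) blocks over At- and Dt-subgenome chromosomes,
#' homoeolog gene pairs, and developmental timepoints. The defaults emulate,
#' at reduced scale, a diversity panel genotyped at MAF > 0.05 and sampled
#' over six fiber developmental stages (0-20 days postanthesis).
#'
#' @param n_accessions number of accessions (>= 2).
#' @param n_snps_per_chrom SNPs simulated per chromosome (before MAF
#'   filtering).
#' @param chromosomes data.frame with columns `chrom`, `length` (bp) and
#'   `subgenome` (`"At"` or `"Dt"`). Default: one 10-Mb chromosome per
#'   subgenome.
#' @param n_pairs number of homoeolog gene pairs (one member per subgenome).
#' @param timepoints ordered character vector of stage labels.
#' @param maf_range allele-frequency interval in (0, 0.5] from which
#'   founder-haplotype allele frequencies are drawn.
#' @param ld_block_len LD block length in bp; SNPs within one block are
#'   copied from a shared founder-haplotype pool.
#' @param n_founders founder haplotypes per LD block (controls within-block
#'   LD; fewer founders, stronger LD).
#' @param noise_sd residual standard deviation on the log2 expression scale.
#' @param seed integer seed; all generators derive their randomness from it.
#'
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_accessions = 50, n_snps_per_chrom = 40, n_pairs = 10)
cohort_config <- function(n_accessions = 200L,
                          n_snps_per_chrom = 200L,
                          chromosomes = NULL,
                          n_pairs = 50L,
                          timepoints = c("0DPA", "4DPA", "8DPA",
                                         "12DPA", "16DPA", "20DPA"),
                          maf_range = c(0.05, 0.5),
                          ld_block_len = 2e5,
                          n_founders = 20L,
                          noise_sd = 0.5,
                          seed = 1L) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(
      chrom = c("A01", "D01"),
      length = c(1e7, 1e7),
      subgenome = c("At", "Dt"),
      stringsAsFactors = FALSE
    )
  }
  assert_scalar_number(n_accessions, "n_accessions", min = 2)
  assert_scalar_number(n_pairs, "n_pairs", min = 1)
  if (length(timepoints) < 1L) stop("need at least one timepoint")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval within (0, 0.5]")
  }
  if (!all(chromosomes$subgenome %in% c("At", "Dt"))) {
    stop("every chromosome must be assigned subgenome 'At' or 'Dt'")
  }
  if (!any(chromosomes$subgenome == "At") || !any(chromosomes$subgenome == "Dt")) {
    stop("need at least one chromosome per subgenome to host homoeolog pairs")
  }
  structure(
    list(
      n_accessions = as.integer(n_accessions),
      n_snps_per_chrom = as.integer(n_snps_per_chrom),
      chromosomes = chromosomes,
      n_pairs = as.integer(n_pairs),
      timepoints = as.character(timepoints),
      maf_range = as.numeric(maf_range),
      ld_block_len = as.numeric(ld_block_len),
      n_founders = as.integer(n_founders),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Assemble a truth set of planted effects for a synthetic cohort
#'
#' The truth set is the machine-readable ground truth used by
#' parameter-recovery tests: planted cis/trans expression effects, per-pair
#' subgenome bias offsets, causal phenotype loci and target trait
#' heritabilities.
#'
#' @param cis_effects data.frame with columns `snp`, `gene`, `beta`
#'   (log2 units per dosage) and `timepoints` (comma-separated stage labels
#'   or `"all"`).
#' @param trans_effects same shape as `cis_effects`, for distant SNPs.
#' @param bias_offsets data.frame with columns `pair`, `timepoint` (or
#'   `"all"`) and `offset`, the planted log2 At-Dt offset.
#' @param causal_phenotype_loci data.frame with columns `snp`, `trait`,
#'   `effect` (per favorable-allele copy) and `favorable` (`"ref"`/`"alt"`).
#' @param target_h2 named numeric vector of trait heritabilities in \[0, 1\].
#'
#' @return an object of class `truth_set`.
#' @export
truth_set <- function(cis_effects = NULL, trans_effects = NULL,
                      bias_offsets = NULL, causal_phenotype_loci = NULL,
                      target_h2 = numeric(0)) {
  empty_eff <- data.frame(snp = character(0), gene = character(0),
                          beta = numeric(0), timepoints = character(0),
                          stringsAsFactors = FALSE)
  empty_off <- data.frame(pair = character(0), timepoint = character(0),
                          offset = numeric(0), stringsAsFactors = FALSE)
  empty_loci <- data.frame(snp = character(0), trait = character(0),
                           effect = numeric(0), favorable = character(0),
                           stringsAsFactors = FALSE)
  if (length(target_h2) && (any(target_h2 < 0) || any(target_h2 > 1))) {
    stop("`target_h2` values must lie in [0, 1]")
  }
  structure(
    list(
      cis_effects = cis_effects %||% empty_eff,
      trans_effects = trans_effects %||% empty_eff,
      bias_offsets = bias_offsets %||% empty_off,
      causal_phenotype_loci = causal_phenotype_loci %||% empty_loci,
      target_h2 = target_h2
    ),
    class = "truth_set"
  )
}

#' Simulate genotype dosages in LD blocks
#'
#' Draws biallelic SNP dosages for each accession by copying block
#' haplotypes: each LD block holds a pool of founder haplotypes (allele
#' frequencies drawn from `maf_range`) and every accession draws two
#' founders per block, so within-block r2 exceeds cross-block r2 in
#' expectation. SNPs whose realized minor allele frequency falls below the
#' configured lower bound are filtered out.
#'
#' @param config a [cohort_config()].
#' @return an object of class `genotype_matrix`: list with `dosages`
#'   (accessions x SNPs, values 0/1/2), `snp_meta` (`snp`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`) and `accession_ids`.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_accessions
  with_seed(config$seed, {
    acc <- sprintf("S%03d", seq_len(n))
    per_chrom <- lapply(seq_len(nrow(config$chromosomes)), function(ci) {
      chrom <- config$chromosomes$chrom[ci]
      len <- config$chromosomes$length[ci]
      pos <- sort(sample.int(len, config$n_snps_per_chrom))
      block <- floor((pos - 1) / config$ld_block_len)
      dos <- matrix(0L, nrow = n, ncol = length(pos))
      for (b in unique(block)) {
        idx <- which(block == b)
        p <- runif(length(idx), config$maf_range[1], config$maf_range[2])
        founders <- matrix(
          rbinom(config$n_founders * length(idx), 1L, rep(p, each = config$n_founders)),
          nrow = config$n_founders
        )
        h1 <- sample.int(config$n_founders, n, replace = TRUE)
        h2 <- sample.int(config$n_founders, n, replace = TRUE)
        dos[, idx] <- founders[h1, , drop = FALSE] + founders[h2, , drop = FALSE]
      }
      alleles <- c("A", "C", "G", "T")
      ref <- sample(alleles, length(pos), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
      list(dosages = dos,
           meta = data.frame(snp = sprintf("%s_%d", chrom, pos),
                             chrom = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
    })
    dosages <- do.call(cbind, lapply(per_chrom, `[[`, "dosages"))
    meta <- do.call(rbind, lapply(per_chrom, `[[`, "meta"))
    meta$maf <- maf_from_dosage_matrix(dosages)
    # a lower bound of 0.5 (the maximum possible MAF) cannot be enforced by
    # filtering: realized frequencies scatter just below it by sampling
    maf_floor <- if (config$maf_range[1] >= 0.5) 0 else config$maf_range[1]
    keep <- meta$maf >= maf_floor
    if (!any(keep)) {
      stop("no SNP reached the configured minimum MAF; maf_range impossible ",
           "at this sample size")
    }
    dosages <- dosages[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    rownames(meta) <- NULL
    dimnames(dosages) <- list(acc, meta$snp)
    structure(list(dosages = dosages, snp_meta = meta, accession_ids = acc),
              class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snp_meta$chrom))))
  invisible(x)
}

#' Deterministic gene annotation for a synthetic cohort
#'
#' Places the At member of each homoeolog pair evenly along the At
#' chromosomes and its Dt partner at the mirrored relative position on the
#' Dt chromosomes. Deterministic given the config (no randomness used).
#'
#' @param config a [cohort_config()].
#' @return list with `gene_meta` (`gene`, `chrom`, `tss`, `strand`,
#'   `subgenome`) and `pairs` (`pair`, `gene_At`, `gene_Dt`).
#' @export
generate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  place <- function(sub, prefix) {
    chr <- config$chromosomes[config$chromosomes$subgenome == sub, , drop = FALSE]
    k <- nrow(chr)
    ci <- rep(seq_len(k), length.out = config$n_pairs)
    within <- unlist(lapply(seq_len(k), function(i) seq_len(sum(ci == i))))
    n_on <- tabulate(ci, k)
    tss <- integer(config$n_pairs)
    for (i in seq_len(k)) {
      sel <- ci == i
      tss[sel] <- round(seq(0.05, 0.95, length.out = n_on[i]) * chr$length[i])
    }
    data.frame(
      gene = sprintf("%s%03d", prefix, seq_len(config$n_pairs)),
      chrom = chr$chrom[ci], tss = tss, strand = "+",
      subgenome = sub, stringsAsFactors = FALSE
    )
  }
  at <- place("At", "GA")
  dt <- place("Dt", "GD")
  list(
    gene_meta = rbind(at, dt),
    pairs = data.frame(pair = sprintf("P%03d", seq_len(config$n_pairs)),
                       gene_At = at$gene, gene_Dt = dt$gene,
                       stringsAsFactors = FALSE)
  )
}

# expand "all"/comma-separated stage labels to indices into config timepoints
resolve_timepoints <- function(spec, timepoints) {
  if (is.na(spec) || identical(spec, "all") || !nzchar(spec)) {
    return(seq_along(timepoints))
  }
  labs <- strsplit(spec, ",", fixed = TRUE)[[1]]
  idx <- match(trimws(labs), timepoints)
  if (anyNA(idx)) {
    stop("effect references timepoint(s) absent from the cohort: ",
         paste(labs[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Simulate homoeolog expression over timepoints
#'
#' Expression is generated on the log2(x + 1) scale as the sum of a smooth
#' per-pair baseline stage curve (cubic in timepoint index, shared by both
#' pair members), planted cis and trans dosage effects, a subgenome bias
#' offset added to the At member, and Gaussian noise, then reported on the
#' linear scale (nonnegative).
#'
#' @param genotypes a [generate_genotypes()] result.
#' @param truth a [truth_set()]; `snp`/`gene` ids must exist.
#' @param config the [cohort_config()].
#' @param annotation gene annotation, default [generate_gene_annotation()].
#' @param seed seed for baseline curves and noise; defaults to
#'   `config$seed + 1`.
#' @return list with `expr` (an `expression_cube`: `values` genes x
#'   accessions x timepoints, `gene_meta`, `timepoints`) and `pairs`.
#' @export
generate_expression <- function(genotypes, truth, config,
                                annotation = generate_gene_annotation(config),
                                seed = config$seed + 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(truth, "truth_set"))
  gm <- annotation$gene_meta
  tps <- config$timepoints
  n_t <- length(tps)
  n <- nrow(genotypes$dosages)
  bad <- setdiff(c(truth$cis_effects$gene, truth$trans_effects$gene), gm$gene)
  if (length(bad)) stop("truth references unknown gene(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(c(truth$cis_effects$snp, truth$trans_effects$snp),
                 genotypes$snp_meta$snp)
  if (length(bad)) stop("truth references unknown SNP(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(truth$bias_offsets$pair, annotation$pairs$pair)
  if (length(bad)) stop("truth references unknown pair(s): ", paste(bad, collapse = ", "))

  with_seed(seed, {
    s <- if (n_t > 1) seq(-1, 1, length.out = n_t) else 0
    # one baseline curve per pair, shared by both members
    b0 <- runif(config$n_pairs, 3, 7)
    cc <- matrix(rnorm(config$n_pairs * 3, 0, 0.3), ncol = 3)
    base_pair <- sapply(seq_len(n_t), function(t) {
      b0 + cc[, 1] * s[t] + cc[, 2] * s[t]^2 + cc[, 3] * s[t]^3
    })
    if (is.null(dim(base_pair))) base_pair <- matrix(base_pair, nrow = config$n_pairs)
    v <- array(0, dim = c(nrow(gm), n, n_t),
               dimnames = list(gm$gene, genotypes$accession_ids, tps))
    pair_of_gene <- c(
      stats::setNames(annotation$pairs$pair, annotation$pairs$gene_At),
      stats::setNames(annotation$pairs$pair, annotation$pairs$gene_Dt)
    )
    pair_idx <- match(pair_of_gene[gm$gene], annotation$pairs$pair)
    for (t in seq_len(n_t)) {
      v[, , t] <- matrix(base_pair[pair_idx, t], nrow = nrow(gm), ncol = n)
    }
    add_effects <- function(effects) {
      if (!nrow(effects)) return(invisible())
      for (i in seq_len(nrow(effects))) {
        tp_idx <- resolve_timepoints(effects$timepoints[i], tps)
        d <- genotypes$dosages[, effects$snp[i]]
        g <- effects$gene[i]
        for (t in tp_idx) v[g, , t] <<- v[g, , t] + effects$beta[i] * d
      }
    }
    add_effects(truth$cis_effects)
    add_effects(truth$trans_effects)
    if (nrow(truth$bias_offsets)) {
      for (i in seq_len(nrow(truth$bias_offsets))) {
        pr <- annotation$pairs[annotation$pairs$pair == truth$bias_offsets$pair[i], ]
        tp_idx <- resolve_timepoints(truth$bias_offsets$timepoint[i], tps)
        for (t in tp_idx) {
          v[pr$gene_At, , t] <- v[pr$gene_At, , t] + truth$bias_offsets$offset[i]
        }
      }
    }
    if (config$noise_sd > 0) {
      v <- v + array(rnorm(length(v), 0, config$noise_sd), dim = dim(v))
    }
    values <- pmax(2^v - 1, 0)
    expr <- structure(list(values = values, gene_meta = gm, timepoints = tps),
                      class = "expression_cube")
    list(expr = expr, pairs = annotation$pairs)
  })
}

#' @export
print.expression_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<expression_cube> %d genes x %d accessions x %d timepoints\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate additive phenotypes at a target heritability
#'
#' Each trait is the sum over its causal loci of effect x favorable-allele
#' dosage plus Gaussian noise scaled so the genetic-variance fraction
#' matches `target_h2`. With `target_h2 = 1` the phenotype equals the
#' genetic value; with `target_h2 = 0` it is pure noise.
#'
#' @param genotypes a `genotype_matrix`.
#' @param truth a [truth_set()] with `causal_phenotype_loci` and `target_h2`.
#' @param seed seed for the environmental noise.
#' @return list with `phenotypes` (data.frame, accession + one column per
#'   trait) and `genetic_values` (same shape, noiseless truth).
#' @export
generate_phenotypes <- function(genotypes, truth, seed = 100L) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(truth, "truth_set"))
  loci <- truth$causal_phenotype_loci
  bad <- setdiff(loci$snp, genotypes$snp_meta$snp)
  if (length(bad)) stop("causal loci reference unknown SNP(s): ",
                        paste(bad, collapse = ", "))
  traits <- unique(loci$trait)
  n <- nrow(genotypes$dosages)
  ph <- data.frame(accession = genotypes$accession_ids, stringsAsFactors = FALSE)
  gv <- ph
  with_seed(seed, {
    for (tr in traits) {
      h2 <- truth$target_h2[[tr]] %||% stop("no target_h2 for trait ", tr)
      if (is.na(h2) || h2 < 0 || h2 > 1) stop("target_h2 for ", tr, " outside [0, 1]")
      sub <- loci[loci$trait == tr, , drop = FALSE]
      fav_dos <- sapply(seq_len(nrow(sub)), function(i) {
        d <- genotypes$dosages[, sub$snp[i]]
        if (sub$favorable[i] == "ref") 2 - d else d
      })
      g <- as.numeric(fav_dos %*% sub$effect)
      vg <- var(g)
      if (h2 == 0) {
        y <- rnorm(n, 0, max(sqrt(vg), 1))
      } else if (h2 == 1) {
        y <- g
      } else {
        if (vg == 0) stop("planted genetic variance is zero for trait ", tr,
                          "; cannot target h2 = ", h2)
        y <- g + rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
      }
      gv[[tr]] <- g
      ph[[tr]] <- y
    }
  })
  list(phenotypes = ph, genetic_values = gv)
}

#' Split a cohort into landrace/cultivar groups with shifted allele frequencies
#'
#' Labels accessions as landraces or cultivars and resamples cultivar
#' genotypes at the designated favorable loci so the favorable-allele
#' frequency among cultivars exceeds the landrace frequency by
#' approximately `shift`; loci named in `purifying` are shifted in the
#' opposite direction (favorable allele depleted in cultivars). Target
#' frequencies incompatible with the landrace base frequency are clamped
#' to \[0, 1\] with a warning.
#'
#' @param genotypes a `genotype_matrix`.
#' @param truth a [truth_set()]; designated loci are
#'   `truth$causal_phenotype_loci`.
#' @param shift target frequency difference in \[0, 1\].
#' @param purifying character vector of SNP ids shifted oppositely.
#' @param prop_cultivar fraction of accessions labeled cultivar.
#' @param seed seed for labeling and resampling.
#' @return list with `groups` (data.frame `accession`, `group`) and
#'   `genotypes` (modified `genotype_matrix`, MAF recomputed).
#' @export
generate_populations <- function(genotypes, truth, shift,
                                 purifying = character(0),
                                 prop_cultivar = 0.5, seed = 200L) {
  assert_scalar_number(shift, "shift", min = 0, max = 1)
  loci <- truth$causal_phenotype_loci
  bad <- setdiff(purifying, loci$snp)
  if (length(bad)) stop("purifying loci not in the designated set: ",
                        paste(bad, collapse = ", "))
  n <- nrow(genotypes$dosages)
  with_seed(seed, {
    cult <- sample(c(TRUE, FALSE), n, replace = TRUE,
                   prob = c(prop_cultivar, 1 - prop_cultivar))
    groups <- data.frame(accession = genotypes$accession_ids,
                         group = ifelse(cult, "cultivar", "landrace"),
                         stringsAsFactors = FALSE)
    dos <- genotypes$dosages
    for (i in seq_len(nrow(loci))) {
      snp <- loci$snp[i]
      fav_alt <- loci$favorable[i] != "ref"
      fav <- if (fav_alt) dos[, snp] else 2 - dos[, snp]
      p_land <- mean(fav[!cult]) / 2
      delta <- if (snp %in% purifying) -shift else shift
      target <- p_land + delta
      if (target < 0 || target > 1) {
        warning(sprintf("target favorable frequency %.2f at %s clamped to [0, 1]",
                        target, snp))
        target <- min(max(target, 0), 1)
      }
      new_fav <- rbinom(sum(cult), 2L, target)
      dos[cult, snp] <- if (fav_alt) new_fav else 2L - new_fav
    }
    genotypes$dosages <- dos
    genotypes$snp_meta$maf <- maf_from_dosage_matrix(dos)
    list(groups = groups, genotypes = genotypes)
  })
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper chaining [generate_genotypes()],
#' [generate_expression()] and [generate_phenotypes()]. If `truth` is
#' omitted a default truth set is planted with a handful of cis effects,
#' trans effects, bias offsets and causal phenotype loci.
#'
#' @param config a [cohort_config()].
#' @param truth optional [truth_set()]; default planted via [plant_truth()].
#' @return list with `genotypes`, `expr`, `pairs`, `phenotypes`,
#'   `genetic_values`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), truth = NULL) {
  genotypes <- generate_genotypes(config)
  annotation <- generate_gene_annotation(config)
  if (is.null(truth)) {
    truth <- plant_truth(genotypes, annotation, config)
  }
  ge <- generate_expression(genotypes, truth, config, annotation)
  ph <- generate_phenotypes(genotypes, truth, seed = config$seed + 2L)
  c(list(genotypes = genotypes, expr = ge$expr, pairs = ge$pairs,
         truth = truth, config = config), ph)
}

#' Plant a default truth set into a generated cohort
#'
#' Chooses cis SNPs near gene TSSs and trans SNPs far away, plants log2
#' effects and bias offsets for a subset of pairs, and designates causal
#' phenotype loci with a target heritability.
#'
#' @param genotypes a `genotype_matrix`.
#' @param annotation result of [generate_gene_annotation()].
#' @param config the [cohort_config()].
#' @param n_cis,n_trans,n_bias,n_causal numbers of planted effects.
#' @param beta_cis,beta_trans,bias_offset,causal_effect effect sizes.
#' @param h2 target heritability of the simulated trait.
#' @param trait trait name.
#' @param seed seed for the choices; defaults to `config$seed + 10`.
#' @return a [truth_set()].
#' @export
plant_truth <- function(genotypes, annotation, config,
                        n_cis = 10L, n_trans = 5L, n_bias = 5L, n_causal = 10L,
                        beta_cis = 1, beta_trans = 0.8, bias_offset = 1,
                        causal_effect = 0.5, h2 = 0.5, trait = "FL",
                        seed = config$seed + 10L) {
  gm <- annotation$gene_meta
  sm <- genotypes$snp_meta
  with_seed(seed, {
    pick_near <- function(gene, max_dist = 1e6) {
      g <- gm[gm$gene == gene, ]
      cand <- sm$snp[sm$chrom == g$chrom & abs(sm$pos - g$tss) <= max_dist]
      if (!length(cand)) return(NA_character_)
      sample(cand, 1L)
    }
    pick_far <- function(gene) {
      g <- gm[gm$gene == gene, ]
      cand <- sm$snp[sm$chrom != g$chrom | abs(sm$pos - g$tss) > 1e6]
      sample(cand, 1L)
    }
    cis_genes <- sample(gm$gene, min(n_cis, nrow(gm)))
    cis <- data.frame(snp = vapply(cis_genes, pick_near, ""),
                      gene = cis_genes, beta = beta_cis, timepoints = "all",
                      stringsAsFactors = FALSE)
    cis <- cis[!is.na(cis$snp), , drop = FALSE]
    trans_genes <- sample(gm$gene, min(n_trans, nrow(gm)))
    trans <- data.frame(snp = vapply(trans_genes, pick_far, ""),
                        gene = trans_genes, beta = beta_trans,
                        timepoints = "all", stringsAsFactors = FALSE)
    off_pairs <- sample(annotation$pairs$pair, min(n_bias, nrow(annotation$pairs)))
    offs <- data.frame(pair = off_pairs, timepoint = "all", offset = bias_offset,
                       stringsAsFactors = FALSE)
    causal <- data.frame(snp = sample(sm$snp, min(n_causal, nrow(sm))),
                         trait = trait, effect = causal_effect,
                         favorable = "alt", stringsAsFactors = FALSE)
    truth_set(cis_effects = cis, trans_effects = trans, bias_offsets = offs,
              causal_phenotype_loci = causal,
              target_h2 = stats::setNames(h2, trait))
  })
}
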