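#' Default pipeline configuration
#'
#' All analysis thresholds are named keys with the standard defaults:
#' twofold bias calls on FPKM > 0.1, 5% population fraction, FDR 0.05,
#' +/-1 Mb cis window, 10-kb trans and 20-kb GWAS clump gaps, LD r2 0.6,
#' 100-kb stage-merge and 50-kb network-merge distances, hotspots of more
#' than three genes merged under 20 kb, module filters (heritability >=
#' 0.05, >= 5 genes), 0.6 selection frequency difference.
#'
#' @param dir input directory holding `genotypes.vcf`, `expr_<tp>.tsv`,
#'   `pairs.tsv`, `phenotypes.tsv`, `gene_meta.tsv` (as written by
#'   [write_cohort()]).
#' @param out output directory.
#' @param trait trait column to analyze.
#' @param seed pipeline seed.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(dir, out = file.path(dir, "results"),
                           trait = "FL", seed = 1L) {
  structure(list(
    dir = dir, out = out, trait = trait, seed = as.integer(seed),
    fold = 2, expr_min = 0.1, min_frac = 0.05, fdr = 0.05,
    cis_window = 1e6, n_perm = 200L,
    trans_gap = 1e4, gwas_gap = 2e4, r2_min = 0.6,
    merge_dist_eqtl = 1e5, merge_dist_network = 5e4,
    hotspot_window = 1e5, hotspot_min_genes = 4L, hotspot_merge = 2e4,
    module_min_h2 = 0.05, module_min_genes = 5L,
    selection_diff = 0.6, favorable_freq_diff = 0.2,
    n_geno_pcs = 3L, n_expr_pcs = 5L, maf_min = 0.05,
    coord_min_frac = 0.5
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks file existence, threshold ranges and accession-id consistency
#' across input files. Problems are reported, not raised.
#'
#' @param config a [default_config()] list.
#' @return character vector of problems (empty when clean).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  need <- c("genotypes.vcf", "pairs.tsv", "phenotypes.tsv", "gene_meta.tsv")
  for (f in need) {
    if (!file.exists(file.path(config$dir, f))) note(paste("missing input:", f))
  }
  if (!length(Sys.glob(file.path(config$dir, "expr_*.tsv")))) {
    note("missing input: expr_<timepoint>.tsv files")
  }
  if (config$fold < 1) note("fold < 1")
  if (config$min_frac < 0 || config$min_frac > 1) note("min_frac outside [0, 1]")
  if (config$fdr <= 0 || config$fdr > 1) note("fdr outside (0, 1]")
  if (config$cis_window < 0) note("negative cis window")
  if (!length(problems) &&
      file.exists(file.path(config$dir, "phenotypes.tsv"))) {
    ph <- read_phenotypes(file.path(config$dir, "phenotypes.tsv"))
    vcf_head <- readLines(file.path(config$dir, "genotypes.vcf"), n = 200)
    header <- grep("^#CHROM", vcf_head, value = TRUE)
    if (length(header)) {
      acc <- strsplit(header, "\t")[[1]][-(1:9)]
      extra <- setdiff(ph$accession, acc)
      if (length(extra)) {
        note(paste("accession(s) in phenotypes but not in VCF:",
                   paste(head(extra), collapse = ", ")))
      }
    }
  }
  problems
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Executes the stages in order — bias calling, cis-eQTL, trans-eQTL/GWAS,
#' bias-eQTL, network, coordination, genomic design — on the inputs in
#' `config$dir`, writing per-stage TSVs and a manifest to `config$out`.
#' Deterministic given the config (including its seed). When a stage
#' fails, previously written outputs are retained and the error names the
#' stage.
#'
#' @param config a [default_config()] list (possibly edited).
#' @return invisibly, a named list with the main stage outputs.
#' @export
run_pipeline <- function(config) {
  probs <- validate_config(config)
  if (length(probs)) stop("invalid configuration: ", paste(probs, collapse = "; "))
  stage <- "load"
  # hash ingredients: thresholds and seed, not the run's directory paths
  cfg_hash <- config[setdiff(names(config), c("dir", "out"))]
  result <- tryCatch({
    gene_meta <- utils::read.delim(file.path(config$dir, "gene_meta.tsv"),
                                   stringsAsFactors = FALSE)
    genotypes <- read_vcf(file.path(config$dir, "genotypes.vcf"))
    expr_files <- sort(Sys.glob(file.path(config$dir, "expr_*.tsv")))
    names(expr_files) <- sub("^expr_(.*)\\.tsv$", "\\1", basename(expr_files))
    # restore developmental order by numeric stage prefix when present
    num <- suppressWarnings(as.numeric(sub("^([0-9]+).*", "\\1", names(expr_files))))
    if (!anyNA(num)) expr_files <- expr_files[order(num)]
    expr <- read_expression(expr_files, gene_meta)
    pairs <- read_pairs(file.path(config$dir, "pairs.tsv"))
    phenotypes <- read_phenotypes(file.path(config$dir, "phenotypes.tsv"))
    geno_pcs <- genotype_pcs(genotypes, config$n_geno_pcs)

    stage <- "bias"
    calls <- call_bias_cube(expr, pairs, config$expr_min, config$fold)
    scores <- bias_score_cube(expr, pairs)
    pair_summary <- classify_pair_population(calls, expr, pairs,
                                             config$min_frac, config$fdr)
    class_counts <- temporal_class_counts(calls)
    clusters <- if (nrow(class_counts) >= 3) {
      cluster_pairs_by_class(class_counts, seed = config$seed)
    } else stats::setNames(rep(NA_character_, nrow(class_counts)),
                           rownames(class_counts))
    write_results(list(
      pair_summary = pair_summary,
      temporal_classes = data.frame(pair = rownames(class_counts),
                                    class_counts, cluster = clusters,
                                    row.names = NULL)
    ), config$out, cfg_hash, config$seed)

    stage <- "cis_eqtl"
    mid_tp <- expr$timepoints[ceiling(length(expr$timepoints) / 2)]
    cis <- map_cis_eqtl(expr, mid_tp, genotypes, geno_pcs,
                        window = config$cis_window, n_perm = config$n_perm,
                        fdr = config$fdr, seed = config$seed)
    write_results(list(cis_eqtl = cis), config$out, cfg_hash, config$seed)

    stage <- "gwas"
    gwas <- run_gwas(genotypes, phenotypes, config$trait, geno_pcs,
                     maf_min = config$maf_min, gap = config$gwas_gap,
                     r2_min = config$r2_min)
    write_results(list(gwas_loci = gwas$loci), config$out, cfg_hash, config$seed)

    stage <- "bias_eqtl"
    bias_eqtl <- scan_bias_eqtl(scores, calls, genotypes, geno_pcs, pairs,
                                min_frac = config$min_frac,
                                gap = config$trans_gap,
                                r2_min = config$r2_min,
                                max_dist = config$merge_dist_eqtl)
    write_results(list(bias_eqtl_loci = bias_eqtl$loci), config$out, cfg_hash,
                  config$seed)

    stage <- "coordination"
    candidates <- flag_candidates(expr, phenotypes, config$trait,
                                  cis_results = cis, gwas_loci = gwas$loci,
                                  fdr = config$fdr)
    coordination <- NULL
    if (!is.null(candidates) && nrow(candidates) &&
        any(!is.na(candidates$variant))) {
      states <- pair_state_cube(candidates, pairs, expr, genotypes,
                                fold = config$fold)
      if (dim(states)[1] > 0) {
        coordination <- summarize_pair_states(states, config$coord_min_frac)
        write_results(list(
          coordination_pairs = coordination$pair_summary,
          accession_state_counts = data.frame(
            accession = rownames(coordination$accession_counts),
            coordination$accession_counts, row.names = NULL)
        ), config$out, cfg_hash, config$seed)
      }
    }

    stage <- "network"
    network <- NULL; modules <- NULL
    sig_cis <- cis[cis$significant, , drop = FALSE]
    cand_genes <- if (!is.null(candidates) && nrow(candidates)) {
      candidates$gene
    } else character(0)
    if (nrow(sig_cis) && length(intersect(cand_genes, sig_cis$gene))) {
      eqtl_nodes <- data.frame(locus = paste0("E_", sig_cis$gene),
                               chrom = genotypes$snp_meta$chrom[
                                 match(sig_cis$lead_snp, genotypes$snp_meta$snp)],
                               start = NA, end = NA,
                               lead_snp = sig_cis$lead_snp,
                               target = sig_cis$gene, stages = mid_tp,
                               stringsAsFactors = FALSE)
      network <- build_network(eqtl_nodes, hotspots = NULL,
                               candidates = cand_genes, genotypes = genotypes)
      modules <- detect_modules(network, seed = config$seed)
      write_results(list(modules = data.frame(
        node = names(modules$membership),
        module = as.integer(modules$membership), row.names = NULL)),
        config$out, config, config$seed)
    }

    stage <- "design"
    design <- NULL
    if (nrow(gwas$loci)) {
      beta <- gwas$records$beta[match(gwas$loci$lead_snp, gwas$records$snp)]
      lib_in <- data.frame(lead_snp = gwas$loci$lead_snp, beta = beta,
                           trait = config$trait, stringsAsFactors = FALSE)
      groups_path <- file.path(config$dir, "groups.tsv")
      groups <- if (file.exists(groups_path)) {
        utils::read.delim(groups_path, stringsAsFactors = FALSE)
      } else {
        data.frame(accession = genotypes$accession_ids, group = "cultivar",
                   stringsAsFactors = FALSE)
      }
      lib <- build_allele_library(lib_in, genotypes, groups)
      lib$category <- categorize_c1_c4(lib)
      lib$selection <- classify_selection(lib, config$selection_diff)
      X <- favorable_dosage_matrix(genotypes, lib)
      y <- phenotypes[[config$trait]][match(genotypes$accession_ids,
                                            phenotypes$accession)]
      model <- fit_ridge(X, y, seed = config$seed)
      bv <- best_value(model, X)
      design <- list(library = lib, model = model, best = bv)
      write_results(list(
        allele_library = as.data.frame(lib),
        breeding_values = data.frame(accession = genotypes$accession_ids,
                                     bv = bv$bv, distance = bv$distance)
      ), config$out, cfg_hash, config$seed)
    }
    list(pair_summary = pair_summary, clusters = clusters, cis = cis,
         gwas = gwas, bias_eqtl = bias_eqtl, candidates = candidates,
         coordination = coordination, network = network, modules = modules,
         design = design)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
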