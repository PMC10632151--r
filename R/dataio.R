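#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.x with GT genotypes (via the vcfR package) into an
#' accessions x SNPs dosage matrix: `0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./. -> NA`. Phased separators (`|`) are accepted.
#' Multiallelic records are rejected. MAF is recomputed over non-missing
#' dosages.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a `genotype_matrix` (see [generate_genotypes()]).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multiallelic records present; split or filter them upstream")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    bad <- !is.na(g) & is.na(out) & g != "./."
    if (any(bad)) stop("unparseable GT value(s): ",
                       paste(unique(g[bad]), collapse = ", "))
    out
  }
  dosages <- t(matrix(code(as.vector(gt)), nrow = nrow(gt)))  # accessions x SNPs
  rownames(dosages) <- colnames(gt)
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID)
  colnames(dosages) <- snp_id
  meta <- data.frame(snp = snp_id, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  for (ch in unique(meta$chrom)) {
    p <- meta$pos[meta$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  meta$maf <- maf_from_dosage_matrix(dosages)
  rownames(meta) <- NULL
  structure(list(dosages = dosages, snp_meta = meta,
                 accession_ids = rownames(dosages)),
            class = "genotype_matrix")
}

#' Write a genotype matrix as VCF v4.2 (GT field only)
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  meta <- genotypes$snp_meta
  dos <- genotypes$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=polybias",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$accession_ids),
                     collapse = "\t")), con)
  gt <- matrix("./.", nrow = nrow(meta), ncol = nrow(dos))
  idx <- !is.na(t(dos))
  gt[idx] <- gt_code[t(dos)[idx] + 1L]
  lines <- paste(meta$chrom, meta$pos, meta$snp, meta$ref, meta$alt, ".",
                 "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read per-timepoint expression matrices into a cube
#'
#' Expects one TSV per timepoint (rows = genes, first column `gene`,
#' remaining columns = accessions). Gene sets must agree across timepoints;
#' accessions absent at a timepoint are recorded as missing slices (NA),
#' never as zero.
#'
#' @param files named character vector of paths; names are the stage labels
#'   in developmental order.
#' @param gene_meta data.frame with columns `gene`, `chrom`, `tss`,
#'   `strand`, `subgenome`.
#' @return an `expression_cube`.
#' @export
read_expression <- function(files, gene_meta) {
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("`files` must be named by timepoint")
  }
  mats <- lapply(files, function(f) {
    d <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE)) stop("negative expression value in ", f)
    m
  })
  genes <- rownames(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    if (!setequal(rownames(mats[[i]]), genes)) {
      d1 <- setdiff(genes, rownames(mats[[i]]))
      d2 <- setdiff(rownames(mats[[i]]), genes)
      stop("gene sets differ across timepoints; symmetric difference: ",
           paste(c(d1, d2), collapse = ", "))
    }
  }
  accs <- sort(unique(unlist(lapply(mats, colnames))))
  tps <- names(files)
  cube <- array(NA_real_, dim = c(length(genes), length(accs), length(tps)),
                dimnames = list(genes, accs, tps))
  for (t in seq_along(mats)) {
    m <- mats[[t]][genes, , drop = FALSE]
    cube[, colnames(m), t] <- m
  }
  missing_genes <- setdiff(genes, gene_meta$gene)
  if (length(missing_genes)) {
    stop("genes without annotation: ", paste(head(missing_genes), collapse = ", "))
  }
  gm <- gene_meta[match(genes, gene_meta$gene), , drop = FALSE]
  rownames(gm) <- NULL
  structure(list(values = cube, gene_meta = gm, timepoints = tps),
            class = "expression_cube")
}

#' Write an expression cube as one TSV per timepoint
#'
#' @param expr an `expression_cube`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; files are `<prefix><timepoint>.tsv`.
#' @return named vector of written paths, invisibly.
#' @export
write_expression <- function(expr, dir, prefix = "expr_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in seq_along(expr$timepoints)) {
    tp <- expr$timepoints[t]
    m <- expr$values[, , t, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(expr$values)[1],
                                     dimnames = dimnames(expr$values)[1:2])
    keep <- colSums(is.na(m)) < nrow(m)  # drop all-missing accession slices
    d <- data.frame(gene = rownames(m), m[, keep, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(prefix, tp, ".tsv"))
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[tp] <- p
  }
  invisible(paths)
}

#' Read/write small pipeline tables
#'
#' `read_pairs()` expects columns `pair`, `gene_At`, `gene_Dt` (a missing
#' `pair` column is synthesized); each gene may appear in at most one pair.
#' `read_phenotypes()` expects an `accession` column plus one numeric
#' column per trait.
#'
#' @param path a TSV path.
#' @return data.frame.
#' @export
read_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_At", "gene_Dt") %in% names(d))) {
    stop("pair map must have columns gene_At and gene_Dt")
  }
  if (!"pair" %in% names(d)) d$pair <- sprintf("P%03d", seq_len(nrow(d)))
  g <- c(d$gene_At, d$gene_Dt)
  if (anyDuplicated(g)) {
    stop("gene(s) appear in more than one pair: ",
         paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  d[, c("pair", "gene_At", "gene_Dt")]
}

#' @rdname read_pairs
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"accession" %in% names(d)) stop("phenotype table needs an accession column")
  d
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each table as a TSV with stable column order, plus a
#' `manifest.json` containing a content hash of the tables and the
#' configuration, the seed, and the package version. Re-running with
#' identical inputs yields an identical manifest hash. Empty tables are
#' written as header-only files.
#'
#' @param tables named list of data.frames.
#' @param dir output directory.
#' @param config optional configuration list folded into the hash.
#' @param seed optional seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(tables, dir, config = list(), seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    hash = rlang::hash(list(tables = tables, config = config)),
    seed = seed,
    tables = names(tables),
    package_version = as.character(utils::packageVersion("polybias"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a full synthetic cohort to disk
#'
#' Emits the VCF, per-timepoint expression TSVs, phenotype TSV, pair map
#' and truth-set JSON for a [simulate_cohort()] result.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_expression(cohort$expr, dir)
  utils::write.table(cohort$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$expr$gene_meta, file.path(dir, "gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
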