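#' Build the favorable-allele library
#'
#' For each trait-associated locus, the favorable allele is the one whose
#' dosage increase moves the trait in the beneficial direction (effect
#' sign x trait polarity). Favorable-allele frequencies are computed per
#' population group; the sharing ratio is the favorable-allele frequency
#' among cultivars.
#'
#' @param loci data.frame with columns `lead_snp`, `beta` (effect of the
#'   alt allele per dosage) and optionally `trait`.
#' @param genotypes a `genotype_matrix`.
#' @param groups data.frame `accession`, `group` with groups `landrace`
#'   and `cultivar`.
#' @param higher_is_better trait polarity (default TRUE).
#' @return data.frame of class `allele_library`: `lead_snp`, `trait`,
#'   `effect`, `favorable`, `freq_landrace`, `freq_cultivar`,
#'   `sharing_ratio`. Zero-effect loci are excluded (attribute
#'   `excluded`).
#' @export
build_allele_library <- function(loci, genotypes, groups,
                                 higher_is_better = TRUE) {
  excluded <- loci$lead_snp[loci$beta == 0]
  loci <- loci[loci$beta != 0, , drop = FALSE]
  if (!nrow(loci)) stop("no locus with nonzero effect")
  sign_good <- if (higher_is_better) 1 else -1
  grp <- groups$group[match(genotypes$accession_ids, groups$accession)]
  fav_freq <- function(snp, favorable, sel) {
    d <- genotypes$dosages[sel, snp]
    f <- mean(d, na.rm = TRUE) / 2
    if (favorable == "ref") 1 - f else f
  }
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    fav <- if (sign(loci$beta[i]) == sign_good) "alt" else "ref"
    data.frame(
      lead_snp = loci$lead_snp[i],
      trait = loci$trait[i] %||% NA_character_,
      effect = abs(loci$beta[i]),
      favorable = fav,
      freq_landrace = fav_freq(loci$lead_snp[i], fav, grp == "landrace"),
      freq_cultivar = fav_freq(loci$lead_snp[i], fav, grp == "cultivar"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sharing_ratio <- out$freq_cultivar
  attr(out, "excluded") <- excluded
  class(out) <- c("allele_library", class(out))
  out
}

#' Bin loci into sharing-ratio categories C1-C4
#'
#' C1: \[0, 0.25), C2: \[0.25, 0.5), C3: \[0.5, 0.75), C4: \[0.75, 1\] by
#' default — from C1 to C4 the utilization of the favorable allele in
#' modern cultivars increases.
#'
#' @param sharing_ratio numeric vector in \[0, 1\] (or an `allele_library`).
#' @param edges interior bin edges (default `c(0.25, 0.5, 0.75)`).
#' @return character vector of categories `"C1"`..`"C4"`.
#' @export
categorize_c1_c4 <- function(sharing_ratio, edges = c(0.25, 0.5, 0.75)) {
  if (inherits(sharing_ratio, "allele_library")) {
    sharing_ratio <- sharing_ratio$sharing_ratio
  }
  if (any(sharing_ratio < 0 | sharing_ratio > 1, na.rm = TRUE)) {
    stop("sharing ratios must lie in [0, 1]")
  }
  idx <- findInterval(sharing_ratio, edges) + 1L
  paste0("C", idx)
}

#' Classify selection status of favorable alleles
#'
#' A locus is `favorable_selected` when the favorable-allele frequency in
#' cultivars exceeds the landrace frequency by more than `diff_min`
#' (strict), `purifying` when the landrace frequency exceeds the cultivar
#' frequency by more than `diff_min`, otherwise `neutral`.
#'
#' @param library an `allele_library` (or data.frame with `freq_cultivar`,
#'   `freq_landrace`).
#' @param diff_min frequency-difference threshold (default 0.6, strict >).
#' @return character vector of statuses (NA when either frequency is
#'   missing).
#' @export
classify_selection <- function(library, diff_min = 0.6) {
  d <- library$freq_cultivar - library$freq_landrace
  out <- rep("neutral", length(d))
  out[!is.na(d) & d > diff_min] <- "favorable_selected"
  out[!is.na(d) & -d > diff_min] <- "purifying"
  out[is.na(d)] <- NA_character_
  out
}

#' Favorable-allele dosage features
#'
#' Recodes dosages so each column counts copies of the favorable allele at
#' a library locus (0, 1 or 2).
#'
#' @param genotypes a `genotype_matrix`.
#' @param library an `allele_library`.
#' @return numeric matrix accessions x loci.
#' @export
favorable_dosage_matrix <- function(genotypes, library) {
  X <- genotypes$dosages[, library$lead_snp, drop = FALSE]
  flip <- library$favorable == "ref"
  X[, flip] <- 2 - X[, flip]
  X
}

#' Fit a ridge-regression genomic prediction model
#'
#' Closed-form L2-penalized linear regression of the phenotype on
#' favorable-allele dosage features (0/1/2), with the penalty chosen by
#' k-fold cross-validation to minimize mean squared error and the final
#' model refit on all data at the selected penalty. The intercept is
#' unpenalized (features and response are centered internally).
#'
#' @param X feature matrix accessions x features (dosage-coded loci,
#'   optionally expression-augmented via [augment_with_expression()]).
#' @param y phenotype vector.
#' @param lambda penalty grid; default a log-spaced grid.
#' @param k CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param engine `"closed_form"` (default) or `"glmnet"` (pass-through to
#'   `glmnet::cv.glmnet`, with `alpha` selecting the elastic-net mixing).
#' @param alpha elastic-net mixing for the glmnet engine (0 = ridge).
#' @return object of class `ridge_model`: `intercept`, `coef` (named),
#'   `lambda`, `cv` (lambda x mean CV MSE), `feature_names`,
#'   `feature_means`.
#' @export
fit_ridge <- function(X, y, lambda = NULL, k = 5L, seed = 1L,
                      engine = c("closed_form", "glmnet"), alpha = 0) {
  engine <- match.arg(engine)
  X <- as.matrix(X)
  ok <- !is.na(y) & rowSums(is.na(X)) == 0
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X)
  if (n < k) stop("need at least k observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (engine == "glmnet") {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("the glmnet engine requires the glmnet package")
    }
    fit <- with_seed(seed, glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = k))
    cf <- as.numeric(coef(fit, s = "lambda.min"))
    return(structure(list(intercept = cf[1],
                          coef = stats::setNames(cf[-1], colnames(X)),
                          lambda = fit$lambda.min,
                          cv = data.frame(lambda = fit$lambda, mse = fit$cvm),
                          feature_names = colnames(X),
                          feature_means = colMeans(X)),
                     class = "ridge_model"))
  }
  if (is.null(lambda)) lambda <- 10^seq(-2, 5, length.out = 40)
  if (!length(lambda)) stop("empty lambda grid")
  ridge_solve <- function(Xtr, ytr, lam) {
    xm <- colMeans(Xtr); ym <- mean(ytr)
    Xc <- sweep(Xtr, 2, xm); yc <- ytr - ym
    p <- ncol(Xc)
    b <- if (nrow(Xc) >= p) {
      solve(crossprod(Xc) + diag(lam, p), crossprod(Xc, yc))
    } else {
      # dual form for p > n
      K <- tcrossprod(Xc)
      a <- solve(K + diag(lam, nrow(Xc)), yc)
      crossprod(Xc, a)
    }
    list(coef = as.numeric(b), intercept = ym - sum(xm * b))
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  # per fold, factor the Gram matrix once and reuse it across the lambda grid
  cv_err <- matrix(NA_real_, nrow = k, ncol = length(lambda))
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    xm <- colMeans(Xtr); ym <- mean(ytr)
    Xc <- sweep(Xtr, 2, xm); yc <- ytr - ym
    dual <- nrow(Xc) < ncol(Xc)
    G <- if (dual) tcrossprod(Xc) else crossprod(Xc)
    ev <- eigen(G, symmetric = TRUE)
    rot <- if (dual) crossprod(ev$vectors, yc) else
      crossprod(ev$vectors, crossprod(Xc, yc))
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    for (li in seq_along(lambda)) {
      w <- rot / (ev$values + lambda[li])
      b <- if (dual) crossprod(Xc, ev$vectors %*% w) else ev$vectors %*% w
      pred <- (ym - sum(xm * b)) + Xte %*% b
      cv_err[f, li] <- mean((yte - pred)^2)
    }
  }
  cv_mse <- colMeans(cv_err)
  lam_star <- lambda[which.min(cv_mse)]
  m <- ridge_solve(X, y, lam_star)
  structure(list(intercept = m$intercept,
                 coef = stats::setNames(m$coef, colnames(X)),
                 lambda = lam_star,
                 cv = data.frame(lambda = lambda, mse = cv_mse),
                 feature_names = colnames(X),
                 feature_means = colMeans(X)),
            class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d features, lambda = %.4g\n",
              length(x$coef), x$lambda))
  invisible(x)
}

#' Predict breeding values
#'
#' Linear prediction `intercept + x . coef`; missing features are
#' mean-imputed with the training means (flagged via attribute
#' `imputed`).
#'
#' @param model a `ridge_model`.
#' @param X feature matrix with the model's feature columns.
#' @return numeric vector of breeding values.
#' @export
predict_bv <- function(model, X) {
  X <- as.matrix(X)
  if (!all(model$feature_names %in% colnames(X))) {
    stop("feature mismatch: missing ",
         paste(setdiff(model$feature_names, colnames(X)), collapse = ", "))
  }
  X <- X[, model$feature_names, drop = FALSE]
  imputed <- anyNA(X)
  if (imputed) {
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- model$feature_means[j]
    }
  }
  bv <- as.numeric(model$intercept + X %*% model$coef)
  attr(bv, "imputed") <- imputed
  bv
}

#' Append trait-correlated homoeolog expression features
#'
#' Tests, per homoeolog gene and timepoint, the correlation of (log2)
#' expression with the trait; genes passing Benjamini-Hochberg q < `fdr`
#' at one or more timepoints contribute standardized expression features
#' at their qualifying timepoints. With no qualifying gene the feature
#' matrix is returned unchanged (attribute `n_added` = 0).
#'
#' @param X genotype feature matrix (accessions x loci), rownames =
#'   accession ids.
#' @param expr an `expression_cube`.
#' @param genes homoeolog gene ids to consider.
#' @param phenotypes data.frame with `accession` + trait column.
#' @param trait trait name.
#' @param fdr correlation threshold (default 0.05).
#' @return augmented feature matrix with attribute `n_added`.
#' @export
augment_with_expression <- function(X, expr, genes, phenotypes, trait,
                                    fdr = 0.05) {
  acc <- rownames(X)
  y <- phenotypes[[trait]][match(acc, phenotypes$accession)]
  tests <- list()
  for (g in intersect(genes, rownames(expr$values))) {
    for (t in seq_along(expr$timepoints)) {
      x <- log2(expr$values[g, acc, t] + 1)
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 10 || sd(x[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok])
      tests[[length(tests) + 1L]] <- data.frame(
        gene = g, timepoint = expr$timepoints[t], t_idx = t,
        cor = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(tests)) {
    attr(X, "n_added") <- 0L
    return(X)
  }
  tab <- do.call(rbind, tests)
  tab$q <- p.adjust(tab$p, "BH")
  sel <- tab[tab$q < fdr, , drop = FALSE]
  if (!nrow(sel)) {
    attr(X, "n_added") <- 0L
    return(X)
  }
  feats <- sapply(seq_len(nrow(sel)), function(i) {
    as.numeric(scale(log2(expr$values[sel$gene[i], acc, sel$t_idx[i]] + 1)))
  })
  colnames(feats) <- sprintf("expr_%s_%s", sel$gene, sel$timepoint)
  out <- cbind(X, feats)
  attr(out, "n_added") <- nrow(sel)
  out
}

#' Predicted best breeding value and per-accession distances
#'
#' The best value is the breeding value of the ideal genotype: per locus,
#' the favorable dosage in `{0, 1, 2}` maximizing `coefficient x dosage`.
#' Distances are `best - BV_i` and are always nonnegative.
#'
#' @param model a `ridge_model` fit on genotype features only.
#' @param X the genotype feature matrix used for the accessions.
#' @return list with `best_bv`, `bv` (per accession) and `distance`.
#' @export
best_value <- function(model, X) {
  best_bv <- model$intercept + sum(pmax(model$coef * 2, 0))
  bv <- predict_bv(model, X)
  list(best_bv = best_bv, bv = bv, distance = best_bv - bv)
}

#' Donor-parent improvement matrix
#'
#' For every (target, donor) accession pair, an improvable locus is one
#' where the donor carries more favorable-allele copies than the target.
#' The matrix records the improvable-locus count, the breeding-value gain
#' `dBV = sum coefficient x (dosage_donor - dosage_target)` over
#' improvable loci, and the percent gain relative to the target's current
#' breeding value.
#'
#' @param X favorable-dosage feature matrix (accessions x loci), rownames
#'   = accession ids.
#' @param model a `ridge_model` fit on those features.
#' @param accessions optional subset of accession ids (default all rows).
#' @return list of matrices `count`, `dbv`, `pct` (targets x donors;
#'   diagonals zero) plus `bv`.
#' @export
improvement_matrix <- function(X, model, accessions = NULL) {
  if (is.null(accessions)) accessions <- rownames(X)
  X <- X[accessions, model$feature_names, drop = FALSE]
  bv <- predict_bv(model, X)
  names(bv) <- accessions
  n <- length(accessions)
  count <- dbv <- pct <- matrix(0, n, n, dimnames = list(accessions, accessions))
  for (t in seq_len(n)) for (d in seq_len(n)) {
    if (t == d) next
    imp <- X[d, ] > X[t, ]
    count[t, d] <- sum(imp)
    dbv[t, d] <- sum(model$coef[imp] * (X[d, imp] - X[t, imp]))
    pct[t, d] <- if (bv[t] != 0) 100 * dbv[t, d] / bv[t] else NA_real_
  }
  list(count = count, dbv = dbv, pct = pct, bv = bv)
}
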