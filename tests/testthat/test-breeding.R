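mk_groups <- function(acc, n_land = floor(length(acc) / 2)) {
  data.frame(accession = acc,
             group = c(rep("landrace", n_land),
                       rep("cultivar", length(acc) - n_land)),
             stringsAsFactors = FALSE)
}

test_that("favorable alleles follow the effect-sign x polarity rule", {
  dos <- cbind(s1 = c(0, 1, 2, 2), s2 = c(2, 2, 2, 2), s3 = c(0, 0, 1, 2))
  g <- make_genotype_matrix(dos)
  groups <- mk_groups(g$accession_ids, 2)
  loci <- data.frame(lead_snp = g$snp_meta$snp, beta = c(0.5, 0.2, -0.5),
                     trait = "FL", stringsAsFactors = FALSE)
  lib <- build_allele_library(loci, g, groups)
  expect_equal(lib$favorable, c("alt", "alt", "ref"))
  # all cultivars homozygous favorable at s2 -> sharing ratio 1
  expect_equal(lib$sharing_ratio[2], 1)
  # s3 favorable = ref; cultivar dosages (1, 2) -> ref freq (1 + 0)/4... = 0.25
  expect_equal(lib$freq_cultivar[3], 1 - 3 / 4)
  # lower-is-better flips the rule
  lib2 <- build_allele_library(loci, g, groups, higher_is_better = FALSE)
  expect_equal(lib2$favorable, c("ref", "ref", "alt"))
  expect_error(build_allele_library(data.frame(lead_snp = "x", beta = 0),
                                    g, groups), "nonzero")
})

test_that("C1-C4 binning and selection classes follow their frequency rules", {
  expect_equal(categorize_c1_c4(c(0.1, 0.74, 0.75, 0, 1, 0.25, 0.5)),
               c("C1", "C3", "C4", "C1", "C4", "C2", "C3"))
  # monotone in the sharing ratio
  grid <- seq(0, 1, by = 0.01)
  cats <- as.integer(sub("C", "", categorize_c1_c4(grid)))
  expect_true(all(diff(cats) >= 0))
  expect_error(categorize_c1_c4(1.2), "0, 1")

  lib <- data.frame(freq_cultivar = c(0.9, 0.2, 0.5, 0.7),
                    freq_landrace = c(0.2, 0.9, 0.5, 0.2))
  expect_equal(classify_selection(lib),
               c("favorable_selected", "purifying", "neutral", "neutral"))
  # |difference| = 0.6 exactly stays neutral (strict >)
  lib2 <- data.frame(freq_cultivar = c(0.6, 0), freq_landrace = c(0, 0.6))
  expect_equal(classify_selection(lib2), c("neutral", "neutral"))
})

test_that("ridge limits: OLS at lambda -> 0, the mean at lambda -> Inf", {
  set.seed(51)
  n <- 80
  X <- cbind(a = rbinom(n, 2, 0.4), b = rbinom(n, 2, 0.3),
             c = rbinom(n, 2, 0.2))
  y <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.5)
  m0 <- fit_ridge(X, y, lambda = 1e-8)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(m0$coef), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(m0$intercept, unname(ols[1]), tolerance = 1e-6)
  mInf <- fit_ridge(X, y, lambda = 1e12)
  expect_true(all(abs(mInf$coef) < 1e-6))
  expect_equal(unique(round(predict_bv(mInf, X), 6)), round(mean(y), 6))
  expect_error(fit_ridge(X, y, lambda = numeric(0)), "empty")
})

test_that("closed-form ridge agrees with glmnet at matched penalty", {
  set.seed(52)
  n <- 200; p <- 10
  X <- matrix(rbinom(n * p, 2, 0.3), n)
  colnames(X) <- paste0("s", 1:p)
  y <- X %*% rnorm(p, 0, 0.3) + rnorm(n)
  lam <- 2
  m <- fit_ridge(X, y, lambda = lam)
  # glmnet ridge: objective (1/2n)||y - Xb||^2 + lambda/2 ||b||^2 with
  # internal standardization off -> its lambda equals ours / n
  gfit <- glmnet::glmnet(X, y, alpha = 0, lambda = lam / n,
                         standardize = FALSE, thresh = 1e-12)
  # glmnet converges by coordinate descent; agreement to ~1% is its accuracy
  expect_equal(unname(m$coef), as.numeric(coef(gfit))[-1], tolerance = 0.02)
})

test_that("prediction handles imputation, optimism and the null", {
  set.seed(53)
  n <- 300; p <- 40
  X <- matrix(rbinom(n * p, 2, 0.3), n)
  colnames(X) <- paste0("s", 1:p)
  y <- as.numeric(X %*% rnorm(p, 0, 0.2) + rnorm(n))
  tr <- 1:200; te <- 201:300
  m <- fit_ridge(X[tr, ], y[tr])
  r_in <- cor(predict_bv(m, X[tr, ]), y[tr])
  r_out <- cor(predict_bv(m, X[te, ]), y[te])
  expect_gte(r_in, r_out)
  # all-zero features -> the intercept
  expect_equal(unique(predict_bv(m, matrix(0, 2, p,
                                           dimnames = list(NULL, colnames(X))))),
               m$intercept)
  # permuted phenotype: held-out correlation near zero
  m0 <- fit_ridge(X[tr, ], sample(y[tr]))
  expect_lt(abs(cor(predict_bv(m0, X[te, ]), y[te])), 0.25)
  # missing dosages are mean-imputed and flagged
  Xm <- X[te, ]; Xm[1, 1] <- NA
  bv <- predict_bv(m, Xm)
  expect_true(attr(bv, "imputed"))
  expect_false(anyNA(bv))
  expect_error(predict_bv(m, X[, 1:10]), "feature mismatch")
})

test_that("expression augmentation appends only trait-correlated features", {
  set.seed(54)
  n <- 150
  acc <- sprintf("S%03d", 1:n)
  X <- matrix(rbinom(n * 5, 2, 0.3), n, dimnames = list(acc, paste0("s", 1:5)))
  v <- array(2^rnorm(3 * n * 2, 4, 1) - 1, dim = c(3, n, 2),
             dimnames = list(paste0("g", 1:3), acc, c("t1", "t2")))
  e <- make_expression_cube(v)
  ph <- data.frame(accession = acc,
                   FL = log2(v["g1", , 1] + 1) + rnorm(n, 0, 0.3))
  X2 <- augment_with_expression(X, e, paste0("g", 1:3), ph, "FL")
  expect_gt(attr(X2, "n_added"), 0)
  expect_true(any(grepl("^expr_g1", colnames(X2))))
  expect_false(any(grepl("^expr_g2_|^expr_g3_", colnames(X2))))
  # no qualifying gene: unchanged matrix
  ph0 <- data.frame(accession = acc, FL = rnorm(n))
  X0 <- augment_with_expression(X, e, paste0("g", 1:3), ph0, "FL")
  expect_equal(attr(X0, "n_added"), 0)
  expect_identical(dim(X0), dim(X))
})

test_that("the best value upper-bounds every realizable breeding value", {
  set.seed(55)
  n <- 100; p <- 12
  X <- matrix(rbinom(n * p, 2, 0.4), n, dimnames = list(NULL, paste0("s", 1:p)))
  y <- as.numeric(X %*% rnorm(p) + rnorm(n))
  m <- fit_ridge(X, y)
  bv <- best_value(m, X)
  expect_true(all(bv$distance >= -1e-10))
  # random search never beats the closed-form optimum
  rand_bv <- replicate(500, {
    x <- sample(0:2, p, replace = TRUE)
    m$intercept + sum(m$coef * x)
  })
  expect_lte(max(rand_bv), bv$best_bv + 1e-10)
  # an accession carrying the best configuration sits at distance zero
  xbest <- ifelse(m$coef > 0, 2, 0)
  Xb <- rbind(X, best = xbest)
  bv2 <- best_value(m, Xb)
  expect_equal(unname(bv2$distance[n + 1]), 0, tolerance = 1e-10)
})

test_that("improvement matrix counts donor-over-target favorable dosages", {
  # single-locus toy: target 0, donor 2, coefficient 0.3 -> dBV 0.6
  X <- matrix(c(0, 2), 2, 1, dimnames = list(c("tgt", "don"), "s1"))
  m <- structure(list(intercept = 1, coef = c(s1 = 0.3), lambda = 1,
                      cv = NULL, feature_names = "s1",
                      feature_means = c(s1 = 1)), class = "ridge_model")
  im <- improvement_matrix(X, m)
  expect_equal(unname(diag(im$count)), c(0, 0))
  expect_equal(unname(im$count["tgt", "don"]), 1)
  expect_equal(unname(im$dbv["tgt", "don"]), 0.6)
  expect_equal(unname(im$dbv["don", "tgt"]), 0)
  expect_equal(unname(im$pct["tgt", "don"]), 100 * 0.6 / 1)
  # with all-positive coefficients, gains are nonnegative everywhere
  set.seed(56)
  X2 <- matrix(rbinom(60, 2, 0.5), 6, 10,
               dimnames = list(paste0("a", 1:6), paste0("s", 1:10)))
  m2 <- structure(list(intercept = 0, coef = stats::setNames(runif(10, 0.1, 1),
                                                             paste0("s", 1:10)),
                       lambda = 1, cv = NULL,
                       feature_names = paste0("s", 1:10),
                       feature_means = colMeans(X2)), class = "ridge_model")
  im2 <- improvement_matrix(X2, m2)
  expect_true(all(im2$dbv >= 0))
  expect_true(all(im2$count >= 0))
})
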