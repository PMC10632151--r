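#' Homoeolog expression-bias score
#'
#' The bias score of a homoeolog pair is `(At - Dt) / (At + Dt)`, a bounded
#' statistic in \[-1, 1\] of expression imbalance between the At and Dt
#' subgenome copies. It is undefined (NA) when both copies are zero.
#'
#' @param at,dt nonnegative expression values (vectors recycle).
#' @return numeric vector of scores in \[-1, 1\], NA where `at + dt == 0`.
#' @export
#' @examples
#' bias_score(4, 1)   #  0.6
#' bias_score(1, 4)   # -0.6
#' bias_score(0, 0)   #  NA
bias_score <- function(at, dt) {
  if (any(at < 0, na.rm = TRUE) || any(dt < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative")
  }
  s <- (at - dt) / (at + dt)
  s[!is.na(at + dt) & (at + dt) == 0] <- NA_real_
  s
}

#' Per-accession homoeolog bias call
#'
#' A pair is callable when at least one member is expressed
#' (`max(at, dt) > expr_min`); it is called biased toward a subgenome when
#' that member's expression is at least `fold` times the other's (a zero
#' denominator counts as infinite fold change).
#'
#' @param at,dt nonnegative expression values.
#' @param expr_min minimum expression for a pair to count as expressed
#'   (FPKM-like units).
#' @param fold minimum fold change (>= 1) to call bias.
#' @return character vector in `{"BiasA", "BiasD", "none", "not_expressed"}`
#'   (NA propagates from missing input).
#' @export
call_accession_bias <- function(at, dt, expr_min = 0.1, fold = 2) {
  if (fold < 1) stop("`fold` must be >= 1")
  if (any(at < 0, na.rm = TRUE) || any(dt < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative")
  }
  n <- max(length(at), length(dt))
  at <- rep_len(at, n); dt <- rep_len(dt, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(at) & !is.na(dt)
  out[ok] <- "none"
  out[ok & pmax(at, dt) <= expr_min] <- "not_expressed"
  expressed <- ok & pmax(at, dt) > expr_min
  out[expressed & at >= fold * dt] <- "BiasA"
  out[expressed & dt >= fold * at] <- "BiasD"
  out
}

#' Bias scores for all pairs in an expression cube
#'
#' @param expr an `expression_cube`.
#' @param pairs data.frame with `pair`, `gene_At`, `gene_Dt`.
#' @return numeric array pairs x accessions x timepoints of bias scores.
#' @export
bias_score_cube <- function(expr, pairs) {
  at <- expr$values[pairs$gene_At, , , drop = FALSE]
  dt <- expr$values[pairs$gene_Dt, , , drop = FALSE]
  s <- bias_score(at, dt)
  dimnames(s)[[1]] <- pairs$pair
  s
}

#' Per-accession bias calls for all pairs in an expression cube
#'
#' @inheritParams bias_score_cube
#' @inheritParams call_accession_bias
#' @return character array pairs x accessions x timepoints of calls.
#' @export
call_bias_cube <- function(expr, pairs, expr_min = 0.1, fold = 2) {
  at <- expr$values[pairs$gene_At, , , drop = FALSE]
  dt <- expr$values[pairs$gene_Dt, , , drop = FALSE]
  calls <- array(call_accession_bias(as.vector(at), as.vector(dt),
                                     expr_min = expr_min, fold = fold),
                 dim = dim(at),
                 dimnames = c(list(pairs$pair), dimnames(at)[2:3]))
  calls
}

#' Population-level bias labels per pair and timepoint
#'
#' A pair is labeled biased toward a subgenome at a timepoint when at least
#' `min_frac` of accessions carry that per-accession bias call, the paired
#' two-sided Wilcoxon signed-rank test of At versus Dt expression across
#' accessions survives Benjamini-Hochberg correction at `fdr`, and the
#' opposite direction does not also reach `min_frac`; pairs with both
#' directions above `min_frac` are `bidirectional`; everything else is
#' `BiasN`. The fraction-only label (without the FDR condition) is also
#' emitted as `label_raw`.
#'
#' @param calls result of [call_bias_cube()].
#' @param expr the `expression_cube` the calls came from.
#' @param pairs the pair map.
#' @param min_frac minimum fraction of biased accessions (default 5%).
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @return data.frame with one row per pair x timepoint: fractions of
#'   BiasA/BiasD accessions, Wilcoxon q, `label` and `label_raw`.
#' @export
classify_pair_population <- function(calls, expr, pairs,
                                     min_frac = 0.05, fdr = 0.05) {
  tps <- dimnames(calls)[[3]]
  out <- list()
  for (t in seq_along(tps)) {
    ct <- calls[, , t, drop = FALSE]
    n_obs <- rowSums(!is.na(ct[, , 1, drop = FALSE]))
    frac_a <- rowSums(ct[, , 1, drop = FALSE] == "BiasA", na.rm = TRUE) /
      pmax(n_obs, 1)
    frac_d <- rowSums(ct[, , 1, drop = FALSE] == "BiasD", na.rm = TRUE) /
      pmax(n_obs, 1)
    p <- vapply(seq_len(nrow(pairs)), function(i) {
      a <- expr$values[pairs$gene_At[i], , t]
      d <- expr$values[pairs$gene_Dt[i], , t]
      ok <- !is.na(a) & !is.na(d)
      if (sum(ok) < 2 || all(a[ok] == d[ok])) return(NA_real_)
      suppressWarnings(
        wilcox.test(a[ok], d[ok], paired = TRUE, exact = FALSE)$p.value
      )
    }, 0)
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- p.adjust(p[!is.na(p)], "BH")
    lab_of <- function(need_q) {
      lab <- rep("BiasN", nrow(pairs))
      lab[frac_a >= min_frac & frac_d >= min_frac] <- "bidirectional"
      one_a <- frac_a >= min_frac & frac_d < min_frac
      one_d <- frac_d >= min_frac & frac_a < min_frac
      if (need_q) {
        one_a <- one_a & !is.na(q) & q <= fdr
        one_d <- one_d & !is.na(q) & q <= fdr
      }
      lab[one_a] <- "BiasA"
      lab[one_d] <- "BiasD"
      lab[n_obs == 0] <- NA_character_
      lab
    }
    if (any(n_obs == 0)) {
      warning("pair(s) with no data at timepoint ", tps[t], "; label undefined")
    }
    out[[t]] <- data.frame(pair = pairs$pair, timepoint = tps[t],
                           frac_biasA = unname(frac_a), frac_biasD = unname(frac_d),
                           q = q, label = lab_of(TRUE), label_raw = lab_of(FALSE),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Temporal bias class of one accession's call vector
#'
#' Over `T` timepoints (default six), an accession's bias-call vector for a
#' pair maps to one of eight classes: classes 1-6 hold a single bias
#' direction at 6, 5, 4, 3, 2 or 1 timepoints (no bias elsewhere), class 7
#' is balanced (no bias) at all timepoints, and class 8 holds both
#' directions in at least two timepoints. `not_expressed` counts as no
#' bias.
#'
#' @param calls character vector of length `T` over
#'   `{"BiasA", "BiasD", "none", "not_expressed"}`.
#' @param T expected number of timepoints.
#' @return integer class in `1:(T + 2)` (1..8 when `T` = 6).
#' @export
#' @examples
#' assign_temporal_class(rep("BiasA", 6))                     # 1
#' assign_temporal_class(c("BiasA", rep("none", 5)))          # 6
#' assign_temporal_class(rep("none", 6))                      # 7
#' assign_temporal_class(c("BiasA", "BiasD", rep("none", 4))) # 8
assign_temporal_class <- function(calls, T = 6L) {
  if (length(calls) != T) stop("call vector must have length ", T)
  if (anyNA(calls)) stop("call vector must be complete (no NA)")
  has_a <- any(calls == "BiasA")
  has_d <- any(calls == "BiasD")
  if (has_a && has_d) return(T + 2L)          # switched direction
  n_bias <- sum(calls %in% c("BiasA", "BiasD"))
  if (n_bias == 0L) return(T + 1L)            # balanced throughout
  T + 1L - n_bias                             # T biased -> 1, ..., 1 -> T
}

#' Per-pair counts of accessions in each temporal class
#'
#' @param calls result of [call_bias_cube()].
#' @return matrix pairs x classes (columns `class1`..`class8` for six
#'   timepoints); accessions with incomplete call vectors are skipped.
#' @export
temporal_class_counts <- function(calls) {
  T <- dim(calls)[3]
  n_class <- T + 2L
  counts <- matrix(0L, nrow = dim(calls)[1], ncol = n_class,
                   dimnames = list(dimnames(calls)[[1]],
                                   paste0("class", seq_len(n_class))))
  for (i in seq_len(dim(calls)[1])) {
    m <- calls[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = T)
    complete <- rowSums(is.na(m)) == 0
    if (!any(complete)) next
    cls <- apply(m[complete, , drop = FALSE], 1, assign_temporal_class, T = T)
    tab <- tabulate(cls, n_class)
    counts[i, ] <- tab
  }
  counts
}

#' Cluster pairs into switched / time-dependent / dominant groups
#'
#' Pairs are clustered by Ward-linkage hierarchical clustering (Euclidean
#' distance on row-normalized temporal-class fractions) into `k` groups;
#' each cluster is named after the class group that dominates its centroid:
#' class 8 (direction switches) -> `switched`, class 1 (stable direction)
#' -> `dominant`, classes 2-7 (no bias at one or more timepoints) ->
#' `time-dependent`.
#'
#' @param counts result of [temporal_class_counts()].
#' @param k number of clusters (default 3).
#' @param seed kept for interface stability; the clustering is
#'   deterministic.
#' @return character vector of cluster labels, named by pair.
#' @export
cluster_pairs_by_class <- function(counts, k = 3L, seed = 1L) {
  if (nrow(counts) < k) stop("need at least ", k, " pairs to cluster")
  n_class <- ncol(counts)
  frac <- counts / pmax(rowSums(counts), 1)
  hc <- hclust(dist(frac), method = "ward.D2")
  cl <- cutree(hc, k = k)
  labels <- character(k)
  for (g in seq_len(k)) {
    centroid <- colMeans(frac[cl == g, , drop = FALSE])
    mass <- c(switched = unname(centroid[n_class]),
              dominant = unname(centroid[1]),
              `time-dependent` = sum(centroid[2:(n_class - 1)]))
    labels[g] <- names(mass)[which.max(mass)]
  }
  stats::setNames(labels[cl], rownames(counts))
}
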