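# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# minor allele frequency from a dosage vector in {0,1,2}, NA-tolerant
maf_from_dosage <- function(d) {
  f <- mean(d, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

maf_from_dosage_matrix <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
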