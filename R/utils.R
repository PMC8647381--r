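# Internal helpers shared across modules.

# Evaluate `code` under `set.seed(seed)` while leaving the caller's RNG
# state untouched. `seed = NULL` runs the code against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gene-level z from a p-value: the upper-tail normal quantile of p, with p
# capped to [1e-300, 1 - 1e-16] so the quantile stays finite.
gene_z_from_p <- function(p) {
  stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
}

# Strip an optional "chr" prefix so "chr6" and "6" compare equal.
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

# Geometric mean; any zero (or negative clipped to zero) component gives 0.
geom_mean <- function(x) {
  x <- pmax(x, 0)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

stop_scgwas <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "scgwas_error")
}

warn_scgwas <- function(msg, ...) {
  warn(sprintf(msg, ...), class = "scgwas_warning")
}
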