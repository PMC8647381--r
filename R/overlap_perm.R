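# In-silico permutation analysis: does the observed overlap between two
# significant gene sets exceed what random draws from the background give?

#' Observed overlap between two gene sets
#'
#' @param set_a,set_b Character vectors (deduplicated internally).
#' @return `|A intersect B|` as an integer.
#' @export
observed_overlap <- function(set_a, set_b) {
  length(intersect(unique(set_a), unique(set_b)))
}

#' Empirical overlap p-value by random selection
#'
#' Draws `|B|` genes uniformly without replacement from the background
#' `n_draws` times and counts how often the random set overlaps A at least
#' as much as B does:
#' `empirical_p = #\{draws with overlap >= observed\} / n_draws`.
#' An empirical p of exactly 0 is a Monte-Carlo artifact of the formula;
#' such results carry a `"note"` attribute `"< 1/n_draws"`.
#'
#' @param set_a First gene set; members absent from the background are
#'   dropped with a warning.
#' @param set_b Second gene set; must be a subset of the background.
#' @param background Character vector: the gene universe the random sets are
#'   drawn from (passed explicitly, never inferred).
#' @param n_draws Number of random selections (default 100000).
#' @param seed Integer seed.
#' @return A one-row tibble with `n_observed`, `n_total`, `n_background`,
#'   `set_a_size`, `set_b_size`, `empirical_p`, `null_overlap_mean`.
#' @export
empirical_p <- function(set_a, set_b, background, n_draws = 100000,
                        seed = NULL) {
  background <- unique(background)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_b) > length(background)) {
    stop_scgwas("set_b (%d) is larger than the background (%d).",
                length(set_b), length(background))
  }
  if (!all(set_b %in% background)) {
    stop_scgwas("set_b must be a subset of the background.")
  }
  outside <- setdiff(set_a, background)
  if (length(outside) > 0) {
    warn_scgwas("Dropped %d member(s) of set_a absent from the background.",
                length(outside))
    set_a <- setdiff(set_a, outside)
  }
  n_obs <- observed_overlap(set_a, set_b)
  in_a <- background %in% set_a
  n_bg <- length(background)
  k <- length(set_b)
  with_seed(seed, {
    overlaps <- vapply(seq_len(n_draws), function(i) {
      sum(in_a[sample.int(n_bg, k)])
    }, numeric(1))
    p <- sum(overlaps >= n_obs) / n_draws
    out <- tibble(
      n_observed = n_obs,
      n_total = as.integer(n_draws),
      n_background = n_bg,
      set_a_size = length(set_a),
      set_b_size = k,
      empirical_p = p,
      null_overlap_mean = mean(overlaps)
    )
    if (p == 0) attr(out, "note") <- sprintf("< %g", 1 / n_draws)
    out
  })
}
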