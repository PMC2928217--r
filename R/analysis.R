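#' Rescale one biased position of an aggregate profile
#'
#' Micrococcal nuclease and similar enzymes cut with sequence preference,
#' which inflates fragment-start counts at specific offsets (e.g. the
#' conserved A of the AG splice-donor site two bases upstream of an exon).
#' This replaces the profile value at `target_offset` with the mean of the
#' profile over `window` excluding the target, leaving every other value
#' untouched. It operates on the aggregate footprint vector, not on the
#' stored per-read data, and is idempotent.
#'
#' @param profile Numeric footprint mean vector, or a `footprint` object.
#'   A plain vector must carry its offsets as names (or via `offsets`).
#' @param target_offset The offset whose value is replaced.
#' @param window Length-2 numeric `c(lo, hi)`: the offset range whose mean
#'   (excluding `target_offset`) becomes the new value. Must cover more
#'   than just the target.
#' @param offsets Offsets of `profile` when it is an unnamed vector.
#' @return The rescaled profile, same type as the input.
#' @examples
#' p <- c(1, 1, 10, 1, 1); names(p) <- -2:2
#' mnase_rescale(p, target_offset = 0, window = c(-2, 2))
#' @export
mnase_rescale <- function(profile, target_offset, window, offsets = NULL) {
  if (inherits(profile, "footprint")) {
    profile$mean <- mnase_rescale(profile$mean, target_offset, window,
                                  offsets = profile$offsets)
    return(profile)
  }
  offsets <- offsets %||% as.numeric(names(profile))
  if (is.null(offsets) || anyNA(offsets))
    usage_error("profile needs offsets (names or the offsets argument)")
  if (length(window) != 2L || window[1L] > window[2L])
    usage_error("window must be c(lo, hi) with lo <= hi")
  if (!target_offset %in% offsets)
    usage_error("target_offset is outside the profile's offset range")
  in_win <- offsets >= window[1L] & offsets <= window[2L]
  donors <- in_win & offsets != target_offset
  if (!target_offset >= window[1L] || !target_offset <= window[2L])
    usage_error("target_offset lies outside the rescaling window")
  if (!any(donors))
    usage_error("rescaling window contains no offsets besides the target")
  profile[offsets == target_offset] <- mean(profile[donors])
  profile
}

#' Assign features to equal-count score bins
#'
#' Sorts features ascending by score and cuts them into `k` contiguous
#' groups whose sizes differ by at most one (any remainder goes to the
#' lowest bins); ties keep input order. Bin 1 holds the lowest scores.
#' Typical use: exons split into expression deciles.
#'
#' @param values Numeric per-feature scores.
#' @param k Number of bins, `1 <= k <= length(values)`.
#' @return Integer vector of bin ids (1 = lowest scores), parallel to
#'   `values`.
#' @examples
#' equal_count_bins(c(5, 1, 9, 3, 7), k = 2)
#' @export
equal_count_bins <- function(values, k) {
  n <- length(values)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) usage_error("k must be a positive integer")
  if (k > n) usage_error("k must not exceed the number of features")
  sizes <- rep.int(n %/% k, k)
  rem <- n %% k
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bins <- integer(n)
  bins[order(values)] <- rep.int(seq_len(k), sizes)  # order() is stable
  bins
}

#' Count features above/at vs below a reference mean
#'
#' Partitions per-feature averages against a reference value (e.g. each
#' exon's mean mappability against the genome-wide average). Values equal
#' to the reference count as "above".
#'
#' @param values Numeric per-feature averages.
#' @param reference A single finite reference value.
#' @return Named integer vector `c(above = ..., below = ...)`.
#' @export
above_below_split <- function(values, reference) {
  if (length(reference) != 1L || !is.finite(reference))
    usage_error("reference must be a single finite number")
  c(above = sum(values >= reference), below = sum(values < reference))
}

#' Exact one-sided binomial enrichment test
#'
#' Upper-tail probability `P(X >= k_below)` for `X ~ Binomial(n, p0)`: the
#' chance of seeing at least the observed number of below-reference
#' features if each independently falls below with probability `p0` (the
#' genome-wide below-average fraction). Callers typically compare the
#' result to 0.001. One-sided by design — the question is an excess of
#' low-scoring features, a directional claim.
#'
#' @param k_below Observed count of below-reference features, `0 <= k <= n`.
#' @param n Number of features in the group.
#' @param p0 Null proportion, strictly between 0 and 1.
#' @return The exact upper-tail p-value.
#' @examples
#' binomial_enrichment(10, 10, 0.5)   # 2^-10
#' @export
binomial_enrichment <- function(k_below, n, p0) {
  if (length(k_below) != 1L || length(n) != 1L || length(p0) != 1L ||
      is.na(k_below) || is.na(n) || is.na(p0))
    usage_error("k_below, n and p0 must be single non-missing numbers")
  if (k_below != trunc(k_below) || n != trunc(n) || k_below < 0 || k_below > n)
    usage_error("need integer counts with 0 <= k_below <= n")
  if (p0 <= 0 || p0 >= 1) usage_error("p0 must lie strictly in (0, 1)")
  stats::pbinom(k_below - 1, size = n, prob = p0, lower.tail = FALSE)
}
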