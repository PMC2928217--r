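# Synthetic fragment and query generators. These emulate the shape of a
# short-read experiment — randomly placed stranded fragments on toy
# chromosomes, and uniformly scattered stranded anchors — so every part of
# the pipeline is testable without any download.

#' Generate random aligned fragments on toy chromosomes
#'
#' Fragments are placed uniformly within chromosomes chosen uniformly at
#' random; lengths are drawn from a normal distribution (rounded, floor 1,
#' capped at the chromosome length) mimicking a sonication/size-selection
#' profile. The defaults — 150 bp mean length, sd 20, both strands equally
#' likely — reflect a typical ChIP-seq-era short-read library.
#'
#' @param n Number of fragments (>= 0).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param length_mean,length_sd Fragment length distribution parameters in
#'   bases.
#' @param strand_prob Probability of the forward strand.
#' @param count Multiplicity given to every fragment (default 1).
#' @param seed Optional integer; fixes the stream without touching the
#'   caller's RNG state.
#' @return A fragment record data frame.
#' @examples
#' gen_fragments(5, c(chrT = 1e4), seed = 1)
#' @export
gen_fragments <- function(n, chrom_lengths, length_mean = 150,
                          length_sd = 20, strand_prob = 0.5, count = 1,
                          seed = NULL) {
  stopifnot(n >= 0, length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  if (n == 0) return(empty_fragments())
  with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    clen <- unname(chrom_lengths[chrom])
    len <- pmin(pmax(1, round(stats::rnorm(n, length_mean, length_sd))), clen)
    start <- floor(stats::runif(n, 1, clen - len + 1 + 1))  # 1..clen-len+1
    strand <- ifelse(stats::runif(n) < strand_prob, "+", "-")
    fragment_records(chrom, start, start + len - 1, strand, count)
  })
}

#' Generate random stranded anchor queries
#'
#' Anchors are uniform within chromosomes and chromosomes are uniform
#' (regardless of length), which maximizes switches between signal sources
#' when querying. Optional group labels are assigned uniformly.
#'
#' @param n Number of queries.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param strand_prob Probability of the forward strand.
#' @param labels Optional vector of group labels to sample from.
#' @param seed Optional integer seed (stream-local).
#' @return A footprint query data frame.
#' @export
gen_queries <- function(n, chrom_lengths, strand_prob = 0.5, labels = NULL,
                        seed = NULL) {
  stopifnot(n >= 0, length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  if (n == 0)
    return(footprint_queries(character(), numeric(), character(), character()))
  with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n, replace = TRUE)
    anchor <- floor(stats::runif(n, 1, unname(chrom_lengths[chrom]) + 1))
    strand <- ifelse(stats::runif(n) < strand_prob, "+", "-")
    label <- if (is.null(labels)) NA else sample(labels, n, replace = TRUE)
    footprint_queries(chrom, anchor, strand, label)
  })
}
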