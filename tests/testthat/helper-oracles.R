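# Independent brute-force oracles. These deliberately avoid the package's
# cumsum/seek machinery: plain per-fragment loops over full vectors
# starting at coordinate 1.

# Per-base pileup from coordinate 1 to max_coord, naive loop.
oracle_pileup <- function(records, chrom, stratum, prolong = NULL,
                          starts_only = FALSE, cap = Inf,
                          max_coord = NULL) {
  rc <- records[records$chrom == chrom, , drop = FALSE]
  if (stratum == "forward") rc <- rc[rc$strand == "+", , drop = FALSE]
  if (stratum == "reverse") rc <- rc[rc$strand == "-", , drop = FALSE]
  max_coord <- max_coord %||% max(records$end, if (!is.null(prolong))
    records$start + prolong - 1)
  v <- numeric(max_coord)
  for (i in seq_len(nrow(rc))) {
    s <- rc$start[i]; e <- rc$end[i]
    if (stratum == "combined" && !is.null(prolong)) {
      if (rc$strand[i] == "+") { e <- s + prolong - 1 }
      else { s <- max(1, e - prolong + 1) }
    }
    if (starts_only) {
      p <- if (rc$strand[i] == "+") rc$start[i] else rc$end[i]
      s <- p; e <- p
    }
    for (p in s:min(e, max_coord)) v[p] <- v[p] + rc$count[i]
  }
  pmin(round(v), cap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Slice-and-flip window oracle over a full per-base vector (coordinate 1
# based); zero-pads outside the vector.
oracle_window <- function(full, anchor, strand, U, D) {
  at <- function(p) ifelse(p >= 1 & p <= length(full), full[pmax(p, 1)], 0)
  if (strand == "+") at(seq(anchor - U, anchor + D))
  else rev(at(seq(anchor - D, anchor + U)))
}

# Character-by-character CIGAR walker (independent of the regex parser).
oracle_cigar_span <- function(cigar) {
  num <- ""
  span <- 0
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) num <- paste0(num, ch)
    else {
      if (ch %in% c("M", "D", "N", "=", "X")) span <- span + as.numeric(num)
      num <- ""
    }
  }
  span
}

# Exact binomial upper tail by full enumeration with choose().
oracle_binom_upper <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
             numeric(1)))
}

# A small deterministic fragment set touching both strands and overlaps.
toy_fragments <- function() {
  fragment_records(chrom = c("chr1", "chr1", "chr1", "chr2"),
                   start = c(10, 12, 20, 5),
                   end = c(14, 20, 29, 9),
                   strand = c("+", "+", "-", "-"),
                   count = c(1, 1, 1, 2))
}
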