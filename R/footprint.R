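#' Construct a table of footprint queries
#'
#' A footprint query is an anchor coordinate (e.g. a TSS, exon boundary or
#' motif midpoint) with a strand giving its transcription direction and an
#' optional group label used by [grouped_footprints()].
#'
#' @param chrom Chromosome names.
#' @param anchor 1-based anchor coordinates (>= 1).
#' @param strand `"+"`/`"-"` (or `"forward"`/`"reverse"`). Recycled.
#' @param label Optional group tags. Recycled.
#' @return A data frame with columns `chrom`, `anchor`, `strand`, `label`.
#' @export
footprint_queries <- function(chrom, anchor, strand = "+", label = NA) {
  n <- length(anchor)
  validate_queries(data.frame(
    chrom = as.character(chrom),
    anchor = as.numeric(anchor),
    strand = rep_len(norm_strand(as.character(strand)), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE))
}

validate_queries <- function(queries) {
  need <- c("chrom", "anchor", "strand")
  miss <- setdiff(need, names(queries))
  if (length(miss))
    usage_error(sprintf("queries lack column(s): %s",
                        paste(miss, collapse = ", ")))
  if (!"label" %in% names(queries)) queries$label <- NA_character_
  if (nrow(queries) == 0L) return(queries)
  if (anyNA(queries$anchor) || any(queries$anchor < 1))
    data_error("query anchors must be >= 1")
  if (!all(queries$strand %in% c("+", "-")))
    queries$strand <- norm_strand(queries$strand)
  queries
}

#' Extract one strand-oriented signal window
#'
#' Returns the signal in a window of `U` bases upstream and `D` bases
#' downstream of the anchor, always oriented 5' to 3' along the query's
#' transcription direction: for a forward anchor the genomic slice
#' `[anchor - U, anchor + D]`; for a reverse anchor the slice
#' `[anchor - D, anchor + U]` reversed. Positions outside the stored extent
#' (including below coordinate 1) read as zero.
#'
#' @param store A `signal_store` or `disk_store`.
#' @param query A one-row footprint query (or chrom/anchor/strand list).
#' @param U,D Non-negative upstream/downstream extents in bases.
#' @param stratum Which stored stratum to read.
#' @return Numeric vector of length `U + D + 1`; element `U + 1` is the
#'   anchor itself.
#' @export
extract_window <- function(store, query, U, D, stratum = "combined") {
  if (U < 0 || D < 0) usage_error("U and D must be >= 0")
  stratum <- norm_stratum(stratum)
  if (query$strand == "+") {
    slice_values(store, query$chrom, stratum, query$anchor - U,
                 query$anchor + D)
  } else {
    rev(slice_values(store, query$chrom, stratum, query$anchor - D,
                     query$anchor + U))
  }
}

#' Average signal footprint over a set of anchors
#'
#' The meta-profile: per-offset arithmetic mean of the strand-oriented
#' windows of all queries. Offsets run from `-U` (upstream) to `+D`
#' (downstream) in transcription direction. Windows overhanging coordinate
#' 1 contribute zero-filled positions rather than being excluded, so every
#' query counts at every offset and `n` is constant.
#'
#' @inheritParams extract_window
#' @param queries A footprint query table ([footprint_queries()]);
#'   non-empty.
#' @return An object of class `footprint`: list with `offsets`
#'   (`-U .. +D`), `mean`, `n` (contributing query count per offset) and
#'   `label`.
#' @examples
#' fr <- fragment_records("chr1", 90 + 1:20, 110 + 1:20)
#' st <- build_tracks(fr)
#' fp <- make_footprint(st, footprint_queries("chr1", c(100, 120)),
#'                      U = 10, D = 10, stratum = "forward")
#' plot(fp)
#' @export
make_footprint <- function(store, queries, U, D, stratum = "combined") {
  queries <- validate_queries(queries)
  if (nrow(queries) == 0L) usage_error("query set is empty")
  width <- U + D + 1
  total <- numeric(width)
  for (i in seq_len(nrow(queries)))
    total <- total + extract_window(store, queries[i, ], U, D, stratum)
  new_footprint(offsets = seq.int(-U, D), mean = total / nrow(queries),
                n = rep.int(nrow(queries), width), label = "all")
}

new_footprint <- function(offsets, mean, n, label) {
  structure(list(offsets = offsets, mean = mean, n = n, label = label),
            class = "footprint")
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint '%s': offsets %d..%d over %d queries>\n",
              x$label, min(x$offsets), max(x$offsets), x$n[1L]))
  peak <- which.max(x$mean)
  cat(sprintf("  mean signal %.4g..%.4g, peak %.4g at offset %d\n",
              min(x$mean), max(x$mean), x$mean[peak], x$offsets[peak]))
  invisible(x)
}

#' @export
as.data.frame.footprint <- function(x, ...) {
  data.frame(offset = x$offsets, mean = x$mean, n = x$n, label = x$label,
             stringsAsFactors = FALSE)
}

#' @export
plot.footprint <- function(x, ...,
                           xlab = "offset (transcription direction)",
                           ylab = "mean signal", type = "l") {
  plot(x$offsets, x$mean, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Footprints split by query group label
#'
#' Partitions the queries by their `label` column and computes one
#' footprint per group plus one pooled over all queries (label `"all"`) —
#' e.g. exons split by length class or expression bin.
#'
#' @inheritParams make_footprint
#' @return Named list of `footprint` objects, one per label plus `"all"`.
#' @export
grouped_footprints <- function(store, queries, U, D, stratum = "combined") {
  queries <- validate_queries(queries)
  if (nrow(queries) == 0L) usage_error("query set is empty")
  labels <- unique(queries$label)
  out <- lapply(labels, function(lb) {
    fp <- make_footprint(store, queries[queries$label %in% lb, , drop = FALSE],
                         U, D, stratum)
    fp$label <- as.character(lb)
    fp
  })
  names(out) <- as.character(labels)
  out$all <- make_footprint(store, queries, U, D, stratum)
  out
}

#' Per-query signal matrix over oriented windows
#'
#' One row per query, one column per offset `-U .. +D`; row i is
#' [extract_window()] of query i, rows in query order. The column means
#' equal [make_footprint()]'s `mean`, so this is the input for clustering
#' individual signals (e.g. k-means over TSS windows) or heat maps.
#'
#' @inheritParams make_footprint
#' @return Numeric matrix `nrow(queries)` x `U + D + 1` with offset column
#'   names.
#' @export
extract_signal_matrix <- function(store, queries, U, D, stratum = "combined") {
  queries <- validate_queries(queries)
  if (nrow(queries) == 0L) usage_error("query set is empty")
  m <- t(vapply(seq_len(nrow(queries)),
                function(i) extract_window(store, queries[i, ], U, D, stratum),
                numeric(U + D + 1)))
  dimnames(m) <- list(NULL, as.character(seq.int(-U, D)))
  m
}
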