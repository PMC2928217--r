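#' Accumulate fragments into dense per-base signal tracks
#'
#' The central builder: for every reference sequence it produces a dense
#' per-base count array for fragments on the forward strand and one for the
#' reverse strand, and — when a prolongation length is given — a combined
#' track in which each fragment is replaced by an `prolong`-base interval
#' anchored at its 5' end (forward: `[start, start + L - 1]`; reverse:
#' `[end - L + 1, end]`, clipped at coordinate 1). With
#' `starts_only = TRUE` only the 5' start position of each fragment is
#' counted instead of its full span, which exposes e.g. nuclease cut
#' preferences rather than occupancy.
#'
#' Values are stored per the element specification; unsigned elements
#' saturate at `2^(8 * width) - 1` and the number of saturated (truncated)
#' positions per track is reported in the build statistics. Fractional
#' input (e.g. WIG) destined for an integer element is rounded
#' half-to-even. Input order is irrelevant.
#'
#' @param records Fragment records ([fragment_records()] or a reader's
#'   output).
#' @param prolong Optional prolongation length in bases (>= 1), e.g. the
#'   sonicated fragment size; enables the combined track. Fragments longer
#'   than `prolong` are truncated to it.
#' @param starts_only Count fragment 5' starts instead of full coverage.
#' @param element An [element_spec()].
#' @return An object of class `signal_store`: a list of `binary_track`
#'   objects keyed `<chrom>:<stratum>` plus a `stats` data frame (per track:
#'   low/high coordinates, fragment count, truncated and skipped tallies).
#' @examples
#' fr <- fragment_records("chr1", c(10, 12), c(14, 20))
#' st <- build_tracks(fr)
#' get_values(st, "chr1", "forward", 10, 20)
#' @export
build_tracks <- function(records, prolong = NULL, starts_only = FALSE,
                         element = element_spec()) {
  records <- validate_fragments(records)
  stopifnot(inherits(element, "element_spec"))
  if (!is.null(prolong)) {
    prolong <- as.numeric(prolong)
    if (length(prolong) != 1L || is.na(prolong) || prolong < 1 ||
        prolong != trunc(prolong))
      usage_error("prolong must be a single integer length >= 1")
  }
  skipped <- attr(records, "skipped") %||% 0L
  tracks <- list()
  stats <- list()
  for (chrom in unique(records$chrom)) {
    rc <- records[records$chrom == chrom, , drop = FALSE]
    for (stratum in c("forward", "reverse", if (!is.null(prolong)) "combined")) {
      iv <- stratum_intervals(rc, stratum, prolong, starts_only)
      if (nrow(iv) == 0L) next
      acc <- accumulate_intervals(iv$start, iv$end, iv$count)
      fin <- finalize_values(acc$values, element)
      key <- paste(chrom, stratum, sep = ":")
      tracks[[key]] <- new_binary_track(chrom, stratum, acc$offset,
                                        fin$values, element)
      stats[[key]] <- data.frame(
        chrom = chrom, stratum = stratum, low = acc$offset,
        high = acc$offset + length(fin$values) - 1,
        fragments = sum(iv$count), truncated = fin$truncated,
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  stats_df <- if (length(stats))
    do.call(rbind, c(stats, list(make.row.names = FALSE))) else empty_stats()
  structure(list(tracks = tracks, stats = stats_df,
                 element = element, prolong = prolong,
                 starts_only = starts_only),
            class = "signal_store")
}

# Intervals contributing to one stratum. Forward/reverse strata take the
# fragments of that strand; the combined stratum takes both strands with
# each fragment replaced by its prolonged 5'-anchored interval.
stratum_intervals <- function(rc, stratum, prolong, starts_only) {
  if (stratum == "combined") {
    s <- ifelse(rc$strand == "+", rc$start, pmax(1, rc$end - prolong + 1))
    e <- ifelse(rc$strand == "+", rc$start + prolong - 1, rc$end)
    five <- ifelse(rc$strand == "+", rc$start, rc$end)
    if (starts_only) data.frame(start = five, end = five, count = rc$count)
    else data.frame(start = s, end = e, count = rc$count)
  } else {
    keep <- rc$strand == if (stratum == "forward") "+" else "-"
    rs <- rc[keep, , drop = FALSE]
    if (starts_only) {
      five <- if (stratum == "forward") rs$start else rs$end
      data.frame(start = five, end = five, count = rs$count)
    } else {
      data.frame(start = rs$start, end = rs$end, count = rs$count)
    }
  }
}

# Dense pileup via difference array + cumulative sum: O(n + span).
accumulate_intervals <- function(start, end, count) {
  offset <- min(start)
  len <- max(end) - offset + 1
  delta <- numeric(len + 1)
  agg <- rowsum(c(count, -count), c(start - offset + 1, end - offset + 2))
  delta[as.integer(rownames(agg))] <- agg[, 1L]
  list(offset = offset, values = cumsum(delta)[seq_len(len)])
}

# Round (integer elements) and saturate; tally truncated positions.
finalize_values <- function(values, element) {
  if (element$kind == "uint") {
    values <- round(values)  # round-half-to-even for fractional input
    cap <- element_max(element)
    truncated <- sum(values > cap)
    values <- pmin(values, cap)
  } else {
    truncated <- 0L
  }
  list(values = values, truncated = as.integer(truncated))
}

new_binary_track <- function(chrom, stratum, offset, values, element) {
  structure(list(chrom = chrom, stratum = stratum, offset = offset,
                 values = values, element = element),
            class = "binary_track")
}

empty_stats <- function() {
  data.frame(chrom = character(), stratum = character(), low = numeric(),
             high = numeric(), fragments = numeric(), truncated = integer(),
             skipped = integer(), stringsAsFactors = FALSE)
}

#' @export
print.binary_track <- function(x, ...) {
  cat(sprintf("<binary_track %s [%s]: %s..%s, %d bases, %s %d-byte>\n",
              x$chrom, x$stratum, format(x$offset, scientific = FALSE),
              format(x$offset + length(x$values) - 1, scientific = FALSE),
              length(x$values), x$element$kind, x$element$width))
  invisible(x)
}

#' @export
print.signal_store <- function(x, ...) {
  cat(sprintf("<signal_store: %d track(s), element %s %d-byte%s%s>\n",
              length(x$tracks), x$element$kind, x$element$width,
              if (!is.null(x$prolong)) sprintf(", prolong %d", x$prolong) else "",
              if (isTRUE(x$starts_only)) ", starts-only" else ""))
  if (nrow(x$stats)) print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Build statistics of a signal store
#'
#' One row per (chromosome, stratum): lowest and highest stored coordinate,
#' multiplicity-weighted fragment count, number of positions saturated at
#' the element maximum, and records skipped during lenient parsing.
#'
#' @param store A `signal_store`.
#' @return The statistics data frame.
#' @export
build_stats <- function(store) {
  stopifnot(inherits(store, "signal_store"))
  store$stats
}

#' Write build statistics as labeled text
#'
#' One UTF-8 line per (chromosome, stratum) with `key=value` fields.
#'
#' @param stats A statistics data frame (see [build_stats()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  lines <- sprintf(
    "chrom=%s stratum=%s low=%s high=%s fragments=%s truncated=%d skipped=%d",
    stats$chrom, stats$stratum,
    format(stats$low, scientific = FALSE, trim = TRUE),
    format(stats$high, scientific = FALSE, trim = TRUE),
    format(stats$fragments, scientific = FALSE, trim = TRUE),
    stats$truncated, stats$skipped)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
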