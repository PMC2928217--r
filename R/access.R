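#' Read per-base values from a stored track
#'
#' Returns the dense signal over `[start, end]` (1-based closed) on one
#' stratum. Positions outside the stored extent are zero-filled — zero is
#' the correct pileup value where no fragment aligned — while an unknown
#' chromosome or stratum is an error, kept distinct from zero coverage
#' within a known track. For a `disk_store` the read seeks directly to
#' `payload_start + (start - offset) * width`, so cost does not grow with
#' track size.
#'
#' @param store A `signal_store` or `disk_store`.
#' @param chrom Chromosome name.
#' @param stratum `"forward"`, `"reverse"` or `"combined"`.
#' @param start,end 1-based closed region bounds, `1 <= start <= end`.
#' @return Numeric vector of length `end - start + 1`.
#' @export
get_values <- function(store, chrom, stratum, start, end) {
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end) ||
      start < 1 || end < start)
    usage_error("need 1 <= start <= end")
  slice_values(store, chrom, norm_stratum(stratum), start, end)
}

# Internal slice; tolerates start < 1 (zero-fill below coordinate 1) so
# footprint windows overhanging the chromosome edge work.
slice_values <- function(store, chrom, stratum, start, end) {
  UseMethod("slice_values")
}

lookup_key <- function(keys, chrom, stratum) {
  key <- paste(chrom, stratum, sep = ":")
  if (!key %in% keys) {
    have <- any(startsWith(keys, paste0(chrom, ":")))
    if (have)
      usage_error(sprintf("no %s stratum stored for chromosome %s",
                          stratum, chrom))
    usage_error(sprintf("unknown chromosome: %s", chrom))
  }
  key
}

#' @export
slice_values.signal_store <- function(store, chrom, stratum, start, end) {
  key <- lookup_key(names(store$tracks), chrom, stratum)
  tr <- store$tracks[[key]]
  out <- numeric(end - start + 1)
  lo <- max(start, tr$offset)
  hi <- min(end, tr$offset + length(tr$values) - 1)
  if (lo <= hi)
    out[(lo - start + 1):(hi - start + 1)] <-
      tr$values[(lo - tr$offset + 1):(hi - tr$offset + 1)]
  out
}

#' @export
slice_values.disk_store <- function(store, chrom, stratum, start, end) {
  key <- lookup_key(names(store$index), chrom, stratum)
  h <- store$index[[key]]
  out <- numeric(end - start + 1)
  lo <- max(start, h$offset)
  hi <- min(end, h$offset + h$length - 1)
  if (lo <= hi) {
    con <- file(h$path, "rb")
    on.exit(close(con))
    seek(con, h$data_offset + (lo - h$offset) * h$element$width)
    out[(lo - start + 1):(hi - start + 1)] <-
      read_payload(con, hi - lo + 1, h$element)
  }
  out
}

#' Mean signal over a region
#'
#' Arithmetic mean of [get_values()] over `[start, end]`; zero-filled
#' positions outside the stored extent count in the denominator.
#'
#' @inheritParams get_values
#' @return A single number.
#' @export
region_average <- function(store, chrom, stratum, start, end) {
  mean(get_values(store, chrom, stratum, start, end))
}

#' Keep positions with signal above a threshold
#'
#' Retains positions whose value is strictly greater than `threshold`.
#'
#' @param values Numeric signal vector.
#' @param positions Coordinates of `values` (default `seq_along(values)`).
#' @param threshold Non-negative cutoff; strictly-greater comparison.
#' @return A data frame with columns `pos` and `value`.
#' @export
filter_threshold <- function(values, positions = seq_along(values),
                             threshold = 0) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    usage_error("threshold must be a single non-negative number")
  if (length(values) != length(positions))
    usage_error("values and positions must have equal length")
  keep <- values > threshold
  data.frame(pos = positions[keep], value = values[keep])
}

#' Shift anchor queries along their transcription direction
#'
#' Moves every anchor `d` bases downstream in its own transcription
#' direction (forward: `+d`; reverse: `-d`) — e.g. as a negative control
#' that keeps window geometry relative to gene orientation. Strand and
#' labels are preserved. Anchors that would land below coordinate 1 are
#' dropped and tallied in the `dropped` attribute.
#'
#' @param queries A footprint query data frame ([footprint_queries()]).
#' @param d Signed shift distance in bases.
#' @return The shifted queries, with attribute `dropped`.
#' @export
shift_queries <- function(queries, d) {
  queries <- validate_queries(queries)
  if (length(d) != 1L || is.na(d) || d != trunc(d))
    usage_error("d must be a single integer distance")
  anchor <- queries$anchor + ifelse(queries$strand == "+", d, -d)
  keep <- anchor >= 1
  out <- queries[keep, , drop = FALSE]
  out$anchor <- anchor[keep]
  rownames(out) <- NULL
  structure(out, dropped = sum(!keep))
}
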