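#' Construct a table of normalized fragment records
#'
#' The unified in-memory representation of an aligned fragment or interval:
#' 1-based closed coordinates, strand, and a positive real multiplicity.
#' Every input format (SAM, BED, GFF-like, WIG) is normalized to this form
#' before track building.
#'
#' @param chrom Reference sequence names.
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @param strand `"+"`/`"-"` (or `"forward"`/`"reverse"`). Recycled.
#' @param count Positive multiplicity (default 1). Recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `count`.
#' @examples
#' fragment_records("chr1", c(10, 12), c(14, 20))
#' @export
fragment_records <- function(chrom, start, end, strand = "+", count = 1) {
  n <- length(start)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(norm_strand(as.character(strand)), n),
                   count = rep_len(as.numeric(count), n),
                   stringsAsFactors = FALSE)
  validate_fragments(df)
}

#' Validate fragment record invariants
#'
#' Checks `1 <= start <= end` and `count > 0` on a fragment table; errors on
#' the first violation.
#'
#' @param records A data frame as produced by [fragment_records()].
#' @return The validated records, invisibly usable in a pipeline.
#' @export
validate_fragments <- function(records) {
  need <- c("chrom", "start", "end", "strand", "count")
  miss <- setdiff(need, names(records))
  if (length(miss))
    usage_error(sprintf("fragment records lack column(s): %s",
                        paste(miss, collapse = ", ")))
  if (nrow(records) == 0L) return(records)
  if (anyNA(records$start) || anyNA(records$end) || anyNA(records$count))
    data_error("fragment records contain missing coordinates or counts")
  if (any(records$start < 1))
    data_error("fragment start coordinates must be >= 1 (1-based)")
  if (any(records$end < records$start))
    data_error("fragment end must be >= start")
  if (any(records$count <= 0))
    data_error("fragment count (multiplicity) must be > 0")
  bad <- !records$strand %in% c("+", "-")
  if (any(bad)) records$strand <- norm_strand(records$strand)
  records
}

# Empty table with the right columns.
empty_fragments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), count = numeric(),
             stringsAsFactors = FALSE)
}
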