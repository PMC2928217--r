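# Serializers back to the accepted text formats. These make the parsers
# round-trippable and let one fixture be rendered identically as BED,
# GFF-like text and a minimal SAM dialect.

#' Serialize fragment records to BED lines
#'
#' Emits 6-column BED (name ".", score 0), converting the internal 1-based
#' closed coordinates back to BED's 0-based half-open convention. BED cannot
#' carry a fractional multiplicity; records with `count != 1` are emitted as
#' `count` repeated lines and must therefore have integer counts.
#'
#' @param records A fragment record data frame.
#' @return Character vector of BED lines.
#' @export
emit_bed <- function(records) {
  records <- expand_counts(validate_fragments(records))
  sprintf("%s\t%d\t%d\t.\t0\t%s", records$chrom,
          as.integer(records$start - 1), as.integer(records$end),
          records$strand)
}

#' Serialize fragment records to GFF-like delimited lines
#'
#' Writes chrom/start/end/strand (and count, when a count column is
#' configured) into the columns the [column_spec()] names; any other
#' column up to the highest configured index is filled with ".".
#'
#' @param records A fragment record data frame.
#' @param spec A [column_spec()].
#' @return Character vector of delimited lines.
#' @export
emit_gff_like <- function(records, spec = column_spec()) {
  records <- validate_fragments(records)
  stopifnot(inherits(spec, "column_spec"))
  ncol <- max(spec$chrom, spec$start, spec$end, spec$strand, spec$count,
              na.rm = TRUE)
  m <- matrix(".", nrow = nrow(records), ncol = ncol)
  m[, spec$chrom] <- records$chrom
  m[, spec$start] <- format(records$start, scientific = FALSE, trim = TRUE)
  m[, spec$end] <- format(records$end, scientific = FALSE, trim = TRUE)
  if (!is.na(spec$strand)) {
    # invert the strand map: first symbol mapping to each orientation
    fw <- names(spec$strand_map)[spec$strand_map == "+"][1L]
    rv <- names(spec$strand_map)[spec$strand_map == "-"][1L]
    m[, spec$strand] <- ifelse(records$strand == "+", fw, rv)
  }
  if (!is.na(spec$count))
    m[, spec$count] <- format(records$count, scientific = FALSE, trim = TRUE)
  apply(m, 1L, paste, collapse = spec$delimiter)
}

#' Serialize fragment records to a minimal SAM dialect
#'
#' Produces an @HD/@SQ header followed by one alignment line per fragment
#' (FLAG 0 or 16, CIGAR `<len>M`, SEQ and QUAL `*`). Counts must be
#' integers; a record with `count = k` becomes k identical lines.
#'
#' @param records A fragment record data frame.
#' @param chrom_lengths Named vector of reference lengths for the @SQ
#'   header; defaults to each chromosome's highest end coordinate.
#' @return Character vector of SAM lines (header included).
#' @export
emit_sam <- function(records, chrom_lengths = NULL) {
  records <- expand_counts(validate_fragments(records))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(records$end, records$chrom, max)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  flag <- ifelse(records$strand == "-", 16L, 0L)
  body <- sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  seq_len(nrow(records)), flag, records$chrom,
                  as.integer(records$start),
                  as.integer(records$end - records$start + 1))
  c(hdr, body)
}

# Replicate records with integer multiplicities > 1 into unit-count rows.
expand_counts <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (any(records$count != trunc(records$count)))
    usage_error("this format cannot carry fractional multiplicities")
  idx <- rep(seq_len(nrow(records)), times = as.integer(records$count))
  out <- records[idx, , drop = FALSE]
  out$count <- 1
  rownames(out) <- NULL
  out
}

#' Write fragment records to a file in any accepted format
#'
#' @param records A fragment record data frame.
#' @param path Output file path.
#' @param format One of `"bed"`, `"gff"`, `"sam"`.
#' @param spec A [column_spec()] for the GFF-like writer.
#' @param chrom_lengths Optional reference lengths for the SAM header.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(records, path, format = c("bed", "gff", "sam"),
                            spec = column_spec(), chrom_lengths = NULL) {
  format <- match.arg(format)
  lines <- switch(format,
                  bed = emit_bed(records),
                  gff = emit_gff_like(records, spec),
                  sam = emit_sam(records, chrom_lengths))
  writeLines(lines, path)
  invisible(path)
}
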