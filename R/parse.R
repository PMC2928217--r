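#' Column layout of a delimited GFF-like fragment file
#'
#' The GFF-like reader accepts any delimited text with columns holding the
#' reference name, 1-based closed start/stop coordinates, an orientation
#' symbol and, optionally, a count/score used as fragment multiplicity.
#' Which column holds what, the delimiter string, and the strand-symbol
#' mapping are all configurable here.
#'
#' @param delimiter Field separator string (fixed, not a regex). Default tab.
#' @param chrom,start,end,strand 1-based column indices. `strand = NA`
#'   means no orientation column (all records forward).
#' @param count Column index of the multiplicity, or `NA` (default) for
#'   multiplicity 1.
#' @param strand_map Named character vector mapping the file's orientation
#'   symbols to `"+"`/`"-"`. Symbols outside the map are a parse error.
#' @return An object of class `column_spec`.
#' @examples
#' column_spec(delimiter = " ", chrom = 1, start = 2, end = 3,
#'             strand = 4, count = 5)
#' @export
column_spec <- function(delimiter = "\t", chrom = 1L, start = 2L, end = 3L,
                        strand = 4L, count = NA_integer_,
                        strand_map = c("+" = "+", "-" = "-")) {
  idx <- c(chrom = chrom, start = start, end = end, strand = strand,
           count = count)
  used <- idx[!is.na(idx)]
  if (any(used < 1) || anyDuplicated(used))
    usage_error("column indices must be distinct positive integers")
  if (anyNA(idx[c("chrom", "start", "end")]))
    usage_error("chrom, start and end columns are required")
  if (!all(strand_map %in% c("+", "-")))
    usage_error("strand_map values must be '+' or '-'")
  structure(list(delimiter = delimiter, chrom = as.integer(chrom),
                 start = as.integer(start), end = as.integer(end),
                 strand = as.integer(strand), count = as.integer(count),
                 strand_map = strand_map),
            class = "column_spec")
}

# Extract column i from a list of split fields; NA where absent.
field_col <- function(fields, i) {
  vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_,
         character(1))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# Shared strict/lenient error funnel: `bad` is a logical vector, `why` a
# message per line. Returns indices to keep; errors in strict mode.
settle_bad <- function(bad, why, lnum, strict) {
  if (!any(bad)) return(list(keep = !bad, skipped = 0L))
  first <- which(bad)[1L]
  if (strict) parse_error(why[first], lnum[first])
  list(keep = !bad, skipped = sum(bad))
}

# ---- BED ------------------------------------------------------------------

# Vectorized BED parser over raw data lines (track/browser/comment lines
# already removed). BED is 0-based half-open; records come out 1-based
# closed: start = chromStart + 1, end = chromEnd.
parse_bed_lines <- function(lines, lnum = seq_along(lines), strict = TRUE) {
  if (length(lines) == 0L)
    return(structure(empty_fragments(), skipped = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  s0 <- num_or_na(field_col(fields, 2L))
  e0 <- num_or_na(field_col(fields, 3L))
  why <- rep(NA_character_, length(lines))
  bad <- nf < 3L
  why[bad] <- "BED line has fewer than 3 tab-separated fields"
  malformed <- !bad & (is.na(s0) | is.na(e0) | s0 != trunc(s0) | e0 != trunc(e0) | s0 < 0)
  why[malformed] <- "malformed BED coordinates"
  bad <- bad | malformed
  inverted <- !bad & s0 >= e0
  why[inverted] <- "empty or inverted BED interval (chromStart >= chromEnd)"
  bad <- bad | inverted
  st <- settle_bad(bad, why, lnum, strict)
  keep <- st$keep
  strand6 <- field_col(fields, 6L)
  strand <- ifelse(!is.na(strand6) & strand6 %in% c("+", "-"), strand6, "+")
  out <- data.frame(chrom = field_col(fields, 1L)[keep],
                    start = s0[keep] + 1, end = e0[keep],
                    strand = strand[keep], count = 1,
                    stringsAsFactors = FALSE)
  structure(out, skipped = st$skipped)
}

#' Parse one BED line into a fragment record
#'
#' BED is 0-based, left-closed and right-open; the returned record is
#' 1-based and closed (`start = chromStart + 1`, `end = chromEnd`). Strand
#' is taken from field 6 when present and `+`/`-`, otherwise forward. The
#' BED score field is never used as multiplicity.
#'
#' @param line A single BED line (tab-separated, >= 3 fields).
#' @param line_number Line number reported in parse errors.
#' @return A one-row fragment record data frame.
#' @examples
#' parse_bed("chrX\t0\t10\t.\t0\t+")   # -> chrX 1..10, forward
#' @export
parse_bed <- function(line, line_number = 1L) {
  rec <- parse_bed_lines(line, lnum = line_number, strict = TRUE)
  attr(rec, "skipped") <- NULL
  rec
}

# ---- GFF-like -------------------------------------------------------------

parse_gff_lines <- function(lines, spec = column_spec(),
                            lnum = seq_along(lines), strict = TRUE) {
  stopifnot(inherits(spec, "column_spec"))
  if (length(lines) == 0L)
    return(structure(empty_fragments(), skipped = 0L))
  fields <- strsplit(lines, spec$delimiter, fixed = TRUE)
  nf <- lengths(fields)
  maxcol <- max(spec$chrom, spec$start, spec$end, spec$strand, spec$count,
                na.rm = TRUE)
  why <- rep(NA_character_, length(lines))
  bad <- nf < maxcol
  why[bad] <- sprintf("expected at least %d delimited fields", maxcol)
  s <- num_or_na(field_col(fields, spec$start))
  e <- num_or_na(field_col(fields, spec$end))
  malformed <- !bad & (is.na(s) | is.na(e) | s != trunc(s) | e != trunc(e) |
                         s < 1 | e < s)
  why[malformed] <- "malformed coordinates (need 1 <= start <= stop)"
  bad <- bad | malformed
  if (!is.na(spec$strand)) {
    sym <- field_col(fields, spec$strand)
    unknown <- !bad & !sym %in% names(spec$strand_map)
    why[unknown] <- "strand symbol outside configured mapping"
    bad <- bad | unknown
    strand <- unname(spec$strand_map[sym])
  } else {
    strand <- rep("+", length(lines))
  }
  if (!is.na(spec$count)) {
    cnt <- num_or_na(field_col(fields, spec$count))
    badc <- !bad & (is.na(cnt) | cnt <= 0)
    why[badc] <- "non-numeric or non-positive count"
    bad <- bad | badc
  } else {
    cnt <- rep(1, length(lines))
  }
  st <- settle_bad(bad, why, lnum, strict)
  keep <- st$keep
  out <- data.frame(chrom = field_col(fields, spec$chrom)[keep],
                    start = s[keep], end = e[keep],
                    strand = strand[keep], count = cnt[keep],
                    stringsAsFactors = FALSE)
  structure(out, skipped = st$skipped)
}

#' Parse one GFF-like delimited line into a fragment record
#'
#' Coordinates are taken as already 1-based and closed. If the
#' [column_spec()] configures a count column it becomes the record's
#' multiplicity, otherwise 1.
#'
#' @param line A single delimited line.
#' @param spec A [column_spec()] describing the layout.
#' @param line_number Line number reported in parse errors.
#' @return A one-row fragment record data frame.
#' @examples
#' sp <- column_spec(delimiter = " ", count = 5)
#' parse_gff_like("chr2 100 104 + 3", sp)   # multiplicity 3
#' @export
parse_gff_like <- function(line, spec = column_spec(), line_number = 1L) {
  rec <- parse_gff_lines(line, spec, lnum = line_number, strict = TRUE)
  attr(rec, "skipped") <- NULL
  rec
}

# ---- SAM ------------------------------------------------------------------

# Reference-consuming span of CIGAR strings (M/D/N/=/X ops). NA where the
# CIGAR is malformed or consumes no reference.
cigar_ref_span <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  whole <- vapply(toks, paste, "", collapse = "")
  span <- vapply(toks, function(t) {
    if (length(t) == 0L) return(NA_real_)
    op <- substring(t, nchar(t))
    len <- as.numeric(substring(t, 1L, nchar(t) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
  span[whole != cigar | is.na(span) | span < 1] <- NA_real_
  span
}

parse_sam_lines <- function(lines, lnum = seq_along(lines), strict = TRUE) {
  hdr <- startsWith(lines, "@")
  lines <- lines[!hdr]; lnum <- lnum[!hdr]
  if (length(lines) == 0L)
    return(structure(empty_fragments(), skipped = 0L, unmapped = 0L,
                     no_cigar = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  why <- rep(NA_character_, length(lines))
  bad <- nf < 11L
  why[bad] <- "SAM alignment line has fewer than 11 fields"
  flag <- num_or_na(field_col(fields, 2L))
  pos <- num_or_na(field_col(fields, 4L))
  malformed <- !bad & (is.na(flag) | is.na(pos))
  why[malformed] <- "malformed SAM FLAG or POS"
  bad <- bad | malformed
  rname <- field_col(fields, 3L)
  unmapped <- !bad & (bitwAnd(as.integer(ifelse(is.na(flag), 0, flag)), 4L) != 0L |
                        rname == "*" | pos == 0)
  cigar <- field_col(fields, 6L)
  span <- cigar_ref_span(cigar)
  nocig <- !bad & !unmapped & is.na(span)
  if (any(nocig))
    warning(sprintf("%d mapped SAM record(s) without a usable CIGAR skipped",
                    sum(nocig)), call. = FALSE)
  st <- settle_bad(bad, why, lnum, strict)
  keep <- st$keep & !unmapped & !nocig
  strand <- ifelse(bitwAnd(as.integer(ifelse(is.na(flag), 0, flag)), 16L) != 0L,
                   "-", "+")
  out <- data.frame(chrom = rname[keep], start = pos[keep],
                    end = pos[keep] + span[keep] - 1,
                    strand = strand[keep], count = rep(1, sum(keep)),
                    stringsAsFactors = FALSE)
  structure(out, skipped = st$skipped, unmapped = sum(unmapped),
            no_cigar = sum(nocig))
}

#' Parse one SAM alignment line into a fragment record
#'
#' Header lines and unmapped reads (FLAG bit 0x4, `RNAME == "*"` or
#' `POS == 0`) yield a zero-row result. Strand is reverse iff FLAG bit 0x10
#' is set. The record spans `POS .. POS + span - 1` where `span` is the sum
#' of reference-consuming CIGAR operation lengths (M, D, N, `=`, X). Mapped
#' reads with CIGAR `*` are skipped with a warning.
#'
#' @param record A single SAM line.
#' @param line_number Line number reported in parse errors.
#' @return A fragment record data frame with 0 or 1 rows; skip reasons are
#'   available as attributes `unmapped` and `no_cigar`.
#' @examples
#' sam <- "r1\t16\tchr1\t100\t60\t5M3I5M\t*\t0\t0\t*\t*"
#' parse_sam(sam)   # chr1 100..109, reverse
#' @export
parse_sam <- function(record, line_number = 1L) {
  parse_sam_lines(record, lnum = line_number, strict = TRUE)
}

# ---- WIG ------------------------------------------------------------------

wig_params <- function(decl, lnum) {
  kv <- regmatches(decl, gregexpr("[A-Za-z]+=[^ \t]+", decl))[[1]]
  if (length(kv) == 0L) parse_error("WIG declaration without parameters", lnum)
  keys <- sub("=.*", "", kv)
  vals <- sub("^[A-Za-z]+=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Parse UCSC WIG text into per-base values
#'
#' Supports both `fixedStep` and `variableStep` blocks; `track` and
#' `browser` lines and comments are ignored. A `span` of s expands each
#' value to s consecutive 1-based positions. A data line before any
#' declaration is a parse error.
#'
#' @param lines Character vector of WIG lines (e.g. from [readLines()]).
#' @return A data frame with columns `chrom`, `pos` (1-based), `value`.
#' @examples
#' parse_wig(c("fixedStep chrom=chr1 start=10 step=1", "1", "2", "3"))
#' @export
parse_wig <- function(lines) {
  lnum <- seq_along(lines)
  drop <- grepl("^\\s*$", lines) | startsWith(lines, "track") |
    startsWith(lines, "browser") | startsWith(lines, "#")
  lines <- lines[!drop]; lnum <- lnum[!drop]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  decl <- ifelse(startsWith(lines, "fixedStep"), "f",
                 ifelse(startsWith(lines, "variableStep"), "v", NA))
  if (is.na(decl[1L]))
    parse_error("WIG data line before any fixedStep/variableStep declaration",
                lnum[1L])
  block <- cumsum(!is.na(decl))
  out <- vector("list", max(block))
  for (b in seq_len(max(block))) {
    idx <- which(block == b)
    di <- idx[1L]
    p <- wig_params(lines[di], lnum[di])
    if (is.null(p$chrom)) parse_error("WIG declaration lacks chrom=", lnum[di])
    span <- as.numeric(p$span %||% 1)
    if (is.na(span) || span < 1) parse_error("invalid WIG span", lnum[di])
    data <- lines[idx[-1L]]
    dlnum <- lnum[idx[-1L]]
    if (length(data) == 0L) next
    if (decl[di] == "f") {
      start <- as.numeric(p$start); step <- as.numeric(p$step %||% 1)
      if (is.na(start) || start < 1)
        parse_error("fixedStep declaration lacks a valid start=", lnum[di])
      if (is.na(step) || step < 1) parse_error("invalid WIG step", lnum[di])
      val <- num_or_na(data)
      if (anyNA(val))
        parse_error("non-numeric fixedStep value", dlnum[which(is.na(val))[1L]])
      base <- start + (seq_along(val) - 1) * step
    } else {
      f <- strsplit(data, "[ \t]+")
      n2 <- lengths(f) >= 2L
      if (!all(n2))
        parse_error("variableStep line needs position and value",
                    dlnum[which(!n2)[1L]])
      base <- num_or_na(vapply(f, `[[`, "", 1L))
      val <- num_or_na(vapply(f, `[[`, "", 2L))
      if (anyNA(base) || any(base < 1) || any(base != trunc(base)))
        parse_error("invalid variableStep position",
                    dlnum[which(is.na(base) | base < 1)[1L]])
      if (anyNA(val))
        parse_error("non-numeric variableStep value", dlnum[which(is.na(val))[1L]])
    }
    pos <- rep(base, each = span) + rep(seq_len(span) - 1, times = length(base))
    out[[b]] <- data.frame(chrom = p$chrom, pos = pos,
                           value = rep(val, each = span),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# ---- file-level reader ----------------------------------------------------

#' Read an input file into normalized fragment records
#'
#' Dispatches to the SAM, BED, GFF-like or WIG parser and returns one
#' unified fragment table. Input files need not be sorted. In strict mode
#' (default) the first malformed line aborts with its line number; in
#' lenient mode malformed lines are skipped and tallied in the `skipped`
#' attribute.
#'
#' WIG values become single-base records with the value as multiplicity;
#' zero values are dropped (they carry no signal) and negative values are a
#' parse error.
#'
#' @param path Path to the input file (or a character vector of lines via
#'   `text`).
#' @param format One of `"sam"`, `"bed"`, `"gff"`, `"wig"`.
#' @param spec A [column_spec()], used by the GFF-like reader.
#' @param strict Abort on the first malformed line (default) or skip and
#'   tally.
#' @param text Parse these lines instead of reading `path`.
#' @return A fragment record data frame with attributes `skipped` (malformed
#'   lines dropped in lenient mode) and, for SAM, `unmapped` and `no_cigar`.
#' @export
read_fragments <- function(path, format = c("sam", "bed", "gff", "wig"),
                           spec = column_spec(), strict = TRUE, text = NULL) {
  format <- match.arg(format)
  lines <- if (!is.null(text)) text else {
    if (!file.exists(path)) usage_error(sprintf("input file not found: %s", path))
    readLines(path)
  }
  lnum <- seq_along(lines)
  if (format %in% c("bed", "gff")) {
    drop <- grepl("^\\s*$", lines) | startsWith(lines, "#") |
      (format == "bed" &
         (startsWith(lines, "track") | startsWith(lines, "browser")))
    lines <- lines[!drop]; lnum <- lnum[!drop]
  }
  rec <- switch(format,
    bed = parse_bed_lines(lines, lnum, strict),
    gff = parse_gff_lines(lines, spec, lnum, strict),
    sam = parse_sam_lines(lines, lnum, strict),
    wig = {
      w <- parse_wig(lines)
      if (any(w$value < 0))
        parse_error("negative WIG value cannot be a fragment multiplicity")
      w <- w[w$value > 0, , drop = FALSE]
      structure(data.frame(chrom = w$chrom, start = w$pos, end = w$pos,
                           strand = "+", count = w$value,
                           stringsAsFactors = FALSE),
                skipped = 0L)
    })
  validate_fragments(rec)
}
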