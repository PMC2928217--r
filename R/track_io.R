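# Random-access binary track format.
#
# Layout (little-endian throughout):
#   bytes 0..7    magic "SEQFOOT1"
#   byte  8       format version (1)
#   byte  9       element kind (0 = uint, 1 = float)
#   byte  10      element width in bytes
#   byte  11      stratum code (0 = forward, 1 = reverse, 2 = combined)
#   bytes 12..19  offset: lowest stored genomic coordinate (uint64)
#   bytes 20..27  length: number of stored elements (uint64)
#   bytes 28..29  chromosome-name length n (uint16)
#   n bytes       chromosome name (UTF-8)
#   payload       length * width bytes of raw values
#
# Storing the offset in the header gives near-constant access: a coordinate
# c is read at payload_start + (c - offset) * width.

TRACK_MAGIC <- "SEQFOOT1"
TRACK_VERSION <- 1L
KIND_CODE <- c(uint = 0L, float = 1L)
STRATUM_CODE <- c(forward = 0L, reverse = 1L, combined = 2L)

# Two's-complement mapping so writeBin never sees out-of-range integers.
write_uint <- function(con, v, width) {
  if (width == 1L) {
    writeBin(as.integer(ifelse(v >= 2^7, v - 2^8, v)), con, size = 1L,
             endian = "little")
  } else if (width == 2L) {
    writeBin(as.integer(ifelse(v >= 2^15, v - 2^16, v)), con, size = 2L,
             endian = "little")
  } else if (width == 4L) {
    writeBin(as.integer(ifelse(v >= 2^31, v - 2^32, v)), con, size = 4L,
             endian = "little")
  } else {
    lo <- v %% 2^32
    hi <- v %/% 2^32
    m <- rbind(ifelse(lo >= 2^31, lo - 2^32, lo),
               ifelse(hi >= 2^31, hi - 2^32, hi))
    writeBin(as.integer(m), con, size = 4L, endian = "little")
  }
}

read_uint <- function(con, n, width) {
  if (width <= 2L) {
    as.numeric(readBin(con, integer(), n = n, size = width, signed = FALSE,
                       endian = "little"))
  } else if (width == 4L) {
    v <- as.numeric(readBin(con, integer(), n = n, size = 4L,
                            endian = "little"))
    v[v < 0] <- v[v < 0] + 2^32
    v
  } else {
    w <- as.numeric(readBin(con, integer(), n = 2L * n, size = 4L,
                            endian = "little"))
    w[w < 0] <- w[w < 0] + 2^32
    w[seq(1L, 2L * n, 2L)] + w[seq(2L, 2L * n, 2L)] * 2^32
  }
}

write_payload <- function(con, values, element) {
  if (element$kind == "uint") write_uint(con, values, element$width)
  else writeBin(as.double(values), con, size = element$width,
                endian = "little")
}

read_payload <- function(con, n, element) {
  if (element$kind == "uint") read_uint(con, n, element$width)
  else readBin(con, double(), n = n, size = element$width, endian = "little")
}

#' Write one binary track to disk
#'
#' Persists a `binary_track` in the package's self-describing random-access
#' format: a fixed header (magic, version, element kind and width, stratum,
#' coordinate offset, length, chromosome name) followed by the raw dense
#' payload, little-endian.
#'
#' @param track A `binary_track` (one element of a `signal_store`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "binary_track"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(TRACK_MAGIC), con)
  writeBin(as.raw(c(TRACK_VERSION, KIND_CODE[[track$element$kind]],
                    track$element$width, STRATUM_CODE[[track$stratum]])), con)
  write_uint(con, c(track$offset, length(track$values)), 8L)
  ch <- charToRaw(enc2utf8(track$chrom))
  write_uint(con, length(ch), 2L)
  writeBin(ch, con)
  write_payload(con, track$values, track$element)
  invisible(path)
}

# Read and validate the header; returns fields + data_offset (payload start).
read_track_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 8L)
  if (length(magic) < 8L || rawToChar(magic) != TRACK_MAGIC)
    data_error(sprintf("not a track file (bad magic): %s", path))
  meta <- as.integer(readBin(con, raw(), n = 4L))
  if (meta[1L] != TRACK_VERSION)
    data_error(sprintf("unsupported track format version %d in %s",
                       meta[1L], path))
  kind <- names(KIND_CODE)[match(meta[2L], KIND_CODE)]
  stratum <- names(STRATUM_CODE)[match(meta[4L], STRATUM_CODE)]
  if (is.na(kind) || is.na(stratum))
    data_error(sprintf("corrupt track header in %s", path))
  element <- element_spec(kind, meta[3L])
  off_len <- read_uint(con, 2L, 8L)
  nch <- read_uint(con, 1L, 2L)
  chrom <- rawToChar(readBin(con, raw(), n = nch))
  data_offset <- 8L + 4L + 16L + 2L + nch
  expected <- data_offset + off_len[2L] * element$width
  if (file.size(path) != expected)
    data_error(sprintf(
      "track payload truncated or oversized: %s (expected %s bytes, found %s)",
      path, format(expected, scientific = FALSE),
      format(file.size(path), scientific = FALSE)))
  list(chrom = chrom, stratum = stratum, element = element,
       offset = off_len[1L], length = off_len[2L], data_offset = data_offset,
       path = path)
}

#' Read a binary track from disk
#'
#' The inverse of [write_track()]; round-trips bit-exactly. The header is
#' validated (magic, version, payload size); an `element` argument, when
#' given, must match the stored element spec — a mismatch is an error, never
#' a silent reinterpretation.
#'
#' @param path Track file path.
#' @param element Optional [element_spec()] the caller expects.
#' @return A `binary_track`.
#' @export
read_track <- function(path, element = NULL) {
  h <- read_track_header(path)
  if (!is.null(element) &&
      (element$kind != h$element$kind || element$width != h$element$width))
    data_error(sprintf(
      "track %s holds %s %d-byte elements, not the requested %s %d-byte",
      path, h$element$kind, h$element$width, element$kind, element$width))
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, h$data_offset)
  values <- read_payload(con, h$length, h$element)
  new_binary_track(h$chrom, h$stratum, h$offset, values, h$element)
}

track_filename <- function(base, chrom, stratum) {
  paste(base, chrom, stratum_suffix[[stratum]], sep = ".")
}

#' Write every track of a store to a directory
#'
#' One file per (chromosome, stratum) named `<base>.<chrom>.<fwd|rev|comb>`,
#' plus `<base>.stats.txt` with the build statistics.
#'
#' @param store A `signal_store`.
#' @param dir Output directory (created if needed).
#' @param base File name stem.
#' @return Character vector of the track file paths, invisibly.
#' @export
write_store <- function(store, dir, base) {
  stopifnot(inherits(store, "signal_store"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tr in store$tracks) {
    p <- file.path(dir, track_filename(base, tr$chrom, tr$stratum))
    write_track(tr, p)
    paths <- c(paths, p)
  }
  write_stats(store$stats, file.path(dir, paste0(base, ".stats.txt")))
  invisible(paths)
}

#' Open an on-disk track collection for random access
#'
#' Reads only the headers of every `<base>.<chrom>.<fwd|rev|comb>` file in
#' `dir`; region queries then seek directly into the payloads, so lookup
#' cost is independent of track size. The returned object supports the same
#' query functions ([get_values()], [region_average()], [make_footprint()],
#' ...) as an in-memory `signal_store`.
#'
#' @param dir Directory holding the track files.
#' @param base File name stem used at [write_store()] time.
#' @return An object of class `disk_store`.
#' @export
open_store <- function(dir, base) {
  all <- list.files(dir)
  keep <- startsWith(all, paste0(base, ".")) &
    grepl("\\.(fwd|rev|comb)$", all)
  files <- file.path(dir, all[keep])
  if (length(files) == 0L)
    usage_error(sprintf("no track files matching %s.* in %s", base, dir))
  index <- lapply(files, read_track_header)
  names(index) <- vapply(index, function(h) paste(h$chrom, h$stratum, sep = ":"),
                         character(1))
  structure(list(dir = dir, base = base, index = index),
            class = "disk_store")
}

#' @export
print.disk_store <- function(x, ...) {
  cat(sprintf("<disk_store '%s' in %s: %d track(s)>\n", x$base, x$dir,
              length(x$index)))
  invisible(x)
}

#' Load an on-disk track collection fully into memory
#'
#' @param dir Directory holding the track files.
#' @param base File name stem.
#' @return A `signal_store` with all payloads in memory.
#' @export
read_store <- function(dir, base) {
  ds <- open_store(dir, base)
  tracks <- lapply(ds$index, function(h) read_track(h$path))
  element <- tracks[[1L]]$element
  stats_path <- file.path(dir, paste0(base, ".stats.txt"))
  stats <- if (file.exists(stats_path)) read_stats(stats_path) else empty_stats()
  structure(list(tracks = tracks, stats = stats, element = element,
                 prolong = NULL, starts_only = FALSE),
            class = "signal_store")
}

read_stats <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_stats())
  kv <- lapply(strsplit(lines, " ", fixed = TRUE), function(f) {
    v <- sub("^[a-z]+=", "", f)
    names(v) <- sub("=.*$", "", f)
    v
  })
  data.frame(chrom = vapply(kv, `[[`, "", "chrom"),
             stratum = vapply(kv, `[[`, "", "stratum"),
             low = as.numeric(vapply(kv, `[[`, "", "low")),
             high = as.numeric(vapply(kv, `[[`, "", "high")),
             fragments = as.numeric(vapply(kv, `[[`, "", "fragments")),
             truncated = as.integer(vapply(kv, `[[`, "", "truncated")),
             skipped = as.integer(vapply(kv, `[[`, "", "skipped")),
             stringsAsFactors = FALSE)
}
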