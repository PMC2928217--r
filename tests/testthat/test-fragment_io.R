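test_that("BED lines convert from 0-based half-open to 1-based closed", {
  r <- parse_bed("chrX\t0\t10\t.\t0\t+")
  expect_equal(r$chrom, "chrX")
  expect_equal(r$start, 1)
  expect_equal(r$end, 10)
  expect_equal(r$strand, "+")
  expect_equal(r$count, 1)

  one <- parse_bed("chr1\t5\t6")
  expect_equal(c(one$start, one$end), c(6, 6))
  expect_equal(one$strand, "+")  # strandless defaults to forward

  minus <- parse_bed("chr1\t5\t6\tx\t900\t-")
  expect_equal(minus$strand, "-")
  expect_equal(minus$count, 1)   # score never becomes multiplicity
})

test_that("malformed BED lines error with their line number", {
  expect_error(parse_bed("chr1\t9\t3", line_number = 7),
               "line 7.*inverted")
  expect_error(parse_bed("chr1\t4\t4"), "inverted")
  expect_error(parse_bed("chr1\t2"), "fewer than 3")
  expect_error(parse_bed("chr1\tx\t10"), "malformed")
})

test_that("lenient parsing skips bad lines and tallies them", {
  lines <- c("chr1\t0\t10", "chr1\t9\t3", "chr1\t10\t20")
  rec <- read_fragments(text = lines, path = NULL, format = "bed",
                        strict = FALSE)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "skipped"), 1L)
  expect_error(read_fragments(text = lines, path = NULL, format = "bed",
                              strict = TRUE),
               "line 2")
})

test_that("GFF-like parsing honours the column spec", {
  sp <- column_spec(delimiter = " ", chrom = 1, start = 2, end = 3,
                    strand = 4, count = 5)
  r <- parse_gff_like("chr2 100 104 + 3", sp)
  expect_equal(r$start, 100)       # taken as already 1-based closed
  expect_equal(r$end, 104)
  expect_equal(r$count, 3)

  nocount <- column_spec(delimiter = " ", chrom = 1, start = 2, end = 3,
                         strand = 4)
  expect_equal(parse_gff_like("chr2 100 104 + 3", nocount)$count, 1)

  expect_error(parse_gff_like("chr2 100 104 ? 3", sp),
               "strand symbol")
  expect_error(parse_gff_like("chr2 100 104 + x", sp),
               "count")
  expect_error(parse_gff_like("chr2 100", sp), "fields")

  # custom symbols and shuffled columns
  sp2 <- column_spec(delimiter = ";", chrom = 3, start = 1, end = 2,
                     strand = 4, strand_map = c(F = "+", R = "-"))
  r2 <- parse_gff_like("7;9;chrZ;R", sp2)
  expect_equal(r2[, c("chrom", "start", "end", "strand")],
               data.frame(chrom = "chrZ", start = 7, end = 9, strand = "-",
                          stringsAsFactors = FALSE))
})

test_that("SAM records map flags and CIGAR reference span correctly", {
  sam <- function(flag, pos, cigar)
    sprintf("r\t%d\tchr1\t%d\t60\t%s\t*\t0\t0\t*\t*", flag, pos, cigar)
  r <- parse_sam(sam(0, 100, "10M"))
  expect_equal(c(r$start, r$end), c(100, 109))
  expect_equal(r$strand, "+")

  r <- parse_sam(sam(16, 100, "5M3I5M"))   # insertions consume no reference
  expect_equal(c(r$start, r$end), c(100, 109))
  expect_equal(r$strand, "-")

  expect_equal(nrow(parse_sam(sam(4, 100, "10M"))), 0L)  # unmapped skipped
  expect_equal(nrow(parse_sam("@HD\tVN:1.6")), 0L)       # header skipped
  expect_warning(out <- parse_sam(sam(0, 100, "*")), "CIGAR")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "no_cigar"), 1L)
})

test_that("CIGAR reference span agrees with an independent walker", {
  cigars <- c("10M", "5M3I5M", "2S8M", "3M2D3N4M", "50M", "1M1D1M1I1M",
              "10H5=3X2M")
  expect_equal(seqfoot:::cigar_ref_span(cigars),
               vapply(cigars, oracle_cigar_span, numeric(1), USE.NAMES = FALSE))
})

test_that("WIG fixedStep/variableStep expand positions and spans", {
  fx <- parse_wig(c("fixedStep chrom=chr1 start=10 step=1", "1", "2", "3"))
  expect_equal(fx$pos, c(10, 11, 12))
  expect_equal(fx$value, c(1, 2, 3))

  vs <- parse_wig(c("track type=wiggle_0", "variableStep chrom=chr1 span=3",
                    "100 2.0"))
  expect_equal(vs$pos, 100:102)
  expect_equal(vs$value, rep(2, 3))

  # step=5, span=5: two values tile 10..14 and 15..19
  st <- parse_wig(c("fixedStep chrom=chr1 start=10 step=5 span=5", "1", "1"))
  expect_equal(st$pos, 10:19)
  expect_equal(st$value, rep(1, 10))

  expect_error(parse_wig(c("42", "fixedStep chrom=chr1 start=1 step=1")),
               "before any")
})

test_that("serialize/re-parse round-trips records across all formats", {
  set.seed(42)
  rec <- gen_fragments(60, c(chrA = 5000, chrB = 3000), seed = 11)
  canon <- function(r) {
    r <- r[order(r$chrom, r$start, r$end, r$strand), ]
    rownames(r) <- NULL
    r
  }
  for (fmt in c("bed", "gff", "sam")) {
    path <- withr::local_tempfile()
    write_fragments(rec, path, fmt)
    back <- read_fragments(path, fmt)
    expect_equal(canon(back), canon(rec), ignore_attr = TRUE,
                 label = sprintf("round trip via %s", fmt))
  }
  # record-level BED round trip
  one <- fragment_records("chr9", 123, 456, "-")
  expect_equal(parse_bed(emit_bed(one)), one, ignore_attr = TRUE)
})

test_that("counts > 1 survive GFF round trips and expand in BED/SAM", {
  rec <- fragment_records("chr1", c(10, 50), c(20, 60), c("+", "-"),
                          count = c(3, 1))
  sp <- column_spec(count = 5L)
  back <- read_fragments(text = emit_gff_like(rec, sp), path = NULL,
                         format = "gff", spec = sp)
  expect_equal(back, rec, ignore_attr = TRUE)
  expect_length(emit_bed(rec), 4L)          # 3 + 1 unit-count lines
  expect_error(emit_bed(fragment_records("c", 1, 5, "+", 1.5)),
               "fractional")
})

test_that("BED and WIG parsing agree with rtracklayer's importers", {
  suppressPackageStartupMessages(library(rtracklayer))
  bed <- c("chr1\t0\t10\tn1\t0\t+", "chr1\t99\t200\tn2\t0\t-",
           "chr2\t5\t6\tn3\t0\t+")
  bp <- withr::local_tempfile(fileext = ".bed")
  writeLines(bed, bp)
  gr <- rtracklayer::import(bp, format = "BED")
  ours <- read_fragments(bp, "bed")
  expect_equal(ours$start, BiocGenerics::start(gr))
  expect_equal(ours$end, BiocGenerics::end(gr))
  expect_equal(ours$strand, as.character(BiocGenerics::strand(gr)))

  wig <- c("fixedStep chrom=chr1 start=10 step=2 span=2", "1.5", "2.5",
           "variableStep chrom=chr2 span=1", "7 4")
  wp <- withr::local_tempfile(fileext = ".wig")
  writeLines(wig, wp)
  wgr <- rtracklayer::import(wp, format = "WIG")
  ref <- data.frame(
    chrom = rep(as.character(GenomeInfoDb::seqnames(wgr)),
                BiocGenerics::width(wgr)),
    pos = unlist(mapply(seq, BiocGenerics::start(wgr), BiocGenerics::end(wgr),
                        SIMPLIFY = FALSE)),
    value = rep(wgr$score, BiocGenerics::width(wgr)))
  ours <- parse_wig(wig)
  ours <- ours[order(ours$chrom, ours$pos), ]
  ref <- ref[order(ref$chrom, ref$pos), ]
  expect_equal(ours$pos, ref$pos)
  expect_equal(ours$value, ref$value)
})
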