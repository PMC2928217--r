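test_that("single and overlapping fragments pile up correctly", {
  st <- build_tracks(fragment_records("chr1", 10, 14))
  tr <- st$tracks[["chr1:forward"]]
  expect_equal(tr$offset, 10)
  expect_equal(tr$values, rep(1, 5))

  st2 <- build_tracks(fragment_records("chr1", c(10, 12), c(14, 20)))
  v <- get_values(st2, "chr1", "forward", 10, 20)
  expect_equal(v, c(1, 1, 2, 2, 2, 1, 1, 1, 1, 1, 1))
})

test_that("reverse fragments prolong from their 5' (high-coordinate) end", {
  st <- build_tracks(fragment_records("chr1", 20, 29, "-"), prolong = 5)
  comb <- st$tracks[["chr1:combined"]]
  expect_equal(comb$offset, 25)
  expect_equal(comb$values, rep(1, 5))   # covers 25..29 only
  # clipping at coordinate 1
  st2 <- build_tracks(fragment_records("chr1", 1, 3, "-"), prolong = 10)
  expect_equal(st2$tracks[["chr1:combined"]]$offset, 1)
  expect_equal(get_values(st2, "chr1", "combined", 1, 3), rep(1, 3))
})

test_that("unsigned elements saturate at 2^(8*width)-1 and tally truncation", {
  expect_equal(element_states(element_spec()), 65536)
  st <- build_tracks(fragment_records("chr1", 100, 100, "+", count = 70000))
  expect_equal(get_values(st, "chr1", "forward", 100, 100), 65535)
  expect_equal(build_stats(st)$truncated, 1L)

  # 1-byte element saturates at 255; float never saturates
  st8 <- build_tracks(fragment_records("chr1", 100, 101, "+", count = 300),
                      element = element_spec("uint", 1))
  expect_equal(get_values(st8, "chr1", "forward", 100, 101), c(255, 255))
  expect_equal(build_stats(st8)$truncated, 2L)
  stf <- build_tracks(fragment_records("chr1", 100, 100, "+", count = 70000),
                      element = element_spec("float", 8))
  expect_equal(get_values(stf, "chr1", "forward", 100, 100), 70000)
  expect_equal(build_stats(stf)$truncated, 0L)
})

test_that("payload size arithmetic matches the dense-per-base layout", {
  expect_equal(payload_size(250e6, element_spec()), 500e6)
  expect_equal(3 * payload_size(250e6, element_spec()), 1.5e9)
  expect_equal(payload_size(0), 0)
  expect_equal(payload_size(100, element_spec("float", 8)), 800)
})

test_that("coverage conservation holds with and without starts-only", {
  rec <- gen_fragments(400, c(chrA = 2e4, chrB = 1e4), seed = 3,
                       count = 2)
  st <- build_tracks(rec)
  total <- sum(vapply(st$tracks, function(t) sum(t$values), numeric(1)))
  expect_equal(total, sum(rec$count * (rec$end - rec$start + 1)))
  sto <- build_tracks(rec, starts_only = TRUE)
  expect_equal(sum(vapply(sto$tracks, function(t) sum(t$values), numeric(1))),
               sum(rec$count))
})

test_that("prolongation commutes with accumulation", {
  rec <- gen_fragments(300, c(chrA = 5e4), seed = 9)
  L <- 80
  st <- build_tracks(rec, prolong = L)
  # pre-prolong by hand, then build without prolongation and sum strands
  pre <- rec
  pre$start <- ifelse(rec$strand == "+", rec$start,
                      pmax(1, rec$end - L + 1))
  pre$end <- ifelse(rec$strand == "+", rec$start + L - 1, rec$end)
  stp <- build_tracks(pre)
  lo <- min(pre$start); hi <- max(pre$end)
  expect_equal(get_values(st, "chrA", "combined", lo, hi),
               get_values(stp, "chrA", "forward", lo, hi) +
                 get_values(stp, "chrA", "reverse", lo, hi))
})

test_that("built tracks equal the naive per-base oracle everywhere", {
  chrlen <- c(chrT = 1e5)
  rec <- gen_fragments(1000, chrlen, seed = 271)
  for (L in list(NULL, 50, 200)) {
    for (so in c(FALSE, TRUE)) {
      st <- build_tracks(rec, prolong = L, starts_only = so)
      strata <- c("forward", "reverse", if (!is.null(L)) "combined")
      for (stratum in strata) {
        got <- get_values(st, "chrT", stratum, 1, chrlen)
        want <- oracle_pileup(rec, "chrT", stratum, prolong = L,
                              starts_only = so, cap = 65535,
                              max_coord = chrlen)
        expect_equal(got, want,
                     label = sprintf("stratum %s, prolong %s, starts_only %s",
                                     stratum, deparse(L), so))
      }
    }
  }
})

test_that("fractional WIG-style signal rounds half-to-even for uint elements", {
  rec <- fragment_records("chr1", c(5, 6, 7), c(5, 6, 7), "+",
                          count = c(0.5, 1.5, 2.4))
  st <- build_tracks(rec)
  expect_equal(get_values(st, "chr1", "forward", 5, 7), c(0, 2, 2))
  stf <- build_tracks(rec, element = element_spec("float", 4))
  expect_equal(get_values(stf, "chr1", "forward", 5, 7), c(0.5, 1.5, 2.4),
               tolerance = 1e-6)   # stored as 4-byte floats
})

test_that("track files round-trip bit-exactly and persistence is idempotent", {
  rec <- gen_fragments(200, c(chrA = 1e4, chrB = 5e3), seed = 5)
  for (el in list(element_spec("uint", 1), element_spec("uint", 2),
                  element_spec("uint", 4), element_spec("uint", 8),
                  element_spec("float", 8))) {
    st <- build_tracks(rec, prolong = 100, element = el)
    dir1 <- withr::local_tempdir()
    dir2 <- withr::local_tempdir()
    write_store(st, dir1, "t")
    back <- read_store(dir1, "t")
    for (key in names(st$tracks))
      expect_equal(back$tracks[[key]][c("chrom", "stratum", "offset", "values")],
                   st$tracks[[key]][c("chrom", "stratum", "offset", "values")],
                   label = sprintf("%s (%s-%d)", key, el$kind, el$width))
    # two write/read cycles equal one, byte for byte
    write_store(back, dir2, "t")
    for (f in list.files(dir1))
      expect_identical(readBin(file.path(dir1, f), raw(), 1e6),
                       readBin(file.path(dir2, f), raw(), 1e6))
  }
})

test_that("large stored values survive wide-element round trips", {
  rec <- fragment_records("chr1", c(1, 1), c(1, 1), "+",
                          count = c(3e9, 2^33))
  st <- build_tracks(rec, element = element_spec("uint", 8))
  d <- withr::local_tempdir()
  write_store(st, d, "big")
  expect_equal(get_values(open_store(d, "big"), "chr1", "forward", 1, 1),
               3e9 + 2^33)
  st4 <- build_tracks(fragment_records("chr1", 1, 1, "+", count = 3e9),
                      element = element_spec("uint", 4))
  write_store(st4, d, "u4")
  expect_equal(get_values(open_store(d, "u4"), "chr1", "forward", 1, 1), 3e9)
})

test_that("corrupt or mismatched track files error instead of misreading", {
  st <- build_tracks(fragment_records("chr1", 10, 20))
  d <- withr::local_tempdir()
  p <- file.path(d, "x.chr1.fwd")
  write_track(st$tracks[[1]], p)
  expect_s3_class(read_track(p), "binary_track")

  # truncated payload
  raw <- readBin(p, raw(), file.size(p))
  writeBin(raw[1:(length(raw) - 3)], p)
  expect_error(read_track(p), "truncated")

  # bad magic
  writeBin(c(charToRaw("NOTATRAK"), raw[-(1:8)]), p)
  expect_error(read_track(p), "magic")

  # element width mismatch must not silently reinterpret
  write_track(st$tracks[[1]], p)
  expect_error(read_track(p, element = element_spec("uint", 4)),
               "not the requested")
})

test_that("the stats file reports extremes, counts and truncations", {
  rec <- fragment_records("chr1", c(10, 100), c(14, 100), c("+", "-"),
                          count = c(2, 70000))
  st <- build_tracks(rec)
  d <- withr::local_tempdir()
  write_store(st, d, "s")
  stats <- seqfoot:::read_stats(file.path(d, "s.stats.txt"))
  fwd <- stats[stats$stratum == "forward", ]
  rev <- stats[stats$stratum == "reverse", ]
  expect_equal(c(fwd$low, fwd$high, fwd$fragments, fwd$truncated),
               c(10, 14, 2, 0))
  expect_equal(c(rev$low, rev$high, rev$fragments, rev$truncated),
               c(100, 100, 70000, 1))
})
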