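test_that("depth-TSV and bedGraph dialects parse correctly", {
  p <- write_tmp(c("chrI\t1\t10", "chrI\t2\t12"), ".tsv")
  tr <- read_depth(p, "depth-tsv")
  expect_equal(tr$pos, c(1L, 2L))
  expect_equal(tr$depth, c(10, 12))

  bg <- write_tmp(c("track type=bedGraph", "chrI\t0\t5\t7"), ".bedgraph")
  tb <- read_depth(bg)
  expect_equal(tb$pos, 1:5)
  expect_equal(tb$depth, rep(7, 5))

  empty <- write_tmp(character(), ".tsv")
  expect_warning(te <- read_depth(empty, "depth-tsv"), "no depth records")
  expect_equal(nrow(te), 0)
})

test_that("parse errors name the offending line", {
  p <- write_tmp(c("# a header", "chrI\t1\t10", "chrI\t2"), ".tsv")
  expect_error(read_depth(p, "depth-tsv"), "line 3")
  p2 <- write_tmp(c("chrI\t1\t10", "chrI\t1\t11"), ".tsv")
  expect_error(read_depth(p2, "depth-tsv"), "non-monotone.*line 2")
  p3 <- write_tmp(c("chrI\t1\t-4"), ".tsv")
  expect_error(read_depth(p3, "depth-tsv"), "negative depth at line 1")
  # CRLF endings are tolerated
  p4 <- tempfile(fileext = ".tsv")
  writeLines(c("chrI\t1\t10\r", "chrI\t2\t11\r"), p4, sep = "\n")
  expect_equal(read_depth(p4, "depth-tsv")$depth, c(10, 11))
})

test_that("binning tiles the sequence and averages over bin width", {
  tr <- flat_track("chrA", 10L, 4)
  b <- bin_track(tr, 4L, c(chrA = 10))
  expect_equal(b$start, c(0L, 4L, 8L))
  expect_equal(b$end, c(4L, 8L, 10L))
  expect_equal(b$width, c(4L, 4L, 2L))
  expect_true(all(b$depth == 4))

  tr2 <- depth_track(rep("chrA", 10), 1:10, 1:10)
  b2 <- bin_track(tr2, 5L, c(chrA = 10))
  expect_equal(b2$depth, c(3, 8))

  # absent positions count as zero
  tr3 <- depth_track("chrA", 1L, 10)
  b3 <- bin_track(tr3, 5L, c(chrA = 10))
  expect_equal(b3$depth, c(2, 0))

  expect_error(bin_track(tr2, 5L, c(chrA = 8)), "smaller than max observed")
})

test_that("genome mean is width-weighted and honors masks", {
  b <- bin_track(flat_track("chrA", 10000L, 30), 1000L, c(chrA = 10000))
  expect_equal(genome_mean_depth(b), 30)

  # two sequences, equal width, means 20 and 40 -> 30
  t2 <- depth_track(rep(c("chrA", "chrB"), each = 1000),
                    c(1:1000, 1:1000), c(rep(20, 1000), rep(40, 1000)))
  b2 <- bin_track(t2, 100L, c(chrA = 1000, chrB = 1000))
  expect_equal(genome_mean_depth(b2), 30)

  # one disomic 10% of the genome at 2x30, rest at 30 -> 33
  t3 <- depth_track(rep(c("chrA", "chrB"), c(9000, 1000)),
                    c(1:9000, 1:1000), c(rep(30, 9000), rep(60, 1000)))
  b3 <- bin_track(t3, 100L, c(chrA = 9000, chrB = 1000))
  expect_equal(genome_mean_depth(b3), 33)

  # plasmid sequences never contribute
  expect_equal(genome_mean_depth(b3, plasmid_sequences = "chrB"), 30)
  # masking all bins is an error
  expect_error(genome_mean_depth(b, exclude = region_mask("chrA", 0L, 10000L)),
               "all bins are masked")
  # empty mask equals the plain weighted mean
  expect_equal(genome_mean_depth(b3, exclude = region_mask()),
               genome_mean_depth(b3))
})

test_that("normalization yields euploid expectation 1 and is exact division", {
  b <- bin_track(flat_track("chrA", 5000L, 30), 1000L, c(chrA = 5000))
  n <- normalize_track(b, 30)
  expect_true(all(n$depth == 1))
  n2 <- normalize_track(profile_from_values(c(15, 45), genome_mean = NA), 30)
  expect_equal(n2$depth, c(0.5, 1.5))
})

test_that("normalized values are invariant to global depth rescaling", {
  set.seed(42)
  for (c_mult in c(0.5, 2, 7.3)) {
    d <- rpois(2000, 30)
    tr <- depth_track(rep("chrA", 2000), 1:2000, d)
    trc <- depth_track(rep("chrA", 2000), 1:2000, d * c_mult)
    b <- bin_track(tr, 100L, c(chrA = 2000))
    bc <- bin_track(trc, 100L, c(chrA = 2000))
    n <- normalize_track(b, genome_mean_depth(b))
    nc <- normalize_track(bc, genome_mean_depth(bc))
    expect_equal(n$depth, nc$depth)
  }
})

test_that("write-then-read round-trips at bin resolution", {
  set.seed(7)
  tr <- depth_track(rep("chrA", 3000), 1:3000, rpois(3000, 25))
  b <- bin_track(tr, 500L, c(chrA = 3000))
  # bedGraph keeps exact intervals
  p <- tempfile(fileext = ".bedgraph")
  write_depth(b, p, "bedgraph")
  b2 <- bin_track(read_depth(p), 500L, c(chrA = 3000))
  expect_equal(b2$depth, b$depth)
  # per-base depth-TSV round-trips exactly
  p2 <- tempfile(fileext = ".tsv")
  write_depth(tr, p2, "depth-tsv")
  tr2 <- read_depth(p2, "depth-tsv")
  expect_equal(tr2$depth, tr$depth)
  expect_equal(tr2$pos, tr$pos)
})

test_that("region masks merge, complement and measure correctly", {
  m <- region_mask(rep("chrA", 3), c(10L, 5L, 50L), c(20L, 12L, 60L))
  expect_equal(nrow(m), 2)  # [5,20) and [50,60)
  expect_equal(mask_width(m), 25)
  expect_true(in_mask(m, "chrA", 6))
  expect_false(in_mask(m, "chrA", 21))
  comp <- mask_complement(m, "chrA", 100L)
  expect_equal(comp$start, c(0L, 20L, 60L))
  expect_equal(comp$end, c(5L, 50L, 100L))
  # BED round trip
  p <- tempfile(fileext = ".bed")
  write_bed_mask(m, p)
  expect_equal(read_bed_mask(p)$start, m$start)
})
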