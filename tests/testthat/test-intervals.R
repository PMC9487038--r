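test_that("BED and GFF3 records map to 0-based half-open ranges", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tA\t0\t+", bed)
  r <- read_annotation(bed, "bed")
  expect_equal(r$chrom, "chr1")
  expect_equal(r$start, 10L)
  expect_equal(r$end, 20L)
  expect_equal(r$strand, "+")
  expect_equal(r$name, "A")

  gff <- tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1", gff)
  g <- read_annotation(gff, "gff3")
  expect_equal(g$start, 10L)
  expect_equal(g$end, 20L)
  expect_equal(g$name, "g1")

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", bad)
  expect_error(read_annotation(bad, "bed"), "start >= end")

  # unknown strand becomes '.'
  writeLines("chr1\t5\t9\tB\t0\t?", bed)
  expect_equal(read_annotation(bed, "bed")$strand, ".")
})

test_that("canonical 6-column BED round-trips byte-identically", {
  lines <- c("chr1\t10\t20\tA\t0\t+", "chr1\t30\t45\tB\t5\t-",
             "chr2\t0\t7\tC\t0\t.")
  p1 <- tempfile(fileext = ".bed")
  writeLines(lines, p1)
  p2 <- tempfile(fileext = ".bed")
  write_bed(read_annotation(p1, "bed"), p2)
  expect_identical(readLines(p2), lines)
})

test_that("merge_close merges transitively under a strict distance rule", {
  x <- granges(c("chr1", "chr1"), c(0, 15), c(10, 25))
  m6 <- merge_close(x, 6)
  expect_equal(nrow(m6), 1)
  expect_equal(c(m6$start, m6$end), c(0, 25))

  m5 <- merge_close(x, 5)  # gap of 5 is not < 5
  expect_equal(nrow(m5), 2)

  single <- granges("chr1", 3, 9)
  expect_equal(merge_close(single, 100)$end, 9)

  expect_error(merge_close(granges(c("chr1", "chr2"), c(0, 0), c(5, 5)), 1),
               "single chromosome")

  # overlapping/abutting ranges merge even with max_dist = 0
  ab <- merge_close(granges(c("chr1", "chr1"), c(0, 10), c(10, 20)), 0)
  expect_equal(nrow(ab), 1)

  # oracle + idempotence on random sets
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:60, n, replace = TRUE)
    d <- sample(0:50, 1)
    got <- merge_close(granges(rep("chr1", n), s, e), d)
    exp <- merge_enum(s, e, d)
    expect_equal(cbind(got$start, got$end), unname(exp))
    again <- merge_close(got, d)
    expect_equal(again[c("start", "end")], got[c("start", "end")])
    # pairwise gaps in output are >= d
    if (nrow(got) > 1) expect_true(all(diff(got$start) - range_width(got)[-nrow(got)] >= d))
  }
})

test_that("flank clamps to chromosome bounds and composes", {
  cs <- c(chr1 = 1000)
  mid <- flank_ranges(gr1("chr1", 100, 200), 50, cs)
  expect_equal(c(mid$start, mid$end), c(50L, 250L))
  expect_equal(flank_ranges(gr1("chr1", 10, 20), 50, cs)$start, 0L)
  expect_equal(flank_ranges(gr1("chr1", 10, 20), 50, cs)$end, 70L)
  expect_equal(flank_ranges(gr1("chr1", 980, 990), 50, cs)$end, 1000L)
  expect_equal(flank_ranges(gr1("chr1", 980, 990), 50, cs)$start, 930L)
  expect_error(flank_ranges(gr1("chrX", 1, 2), 5, cs), "absent")

  # composition away from edges
  set.seed(7)
  for (i in 1:20) {
    r <- gr1("chr1", sample(300:500, 1), sample(510:700, 1))
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    expect_equal(
      flank_ranges(flank_ranges(r, a, cs), b, cs)[c("start", "end")],
      flank_ranges(r, a + b, cs)[c("start", "end")])
  }
})

test_that("jaccard and overlap coefficient match base enumeration", {
  a <- gr1("chr1", 0, 10); b <- gr1("chr1", 5, 20)
  expect_equal(range_jaccard(a, a), 1.0)
  expect_equal(range_jaccard(a, gr1("chr1", 50, 60)), 0.0)
  expect_equal(range_jaccard(a, b), 0.25)
  expect_equal(range_overlap_coefficient(a, b), 0.5)
  expect_equal(range_overlap_coefficient(gr1("chr1", 0, 10),
                                          gr1("chr1", 0, 100)), 1.0)
  expect_equal(range_overlap_coefficient(a, gr1("chr1", 50, 60)), 0.0)
  expect_equal(range_jaccard(a, gr1("chr2", 0, 10)), 0.0)

  set.seed(11)
  for (i in 1:100) {
    a <- gr1("chr1", s <- sample(0:80, 1), s + sample(1:40, 1))
    b <- gr1("chr1", t <- sample(0:80, 1), t + sample(1:40, 1))
    expect_equal(range_jaccard(a, b), jaccard_enum(a, b))
    expect_equal(range_overlap_coefficient(a, b), overlap_enum(a, b))
    expect_equal(range_jaccard(a, b), range_jaccard(b, a))
    expect_equal(range_overlap_coefficient(a, b),
                 range_overlap_coefficient(b, a))
    expect_lte(range_jaccard(a, b), range_overlap_coefficient(a, b))
  }
})

test_that("shuffled background ranges respect exclusions, seed and lengths", {
  ann <- annotation_set(
    granges(rep(c("c1", "c2"), each = 5),
            rep(seq(0, 4000, 1000), 2),
            rep(seq(0, 4000, 1000), 2) + rep(c(100, 300), 5),
            name = sprintf("r%d", 1:10)),
    c(c1 = 10000, c2 = 20000))

  s1 <- sample_shuffled_ranges(ann, 25, seed = 99)
  s2 <- sample_shuffled_ranges(ann, 25, seed = 99)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_shuffled_ranges(ann, 25, seed = 100)))
  expect_equal(nrow(s1), 25)
  # lengths are resampled annotation lengths
  expect_true(all(range_width(s1) %in% c(100, 300)))

  excl <- granges("c1", 0, 10000)  # whole first chromosome
  s3 <- sample_shuffled_ranges(ann, 40, exclusions = excl, seed = 1)
  expect_false(any(overlaps_any(s3, excl)))
  expect_true(all(s3$chrom == "c2"))

  whole <- granges(c("c1", "c2"), c(0, 0), c(10000, 20000))
  expect_error(sample_shuffled_ranges(ann, 5, exclusions = whole, seed = 1),
               "attempts")

  # law of large numbers on mean length
  big <- sample_shuffled_ranges(ann, 1000, seed = 5)
  expect_lt(abs(mean(range_width(big)) - mean(range_width(ann$ranges))),
            0.05 * mean(range_width(ann$ranges)))
})

test_that("annotation_set validates bounds and orders deterministically", {
  expect_error(annotation_set(granges("c1", 0, 50), c(c1 = 20)), "beyond")
  expect_error(annotation_set(granges("cX", 0, 5), c(c1 = 20)), "absent")
  shuffled <- granges(c("c2", "c1", "c1"), c(5, 9, 2), c(8, 12, 4))
  a <- annotation_set(shuffled, c(c1 = 100, c2 = 100))
  expect_equal(a$ranges$chrom, c("c1", "c1", "c2"))
  expect_equal(a$ranges$start, c(2L, 9L, 5L))
})
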