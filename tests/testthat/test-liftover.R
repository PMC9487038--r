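write_chain_text <- function(lines) {
  p <- tempfile(fileext = ".chain")
  writeLines(lines, p)
  p
}

test_that("chain files parse, validate block sums and accept gzip", {
  p <- write_chain_text(c("chain 100 chr1 1000 + 0 1000 chrA 1000 + 0 1000 1",
                          "1000", ""))
  ch <- parse_chain_file(p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 1)
  expect_equal(ch[[1]]$t_end, 1000L)

  bad <- write_chain_text(c("chain 100 chr1 1000 + 0 1000 chrA 1000 + 0 1000 7",
                            "900", ""))
  expect_error(parse_chain_file(bad), "chain 7")

  short_hdr <- write_chain_text(c("chain 100 chr1 1000 + 0 1000 chrA 1000 + 0 1000",
                                  "1000", ""))
  expect_error(parse_chain_file(short_hdr), "12 tokens")

  gz <- tempfile(fileext = ".chain.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(p), con)
  close(con)
  expect_identical(parse_chain_file(gz), ch)
})

test_that("chain write/parse round-trips", {
  set.seed(3)
  chains <- list(random_chain(id = 1L), random_chain(q_strand = "-", id = 2L))
  p <- tempfile(fileext = ".chain")
  write_chain_file(chains, p)
  back <- parse_chain_file(p)
  for (i in 1:2) {
    expect_equal(back[[i]]$blocks, chains[[i]]$blocks,
                 ignore_attr = FALSE)
    expect_equal(back[[i]]$q_strand, chains[[i]]$q_strand)
    expect_equal(back[[i]]$t_start, chains[[i]]$t_start)
  }
})

test_that("lift through an identity chain is the identity map", {
  ch <- list(identity_chain(1000))
  r <- gr1("chr1", 10, 20, "+", "x")
  l <- lift_range(r, ch)
  expect_equal(nrow(l), 1)
  expect_equal(l$chrom, "chrA")
  expect_equal(c(l$start, l$end), c(10L, 20L))
  expect_equal(l$match_fraction, 1.0)
  expect_equal(l$strand, "+")
})

test_that("minMatch filters lifts by mapped fraction, monotonically", {
  # 100-bp range, only a 4-bp block maps: fraction 0.04
  ch <- list(list(score = 1, t_name = "chr1", t_size = 500L, t_strand = "+",
                  t_start = 50L, t_end = 54L, q_name = "chrA", q_size = 500L,
                  q_strand = "+", q_start = 10L, q_end = 14L, chain_id = 1L,
                  blocks = matrix(c(4L, 0L, 0L), 1,
                                  dimnames = list(NULL, c("size", "dt", "dq")))))
  r <- gr1("chr1", 0, 100, "+")
  expect_equal(nrow(lift_range(r, ch, min_match = 0.05)), 0)
  low <- lift_range(r, ch, min_match = 0.03)
  expect_equal(nrow(low), 1)
  expect_equal(low$match_fraction, 0.04)

  # lowering min_match never reduces the number of lifted regions
  set.seed(21)
  chains <- lapply(1:5, function(i) random_chain(id = i))
  for (i in 1:30) {
    r <- gr1("chr1", s <- sample(0:150, 1), s + sample(5:80, 1))
    counts <- vapply(c(0.8, 0.4, 0.2, 0.05, 0.01),
                     function(mm) nrow(lift_range(r, chains, mm)), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("a range spanning a target gap maps only its in-block bases", {
  ch <- list(list(score = 1, t_name = "chr1", t_size = 100L, t_strand = "+",
                  t_start = 0L, t_end = 20L, q_name = "chrA", q_size = 100L,
                  q_strand = "+", q_start = 0L, q_end = 10L, chain_id = 1L,
                  blocks = matrix(c(5L, 10L, 0L, 5L, 0L, 0L), 2, byrow = TRUE,
                                  dimnames = list(NULL, c("size", "dt", "dq")))))
  r <- gr1("chr1", 0, 20, "+")
  l <- lift_range(r, ch, min_match = 0.05)
  expect_equal(l$matched_bases, 10L)
  o <- lift_oracle(r, ch[[1]])
  expect_equal(l$matched_bases, o$matched)
  expect_equal(c(l$start, l$end), c(o$start, o$end))
})

test_that("lift_range agrees with the per-base block-walking oracle", {
  set.seed(1234)
  n_checked <- 0
  for (trial in 1:120) {
    strand <- sample(c("+", "-"), 1)
    ch <- random_chain(q_strand = strand, id = trial)
    for (k in 1:9) {
      s <- sample(0:(ch$t_size - 5), 1)
      r <- gr1("chr1", s, s + sample(4:60, 1), sample(c("+", "-", "."), 1))
      got <- lift_range(r, list(ch), min_match = 1e-9)
      o <- lift_oracle(r, ch)
      if (o$matched == 0) {
        expect_equal(nrow(got), 0)
      } else {
        n_checked <- n_checked + 1
        expect_equal(got$matched_bases, o$matched)
        expect_equal(c(got$start, got$end), c(o$start, o$end))
        expect_equal(got$match_fraction, o$matched / (r$end - r$start))
      }
    }
  }
  expect_gt(n_checked, 500)
})

test_that("lifting back through the inverted chain recovers mapped bases", {
  set.seed(55)
  for (trial in 1:40) {
    ch <- random_chain(id = trial)  # plus strand
    inv <- invert_chain(ch)
    s <- sample(ch$t_start:(ch$t_end - 10), 1)
    r <- gr1("chr1", s, s + sample(5:40, 1), "+")
    fwd <- lift_range(r, list(ch), min_match = 1e-9)
    if (nrow(fwd) == 0) next
    back <- lift_range(gr1(ch$q_name, fwd$start, fwd$end, "+"), list(inv),
                       min_match = 1e-9)
    expect_equal(nrow(back), 1)
    # the returned interval contains every block-mapped base of the original
    mapped <- vapply(seq(r$start, r$end - 1), function(p) {
      synorth:::map_base_through_chain(p, ch)
    }, integer(1))
    mapped_src <- seq(r$start, r$end - 1)[!is.na(mapped)]
    expect_true(all(mapped_src >= back$start & mapped_src < back$end))
  }
})

test_that("syntenies merge lifted duplications and respect strand groups", {
  lifted <- rbind(
    lift_range(gr1("chr1", 100, 200, "+", "x"), list(identity_chain(100000))),
    lift_range(gr1("chr1", 300, 400, "+", "x"), list(identity_chain(100000))))
  cs <- c(chrA = 100000)
  one <- build_syntenies(lifted, merge_dist = 1000, flank_len = 0, cs)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(100L, 400L))

  two <- build_syntenies(lifted, merge_dist = 50, flank_len = 0, cs)
  expect_equal(nrow(two), 2)

  flanked <- build_syntenies(lifted, merge_dist = 1000, flank_len = 500, cs)
  expect_equal(c(flanked$start, flanked$end), c(0L, 900L))

  expect_equal(nrow(build_syntenies(synorth:::empty_lifted(), 10, 10, cs)), 0)

  # opposite-strand lifts never merge
  opp <- lifted
  opp$strand <- c("+", "-")
  expect_equal(nrow(build_syntenies(opp, merge_dist = 1000, flank_len = 0, cs)),
               2)
})
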