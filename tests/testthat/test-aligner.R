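test_that("extract_sequence honors strand and bounds", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT", chr2 = "AAACGGGT"))
  expect_equal(extract_sequence(g, gr1("chr1", 0, 4, "+")), "ACGT")
  # palindromic reverse complement, then a non-palindromic case
  expect_equal(extract_sequence(g, gr1("chr1", 0, 4, "-")), "ACGT")
  expect_equal(extract_sequence(g, gr1("chr2", 0, 4, "-")), "GTTT")
  expect_error(extract_sequence(g, gr1("chr1", 4, 12, "+")), "out of bounds")
  expect_error(extract_sequence(g, gr1("chrX", 0, 2, "+")), "not in genome")
})

test_that("self-alignment yields one full-length HSP with the expected score", {
  set.seed(2)
  q <- rand_dna(100)
  h <- find_hsps(q, q, aligner_params(word_size = 6, match_reward = 1,
                                      mismatch_penalty = 1, min_score = 20))
  expect_equal(nrow(h), 1)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(0L, 100L, 0L, 100L))
  expect_equal(h$score, 100)
  expect_equal(h$orientation, "same")
  expect_equal(h$identity, 1)
})

test_that("reverse-complement homology is reported as opposite orientation", {
  set.seed(3)
  q <- rand_dna(40)
  h <- find_hsps(q, revcomp_chr(q), aligner_params(min_score = 20))
  top <- h[1, ]
  expect_equal(top$orientation, "opposite")
  expect_equal(c(top$q_start, top$q_end), c(0L, 40L))
  expect_equal(c(top$s_start, top$s_end), c(0L, 40L))
  expect_equal(top$score, 40)
})

test_that("HSP scores are self-consistent with the reported intervals", {
  set.seed(4)
  for (trial in 1:25) {
    q <- rand_dna(300)
    # subject shares a mutated 120-bp window with the query
    core <- substr(q, 101, 220)
    core_chars <- strsplit(core, "")[[1]]
    hit <- which(runif(120) < 0.1)
    for (i in hit) core_chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   core_chars[i]), 1)
    s <- paste0(rand_dna(60), paste(core_chars, collapse = ""), rand_dna(60))
    if (trial %% 2 == 0) s <- revcomp_chr(s)
    h <- find_hsps(q, s, aligner_params())
    expect_gt(nrow(h), 0)
    for (k in seq_len(nrow(h))) {
      re <- rescore_hsp(h[k, ], q, s)
      expect_equal(h$score[k], re$score)
      expect_equal(h$identity[k] * h$aligned_length[k], re$matches)
      expect_lte(h$score[k], h$aligned_length[k])  # <= reward * length
    }
  }
})

test_that("an exact shared substring of word_size + 10 is never missed", {
  set.seed(5)
  for (trial in 1:50) {
    motif <- rand_dna(16)
    q <- paste0(rand_dna(50), motif, rand_dna(50))
    s <- paste0(rand_dna(70), motif, rand_dna(30))
    h <- find_hsps(q, s, aligner_params(word_size = 6, min_score = 16))
    covered <- any(h$orientation == "same" & h$q_start <= 50 & h$q_end >= 66 &
                     h$score >= 16)
    expect_true(covered)
  }
  # and with default reporting threshold, a 40-bp exact motif
  set.seed(6)
  for (trial in 1:20) {
    motif <- rand_dna(40)
    q <- paste0(rand_dna(30), motif)
    s <- paste0(motif, rand_dna(30))
    h <- find_hsps(q, s, aligner_params())
    expect_true(any(h$score >= 40))
  }
})

test_that("random sequence pairs almost never produce an HSP", {
  set.seed(7)
  none <- 0
  for (trial in 1:100) {
    h <- find_hsps(rand_dna(200), rand_dna(200),
                   aligner_params(min_score = 30))
    if (nrow(h) == 0) none <- none + 1
  }
  expect_gte(none, 95)
})

test_that("top HSP equals the seeded ungapped Smith-Waterman optimum", {
  set.seed(8)
  for (trial in 1:60) {
    nq <- sample(20:50, 1); ns <- sample(20:50, 1)
    q <- rand_dna(nq)
    s <- if (trial %% 3 == 0) {
      # force some shared signal
      paste0(substr(q, 1, sample(8:15, 1)), rand_dna(ns))
    } else rand_dna(ns)
    w <- 4
    opt <- sw_seeded(q, s, w)
    h <- find_hsps(q, s, aligner_params(word_size = w, xdrop = 1000,
                                        min_score = 1))
    got <- if (any(h$orientation == "same")) {
      max(h$score[h$orientation == "same"])
    } else -Inf
    if (is.infinite(opt)) {
      expect_true(is.infinite(got))
    } else {
      expect_equal(got, opt)
    }
  }
})

test_that("swapping query and subject transposes HSP coordinates", {
  set.seed(9)
  for (trial in 1:15) {
    q <- rand_dna(150)
    core <- substr(q, 40, 110)
    s <- paste0(rand_dna(25), core, rand_dna(25))
    a <- find_hsps(q, s, aligner_params())
    b <- find_hsps(s, q, aligner_params())
    a_same <- a[a$orientation == "same", c("q_start", "q_end", "s_start", "s_end", "score")]
    b_same <- b[b$orientation == "same", c("s_start", "s_end", "q_start", "q_end", "score")]
    names(b_same) <- names(a_same)
    expect_equal(a_same[order(a_same$q_start), ],
                 b_same[order(b_same$q_start), ], ignore_attr = TRUE)
  }
})

test_that("N never seeds or matches and junk alphabets are rejected", {
  q <- paste(rep("N", 60), collapse = "")
  set.seed(10)
  h <- find_hsps(q, rand_dna(100), aligner_params(min_score = 6))
  expect_equal(nrow(h), 0)
  expect_error(find_hsps("ACGTXXXXXXXX", "ACGTACGTAAAA", aligner_params()),
               "degenerate")
})

test_that("tabular 12-column HSPs convert coordinates and orientation", {
  p <- tempfile()
  writeLines(c(
    "q1\ts1\t95.0\t10\t0\t0\t1\t10\t5\t14\t1e-5\t19.1",
    "q1\ts1\t90.0\t10\t1\t0\t3\t12\t20\t11\t1e-4\t15.5"), p)
  h <- parse_tabular_hsps(p)
  expect_equal(c(h$q_start[1], h$q_end[1]), c(0L, 10L))
  expect_equal(c(h$s_start[1], h$s_end[1]), c(4L, 14L))
  expect_equal(h$orientation, c("same", "opposite"))
  expect_equal(c(h$s_start[2], h$s_end[2]), c(10L, 20L))
  expect_equal(h$score, c(19.1, 15.5))

  off <- parse_tabular_hsps(p, query_offset = gr1("chr1", 1000, 2000),
                            subject_offset = gr1("chrA", 500, 1500))
  expect_equal(off$q_start[1], 1000L)
  expect_equal(off$s_start[1], 504L)

  bad <- tempfile()
  writeLines("q1\ts1\t95\t10\t0\t0\t1\t10\t5\t14\t1e-5", bad)
  expect_error(parse_tabular_hsps(bad), "expected 12")
})

test_that("pruning keeps whole HSPs overlapping the lncRNA by >= 1 bp", {
  lnc <- gr1("chr1", 100, 200, "+", "lnc")
  h <- data.frame(query_chrom = "chr1",
                  query_start = c(10L, 99L, 150L, 200L),
                  query_end = c(50L, 101L, 260L, 290L),
                  score = 1:4)
  kept <- prune_hsps(h, lnc)
  expect_equal(kept$score, c(2L, 3L))  # 1-bp overlap kept whole, disjoint dropped
  expect_equal(kept$query_end[1], 101L)
  expect_equal(nrow(prune_hsps(h[0, ], lnc)), 0)
})
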