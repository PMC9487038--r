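# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

gr1 <- function(chrom, start, end, strand = ".", name = "", score = 0) {
  granges(chrom, start, end, strand = strand, name = name, score = score)
}

# --- interval oracles -------------------------------------------------

# jaccard / overlap coefficient by explicit base enumeration
jaccard_enum <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ba <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  i <- length(intersect(ba, bb))
  if (i == 0) 0 else i / length(union(ba, bb))
}

overlap_enum <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ba <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  i <- length(intersect(ba, bb))
  if (i == 0) 0 else i / min(length(ba), length(bb))
}

# sequential-scan merge oracle for the strict rule: sorted ranges join the
# open cluster when gap < d (or they overlap/abut), else start a new one
merge_enum <- function(starts, ends, d) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    gap <- starts[i] - me
    if (gap < d || gap <= 0) {
      me <- max(me, ends[i])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- starts[i]; me <- ends[i]
    }
  }
  rbind(out, c(ms, me))
}

# --- chain / lift oracles ---------------------------------------------

identity_chain <- function(len = 1000, t_name = "chr1", q_name = "chrA",
                           id = 1L) {
  list(score = 100, t_name = t_name, t_size = as.integer(len),
       t_strand = "+", t_start = 0L, t_end = as.integer(len),
       q_name = q_name, q_size = as.integer(len), q_strand = "+",
       q_start = 0L, q_end = as.integer(len), chain_id = as.integer(id),
       blocks = matrix(c(len, 0L, 0L), 1,
                       dimnames = list(NULL, c("size", "dt", "dq"))))
}

random_chain <- function(t_name = "chr1", q_name = "chrA", q_strand = "+",
                         n_blocks = sample(1:6, 1), id = 1L) {
  sizes <- sample(5:50, n_blocks, replace = TRUE)
  dt <- c(sample(0:30, max(n_blocks - 1, 0), replace = TRUE), 0L)
  dq <- c(sample(0:30, max(n_blocks - 1, 0), replace = TRUE), 0L)
  t_start <- sample(0:50, 1)
  q_start <- sample(0:50, 1)
  t_span <- sum(sizes + dt)
  q_span <- sum(sizes + dq)
  list(score = 100, t_name = t_name, t_size = as.integer(t_start + t_span + 20),
       t_strand = "+", t_start = as.integer(t_start),
       t_end = as.integer(t_start + t_span), q_name = q_name,
       q_size = as.integer(q_start + q_span + sample(0:40, 1)),
       q_strand = q_strand, q_start = as.integer(q_start),
       q_end = as.integer(q_start + q_span), chain_id = as.integer(id),
       blocks = matrix(c(sizes, dt, dq), ncol = 3,
                       dimnames = list(NULL, c("size", "dt", "dq"))))
}

# per-base lift oracle: map each base independently via block walking
lift_oracle <- function(range, chain) {
  mapped <- vapply(seq(range$start, range$end - 1), function(p) {
    synorth:::map_base_through_chain(p, chain)
  }, integer(1))
  mapped <- mapped[!is.na(mapped)]
  if (length(mapped) == 0) {
    return(list(matched = 0L, start = NA_integer_, end = NA_integer_))
  }
  list(matched = length(mapped), start = min(mapped), end = max(mapped) + 1L)
}

# swap the two sides of a plus-strand chain
invert_chain <- function(ch) {
  stopifnot(ch$q_strand == "+")
  bm <- ch$blocks
  bm2 <- bm
  bm2[, "dt"] <- bm[, "dq"]
  bm2[, "dq"] <- bm[, "dt"]
  list(score = ch$score, t_name = ch$q_name, t_size = ch$q_size,
       t_strand = "+", t_start = ch$q_start, t_end = ch$q_end,
       q_name = ch$t_name, q_size = ch$t_size, q_strand = "+",
       q_start = ch$t_start, q_end = ch$t_end, chain_id = ch$chain_id,
       blocks = bm2)
}

# --- alignment oracle --------------------------------------------------

# ungapped Smith-Waterman restricted to segments containing an exact match
# run of >= w: exhaustive over diagonals and segment endpoints
sw_seeded <- function(q, s, w, match = 1, mis = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  nq <- length(qc); ns <- length(sc)
  best <- -Inf
  for (d in (-(ns - 1)):(nq - 1)) {
    i0 <- max(1, d + 1); i1 <- min(nq, ns + d)
    if (i1 - i0 + 1 < w) next
    is <- i0:i1
    m <- qc[is] == sc[is - d]
    v <- ifelse(m, match, -mis)
    L <- length(is)
    for (a in 1:L) {
      tot <- 0; run <- 0; maxrun <- 0
      for (b in a:L) {
        tot <- tot + v[b]
        run <- if (m[b]) run + 1 else 0
        if (run > maxrun) maxrun <- run
        if (maxrun >= w && tot > best) best <- tot
      }
    }
  }
  best
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# recompute an HSP's score and identity from its reported intervals
rescore_hsp <- function(h, qseq, sseq, match = 1, mis = 2) {
  qs <- substr(qseq, h$q_start + 1, h$q_end)
  ss <- substr(sseq, h$s_start + 1, h$s_end)
  if (h$orientation == "opposite") ss <- revcomp_chr(ss)
  a <- strsplit(qs, "")[[1]]
  b <- strsplit(ss, "")[[1]]
  stopifnot(length(a) == length(b))
  eq <- a == b & a %in% c("A", "C", "G", "T")
  list(score = sum(ifelse(eq, match, -mis)), matches = sum(eq))
}

# --- BH oracle ----------------------------------------------------------

bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# --- chaining oracle ----------------------------------------------------

random_hsp_set <- function(n, orientation = c("same", "opposite")) {
  ori <- sample(orientation, n, replace = TRUE)
  qs <- sample(0:400, n, replace = TRUE)
  ql <- sample(10:80, n, replace = TRUE)
  ss <- sample(0:400, n, replace = TRUE)
  sl <- sample(10:80, n, replace = TRUE)
  data.frame(
    lncrna = "x", synteny_id = "x|1",
    query_chrom = "chr1", query_start = qs, query_end = qs + ql,
    subject_chrom = "chrA", subject_start = ss, subject_end = ss + sl,
    subject_strand = ifelse(ori == "same", "+", "-"), orientation = ori,
    score = sample(1:100, n, replace = TRUE),
    aligned_length = ql, identity = 1,
    stringsAsFactors = FALSE
  )
}

subset_collinear <- function(h, idx, orientation) {
  if (length(idx) == 0) return(FALSE)
  hh <- h[idx, , drop = FALSE]
  o <- order(hh$query_start, hh$query_end)
  hh <- hh[o, , drop = FALSE]
  n <- nrow(hh)
  if (n == 1) return(TRUE)
  for (i in 2:n) {
    if (hh$query_start[i] < hh$query_end[i - 1]) return(FALSE)
    if (orientation == "same") {
      if (hh$subject_start[i] < hh$subject_end[i - 1]) return(FALSE)
    } else {
      if (hh$subject_end[i] > hh$subject_start[i - 1]) return(FALSE)
    }
  }
  TRUE
}

# exhaustive best chain score over all subsets, per orientation class
chain_brute_score <- function(h) {
  best <- 0
  for (ori in unique(h$orientation)) {
    idx_all <- which(h$orientation == ori)
    k <- length(idx_all)
    for (mask in 1:(2^k - 1)) {
      idx <- idx_all[which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)]
      if (subset_collinear(h, idx, ori)) {
        sc <- sum(h$score[idx])
        if (sc > best) best <- sc
      }
    }
  }
  best
}

md5_dir <- function(dir, files) {
  vapply(files, function(f) unname(tools::md5sum(file.path(dir, f))),
         character(1))
}

# --- pipeline fixture helper -------------------------------------------

run_fixture_pipeline <- function(bundle, outdir, ...) {
  paths <- write_fixtures(bundle, file.path(outdir, "fixtures"))
  cfg <- pipeline_config(
    lncrna_bed = paths[["lncrna_bed"]], query_fasta = paths[["query_fasta"]],
    subject_fasta = paths[["subject_fasta"]],
    subject_annotation = paths[["gene_bed"]], chain = paths[["chain"]],
    outdir = file.path(outdir, "run"), flank_len = 500, merge_dist = 1000,
    ...)
  run_pipeline(cfg)
  list(config = cfg, paths = paths,
       summary = read_pipeline_summary(cfg$outdir))
}
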