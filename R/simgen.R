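#' Configuration for the synthetic genome-pair simulator
#'
#' The generator emulates the five pipeline inputs at desk scale: a query
#' genome with annotated lncRNA-like elements, a subject genome in which a
#' configurable fraction of those elements has a planted, mutated copy, a
#' UCSC chain file consistent with both genomes, a subject gene annotation
#' (planted copies plus decoy genes), and a ground-truth orthologue table.
#'
#' @param n_chroms number of chromosomes per genome.
#' @param chrom_len query chromosome length in bp.
#' @param n_lncrnas number of query lncRNAs, placed without overlap.
#' @param lncrna_len_range length range (bp) of lncRNAs, sampled uniformly.
#' @param conserved_fraction share of lncRNAs given a planted orthologue.
#' @param sub_rate per-base substitution probability in planted copies.
#' @param indel_rate per-base probability of a single-base indel in
#'   planted copies (insertions and deletions equally likely).
#' @param rearrange when TRUE, subject chromosomes are a permutation of
#'   the query chromosomes and chains may be minus-strand.
#' @param n_genes number of decoy gene records in the subject annotation.
#' @param gene_len_range decoy gene length range (bp).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   fixtures.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_chroms = 3, chrom_len = 100000, n_lncrnas = 30,
                       lncrna_len_range = c(300, 800),
                       conserved_fraction = 0.5, sub_rate = 0.1,
                       indel_rate = 0, rearrange = FALSE, n_genes = 100,
                       gene_len_range = c(200, 1000), seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            conserved_fraction >= 0, conserved_fraction <= 1,
            n_chroms >= 1, n_lncrnas >= 1,
            lncrna_len_range[1] <= lncrna_len_range[2])
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len),
                 n_lncrnas = as.integer(n_lncrnas),
                 lncrna_len_range = as.integer(lncrna_len_range),
                 conserved_fraction = conserved_fraction,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 rearrange = isTRUE(rearrange),
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitutions to a different base + optional single-base indels
mutate_seq <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (sub_rate > 0) {
    hit <- which(stats::runif(n) < sub_rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_len(n)) {
      r <- stats::runif(1)
      if (r < indel_rate / 2) {
        next                                    # deletion
      } else if (r < indel_rate) {
        out <- c(out, sample(c("A", "C", "G", "T"), 1), chars[i])  # insertion
      } else {
        out <- c(out, chars[i])
      }
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

# place n non-overlapping intervals of the given lengths on one chromosome,
# keeping min_gap bp between neighbours and edge_margin bp from the ends
place_intervals <- function(chrom_len, lens, min_gap = 300, edge_margin = 1000,
                            max_attempts = 10000) {
  placed_s <- integer(0)
  placed_e <- integer(0)
  for (len in lens) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- sample.int(chrom_len - 2 * edge_margin - len, 1) + edge_margin
      e <- s + len
      if (all(s - min_gap >= placed_e | e + min_gap <= placed_s)) {
        placed_s <- c(placed_s, s)
        placed_e <- c(placed_e, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("cannot place elements: genome too small for the requested load")
  }
  o <- order(placed_s)
  data.frame(start = placed_s[o], end = placed_e[o])
}

# build one multi-block chain for a chromosome; gap cuts avoid the
# forbidden intervals (lncRNA loci) so every element maps fully
make_chain <- function(t_name, t_size, q_name, q_strand, forbid, chain_id) {
  margin <- 250L
  pick_cut <- function(lo, hi) {
    for (a in 1:1000) {
      c0 <- sample.int(hi - lo, 1) + lo
      if (all(c0 < forbid$start - margin | c0 > forbid$end + margin)) return(c0)
    }
    stop("no room for chain gap cuts")
  }
  c1 <- pick_cut(round(t_size * 0.2), round(t_size * 0.45))
  c2 <- pick_cut(round(t_size * 0.55), round(t_size * 0.8))
  gt <- sample(20:200, 2, replace = TRUE)
  gq <- sample(20:200, 2, replace = TRUE)
  b1 <- c1
  b2 <- c2 - (c1 + gt[1])
  b3 <- t_size - (c2 + gt[2])
  stopifnot(b1 > 0, b2 > 0, b3 > 0)
  q_size <- b1 + b2 + b3 + gq[1] + gq[2]
  blocks <- rbind(c(b1, gt[1], gq[1]), c(b2, gt[2], gq[2]), c(b3, 0L, 0L))
  colnames(blocks) <- c("size", "dt", "dq")
  list(score = 1000, t_name = t_name, t_size = as.integer(t_size),
       t_strand = "+", t_start = 0L, t_end = as.integer(t_size),
       q_name = q_name, q_size = as.integer(q_size), q_strand = q_strand,
       q_start = 0L, q_end = as.integer(q_size),
       chain_id = as.integer(chain_id), blocks = blocks)
}

#' Simulate a self-consistent query/subject fixture bundle
#'
#' The query genome is i.i.d. uniform ACGT with non-overlapping lncRNAs.
#' Each chromosome maps to one subject chromosome through a three-block
#' chain whose gap cuts avoid lncRNA loci, so every lncRNA lifts fully.
#' For each conserved lncRNA a mutated copy of its transcript sequence is
#' embedded in the subject genome at the chain-mapped location;
#' non-conserved lncRNAs lift onto plain random sequence. The subject gene
#' annotation holds the planted copies plus decoy genes.
#'
#' @param config a [sim_config()].
#' @return list of class \code{sim_bundle} with elements
#'   \code{query_genome}, \code{subject_genome} (DNAStringSet),
#'   \code{lncrnas}, \code{genes}, \code{truth_bed} (ranges data frames),
#'   \code{chains} (list), \code{truth} (data frame lncrna/orthologue) and
#'   \code{config}.
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  qnames <- sprintf("chrQ%d", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$n_lncrnas, length.out = config$n_chroms + 1)))
  subj_of <- if (config$rearrange) sample(config$n_chroms) else seq_len(config$n_chroms)
  snames_by_q <- sprintf("chrS%d", subj_of)

  query_seqs <- character(config$n_chroms)
  lnc_rows <- list()
  chains <- vector("list", config$n_chroms)
  k <- 0L
  for (ci in seq_len(config$n_chroms)) {
    query_seqs[ci] <- random_seq(config$chrom_len)
    nl <- per_chrom[ci]
    lens <- sample(config$lncrna_len_range[1]:config$lncrna_len_range[2],
                   max(nl, 1), replace = TRUE)[seq_len(nl)]
    if (nl > 0) {
      pos <- place_intervals(config$chrom_len, lens)
      for (r in seq_len(nrow(pos))) {
        k <- k + 1L
        lnc_rows[[k]] <- data.frame(
          chrom = qnames[ci], start = pos$start[r], end = pos$end[r],
          name = sprintf("lnc%04d", k), score = 0,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
      forbid <- pos
    } else {
      forbid <- data.frame(start = integer(), end = integer())
    }
    q_strand <- if (config$rearrange) sample(c("+", "-"), 1) else "+"
    chains[[ci]] <- make_chain(qnames[ci], config$chrom_len, snames_by_q[ci],
                               q_strand, forbid, ci)
  }
  lncrnas <- validate_granges(do.call(rbind, lnc_rows))

  # subject chromosomes: random sequence sized by the chain q spans
  s_sizes <- integer(config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    s_sizes[match(snames_by_q[ci], sprintf("chrS%d", seq_len(config$n_chroms)))] <-
      chains[[ci]]$q_size
  }
  snames <- sprintf("chrS%d", seq_len(config$n_chroms))
  subject_seqs <- stats::setNames(vapply(s_sizes, random_seq, character(1)), snames)

  # choose conserved lncRNAs and plant mutated copies at lifted locations
  n_cons <- round(config$conserved_fraction * nrow(lncrnas))
  cons_idx <- sort(sample.int(nrow(lncrnas), n_cons))
  query_genome <- Biostrings::DNAStringSet(stats::setNames(query_seqs, qnames))
  truth_rows <- list()
  truth_map <- list()
  for (i in cons_idx) {
    lnc <- lncrnas[i, , drop = FALSE]
    lifted <- lift_range(lnc, chains, min_match = 0.999)
    if (nrow(lifted) != 1) stop("fixture inconsistency: lncRNA did not lift fully")
    transcript <- extract_sequence(query_genome, lnc)
    copy <- mutate_seq(transcript, config$sub_rate, config$indel_rate)
    s <- lifted$start
    e <- s + nchar(copy)
    if (e > nchar(subject_seqs[[lifted$chrom]])) {
      s <- nchar(subject_seqs[[lifted$chrom]]) - nchar(copy)
      e <- s + nchar(copy)
    }
    substr(subject_seqs[[lifted$chrom]], s + 1, e) <- copy
    orth_name <- paste0(lnc$name, "_orth")
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      chrom = lifted$chrom, start = as.integer(s), end = as.integer(e),
      name = orth_name, score = 0, strand = "+", stringsAsFactors = FALSE)
    truth_map[[length(truth_map) + 1L]] <- data.frame(
      lncrna = lnc$name, orthologue = orth_name, stringsAsFactors = FALSE)
  }
  truth_bed <- if (length(truth_rows) > 0) {
    validate_granges(do.call(rbind, truth_rows))
  } else granges()
  truth <- if (length(truth_map) > 0) do.call(rbind, truth_map) else
    data.frame(lncrna = character(), orthologue = character(),
               stringsAsFactors = FALSE)

  # subject gene annotation: planted copies + decoy genes
  decoys <- list()
  for (g in seq_len(config$n_genes)) {
    len <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1)
    ci <- sample.int(config$n_chroms, 1, prob = s_sizes)
    if (s_sizes[ci] <= len + 2) next
    s <- sample.int(s_sizes[ci] - len, 1) - 1L
    decoys[[length(decoys) + 1L]] <- data.frame(
      chrom = snames[ci], start = s, end = s + len,
      name = sprintf("gene%04d", g), score = 0,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  genes <- validate_granges(rbind(do.call(rbind, decoys), truth_bed))

  structure(list(
    query_genome = query_genome,
    subject_genome = Biostrings::DNAStringSet(subject_seqs),
    lncrnas = lncrnas, genes = genes, chains = chains,
    truth = truth, truth_bed = truth_bed, config = config
  ), class = "sim_bundle")
}

#' Simulate a fully null fixture (no planted orthologues)
#'
#' Same construction as [simulate_pair()] with
#' \code{conserved_fraction = 0}: every lncRNA lifts through the chain
#' onto plain random subject sequence and the truth table is empty. Drives
#' the false-discovery-rate control check.
#'
#' @param config a [sim_config()]; its conserved_fraction is overridden.
#' @return a \code{sim_bundle}.
#' @export
simulate_null <- function(config = sim_config()) {
  config$conserved_fraction <- 0
  simulate_pair(config)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d lncRNAs on %d+%d chromosomes, %d conserved\n",
              nrow(x$lncrnas), length(x$query_genome),
              length(x$subject_genome), nrow(x$truth)))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Emits the five pipeline inputs plus the ground truth: query.fa,
#' subject.fa, lncrnas.bed, genes.bed, map.chain, truth.tsv, truth.bed and
#' two chrom.sizes files.
#'
#' @param bundle a \code{sim_bundle}.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(bundle$query_genome, p("query.fa"))
  Biostrings::writeXStringSet(bundle$subject_genome, p("subject.fa"))
  write_bed(bundle$lncrnas, p("lncrnas.bed"))
  write_bed(bundle$genes, p("genes.bed"))
  write_chain_file(bundle$chains, p("map.chain"))
  utils::write.table(bundle$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (nrow(bundle$truth_bed) > 0) write_bed(bundle$truth_bed, p("truth.bed"))
  sizes <- function(g) sprintf("%s\t%d", names(g), Biostrings::width(g))
  writeLines(sizes(bundle$query_genome), p("query.chrom.sizes"))
  writeLines(sizes(bundle$subject_genome), p("subject.chrom.sizes"))
  invisible(c(query_fasta = p("query.fa"), subject_fasta = p("subject.fa"),
              lncrna_bed = p("lncrnas.bed"), gene_bed = p("genes.bed"),
              chain = p("map.chain"), truth_tsv = p("truth.tsv"),
              truth_bed = p("truth.bed")))
}
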