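#' Parse a UCSC chain file
#'
#' A chain describes a pairwise genome alignment as gapless blocks with
#' inter-block gaps on either sequence. Headers have 13 tokens:
#' \code{chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id}. Here the target (t) side is the query-species genome
#' the ranges are lifted FROM and the q side is the subject-species genome
#' they are lifted TO, following liftOver usage. Block lines carry
#' \code{size [dt dq]}; the last block has no gaps. q coordinates are
#' strand-relative as in the chain standard.
#'
#' @param path chain file, plain text or gzip.
#' @return list of chains; each a list with fields \code{score}, \code{t_name},
#'   \code{t_size}, \code{t_start}, \code{t_end}, \code{q_name},
#'   \code{q_size}, \code{q_strand}, \code{q_start}, \code{q_end},
#'   \code{chain_id} and \code{blocks}, a matrix with columns
#'   \code{size, dt, dq}.
#' @export
parse_chain_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- trimws(lines)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain")) {
      stop("expected chain header at line ", i)
    }
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(tok) != 13) {
      stop("chain header at line ", i, " has ", length(tok), " tokens, expected 13")
    }
    hdr <- list(
      score = as.numeric(tok[2]),
      t_name = tok[3], t_size = as.integer(tok[4]),
      t_strand = tok[5],
      t_start = as.integer(tok[6]), t_end = as.integer(tok[7]),
      q_name = tok[8], q_size = as.integer(tok[9]), q_strand = tok[10],
      q_start = as.integer(tok[11]), q_end = as.integer(tok[12]),
      chain_id = as.integer(tok[13])
    )
    if (hdr$t_strand != "+") stop("chain ", hdr$chain_id, ": target strand must be +")
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > length(lines) || !nzchar(lines[i])) break
      btok <- as.integer(strsplit(lines[i], "[ \t]+")[[1]])
      if (length(btok) == 3) {
        blocks[[length(blocks) + 1L]] <- btok
      } else if (length(btok) == 1) {
        blocks[[length(blocks) + 1L]] <- c(btok, 0L, 0L)
        i <- i + 1L
        break
      } else {
        stop("malformed block line ", i, " in chain ", hdr$chain_id)
      }
      i <- i + 1L
    }
    if (length(blocks) == 0) stop("chain ", hdr$chain_id, " has no blocks")
    bm <- do.call(rbind, blocks)
    colnames(bm) <- c("size", "dt", "dq")
    if (any(bm[, "size"] <= 0) || any(bm[, c("dt", "dq")] < 0)) {
      stop("chain ", hdr$chain_id, ": block sizes must be > 0 and gaps >= 0")
    }
    if (sum(bm[, "size"] + bm[, "dt"]) != hdr$t_end - hdr$t_start) {
      stop("chain ", hdr$chain_id, ": blocks do not sum to target span")
    }
    if (sum(bm[, "size"] + bm[, "dq"]) != hdr$q_end - hdr$q_start) {
      stop("chain ", hdr$chain_id, ": blocks do not sum to subject span")
    }
    hdr$blocks <- bm
    chains[[length(chains) + 1L]] <- hdr
  }
  chains
}

#' Write chains in UCSC chain format
#' @param chains list of chains as returned by [parse_chain_file()].
#' @param path output file (plain text).
#' @return \code{path}, invisibly.
#' @export
write_chain_file <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    out <- c(out, sprintf("chain %s %s %d + %d %d %s %d %s %d %d %d",
                          format(ch$score, scientific = FALSE), ch$t_name,
                          ch$t_size, ch$t_start, ch$t_end, ch$q_name,
                          ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                          ch$chain_id))
    bm <- ch$blocks
    n <- nrow(bm)
    if (n > 1) {
      out <- c(out, sprintf("%d %d %d", bm[-n, "size"], bm[-n, "dt"], bm[-n, "dq"]))
    }
    out <- c(out, sprintf("%d", bm[n, "size"]), "")
  }
  writeLines(out, path)
  invisible(path)
}

# Map one target-genome base through one chain. Returns the subject
# FORWARD-strand position, or NA when the base falls in a gap / outside.
map_base_through_chain <- function(pos, chain) {
  if (pos < chain$t_start || pos >= chain$t_end) return(NA_integer_)
  tpos <- chain$t_start
  qpos <- chain$q_start
  bm <- chain$blocks
  for (b in seq_len(nrow(bm))) {
    size <- bm[b, "size"]
    if (pos < tpos) return(NA_integer_)  # fell in the preceding dt gap
    if (pos < tpos + size) {
      qrel <- qpos + (pos - tpos)
      if (chain$q_strand == "-") {
        return(as.integer(chain$q_size - 1L - qrel))
      }
      return(as.integer(qrel))
    }
    tpos <- tpos + size + bm[b, "dt"]
    qpos <- qpos + size + bm[b, "dq"]
  }
  NA_integer_
}

compose_strand <- function(source, q_strand) {
  if (source == ".") return(".")
  if (q_strand == "+") source else if (source == "+") "-" else "+"
}

#' Lift a range through alignment chains to the subject genome
#'
#' For every chain overlapping the range on its target side, bases inside
#' gapless blocks are mapped; a lifted region is emitted per chain whose
#' mapped fraction reaches \code{min_match}. Duplications are allowed:
#' several chains yield several lifted regions.
#'
#' @param range single-row ranges data frame on the query genome.
#' @param chains list of chains from [parse_chain_file()].
#' @param min_match minimum fraction of the range's bases that must map
#'   through chain blocks (liftOver minMatch; default 0.05).
#' @return data frame with one row per accepted chain: the source
#'   coordinates, the subject target interval (forward-strand coordinates,
#'   minimal interval spanning all mapped bases), \code{matched_bases} and
#'   \code{match_fraction}; zero rows when the range does not lift.
#' @export
lift_range <- function(range, chains, min_match = 0.05) {
  stopifnot(min_match > 0, min_match <= 1, nrow(range) == 1)
  res <- list()
  for (ch in chains) {
    if (ch$t_name != range$chrom) next
    if (ch$t_end <= range$start || ch$t_start >= range$end) next
    mb <- 0L
    qmin <- NA_integer_
    qmax <- NA_integer_
    tpos <- ch$t_start
    qpos <- ch$q_start
    bm <- ch$blocks
    for (b in seq_len(nrow(bm))) {
      size <- bm[b, "size"]
      ov_s <- max(tpos, range$start)
      ov_e <- min(tpos + size, range$end)
      if (ov_e > ov_s) {
        mb <- mb + (ov_e - ov_s)
        q_s <- qpos + (ov_s - tpos)
        q_e <- qpos + (ov_e - tpos)   # strand-relative half-open
        if (is.na(qmin) || q_s < qmin) qmin <- q_s
        if (is.na(qmax) || q_e > qmax) qmax <- q_e
      }
      tpos <- tpos + size + bm[b, "dt"]
      qpos <- qpos + size + bm[b, "dq"]
    }
    if (mb == 0L) next
    frac <- mb / (range$end - range$start)
    if (frac < min_match) next
    if (ch$q_strand == "-") {
      fstart <- ch$q_size - qmax
      fend <- ch$q_size - qmin
    } else {
      fstart <- qmin
      fend <- qmax
    }
    res[[length(res) + 1L]] <- data.frame(
      name = range$name,
      source_chrom = range$chrom, source_start = range$start,
      source_end = range$end, source_strand = range$strand,
      chrom = ch$q_name, start = as.integer(fstart), end = as.integer(fend),
      strand = compose_strand(range$strand, ch$q_strand),
      matched_bases = as.integer(mb), match_fraction = frac,
      chain_id = ch$chain_id, stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0) return(empty_lifted())
  do.call(rbind, res)
}

empty_lifted <- function() {
  data.frame(name = character(), source_chrom = character(),
             source_start = integer(), source_end = integer(),
             source_strand = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             matched_bases = integer(), match_fraction = numeric(),
             chain_id = integer(), stringsAsFactors = FALSE)
}

lifted_to_granges <- function(lifted) {
  if (nrow(lifted) == 0) return(granges())
  granges(chrom = lifted$chrom, start = lifted$start, end = lifted$end,
          name = lifted$name, score = 0, strand = lifted$strand)
}

#' Build flanked syntenic regions from lifted coordinates of one lncRNA
#'
#' Lifted target ranges are grouped by (chromosome, strand); each group is
#' merged with [merge_close()] at \code{merge_dist} and each merged range
#' is extended by \code{flank_len}, clamped to the chromosome.
#'
#' @param lifted data frame from [lift_range()] (may have zero rows,
#'   meaning the lncRNA did not lift).
#' @param merge_dist merge distance in bp (duplications closer than this
#'   are merged).
#' @param flank_len flank length in bp added to each synteny.
#' @param chrom_sizes named vector of subject chromosome lengths.
#' @return ranges data frame of syntenic regions (possibly empty).
#' @export
build_syntenies <- function(lifted, merge_dist, flank_len, chrom_sizes) {
  if (nrow(lifted) == 0) return(granges())
  gr <- lifted_to_granges(lifted)
  parts <- split(seq_len(nrow(gr)), paste(gr$chrom, gr$strand, sep = "\r"))
  out <- lapply(parts, function(idx) {
    merged <- merge_close(gr[idx, , drop = FALSE], merge_dist)
    merged$strand <- gr$strand[idx[1]]
    flank_ranges(merged, flank_len, chrom_sizes)
  })
  res <- do.call(rbind, out)
  o <- order(res$chrom, res$start, res$end, res$strand)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  validate_granges(res)
}
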