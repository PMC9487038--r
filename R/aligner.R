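#' Load a genome FASTA into memory
#'
#' @param path FASTA file (plain or gzip).
#' @return a \code{Biostrings::DNAStringSet} keyed by sequence name
#'   (first whitespace-delimited token of each header).
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome sizes of a loaded genome
#' @param genome a \code{DNAStringSet} from [load_genome()].
#' @return named numeric vector of sequence lengths.
#' @export
genome_sizes <- function(genome) {
  stats::setNames(as.numeric(Biostrings::width(genome)), names(genome))
}

#' Extract the sequence of a genomic range
#'
#' Returns the uppercase sequence; minus-strand ranges are
#' reverse-complemented so the result reads 5'→3' on the annotated strand.
#'
#' @param genome a \code{DNAStringSet}.
#' @param range single-row ranges data frame.
#' @return character string of length \code{end - start}.
#' @export
extract_sequence <- function(genome, range) {
  stopifnot(nrow(range) == 1)
  if (!range$chrom %in% names(genome)) {
    stop("sequence not in genome: ", range$chrom)
  }
  L <- length(genome[[range$chrom]])
  if (range$end > L || range$start < 0) {
    stop(sprintf("range %s:%d-%d out of bounds (length %d)",
                 range$chrom, range$start, range$end, L))
  }
  s <- Biostrings::subseq(genome[[range$chrom]], range$start + 1L, range$end)
  if (range$strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_alphabet <- function(seq, what, tolerance = 0.1) {
  n_bad <- nchar(gsub("[ACGTN]", "", seq))
  if (n_bad > tolerance * nchar(seq)) {
    stop(what, ": degenerate alphabet (", n_bad,
         " non-ACGTN characters beyond tolerance)")
  }
}

#' Default scoring parameters for the built-in aligner
#'
#' Loose settings aimed at weakly conserved elements: a short seed word,
#' mild match reward and strong mismatch penalty keep random extensions
#' short while letting diverged homology seed.
#'
#' @param word_size exact-match seed length (>= 4; 6 by default).
#' @param match_reward score per matching base.
#' @param mismatch_penalty positive penalty per mismatching base.
#' @param xdrop stop extending when the running score falls this far below
#'   the best score seen.
#' @param min_score report only extensions scoring at least this much.
#' @return named list of parameters, tagged with the engine identifier.
#' @export
aligner_params <- function(word_size = 6, match_reward = 1,
                           mismatch_penalty = 2, xdrop = 20, min_score = 20) {
  stopifnot(word_size >= 4, match_reward > 0, mismatch_penalty > 0,
            xdrop > 0, min_score > 0)
  list(word_size = as.integer(word_size), match_reward = match_reward,
       mismatch_penalty = mismatch_penalty, xdrop = xdrop,
       min_score = min_score,
       engine_tag = sprintf("builtin:w%d,m%g,x%g,xd%g,s%g", word_size,
                            match_reward, mismatch_penalty, xdrop, min_score))
}

empty_hsps <- function() {
  data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), orientation = character(), score = numeric(),
             aligned_length = integer(), identity = numeric(),
             stringsAsFactors = FALSE)
}

#' Find high-scoring segment pairs between two sequences
#'
#' Built-in ungapped seed-and-extend search. Exact \code{word_size}-mer
#' matches seed extensions in both directions with X-drop termination;
#' both strands of the subject are searched and the orientation recorded.
#' N never seeds and never matches. Coordinates in the result are local to
#' the input strings, 0-based half-open, with subject coordinates always
#' on the forward strand (opposite-orientation hits are normalized).
#'
#' @param query_seq,subject_seq nucleotide strings (ACGTN after
#'   uppercasing; a small tolerance of other IUPAC letters is allowed but
#'   such positions never match).
#' @param params scoring parameters from [aligner_params()].
#' @return data frame with columns \code{q_start, q_end, s_start, s_end,
#'   orientation (same/opposite), score, aligned_length, identity}, sorted
#'   by decreasing score then query start.
#' @export
find_hsps <- function(query_seq, subject_seq, params = aligner_params()) {
  stopifnot(nchar(query_seq) > 0, nchar(subject_seq) > 0)
  query_seq <- toupper(query_seq)
  subject_seq <- toupper(subject_seq)
  check_alphabet(query_seq, "query")
  check_alphabet(subject_seq, "subject")
  slen <- nchar(subject_seq)

  one_pass <- function(subj, orientation) {
    d <- .seed_extend_cpp(query_seq, subj, params$word_size,
                          params$match_reward, params$mismatch_penalty,
                          params$xdrop, params$min_score)
    if (nrow(d) == 0) return(empty_hsps())
    if (orientation == "opposite") {
      # hit coords are on the reverse complement; map to forward strand
      s_start <- slen - d$s_end
      s_end <- slen - d$s_start
    } else {
      s_start <- d$s_start
      s_end <- d$s_end
    }
    data.frame(q_start = d$q_start, q_end = d$q_end,
               s_start = as.integer(s_start), s_end = as.integer(s_end),
               orientation = orientation, score = d$score,
               aligned_length = d$q_end - d$q_start,
               identity = d$matches / (d$q_end - d$q_start),
               stringsAsFactors = FALSE)
  }

  out <- rbind(one_pass(subject_seq, "same"),
               one_pass(revcomp(subject_seq), "opposite"))
  out <- out[order(-out$score, out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read HSPs from 12-column tabular alignment output
#'
#' Adapter for the standard 12-column tabular format of external local
#' aligners (qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore; 1-based inclusive coordinates). The bit
#' score column is used as the raw score. Subject start > end encodes
#' opposite orientation and is normalized to a forward-strand half-open
#' interval.
#'
#' @param path tabular file.
#' @param query_offset,subject_offset optional single-row ranges giving
#'   the genomic placement of the aligned sequences; local coordinates are
#'   shifted into genome space when supplied (plus-strand placements).
#' @return HSP data frame as from [find_hsps()].
#' @export
parse_tabular_hsps <- function(path, query_offset = NULL, subject_offset = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0) return(empty_hsps())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop("tabular line ", which(nf != 12)[1], " has ", nf[nf != 12][1],
         " columns, expected 12")
  }
  m <- do.call(rbind, fields)
  qstart <- as.integer(m[, 7]); qend <- as.integer(m[, 8])
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  opp <- sstart > send
  s0 <- ifelse(opp, send, sstart) - 1L
  s1 <- ifelse(opp, sstart, send)
  out <- data.frame(
    q_start = qstart - 1L, q_end = qend,
    s_start = s0, s_end = s1,
    orientation = ifelse(opp, "opposite", "same"),
    score = as.numeric(m[, 12]),
    aligned_length = as.integer(m[, 4]),
    identity = as.numeric(m[, 3]) / 100,
    stringsAsFactors = FALSE
  )
  if (!is.null(query_offset)) {
    out$q_start <- out$q_start + query_offset$start
    out$q_end <- out$q_end + query_offset$start
  }
  if (!is.null(subject_offset)) {
    out$s_start <- out$s_start + subject_offset$start
    out$s_end <- out$s_end + subject_offset$start
  }
  out
}

#' Keep HSPs whose query interval overlaps the lncRNA
#'
#' HSPs are filtered, not clipped: any HSP overlapping the unflanked
#' lncRNA interval by at least one base is kept whole, so raw scores stay
#' comparable with the background distribution.
#'
#' @param hsps HSP data frame carrying genome-space query coordinates in
#'   columns \code{query_start}/\code{query_end} (or local
#'   \code{q_start}/\code{q_end} matched against a local interval).
#' @param lncrna single-row ranges data frame (query genome).
#' @return the overlapping subset, order preserved.
#' @export
prune_hsps <- function(hsps, lncrna) {
  if (nrow(hsps) == 0) return(hsps)
  qs <- if ("query_start" %in% names(hsps)) hsps$query_start else hsps$q_start
  qe <- if ("query_end" %in% names(hsps)) hsps$query_end else hsps$q_end
  keep <- qs < lncrna$end & qe > lncrna$start
  if ("query_chrom" %in% names(hsps)) keep <- keep & hsps$query_chrom == lncrna$chrom
  out <- hsps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Map sequence-local HSP coordinates into genome space.
# query_range: the (flanked) query range whose extracted sequence was
# aligned -- extraction respects its strand, so minus-strand local
# coordinates are flipped. subject_range: the synteny, always extracted
# on the forward strand.
hsps_to_genome <- function(hsps, query_range, subject_range) {
  if (nrow(hsps) == 0) {
    out <- cbind(empty_hsps()[0, ],
                 data.frame(query_chrom = character(), query_start = integer(),
                            query_end = integer(), subject_chrom = character(),
                            subject_start = integer(), subject_end = integer(),
                            subject_strand = character(), stringsAsFactors = FALSE))
    return(out)
  }
  if (query_range$strand == "-") {
    q0 <- query_range$end - hsps$q_end
    q1 <- query_range$end - hsps$q_start
  } else {
    q0 <- query_range$start + hsps$q_start
    q1 <- query_range$start + hsps$q_end
  }
  hsps$query_chrom <- query_range$chrom
  hsps$query_start <- as.integer(q0)
  hsps$query_end <- as.integer(q1)
  hsps$subject_chrom <- subject_range$chrom
  hsps$subject_start <- as.integer(subject_range$start + hsps$s_start)
  hsps$subject_end <- as.integer(subject_range$start + hsps$s_end)
  # orientation 'same' means the transcript-oriented query sequence matched
  # the subject forward strand
  hsps$subject_strand <- ifelse(hsps$orientation == "same", "+", "-")
  hsps
}
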