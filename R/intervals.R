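#' Genomic ranges as a data frame
#'
#' The package represents genomic intervals as plain data frames with
#' columns \code{chrom}, \code{start}, \code{end}, \code{name},
#' \code{score}, \code{strand}. Coordinates are 0-based half-open
#' (BED convention) everywhere inside the package; GFF3 input is converted
#' at the boundary. Strand is one of \code{"+"}, \code{"-"}, \code{"."}.
#'
#' @param chrom character vector of sequence names (non-empty strings).
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions; must satisfy
#'   \code{start < end}.
#' @param strand strand characters, recycled; unknown values error.
#' @param name range identifiers, recycled; may be empty strings.
#' @param score numeric scores, recycled (BED column 5; 0 by default).
#' @return A data frame of class \code{c("granges_df", "data.frame")}.
#' @examples
#' granges("chr1", 10, 20, strand = "+", name = "A")
#' @export
granges <- function(chrom = character(), start = integer(), end = integer(),
                    strand = ".", name = "", score = 0) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_granges(df)
}

validate_granges <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing range columns: ", paste(miss, collapse = ", "))
  if (any(is.na(df$chrom) | df$chrom == "")) stop("chrom must be non-empty")
  if (any(df$start < 0)) stop("start must be >= 0")
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop(sprintf("invalid interval: start >= end at row %d (%s:%d-%d)",
                 bad, df$chrom[bad], df$start[bad], df$end[bad]))
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  class(df) <- unique(c("granges_df", class(df)))
  df
}

#' Width of each range in base pairs
#' @param x a ranges data frame.
#' @return integer vector of \code{end - start}.
#' @export
range_width <- function(x) x$end - x$start

#' An annotation set: ranges plus chromosome sizes
#'
#' @param ranges a ranges data frame (see [granges()]).
#' @param chrom_sizes named numeric vector mapping sequence name to length
#'   in bp. Every range must fit within its chromosome.
#' @return An object of class \code{annotation_set} with elements
#'   \code{ranges} (sorted deterministically by chrom, start, end, strand,
#'   name) and \code{chrom_sizes}.
#' @export
annotation_set <- function(ranges, chrom_sizes) {
  ranges <- validate_granges(ranges)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  unknown <- setdiff(unique(ranges$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("ranges on chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  if (any(ranges$end > chrom_sizes[ranges$chrom])) {
    stop("range ends beyond chromosome size")
  }
  o <- order(ranges$chrom, ranges$start, ranges$end, ranges$strand, ranges$name)
  ranges <- ranges[o, , drop = FALSE]
  rownames(ranges) <- NULL
  structure(list(ranges = ranges, chrom_sizes = chrom_sizes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d ranges on %d sequences\n",
              nrow(x$ranges), length(x$chrom_sizes)))
  print(utils::head(x$ranges))
  invisible(x)
}

#' Read a BED or GFF3 annotation
#'
#' BED fields map directly (BED is already 0-based half-open). GFF3 starts
#' are shifted by -1 so 1-based closed records become 0-based half-open.
#' Records with unknown strand get \code{"."}.
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"gff3"}; inferred from the file
#'   extension when missing.
#' @param chrom_sizes optional named vector; when supplied an
#'   [annotation_set()] is returned, otherwise a bare ranges data frame.
#' @return ranges data frame, or \code{annotation_set} when
#'   \code{chrom_sizes} is given.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3"),
                            chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer format from extension: ", path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    df <- granges()
  } else if (format == "bed") {
    df <- parse_bed_lines(lines)
  } else {
    df <- parse_gff3_lines(lines)
  }
  if (is.null(chrom_sizes)) df else annotation_set(df, chrom_sizes)
}

parse_bed_lines <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop(sprintf("malformed BED line %d: start >= end", bad[1]))
  }
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-")] <- "."
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  granges(chrom = get(1, NA), start = start, end = end,
          name = get(4, ""), score = score, strand = strand)
}

parse_gff3_lines <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    stop("malformed GFF3 line ", which(nf < 8)[1], ": fewer than 8 columns")
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:9]))
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    stop("malformed GFF3 line ", which(is.na(start1) | is.na(end1))[1],
         ": non-numeric coordinates")
  }
  bad <- which(start1 > end1)
  if (length(bad) > 0) stop(sprintf("malformed GFF3 line %d: start > end", bad[1]))
  strand <- m[, 7]
  strand[!strand %in% c("+", "-")] <- "."
  # pull ID= or Name= from column 9 when present
  nm <- sub(".*(?:^|;)(?:ID|Name)=([^;]+).*", "\\1", m[, 9], perl = TRUE)
  nm[nm == m[, 9] & !grepl("=", m[, 9])] <- ""
  nm[is.na(m[, 9])] <- ""
  granges(chrom = m[, 1], start = start1 - 1L, end = end1,
          name = nm, score = 0, strand = strand)
}

#' Write ranges as 6-column BED
#' @param x ranges data frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_granges(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   ifelse(x$name == "", ".", x$name),
                   format_score(x$score), x$strand)
  writeLines(lines, path)
  invisible(path)
}

format_score <- function(s) {
  out <- ifelse(s == round(s), sprintf("%d", as.integer(round(s))),
                sub("0+$", "", sprintf("%.6f", s)))
  out
}

#' Read a UCSC chrom.sizes file
#' @param path two-column tab-separated text: sequence name, length (bp).
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}

#' Merge ranges on one chromosome that are closer than a distance
#'
#' Sorted ranges are merged transitively whenever the gap between
#' consecutive ranges (\code{next start - previous end}) is strictly less
#' than \code{max_dist}. Overlapping or abutting ranges always merge.
#'
#' @param x ranges data frame, all on one chromosome.
#' @param max_dist non-negative merge distance in bp (strict \code{<}).
#' @return merged ranges, sorted; name of the first member is kept, strand
#'   kept when uniform within a merged run, else \code{"."}.
#' @export
merge_close <- function(x, max_dist) {
  x <- validate_granges(x)
  stopifnot(max_dist >= 0)
  if (nrow(x) <= 1) return(x)
  if (length(unique(x$chrom)) != 1) stop("merge_close requires a single chromosome")
  o <- order(x$start, x$end)
  x <- x[o, , drop = FALSE]
  # split when the gap is >= max_dist; overlapping/abutting (gap <= 0)
  # ranges always merge, even with max_dist = 0
  gaps <- x$start[-1] - cummax_int(x$end)[-nrow(x)]
  grp <- cumsum(c(1L, as.integer(gaps >= max(max_dist, 1L))))
  out <- do.call(rbind, lapply(split(seq_len(nrow(x)), grp), function(idx) {
    s <- unique(x$strand[idx])
    data.frame(chrom = x$chrom[idx[1]], start = min(x$start[idx]),
               end = max(x$end[idx]), name = x$name[idx[1]],
               score = sum(x$score[idx]),
               strand = if (length(s) == 1) s else ".",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  validate_granges(out)
}

cummax_int <- function(v) as.integer(cummax(v))

#' Extend a range by a flank on both sides, clamped to the chromosome
#'
#' @param x ranges data frame.
#' @param flank_len non-negative flank length in bp.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return ranges with \code{start' = max(0, start - flank_len)} and
#'   \code{end' = min(chrom_size, end + flank_len)}; strand and name kept.
#' @export
flank_ranges <- function(x, flank_len, chrom_sizes) {
  x <- validate_granges(x)
  stopifnot(flank_len >= 0)
  unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    stop("chromosome absent from chrom_sizes: ", paste(unknown, collapse = ", "))
  }
  x$start <- pmax(0L, x$start - as.integer(flank_len))
  x$end <- as.integer(pmin(chrom_sizes[x$chrom], x$end + flank_len))
  validate_granges(x)
}

intersect_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Jaccard index of two intervals
#'
#' Base-count intersection over union of the two intervals. Ranges on
#' different chromosomes score 0.
#'
#' @param a,b single-row ranges data frames (or rows of one).
#' @return fraction in \[0, 1\].
#' @export
range_jaccard <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  i <- intersect_width(a$start, a$end, b$start, b$end)
  if (i == 0) return(0)
  u <- (a$end - a$start) + (b$end - b$start) - i
  i / u
}

#' Overlap coefficient of two intervals
#'
#' Intersection size over the length of the smaller interval.
#'
#' @inheritParams range_jaccard
#' @return fraction in \[0, 1\].
#' @export
range_overlap_coefficient <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  i <- intersect_width(a$start, a$end, b$start, b$end)
  if (i == 0) return(0)
  i / min(a$end - a$start, b$end - b$start)
}

#' Do any ranges in x intersect any ranges in y? (strand-agnostic)
#' @param x,y ranges data frames.
#' @return logical vector over rows of \code{x}.
#' @export
overlaps_any <- function(x, y) {
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  vapply(seq_len(nrow(x)), function(i) {
    same <- y$chrom == x$chrom[i]
    any(same & y$start < x$end[i] & y$end > x$start[i])
  }, logical(1))
}

#' Sample shuffled genomic ranges for a background set
#'
#' Draws annotation records with replacement and relocates each to a
#' uniformly random start on a chromosome chosen with probability
#' proportional to chromosome length (record length preserved, start
#' clamped so the range fits). Any candidate intersecting an exclusion
#' range (strand-agnostic) is rejected and redrawn. Deterministic for a
#' given seed.
#'
#' @param annotation an [annotation_set()].
#' @param n number of ranges to return (>= 1).
#' @param exclusions ranges data frame; sampled ranges never intersect it.
#' @param seed integer seed driving the sampler.
#' @param max_attempts attempt budget before giving up (default
#'   \code{100 * n}).
#' @return ranges data frame with exactly \code{n} rows.
#' @export
sample_shuffled_ranges <- function(annotation, n, exclusions = granges(),
                                   seed = 1L, max_attempts = 100 * n) {
  stopifnot(inherits(annotation, "annotation_set"), n >= 1)
  if (nrow(annotation$ranges) == 0) stop("annotation is empty")
  sizes <- annotation$chrom_sizes
  lens <- range_width(annotation$ranges)
  rng <- local_rng(seed)
  out <- vector("list", n)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " background ranges in ", max_attempts,
           " attempts; reduce exclusions or n")
    }
    len <- lens[rng$int(length(lens))]
    ci <- rng$weighted_int(sizes)
    chrom <- names(sizes)[ci]
    room <- sizes[[ci]] - len
    if (room < 0) next
    start <- rng$int(room + 1) - 1L
    cand <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + len),
                       name = sprintf("bg_%d", got + 1L), score = 0,
                       strand = ".", stringsAsFactors = FALSE)
    if (nrow(exclusions) > 0 && overlaps_any(cand, exclusions)) next
    got <- got + 1L
    out[[got]] <- cand
  }
  validate_granges(do.call(rbind, out))
}

# Self-contained RNG handle: isolates sampling from the global .Random.seed
# so library code never perturbs a caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    int = with_state(function(k) sample.int(k, 1L)),
    weighted_int = with_state(function(w) sample.int(length(w), 1L, prob = w)),
    unif = with_state(function(n = 1L) stats::runif(n)),
    sample_int = with_state(function(k, size, replace = FALSE)
      sample.int(k, size, replace = replace))
  )
}

# Stable 31-bit string hash for deriving per-lncRNA sub-seeds; execution
# order and parallel scheduling then cannot change sampled backgrounds.
stable_hash <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

derive_seed <- function(seed, name) {
  as.integer((as.numeric(seed) + stable_hash(name)) %% 2147483647)
}
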