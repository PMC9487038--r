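#' Annotate orthologue calls with overlapping subject genes
#'
#' Strand-specific intersection of orthologue calls with a gene
#' annotation. Every gene on the same chromosome and strand overlapping an
#' orthologue by at least one base yields one output row with the Jaccard
#' index and overlap coefficient of the interval pair. Orthologues with no
#' same-strand overlap get a single row with gene \code{"."} and both
#' coefficients 0 (the intergenic calls). Strandless (\code{"."})
#' orthologues are matched against both strands and flagged.
#'
#' @param orthologues ranges data frame of orthologue calls (named).
#' @param genes an [annotation_set()] (or bare ranges data frame) of
#'   subject genes.
#' @return data frame with columns \code{orthologue_name, chrom, start,
#'   end, strand, gene_name, jaccard, overlap_coef, strandless}.
#' @export
annotate_orthologues <- function(orthologues, genes) {
  g <- if (inherits(genes, "annotation_set")) genes$ranges else validate_granges(genes)
  orthologues <- validate_granges(orthologues)
  if (nrow(orthologues) == 0) {
    return(data.frame(orthologue_name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), gene_name = character(),
                      jaccard = numeric(), overlap_coef = numeric(),
                      strandless = logical(), stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(orthologues))
  for (i in seq_len(nrow(orthologues))) {
    o <- orthologues[i, , drop = FALSE]
    strandless <- o$strand == "."
    same <- g$chrom == o$chrom &
      g$start < o$end & g$end > o$start &
      (strandless | g$strand == o$strand)
    hit_idx <- which(same)
    base <- data.frame(orthologue_name = o$name, chrom = o$chrom,
                       start = o$start, end = o$end, strand = o$strand,
                       stringsAsFactors = FALSE)
    if (length(hit_idx) == 0) {
      rows[[i]] <- cbind(base, data.frame(gene_name = ".", jaccard = 0,
                                          overlap_coef = 0,
                                          strandless = strandless))
    } else {
      rows[[i]] <- do.call(rbind, lapply(hit_idx, function(j) {
        gj <- g[j, , drop = FALSE]
        cbind(base, data.frame(
          gene_name = if (gj$name == "") "." else gj$name,
          jaccard = range_jaccard(o, gj),
          overlap_coef = range_overlap_coefficient(o, gj),
          strandless = strandless))
      }))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotation hits as TSV
#' @param hits data frame from [annotate_orthologues()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_annotation_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
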