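#' Link significant HSPs of one syntenic region into a collinear chain
#'
#' Dynamic programming over HSPs sorted by query start finds the subset
#' with maximal total raw score under strict collinearity: query intervals
#' increasing and non-overlapping, and subject intervals increasing
#' (same orientation) or decreasing (opposite orientation), also
#' non-overlapping. Orientations never mix; the best chain across the two
#' orientation classes is returned. There is no gap penalty. Ties are
#' broken toward fewer HSPs, then the smallest subject start, making the
#' result deterministic.
#'
#' @param hsps data frame of significant HSPs in genome coordinates
#'   (columns \code{query_start, query_end, subject_start, subject_end,
#'   orientation, score, aligned_length}), all within one synteny.
#' @param synteny single-row ranges data frame (the syntenic region).
#' @param lncrna_name identifier carried on the chain.
#' @return object of class \code{orthologue_chain} (or \code{NULL} when
#'   \code{hsps} is empty): list with the member \code{hsps} (query order),
#'   \code{span} (subject interval from min start to max end),
#'   \code{total_hsp_length}, \code{total_score}, \code{orientation},
#'   \code{synteny} and \code{lncrna_name}.
#' @export
chain_hsps <- function(hsps, synteny = NULL, lncrna_name = "") {
  if (is.null(hsps) || nrow(hsps) == 0) return(NULL)
  best <- NULL
  for (ori in unique(hsps$orientation)) {
    idx <- chain_dp(hsps[hsps$orientation == ori, , drop = FALSE], ori)
    cand <- hsps[hsps$orientation == ori, , drop = FALSE][idx, , drop = FALSE]
    if (is.null(best) || chain_better(cand, best)) best <- cand
  }
  rownames(best) <- NULL
  structure(list(
    lncrna_name = lncrna_name,
    synteny = synteny,
    hsps = best,
    span = data.frame(chrom = best$subject_chrom[1],
                      start = min(best$subject_start),
                      end = max(best$subject_end),
                      name = lncrna_name, score = sum(best$score),
                      strand = if (best$orientation[1] == "same") "+" else "-",
                      stringsAsFactors = FALSE),
    total_hsp_length = sum(best$aligned_length),
    total_score = sum(best$score),
    orientation = best$orientation[1]
  ), class = "orthologue_chain")
}

# is candidate chain (a data frame of member HSPs) better than current?
chain_better <- function(cand, best) {
  sa <- sum(cand$score); sb <- sum(best$score)
  if (sa != sb) return(sa > sb)
  if (nrow(cand) != nrow(best)) return(nrow(cand) < nrow(best))
  min(cand$subject_start) < min(best$subject_start)
}

# DP over one orientation class; returns row indices of the best chain,
# in query order.
chain_dp <- function(h, orientation) {
  n <- nrow(h)
  o <- order(h$query_start, h$query_end, h$subject_start)
  h <- h[o, , drop = FALSE]
  score <- h$score
  best_score <- score
  best_count <- rep(1L, n)
  best_sstart <- h$subject_start
  pred <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (h$query_end[j] > h$query_start[i]) next
      ok <- if (orientation == "same") {
        h$subject_end[j] <= h$subject_start[i]
      } else {
        h$subject_start[j] >= h$subject_end[i]
      }
      if (!ok) next
      cand_score <- best_score[j] + score[i]
      cand_count <- best_count[j] + 1L
      cand_sstart <- min(best_sstart[j], h$subject_start[i])
      better <- cand_score > best_score[i] ||
        (cand_score == best_score[i] &&
           (cand_count < best_count[i] ||
              (cand_count == best_count[i] && cand_sstart < best_sstart[i])))
      if (better) {
        best_score[i] <- cand_score
        best_count[i] <- cand_count
        best_sstart[i] <- cand_sstart
        pred[i] <- j
      }
    }
  }
  end <- 1L
  for (i in seq_len(n)) {
    if (best_score[i] > best_score[end] ||
        (best_score[i] == best_score[end] &&
           (best_count[i] < best_count[end] ||
              (best_count[i] == best_count[end] &&
                 best_sstart[i] < best_sstart[end])))) end <- i
  }
  path <- integer(0)
  i <- end
  while (i != 0L) { path <- c(i, path); i <- pred[i] }
  o[path]
}

#' @export
print.orthologue_chain <- function(x, ...) {
  cat(sprintf("orthologue_chain '%s': %d HSPs, %s orientation, span %s:%d-%d(%s), total length %d, total score %g\n",
              x$lncrna_name, nrow(x$hsps), x$orientation, x$span$chrom,
              x$span$start, x$span$end, x$span$strand,
              x$total_hsp_length, x$total_score))
  invisible(x)
}

#' Select the best significant orthologue among a lncRNA's chains
#'
#' The chain with the maximal sum of member-HSP lengths wins; ties are
#' broken by higher total score, then by the lexicographically smallest
#' (chromosome, start) of the subject span.
#'
#' @param chains non-empty list of \code{orthologue_chain} objects for one
#'   lncRNA.
#' @return the chosen chain, with \code{$best = TRUE} set.
#' @export
select_best <- function(chains) {
  if (length(chains) == 0) stop("no chains to select from")
  best <- 1L
  for (i in seq_along(chains)[-1]) {
    a <- chains[[i]]; b <- chains[[best]]
    pick <- if (a$total_hsp_length != b$total_hsp_length) {
      a$total_hsp_length > b$total_hsp_length
    } else if (a$total_score != b$total_score) {
      a$total_score > b$total_score
    } else if (a$span$chrom != b$span$chrom) {
      a$span$chrom < b$span$chrom
    } else {
      a$span$start < b$span$start
    }
    if (pick) best <- i
  }
  out <- chains[[best]]
  out$best <- TRUE
  out
}

#' Conservation status of one lncRNA
#'
#' The five-way vocabulary of the pipeline: \emph{unlifted} (no chain
#' mapping at all), \emph{unaligned} (lifted, but zero HSPs in its
#' syntenic regions), \emph{insignificant} (HSPs exist, none survive the
#' FDR filter; all HSPs are reported), \emph{significant} (at least one
#' chain of significant HSPs), with the single best chain additionally
#' labelled \emph{bestSignificant}.
#'
#' @param lifted lifted-region data frame (possibly 0 rows).
#' @param all_hsps HSP data frame before significance filtering.
#' @param significant_chains list of \code{orthologue_chain}.
#' @param lncrna_name identifier.
#' @return object of class \code{conservation_status}: list with
#'   \code{lncrna_name}, \code{status} and a status-appropriate
#'   \code{payload} (chains / HSPs / lifted coordinates). For significant
#'   lncRNAs \code{payload$best} is the bestSignificant chain and
#'   \code{payload$chains} all significant chains.
#' @export
classify_lncrna <- function(lifted, all_hsps, significant_chains,
                            lncrna_name = "") {
  if (is.null(lifted) || nrow(lifted) == 0) {
    status <- "unlifted"; payload <- NULL
  } else if (is.null(all_hsps) || nrow(all_hsps) == 0) {
    status <- "unaligned"; payload <- list(lifted = lifted)
  } else if (length(significant_chains) == 0) {
    status <- "insignificant"; payload <- list(hsps = all_hsps)
  } else {
    status <- "significant"
    payload <- list(best = select_best(significant_chains),
                    chains = significant_chains)
  }
  structure(list(lncrna_name = lncrna_name, status = status,
                 payload = payload), class = "conservation_status")
}

#' @export
print.conservation_status <- function(x, ...) {
  cat(sprintf("conservation_status '%s': %s\n", x$lncrna_name, x$status))
  invisible(x)
}
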