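#' Evaluate predicted orthologues against a truth mapping
#'
#' A true positive is a lncRNA whose prediction intersects (>= 1 bp, same
#' strand) one of its own true orthologues; a false positive is any
#' prediction for a lncRNA with no annotated orthologue. TN and FN follow
#' by subtraction from the totals of non-orthologous and orthologous
#' lncRNAs. Under \code{weighted = TRUE} (for tools emitting several
#' predictions per lncRNA) each lncRNA contributes not 1 but the share of
#' true (or false) predictions among its predictions.
#'
#' A prediction for an orthologous lncRNA that misses that lncRNA's own
#' truth counts toward neither TP nor FP; it surfaces as FN mass only.
#'
#' @param predictions named list: lncRNA name -> ranges data frame of
#'   predicted orthologues (zero rows allowed). Every name must appear in
#'   \code{truth}.
#' @param truth named list: lncRNA name -> ranges data frame of true
#'   orthologues; an empty data frame marks a non-orthologous lncRNA. The
#'   names of \code{truth} define the evaluation universe.
#' @param weighted apply the share rule for multi-prediction tools.
#' @return list with \code{counts} (tp, fp, tn, fn, total_ortho,
#'   total_non_ortho) and \code{metrics} (TPR, FPR, TNR, FNR, accuracy,
#'   precision, F1); metrics with zero denominators are \code{NA}.
#' @export
evaluate_predictions <- function(predictions, truth, weighted = FALSE) {
  if (is.null(names(truth)) || any(names(truth) == "")) {
    stop("truth must be a named list")
  }
  stray <- setdiff(names(predictions), names(truth))
  if (length(stray) > 0) {
    stop("predictions for lncRNAs absent from truth: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  is_ortho <- vapply(truth, function(t) nrow(t) > 0, logical(1))
  total_ortho <- sum(is_ortho)
  total_non_ortho <- sum(!is_ortho)

  tp <- 0; fp <- 0
  for (nm in names(truth)) {
    preds <- predictions[[nm]]
    k <- if (is.null(preds)) 0L else nrow(preds)
    if (k == 0L) next
    if (is_ortho[[nm]]) {
      hits <- vapply(seq_len(k), function(i) {
        p <- preds[i, , drop = FALSE]
        t <- truth[[nm]]
        any(t$chrom == p$chrom & t$strand == p$strand &
              t$start < p$end & t$end > p$start)
      }, logical(1))
      if (weighted) {
        tp <- tp + sum(hits) / k
      } else if (any(hits)) {
        tp <- tp + 1
      }
    } else {
      # all predictions for a non-orthologous lncRNA are false: the share
      # is k/k = 1 under weighting, identical to the unweighted count
      fp <- fp + 1
    }
  }
  tn <- total_non_ortho - fp
  fn <- total_ortho - tp
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  counts <- list(tp = tp, fp = fp, tn = tn, fn = fn,
                 total_ortho = total_ortho,
                 total_non_ortho = total_non_ortho)
  metrics <- list(
    TPR = ratio(tp, total_ortho),
    FPR = ratio(fp, total_non_ortho),
    TNR = ratio(tn, total_non_ortho),
    FNR = ratio(fn, total_ortho),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    precision = ratio(tp, tp + fp),
    F1 = ratio(tp, tp + 0.5 * (fp + fn))
  )
  list(counts = counts, metrics = metrics)
}

#' Read a two-column truth mapping plus the subject truth BED
#'
#' @param mapping_path TSV with columns: query lncRNA name, subject
#'   orthologue name (no header). lncRNAs absent from the mapping are
#'   non-orthologous.
#' @param truth_bed_path BED of true subject orthologues (named).
#' @param universe character vector of all evaluated lncRNA names.
#' @return named list suitable as \code{truth} for
#'   [evaluate_predictions()].
#' @export
read_truth <- function(mapping_path, truth_bed_path, universe) {
  truth_bed <- read_annotation(truth_bed_path, "bed")
  map <- tryCatch(
    utils::read.table(mapping_path, sep = "\t", header = FALSE,
                      col.names = c("lncrna", "orthologue"),
                      colClasses = "character"),
    error = function(e) data.frame(lncrna = character(),
                                   orthologue = character()))
  out <- stats::setNames(vector("list", length(universe)), universe)
  for (nm in universe) {
    onames <- map$orthologue[map$lncrna == nm]
    out[[nm]] <- truth_bed[truth_bed$name %in% onames, , drop = FALSE]
  }
  out
}

#' Write benchmark metrics as JSON and a one-line TSV
#' @param result list from [evaluate_predictions()].
#' @param json_path,tsv_path output files (either may be NULL).
#' @return \code{result}, invisibly.
#' @export
write_bench_result <- function(result, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(result, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path)) {
    row <- c(result$counts, result$metrics)
    utils::write.table(as.data.frame(row), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(result)
}
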