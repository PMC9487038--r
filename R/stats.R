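#' Build a background distribution of HSP scores for one lncRNA
#'
#' The query sequence is aligned, with the same engine and parameters as
#' the foreground, to the sequence of every background range; all raw HSP
#' scores are pooled. Ranges yielding no HSP contribute nothing to the
#' score pool but still count in \code{n_ranges}, so the pool's resolution
#' is known even when it is empty.
#'
#' @param query_seq nucleotide string (the same sequence aligned to the
#'   syntenic regions).
#' @param bg_ranges background ranges (already exclusion-filtered), e.g.
#'   from [sample_shuffled_ranges()].
#' @param subject_genome \code{DNAStringSet} of the subject genome.
#' @param params aligner parameters ([aligner_params()]).
#' @param lncrna_name identifier stored with the distribution.
#' @return object of class \code{background_distribution}: list with
#'   \code{lncrna_name}, sorted numeric \code{scores}, \code{n_ranges} and
#'   \code{engine_tag}.
#' @export
build_background <- function(query_seq, bg_ranges, subject_genome,
                             params = aligner_params(), lncrna_name = "") {
  if (nrow(bg_ranges) == 0) stop("bg_ranges is empty")
  scores <- numeric(0)
  for (i in seq_len(nrow(bg_ranges))) {
    subj <- extract_sequence(subject_genome, bg_ranges[i, , drop = FALSE])
    h <- find_hsps(query_seq, subj, params)
    if (nrow(h) > 0) scores <- c(scores, h$score)
  }
  structure(list(lncrna_name = lncrna_name, scores = sort(scores),
                 n_ranges = nrow(bg_ranges), engine_tag = params$engine_tag),
            class = "background_distribution")
}

#' @export
print.background_distribution <- function(x, ...) {
  cat(sprintf("background_distribution '%s': %d scores from %d ranges [%s]\n",
              x$lncrna_name, length(x$scores), x$n_ranges, x$engine_tag))
  invisible(x)
}

#' Serialize / load a background distribution as JSON
#'
#' Lets the significance step be rerun without realigning.
#' @param bg a \code{background_distribution}.
#' @param path JSON file path.
#' @return \code{path} (write) or the restored object (read).
#' @export
write_background <- function(bg, path) {
  jsonlite::write_json(
    list(name = bg$lncrna_name, engine_tag = bg$engine_tag,
         n_ranges = bg$n_ranges, scores = bg$scores),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lncrna_name = x$name, scores = sort(as.numeric(x$scores)),
                 n_ranges = as.integer(x$n_ranges), engine_tag = x$engine_tag),
            class = "background_distribution")
}

#' Empirical right-sided p-value of an HSP score
#'
#' Permutation-test estimator with a pseudo-count:
#' \deqn{p = (1 + \#\{b \ge s\}) / (1 + |B|)}
#' over the background score multiset B, which guarantees p in (0, 1].
#' When the background produced zero HSPs the resolution of the null is
#' bounded by the number of ranges aligned, and the p-value is defined as
#' \code{1 / (1 + n_ranges)}: the query aligned nowhere random in
#' \code{n_ranges} attempts, which is evidence of specificity.
#'
#' @param score raw HSP score (vectorized).
#' @param bg a \code{background_distribution}.
#' @return p-values in (0, 1].
#' @export
empirical_pvalue <- function(score, bg) {
  stopifnot(inherits(bg, "background_distribution"))
  if (length(bg$scores) == 0) {
    return(rep(1 / (1 + bg$n_ranges), length(score)))
  }
  nb <- length(bg$scores)
  # scores are sorted ascending: count b >= s by binary search
  vapply(score, function(s) {
    ge <- nb - findInterval(s - 1e-12, bg$scores)
    (1 + ge) / (1 + nb)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment: \code{q_(i) = min_{j >= i} m p_(j) / j} on the
#' sorted p-values, mapped back to input order.
#'
#' @param pvals p-values in (0, 1].
#' @return q-values in (0, 1], same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Assign q-values and significance flags to a family of HSPs
#'
#' The multiple-testing family is all HSPs of one lncRNA across all its
#' syntenic regions. Significance is strict: \code{q < alpha}, controlling
#' the false discovery rate at \code{alpha * 100\%}.
#'
#' @param hsps HSP data frame with a \code{p_value} column.
#' @param alpha FDR level in (0, 1); default 0.05.
#' @return the same data frame with \code{q_value} and logical
#'   \code{significant} columns appended.
#' @export
filter_significant <- function(hsps, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(hsps) == 0) {
    hsps$q_value <- numeric(0)
    hsps$significant <- logical(0)
    return(hsps)
  }
  hsps$q_value <- benjamini_hochberg(hsps$p_value)
  hsps$significant <- hsps$q_value < alpha
  hsps
}
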