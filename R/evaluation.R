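## evaluation: exact intron-chain matching, precision, adjusted precision.
##
## A predicted multi-exon transcript "matches" iff its (chrom, strand,
## intron chain) equals that of some ground-truth transcript exactly;
## terminal exon boundaries are not compared. Precision is
## matching / assembled. Adjusted precision compares two methods at equal
## sensitivity: the lower-scoring predictions of X are removed, one at a
## time in ascending score order, until X's matching count first equals
## the target sensitivity; the precision of the retained set is reported.

#' Match predictions against ground truth
#'
#' @param predicted Table with chrom, strand, chain (one cell's
#'   predictions; duplicates are counted once).
#' @param truth Table with chrom, strand, chain.
#' @param cell Optional cell id recorded in the result.
#' @return List of class \code{eval_result}: cell, n_assembled,
#'   n_matching, precision (0 when nothing is assembled).
#' @export
match_transcripts <- function(predicted, truth, cell = NA_character_) {
  predicted <- as.data.table(predicted); truth <- as.data.table(truth)
  pk <- unique(full_chain_key(predicted$chrom, predicted$strand, predicted$chain))
  tk <- unique(full_chain_key(truth$chrom, truth$strand, truth$chain))
  n_assembled <- length(pk)
  n_matching <- sum(pk %chin% tk)
  structure(list(cell = cell, n_assembled = n_assembled,
                 n_matching = n_matching,
                 precision = if (n_assembled) n_matching / n_assembled else 0),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result>%s %d/%d matching, precision %.4f\n",
              if (is.na(x$cell)) "" else paste0(" cell=", x$cell),
              x$n_matching, x$n_assembled, x$precision))
  invisible(x)
}

#' Per-cell evaluation of a prediction set
#'
#' @param predictions Table with cell, chrom, strand, chain.
#' @param truth_cells Table with cell, chrom, strand, chain.
#' @return data.table with one row per cell present in either input:
#'   n_assembled, n_matching, precision.
#' @export
evaluate_cells <- function(predictions, truth_cells) {
  predictions <- as.data.table(predictions)
  truth_cells <- as.data.table(truth_cells)
  cells <- sort(unique(c(predictions$cell, truth_cells$cell)))
  rbindlist(lapply(cells, function(cc) {
    r <- match_transcripts(predictions[cell == cc], truth_cells[cell == cc], cc)
    data.table(cell = cc, n_assembled = r$n_assembled,
               n_matching = r$n_matching, precision = r$precision)
  }))
}

## deduplicate scored predictions by chain key, keeping max score, and
## flag matches
dedup_scored <- function(X, truth) {
  X <- as.data.table(X)
  truth <- as.data.table(truth)
  X[, key_ := full_chain_key(chrom, strand, chain)]
  setorder(X, key_, -score)
  X <- X[!duplicated(key_)]
  tk <- unique(full_chain_key(truth$chrom, truth$strand, truth$chain))
  X[, matched := key_ %chin% tk]
  X
}

#' Adjusted precision at a target sensitivity
#'
#' Removes X's transcripts in ascending score order (ties broken by
#' descending lexicographic chain order, blind to match status) until X's
#' matching count first equals \code{y_sensitivity}, then returns the
#' precision of the retained set. If X cannot reach the target (its
#' matching count is already below it), the comparison is undefined and
#' \code{NA} is returned.
#'
#' @param X Scored predictions: chrom, strand, chain, score.
#' @param y_sensitivity Target matching count (the other method's
#'   sensitivity).
#' @param truth Ground-truth table (chrom, strand, chain).
#' @return Precision of the retained set, or \code{NA_real_} when not
#'   comparable.
#' @export
adjusted_precision <- function(X, y_sensitivity, truth) {
  X <- dedup_scored(X, truth)
  m <- sum(X$matched)
  if (y_sensitivity > m) return(NA_real_)
  ## removal order: ascending score, ties by descending padded chain key
  pk <- padded_chain_key(X$chain)
  o <- order(X$score, -xtfrm(pk))
  removed <- logical(nrow(X))
  cur <- m
  for (i in o) {
    if (cur == y_sensitivity) break
    removed[i] <- TRUE
    if (X$matched[i]) cur <- cur - 1L
  }
  kept <- !removed
  n_kept <- sum(kept)
  if (n_kept == 0L) return(0)
  sum(X$matched[kept]) / n_kept
}

#' Precision-recall curve over score thresholds
#'
#' Sweeps the distinct score values as retention thresholds (retain
#' score >= threshold); the final point (lowest threshold) equals the raw
#' sensitivity and precision of the full set.
#'
#' @inheritParams adjusted_precision
#' @return data.table with columns threshold, n_retained, n_matching
#'   (sensitivity) and precision, ordered by descending threshold.
#' @export
pr_curve <- function(X, truth) {
  X <- dedup_scored(X, truth)
  if (nrow(X) == 0L) {
    return(data.table(threshold = numeric(0), n_retained = integer(0),
                      n_matching = integer(0), precision = numeric(0)))
  }
  ths <- sort(unique(X$score), decreasing = TRUE)
  rbindlist(lapply(ths, function(th) {
    keep <- X$score >= th
    data.table(threshold = th, n_retained = sum(keep),
               n_matching = sum(X$matched & keep),
               precision = sum(X$matched & keep) / sum(keep))
  }))
}

#' Write a per-cell evaluation report
#'
#' @param results \code{\link{evaluate_cells}} output.
#' @param path TSV path; \code{NULL} returns the summary list instead.
#' @return List with the per-cell table and aggregate medians.
#' @export
evaluation_report <- function(results, path = NULL) {
  results <- as.data.table(results)
  summary <- list(per_cell = results,
                  median_matching = stats::median(results$n_matching),
                  median_precision = stats::median(results$precision))
  if (!is.null(path)) fwrite(results, path, sep = "\t")
  summary
}
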