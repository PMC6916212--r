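# Ground-truth-based evaluation metrics: sum-of-pairs alignment
# precision/recall/F-score against a reference alignment, and the Rand
# index of a clustering against reference groups. Character-agnostic
# (nucleotide or amino acid alike).

msa_matrix <- function(msa) {
  if (is.null(names(msa)) || anyDuplicated(names(msa))) {
    stopf("MSA must be a named character vector with unique ids")
  }
  w <- unique(nchar(msa))
  if (length(w) != 1L) stopf("ragged MSA: rows have unequal widths")
  do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
}

#' Aligned residue pairs of an MSA
#'
#' For every column and every pair of rows with non-gap characters in that
#' column, emits the unordered pair of their 0-based ungapped residue
#' indices. These are the "nucleotide pairs" underlying the sum-of-pairs
#' precision and recall of an alignment.
#'
#' @param msa named character vector of equal-width aligned rows (gap `-`).
#' @return character vector of canonical pair keys
#'   (`"id1#i|id2#j"` with `id1 < id2`).
#' @export
alignment_pairs <- function(msa) {
  m <- msa_matrix(msa)
  ids <- names(msa)
  nongap <- m != "-"
  # 0-based residue index per row at each non-gap column
  ridx <- matrix(NA_integer_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    ridx[r, nongap[r, ]] <- seq_len(sum(nongap[r, ])) - 1L
  }
  ord <- order(ids)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    rows <- ord[nongap[ord, j]]
    if (length(rows) < 2L) next
    pr <- utils::combn(rows, 2L)
    out <- c(out, sprintf("%s#%d|%s#%d", ids[pr[1, ]], ridx[cbind(pr[1, ], j)],
                          ids[pr[2, ]], ridx[cbind(pr[2, ], j)]))
  }
  unique(out)
}

#' Alignment precision, recall and F-score against a reference
#'
#' Precision is the fraction of residue pairs of the estimated alignment
#' that are also in the true alignment; recall the fraction of true pairs
#' recovered; the F-score is their harmonic mean. Conventions: when both
#' pair sets are empty, precision and recall are 1; when `P + R = 0`, F is
#' 0. Both alignments must cover the same sequences (same ids, identical
#' ungapped sequences).
#'
#' @param est_msa,true_msa named character vectors of aligned rows.
#' @return named numeric vector `c(precision, recall, f_score)`.
#' @export
precision_recall_fscore <- function(est_msa, true_msa) {
  if (!setequal(names(est_msa), names(true_msa))) {
    stopf("MSAs cover different sequences: %s",
          paste(union(setdiff(names(est_msa), names(true_msa)),
                      setdiff(names(true_msa), names(est_msa))),
                collapse = ", "))
  }
  for (id in names(est_msa)) {
    if (gsub("-", "", est_msa[[id]], fixed = TRUE) !=
        gsub("-", "", true_msa[[id]], fixed = TRUE)) {
      stopf("ungapped sequence mismatch for id '%s'", id)
    }
  }
  pe <- alignment_pairs(est_msa)
  pt <- alignment_pairs(true_msa)
  inter <- length(intersect(pe, pt))
  precision <- if (length(pe)) inter / length(pe) else
    if (length(pt) == 0L) 1 else 0
  recall <- if (length(pt)) inter / length(pt) else
    if (length(pe) == 0L) 1 else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f_score = f)
}

#' Rand index of two clusterings
#'
#' The fraction of item pairs that have the same relation in both
#' clusterings: co-clustered in both or separated in both. Defined as 1
#' when there are fewer than two items. Symmetric in its arguments and
#' invariant under cluster relabelling.
#'
#' @param est,truth named vectors mapping item id -> cluster label; the
#'   two item sets must be identical.
#' @return a number in `[0, 1]`.
#' @export
rand_index <- function(est, truth) {
  if (!setequal(names(est), names(truth))) {
    stopf("clusterings cover different items: %s",
          paste(union(setdiff(names(est), names(truth)),
                      setdiff(names(truth), names(est))),
                collapse = ", "))
  }
  items <- names(truth)
  n <- length(items)
  if (n < 2L) return(1)
  a <- as.character(est[items])
  b <- as.character(truth[items])
  ut <- upper.tri(matrix(0, n, n))
  same_a <- outer(a, a, "==")[ut]
  same_b <- outer(b, b, "==")[ut]
  mean(same_a == same_b)
}
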