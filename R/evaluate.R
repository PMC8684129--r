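# Recovery metrics for comparing pipeline output against a planted truth.

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper over [mclust::adjustedRandIndex()]; labels may differ, only
#' the partition matters.
#'
#' @param a,b Group labels (vectors of equal length, any label type).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Precision and recall of a called set against a planted set
#'
#' @param called,truth Character vectors of ids.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(called, truth) {
  called <- unique(called)
  truth <- unique(truth)
  tp <- length(intersect(called, truth))
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       tp = tp, fp = length(called) - tp, fn = length(truth) - tp)
}

#' Match assigned groups to planted groups by best overlap
#'
#' Greedy maximum-overlap matching of assigned labels to truth labels, so
#' signature recovery can be evaluated per planted group.
#'
#' @param assigned Named (by sample id) assigned labels.
#' @param truth Named planted labels.
#' @return Named vector mapping each assigned label to a truth label.
#' @export
match_groups <- function(assigned, truth) {
  truth <- truth[names(assigned)]
  tab <- table(assigned, truth)
  map <- character(0)
  while (length(dim(tab)) == 2 && all(dim(tab) > 0)) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    map[rownames(tab)[i[1]]] <- colnames(tab)[i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  map
}
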