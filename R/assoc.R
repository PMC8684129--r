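# Stage trends, expression-accessibility correlations, marker filters and
# GSEA input tables.

#' One-tailed Welch t-test
#'
#' Welch (unequal-variance) two-sample t statistic with a one-sided p-value in
#' the stated direction. When both samples have zero variance and equal means
#' there is no evidence either way and p = 0.5.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param direction `"greater"` (mean of `x` exceeds mean of `y`) or
#'   `"less"`.
#' @return One-sided p-value, with the t statistic and df in attributes.
#' @export
one_tailed_t <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per sample")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(0.5, t = 0, df = NA_real_))
    }
    # constant but different: direction decides completely
    agrees <- (mean(x) > mean(y)) == (direction == "greater")
    return(structure(if (agrees) 0 else 1, t = Inf * sign(mean(x) - mean(y)),
                     df = NA_real_))
  }
  ht <- t.test(x, y, alternative = direction, var.equal = FALSE)
  structure(unname(ht$p.value), t = unname(ht$statistic),
            df = unname(ht$parameter))
}

#' Pearson correlation with two-sided p
#'
#' @param x,y Numeric vectors, n >= 3, finite, non-constant.
#' @return list with `r` and `p` (two-sided, t-based).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}

#' Significance stars
#'
#' @param p p-value(s).
#' @param alpha_stars Decreasing bands; default `*` p<0.01, `**` p<0.001,
#'   `***` p<0.0001.
#' @return Character vector of star annotations (`""` when not significant).
#' @export
p_stars <- function(p, alpha_stars = c(0.01, 0.001, 0.0001)) {
  vapply(p, function(pv) {
    strrep("*", sum(pv < alpha_stars))
  }, "")
}

#' Remove tumors in the bottom expression quartile of both marker genes
#'
#' For each marker, the cut is the type-7 quantile of its expression across
#' all samples; samples at or below the cut (`boundary = "lte"`) for BOTH
#' markers are removed. Used with FOXA1 and GATA3 to deplete Basal-like
#' tumors from an expression cohort.
#'
#' @param expr gene x sample expression matrix.
#' @param markers Two marker gene ids (default `c("FOXA1", "GATA3")`).
#' @param quartile Quantile cut (default 0.25).
#' @param boundary `"lte"` (remove when `<=` cut; default) or `"lt"`.
#' @return list with `kept` and `removed` sample id vectors and the `cuts`
#'   used.
#' @export
basal_filter <- function(expr, markers = c("FOXA1", "GATA3"), quartile = 0.25,
                         boundary = c("lte", "lt")) {
  boundary <- match.arg(boundary)
  miss <- setdiff(markers, rownames(expr))
  if (length(miss)) stop("marker gene(s) missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  below <- vapply(markers, function(g) {
    v <- expr[g, ]
    cut <- quantile(v, probs = quartile, type = 7, names = FALSE)
    if (boundary == "lte") v <= cut else v < cut
  }, logical(ncol(expr)))
  cuts <- vapply(markers, function(g) {
    quantile(expr[g, ], probs = quartile, type = 7, names = FALSE)
  }, 0)
  if (all(apply(expr[markers, , drop = FALSE], 1, sd) == 0)) {
    warning("degenerate input: marker expression constant across samples")
  }
  rm_mask <- rowSums(below) == length(markers)
  list(kept = colnames(expr)[!rm_mask], removed = colnames(expr)[rm_mask],
       cuts = cuts)
}

#' Genes with divergent expression between two sample sets
#'
#' Per-gene `log2((mean_a + pc) / (mean_b + pc))`; genes strictly beyond the
#' threshold in either direction are returned.
#'
#' @param expr gene x sample expression matrix.
#' @param samples_a,samples_b Disjoint, non-empty sample id sets.
#' @param pseudo_count Pseudo-count (default 1).
#' @param lfc_threshold Absolute log2FC threshold.
#' @return list: `higher_in_a`, `lower_in_a` (data.frames of `gene_id`,
#'   `log2fc`), and `log2fc` for all genes.
#' @export
divergent_genes <- function(expr, samples_a, samples_b, pseudo_count = 1,
                            lfc_threshold = 1) {
  if (length(intersect(samples_a, samples_b))) stop("sample sets overlap")
  if (!length(samples_a) || !length(samples_b)) stop("empty sample set")
  miss <- setdiff(c(samples_a, samples_b), colnames(expr))
  if (length(miss)) stop("unknown sample(s): ", paste(head(miss, 3), collapse = ", "))
  lfc <- log2((rowMeans(expr[, samples_a, drop = FALSE]) + pseudo_count) /
              (rowMeans(expr[, samples_b, drop = FALSE]) + pseudo_count))
  mk <- function(sel, desc) {
    d <- data.frame(gene_id = names(lfc)[sel], log2fc = unname(lfc[sel]),
                    stringsAsFactors = FALSE)
    d[order(if (desc) -d$log2fc else d$log2fc, d$gene_id), , drop = FALSE]
  }
  list(higher_in_a = mk(lfc > lfc_threshold, TRUE),
       lower_in_a = mk(lfc < -lfc_threshold, FALSE),
       log2fc = lfc)
}

#' Expression tables for the top and bottom deciles of one gene
#'
#' Samples are sorted by the gene's expression (ties broken by sample id for
#' determinism); the top and bottom `floor(n * decile)` samples are selected
#' and the per-gene mean expression within each selection is returned — the
#' input GSEA consumes.
#'
#' @param expr gene x sample expression matrix.
#' @param gene Gene id to rank samples by.
#' @param decile Selection fraction (default 0.10).
#' @return list: `top` and `bottom`, each with `samples` and `means`
#'   (named per-gene mean expression); and `n_selected`.
#' @export
decile_tables <- function(expr, gene, decile = 0.10) {
  if (!gene %in% rownames(expr)) stop("gene not in expression matrix: ", gene)
  n <- ncol(expr)
  k <- floor(n * decile)
  if (k < 1) stop("n * decile < 1 (n = ", n, ")")
  ord <- order(expr[gene, ], colnames(expr))
  bottom <- colnames(expr)[ord[seq_len(k)]]
  top <- colnames(expr)[ord[seq(n - k + 1L, n)]]
  list(top = list(samples = top, means = rowMeans(expr[, top, drop = FALSE])),
       bottom = list(samples = bottom,
                     means = rowMeans(expr[, bottom, drop = FALSE])),
       n_selected = k)
}

#' Stage trend comparisons
#'
#' One-tailed Welch t-tests between all adjacent stage pairs plus the extreme
#' (first vs last) pair, in the stated direction, with significance stars.
#'
#' @param values_by_stage Named list of numeric vectors, ordered by stage
#'   (e.g. `list(I = ..., II = ..., III = ..., IV = ...)`); each stage needs
#'   at least 2 values.
#' @param direction `"increasing"` (later stage larger) or `"decreasing"`.
#' @param alpha_stars Star bands, see [p_stars()].
#' @return data.frame of class `stage_comparison`: `stage_a`, `stage_b`,
#'   `mean_a`, `mean_b`, `p`, `stars`.
#' @export
stage_trend <- function(values_by_stage, direction = c("increasing", "decreasing"),
                        alpha_stars = c(0.01, 0.001, 0.0001)) {
  direction <- match.arg(direction)
  stages <- names(values_by_stage)
  if (length(stages) < 2) stop("need at least two stages")
  if (any(lengths(values_by_stage) < 2)) stop("each stage needs >= 2 values")
  pairs <- cbind(seq_len(length(stages) - 1L), seq_len(length(stages) - 1L) + 1L)
  if (length(stages) > 2) pairs <- rbind(pairs, c(1L, length(stages)))
  # "increasing": later stage greater, so test stage_b > stage_a
  dir_b <- if (direction == "increasing") "greater" else "less"
  res <- apply(pairs, 1, function(ij) {
    a <- values_by_stage[[ij[1]]]
    b <- values_by_stage[[ij[2]]]
    p <- one_tailed_t(b, a, direction = dir_b)
    c(mean_a = mean(a), mean_b = mean(b), p = as.numeric(p))
  })
  out <- data.frame(stage_a = stages[pairs[, 1]], stage_b = stages[pairs[, 2]],
                    t(res), stringsAsFactors = FALSE)
  out$stars <- p_stars(out$p, alpha_stars)
  class(out) <- c("stage_comparison", "data.frame")
  out
}

#' Split a per-sample vector by tumor stage
#'
#' @param values Named per-sample numeric vector.
#' @param metadata Metadata data.frame with `sample_id` and `stage`.
#' @param stages Stage order (default I-IV; `"unknown"` dropped).
#' @return Named list of per-stage value vectors (stages present only).
#' @export
split_by_stage <- function(values, metadata,
                           stages = c("I", "II", "III", "IV")) {
  stage <- setNames(metadata$stage, metadata$sample_id)[names(values)]
  out <- lapply(stages, function(s) unname(values[!is.na(stage) & stage == s]))
  names(out) <- stages
  out[lengths(out) > 0]
}
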