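# Embedding of tumors from the rank matrix and chromatin-group assignment.

#' Embed tumors in two dimensions
#'
#' Projects the samples (columns of the rank-normalized matrix) to 2-D. The
#' default reducer is UMAP (n_neighbors = 10) on Euclidean distances between
#' rank columns; the reducer is pluggable and `"mds"` (classical
#' multidimensional scaling, fully deterministic) satisfies the same contract.
#'
#' @param ranks region x sample rank matrix (samples are embedded).
#' @param n_neighbors UMAP neighborhood size; requires at least
#'   `n_neighbors + 1` samples.
#' @param seed Integer seed controlling the embedding's stochastic steps.
#' @param method `"umap"` (default) or `"mds"`.
#' @return data.frame with columns `sample_id`, `dim1`, `dim2`; the seed and
#'   method used are kept in attributes.
#' @export
embed_samples <- function(ranks, n_neighbors = 10, seed = 1,
                          method = c("umap", "mds")) {
  method <- match.arg(method)
  stopifnot(is.matrix(ranks), !is.null(colnames(ranks)))
  x <- t(ranks)  # samples in rows
  if (method == "umap") {
    if (nrow(x) < n_neighbors + 1) {
      stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " samples, got ",
           nrow(x))
    }
    set.seed(as.integer(seed))
    coords <- uwot::umap(x, n_neighbors = n_neighbors, n_components = 2,
                         metric = "euclidean", n_threads = 1,
                         n_sgd_threads = 0, batch = FALSE)
  } else {
    if (nrow(x) < 3) stop("need at least 3 samples")
    coords <- cmdscale(dist(x), k = 2)
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  }
  if (any(!is.finite(coords))) stop("non-finite embedding coordinates")
  out <- data.frame(sample_id = colnames(ranks),
                    dim1 = coords[, 1], dim2 = coords[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  attr(out, "n_neighbors") <- n_neighbors
  out
}

#' Assign chromatin groups from an embedding
#'
#' Centroid-based k-partition clustering (k-means with multiple restarts,
#' seeded) of the 2-D embedding coordinates. Group labels are re-indexed
#' 1..k by decreasing separation along embedding dimension 2 — the axis along
#' which most chromatin differences fall — so group 1 is the most distinct
#' group; ties break by decreasing group size, then centroid order.
#'
#' @param embedding Output of [embed_samples()].
#' @param k Number of groups (>= 2).
#' @param seed Integer seed for the clustering restarts.
#' @return data.frame with columns `sample_id`, `group` (integer in 1..k).
#' @export
assign_groups <- function(embedding, k = 3, seed = 1) {
  stopifnot(is.data.frame(embedding),
            all(c("sample_id", "dim1", "dim2") %in% colnames(embedding)))
  n <- nrow(embedding)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the ", n, " samples")
  xy <- as.matrix(embedding[, c("dim1", "dim2")])
  set.seed(as.integer(seed))
  uniq <- nrow(unique(xy))
  if (uniq < k) {
    # degenerate: fewer distinct points than groups; each distinct point is a
    # group, extra labels unused collapse onto label 1
    key <- apply(xy, 1, paste, collapse = ",")
    cl <- as.integer(factor(key, levels = unique(key)))
  } else {
    cl <- kmeans(xy, centers = k, nstart = 25, iter.max = 100)$cluster
  }
  # separation along dim2: mean absolute distance of this group's dim2
  # centroid from the other groups' centroids
  cent2 <- tapply(embedding$dim2, cl, mean)
  labs <- as.integer(names(cent2))
  sep <- vapply(seq_along(cent2), function(i) {
    others <- cent2[-i]
    if (!length(others)) 0 else mean(abs(cent2[i] - others))
  }, 0)
  sizes <- as.integer(table(cl)[as.character(labs)])
  ord <- order(-sep, -sizes, labs)
  relabel <- integer(max(labs))
  relabel[labs[ord]] <- seq_along(ord)
  data.frame(sample_id = embedding$sample_id,
             group = relabel[cl],
             stringsAsFactors = FALSE)
}

#' Stratify tumors from a rank matrix
#'
#' Convenience wrapper: embed, then assign groups.
#'
#' @inheritParams embed_samples
#' @inheritParams assign_groups
#' @return list with `embedding` and `groups`.
#' @export
stratify_tumors <- function(ranks, n_neighbors = 10, k = 3, seed = 1,
                            method = c("umap", "mds")) {
  emb <- embed_samples(ranks, n_neighbors = n_neighbors, seed = seed,
                       method = method)
  grp <- assign_groups(emb, k = k, seed = seed)
  list(embedding = emb, groups = grp)
}
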