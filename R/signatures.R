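# Chromatin signature calling and region annotation.

#' Analysis configuration
#'
#' Bundles the thresholds the downstream analyses share: the log2FC
#' pseudo-count (1), the signature threshold (log2FC > 2.5, strict), the UMAP
#' neighborhood (10), the number of chromatin groups (3), the background
#' sample size (5000), the region-to-gene window (1 Mb), the decile and
#' quartile fractions for expression tables and the marker filter, and the
#' significance star bands (p < 0.01, 0.001, 0.0001).
#'
#' @param pseudo_count Pseudo-count added to group means before log2.
#' @param lfc_threshold Signature log2FC threshold (strict `>`).
#' @param n_neighbors UMAP neighborhood size.
#' @param k_groups Number of chromatin groups.
#' @param background_n Background regions sampled for motif enrichment.
#' @param gene_window Region-to-gene association window in bp.
#' @param decile,quartile Fractions for expression decile tables and the
#'   marker-gene quartile filter.
#' @param alpha_stars Decreasing p-value bands for `*`, `**`, `***`.
#' @param seed Default seed for stochastic steps.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(pseudo_count = 1, lfc_threshold = 2.5,
                            n_neighbors = 10, k_groups = 3,
                            background_n = 5000, gene_window = 1e6,
                            decile = 0.10, quartile = 0.25,
                            alpha_stars = c(0.01, 0.001, 0.0001),
                            seed = 1) {
  stopifnot(pseudo_count > 0, lfc_threshold > 0, n_neighbors > 0,
            k_groups >= 2, background_n > 0, gene_window > 0,
            decile > 0, decile < 0.5, quartile > 0, quartile < 0.5,
            all(diff(alpha_stars) < 0))
  structure(list(pseudo_count = pseudo_count, lfc_threshold = lfc_threshold,
                 n_neighbors = n_neighbors, k_groups = k_groups,
                 background_n = background_n, gene_window = gene_window,
                 decile = decile, quartile = quartile,
                 alpha_stars = alpha_stars, seed = seed),
            class = "analysis_config")
}

# normalize a group assignment (data.frame or named vector) to an integer
# vector aligned with the matrix columns
group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    g <- setNames(as.integer(groups$group), groups$sample_id)
  } else {
    g <- setNames(as.integer(groups), names(groups))
  }
  miss <- setdiff(sample_ids, names(g))
  if (length(miss)) stop("no group for sample(s): ", paste(head(miss, 3), collapse = ", "))
  unname(g[sample_ids])
}

#' Group-vs-rest log2 fold change of accessibility
#'
#' For each region, log2 of the ratio of its average accessibility within the
#' given tumor group to its average in all other tumors, with a pseudo-count
#' added to both means: `log2((mean_in + pc) / (mean_out + pc))`.
#'
#' @param m region x sample accessibility matrix (raw scale, not ranks).
#' @param groups Group assignment (data.frame from [assign_groups()] or named
#'   vector).
#' @param g Group to contrast against the rest.
#' @param pseudo_count Pseudo-count (default 1).
#' @return Named numeric vector of per-region log2FC.
#' @export
group_log2fc <- function(m, groups, g, pseudo_count = 1) {
  gv <- group_vector(groups, colnames(m))
  inside <- gv == g
  if (!any(inside)) stop("group ", g, " has no members")
  if (all(inside)) stop("group ", g, " contains every sample")
  mean_in <- rowMeans(m[, inside, drop = FALSE])
  mean_out <- rowMeans(m[, !inside, drop = FALSE])
  setNames(log2((mean_in + pseudo_count) / (mean_out + pseudo_count)),
           rownames(m))
}

#' Define one group's chromatin signature
#'
#' Regions whose group-vs-rest log2FC strictly exceeds the threshold.
#'
#' @inheritParams group_log2fc
#' @param lfc_threshold Strict threshold on log2FC (default 2.5).
#' @return data.frame with `region_id`, `log2fc`, sorted by decreasing
#'   log2fc; possibly empty.
#' @export
define_signature <- function(m, groups, g, lfc_threshold = 2.5,
                             pseudo_count = 1) {
  lfc <- group_log2fc(m, groups, g, pseudo_count = pseudo_count)
  keep <- lfc > lfc_threshold
  out <- data.frame(region_id = names(lfc)[keep], log2fc = unname(lfc[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$log2fc, out$region_id), , drop = FALSE]
}

#' Call all chromatin signatures
#'
#' @inheritParams group_log2fc
#' @param cfg An [analysis_config()].
#' @return Named list (`"1"`, `"2"`, ...) of [define_signature()] tables, plus
#'   the thresholds used in attributes.
#' @export
call_signatures <- function(m, groups, cfg = analysis_config()) {
  gv <- group_vector(groups, colnames(m))
  out <- lapply(sort(unique(gv)), function(g) {
    define_signature(m, groups, g, lfc_threshold = cfg$lfc_threshold,
                     pseudo_count = cfg$pseudo_count)
  })
  names(out) <- as.character(sort(unique(gv)))
  attr(out, "lfc_threshold") <- cfg$lfc_threshold
  attr(out, "pseudo_count") <- cfg$pseudo_count
  out
}

#' Distance from region midpoints to the nearest TSS
#'
#' Midpoint is `floor((start + end) / 2)` in 0-based coordinates. Regions on
#' chromosomes without any TSS get `NA` with a warning.
#'
#' @param regions Region set (`GRanges`).
#' @param tss data.frame with columns `chrom`, `position` (0-based) and
#'   optionally `gene_id`, `strand`.
#' @return Named numeric vector of absolute distances in bp (`NA` when
#'   undefined).
#' @export
distance_to_tss <- function(regions, tss) {
  stopifnot(nrow(tss) > 0, all(c("chrom", "position") %in% colnames(tss)))
  df <- region_df(regions)
  mid <- (df$start + df$end) %/% 2L
  out <- rep(NA_real_, nrow(df))
  names(out) <- df$region_id
  for (ch in unique(df$chrom)) {
    pos <- sort(tss$position[tss$chrom == ch])
    ri <- which(df$chrom == ch)
    if (!length(pos)) next
    out[ri] <- vapply(mid[ri], function(p) min(abs(pos - p)), 0)
  }
  if (anyNA(out)) warning(sum(is.na(out)), " region(s) on chromosomes without a TSS")
  out
}

#' CpG dinucleotide density of regions
#'
#' Count of `CG` dinucleotides (case-insensitive; windows containing `N` never
#' match) divided by region length.
#'
#' @param regions Region set (`GRanges`).
#' @param genome Named character vector from [read_fasta()].
#' @return Named numeric vector of per-region CpG density.
#' @export
cpg_density <- function(regions, genome) {
  df <- region_df(regions)
  miss <- setdiff(unique(df$chrom), names(genome))
  if (length(miss)) stop("region chromosome(s) absent from genome: ",
                         paste(miss, collapse = ", "))
  too_long <- df$end > nchar(genome[df$chrom])
  if (any(too_long)) stop("region exceeds chromosome length: ",
                          df$region_id[which(too_long)[1]])
  seqs <- toupper(substring(genome[df$chrom], df$start + 1L, df$end))
  counts <- vapply(seqs, function(s) {
    if (nchar(s) < 2L) return(0L)
    sum(substring(s, 1:(nchar(s) - 1L), 2:nchar(s)) == "CG")
  }, 0L, USE.NAMES = FALSE)
  setNames(counts / (df$end - df$start), df$region_id)
}

#' Associate regions with nearby genes
#'
#' For each region, all genes whose TSS lies within `window` bp (inclusive) of
#' the region midpoint, on the same chromosome.
#'
#' @param regions Region set (`GRanges`).
#' @param gene_tss data.frame with columns `gene_id`, `chrom`, `position`
#'   (0-based TSS).
#' @param window Association window in bp (default 1 Mb).
#' @return Named list: region id -> character vector of gene ids.
#' @export
nearby_genes <- function(regions, gene_tss, window = 1e6) {
  stopifnot(all(c("gene_id", "chrom", "position") %in% colnames(gene_tss)))
  if (anyDuplicated(gene_tss$gene_id)) stop("duplicate gene ids in TSS table")
  df <- region_df(regions)
  mid <- (df$start + df$end) %/% 2L
  out <- vector("list", nrow(df))
  names(out) <- df$region_id
  for (i in seq_len(nrow(df))) {
    sel <- gene_tss$chrom == df$chrom[i] &
      abs(gene_tss$position - mid[i]) <= window
    out[[i]] <- gene_tss$gene_id[sel]
  }
  out
}

#' Sample size-matched background regions
#'
#' Draws `n` accessible peak regions without replacement, matched to the
#' target regions' length distribution: targets are split into length-decile
#' strata and each stratum contributes its share of the sample, drawn from
#' peaks whose lengths fall in the same stratum. Deterministic given the seed.
#'
#' @param peaks Region set to sample from (the accessible peak universe).
#' @param targets Region set whose length distribution is matched.
#' @param n Number of background regions (default 5000).
#' @param seed Integer seed.
#' @return Region set of `n` sampled peaks (original ids kept).
#' @export
sample_background <- function(peaks, targets, n = 5000, seed = 1) {
  np <- length(peaks)
  if (n > np) stop("requested ", n, " background regions from ", np, " peaks")
  if (n == np) return(peaks)
  plen <- GenomicRanges::width(peaks)
  tlen <- GenomicRanges::width(targets)
  breaks <- unique(quantile(tlen, probs = seq(0, 1, 0.1), type = 7))
  if (length(breaks) < 3) {
    # degenerate target lengths: stratify by the peak length deciles instead,
    # so draws stay inside the decile containing the target length
    breaks <- unique(quantile(plen, probs = seq(0, 1, 0.1), type = 7))
  }
  breaks <- c(-Inf, breaks[-c(1, length(breaks))], Inf)
  t_str <- cut(tlen, breaks = breaks, include.lowest = TRUE)
  p_str <- cut(plen, breaks = breaks, include.lowest = TRUE)
  quota <- round(n * as.numeric(table(t_str)) / length(tlen))
  # fix rounding drift so the quotas sum to n
  drift <- n - sum(quota)
  if (drift != 0) {
    i <- which.max(quota)
    quota[i] <- quota[i] + drift
  }
  set.seed(as.integer(seed))
  picked <- integer(0)
  short <- 0L
  for (s in seq_along(levels(t_str))) {
    pool <- setdiff(which(as.integer(p_str) == s), picked)
    take <- min(quota[s], length(pool))
    short <- short + quota[s] - take
    if (take > 0) picked <- c(picked, sample(pool, take))
  }
  if (short > 0) {  # strata exhausted; top up from the remaining peaks
    pool <- setdiff(seq_len(np), picked)
    picked <- c(picked, sample(pool, short))
    warning("length strata exhausted for ", short,
            " draw(s); topped up from all peaks")
  }
  peaks[sort(picked)]
}
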