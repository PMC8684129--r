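# Union peak construction and the cohort accessibility matrix.

#' Merge peak sets into a union peak set
#'
#' Base-pair union across all input peak sets: overlapping and book-ended
#' (abutting, in half-open coordinates) intervals are merged into maximal
#' intervals, and the result is sorted. This is the shared coordinate system
#' the whole cohort is scored on.
#'
#' @param peak_sets List of region sets (`GRanges`), one per sample, or a
#'   single region set.
#' @return Sorted, merged region set with fresh region ids.
#' @export
merge_peaks <- function(peak_sets) {
  if (is(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  if (!length(peak_sets)) stop("no peak sets given")
  if (any(!vapply(peak_sets, length, 0L))) stop("empty peak set in input")
  stripped <- lapply(unname(peak_sets), function(g) {
    g <- GenomicRanges::granges(g)
    names(g) <- NULL
    GenomicRanges::strand(g) <- "*"
    g
  })
  all_peaks <- suppressWarnings(Reduce(c, stripped))
  # reduce() with the default min.gapwidth = 1 merges book-ended intervals
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_peaks),
                                  ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                   start = GenomicRanges::start(merged) - 1L,
                   end = GenomicRanges::end(merged))
  region_set(df$chrom, df$start, df$end)
}

#' Score regions against a coverage track
#'
#' Length-weighted mean of the track's step values over each region, counting
#' uncovered bases as zero signal. Regions on chromosomes absent from the
#' track score 0 with a warning.
#'
#' @param regions Sorted region set (`GRanges`).
#' @param track A `coverage_track`.
#' @return Numeric vector of per-region mean signal, named by region id.
#' @export
score_regions <- function(regions, track) {
  stopifnot(is(regions, "GRanges"), inherits(track, "coverage_track"))
  out <- numeric(length(regions))
  names(out) <- names(regions)
  if (!length(regions) || !nrow(track)) return(out)
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  missing_chrom <- setdiff(unique(rchrom), unique(track$chrom))
  if (length(missing_chrom)) {
    warning("track has no steps on: ", paste(missing_chrom, collapse = ", "),
            "; those regions score 0")
  }
  for (ch in intersect(unique(rchrom), unique(track$chrom))) {
    ri <- which(rchrom == ch)
    ti <- which(track$chrom == ch)
    r_ir <- IRanges::IRanges(GenomicRanges::start(regions)[ri],
                             GenomicRanges::end(regions)[ri])
    t_ir <- IRanges::IRanges(track$start[ti] + 1L, track$end[ti])
    ov <- IRanges::findOverlaps(r_ir, t_ir)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(r_ir[queryHits(ov)],
                                            t_ir[subjectHits(ov)]))
    sums <- tapply(w * track$value[ti][subjectHits(ov)], queryHits(ov), sum)
    out[ri[as.integer(names(sums))]] <- as.numeric(sums) /
      IRanges::width(r_ir)[as.integer(names(sums))]
  }
  out
}

#' Build the cohort accessibility matrix
#'
#' Scores every sample's coverage track over the union peak set.
#'
#' @param regions Union peak set.
#' @param tracks Named list of `coverage_track`s, one per sample.
#' @return region x sample numeric matrix.
#' @export
build_accessibility_matrix <- function(regions, tracks) {
  stopifnot(length(tracks) > 0, !is.null(names(tracks)))
  m <- vapply(tracks, function(tr) score_regions(regions, tr),
              numeric(length(regions)))
  m <- matrix(m, nrow = length(regions),
              dimnames = list(names(regions), names(tracks)))
  m
}

#' Rank-normalize an accessibility matrix
#'
#' Replaces each tumor's (column's) scores by their ascending ranks, from
#' least to most accessible region; ties get the mean of the ranks they cover
#' (fractional ranking), so every column sums to n(n+1)/2.
#'
#' @param m region x sample accessibility matrix, non-negative.
#' @return Matrix of the same shape holding per-column ranks.
#' @export
rank_normalize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) > 0, ncol(m) > 0)
  if (any(!is.finite(m))) stop("non-finite accessibility values")
  r <- apply(m, 2L, rank, ties.method = "average")
  dimnames(r) <- dimnames(m)
  r
}
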