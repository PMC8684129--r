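# Motif scanning in accessible regions and motif-level summaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param s Character vector of sequences (A/C/G/T/N).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Construct a motif model
#'
#' Either a 4 x L probability matrix (rows A, C, G, T; columns sum to 1) or a
#' consensus string, which is converted to a sharp probability matrix (0.991
#' on the consensus base, 0.003 elsewhere). A hit requires a log-odds score of
#' at least `score_fraction` times the maximum achievable score.
#'
#' @param name Motif name.
#' @param consensus Consensus string over A/C/G/T (>= 4 bases), or `NULL`.
#' @param matrix 4 x L probability matrix, or `NULL`.
#' @param score_fraction Fraction of the maximum log-odds score required for a
#'   hit (default 0.8).
#' @return list of class `motif_model` with elements `name`, `prob` (4 x L),
#'   `consensus`, `score_fraction`.
#' @export
motif_model <- function(name, consensus = NULL, matrix = NULL,
                        score_fraction = 0.8) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  if (is.null(matrix)) {
    if (is.null(consensus)) stop("need a consensus or a probability matrix")
    consensus <- toupper(consensus)
    bases <- strsplit(consensus, "")[[1]]
    if (length(bases) < 4) stop("motif must be at least 4 bases long")
    if (!all(bases %in% DNA_BASES)) stop("consensus must be over A/C/G/T")
    matrix <- vapply(bases, function(b) {
      p <- rep(0.003, 4)
      p[match(b, DNA_BASES)] <- 0.991
      p
    }, numeric(4))
  } else {
    matrix <- as.matrix(matrix)
    if (nrow(matrix) != 4 || ncol(matrix) < 4) stop("matrix must be 4 x L, L >= 4")
    if (any(abs(colSums(matrix) - 1) > 1e-6)) stop("matrix columns must sum to 1")
    if (is.null(consensus)) {
      consensus <- paste(DNA_BASES[apply(matrix, 2, which.max)], collapse = "")
    }
  }
  rownames(matrix) <- DNA_BASES
  structure(list(name = name, prob = matrix, consensus = consensus,
                 score_fraction = score_fraction),
            class = "motif_model")
}

#' Read motif models from a TSV
#'
#' Two tab-separated columns: motif name and consensus string; an optional
#' third column overrides the default score fraction.
#'
#' @param path Path to the motif TSV (a header line is allowed).
#' @param score_fraction Default hit threshold as fraction of max score.
#' @return Named list of `motif_model`s.
#' @export
read_motifs <- function(path, score_fraction = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][1]), "name")) {
    fields <- fields[-1]
  }
  if (!length(fields)) stop("no motifs in ", path)
  models <- lapply(fields, function(f) {
    sf <- if (length(f) >= 3) as.numeric(f[3]) else score_fraction
    motif_model(f[1], consensus = f[2], score_fraction = sf)
  })
  setNames(models, vapply(models, `[[`, "", "name"))
}

# log-odds score of every window of `code` (integer codes 1..4, NA for N)
# against a 4 x L log-odds matrix; windows containing NA score NA
score_windows <- function(code, lo) {
  L <- ncol(lo)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n - 1L)]
    v <- lo[cbind(cj, j)]
    v[is.na(cj)] <- NA_real_
    s <- s + v
  }
  s
}

encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

#' Scan a motif over accessible regions
#'
#' Scores the motif's log-odds (base-2, against the given background base
#' frequencies) at every window of every region, on both strands. A window is
#' a hit when its score reaches `score_fraction` of the maximum achievable
#' score; windows containing `N` never hit. Regions shorter than the motif
#' yield no hits.
#'
#' @param model A [motif_model()].
#' @param regions Region set (`GRanges`).
#' @param genome Named character vector from [read_fasta()].
#' @param background Background base frequencies for A, C, G, T (default
#'   uniform 0.25).
#' @return data.frame of occurrences: `motif`, `region_id`, `chrom`, `start`
#'   (0-based genome coordinate), `end`, `strand`, `score`.
#' @export
scan_motif <- function(model, regions, genome,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(model, "motif_model"), length(background) == 4,
            all(background > 0))
  lo <- log2(model$prob / as.numeric(background))
  L <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  threshold <- model$score_fraction * max_score
  # minus-strand hits = plus-strand hits of the reverse-complemented matrix
  lo_rc <- lo[4:1, L:1, drop = FALSE]
  rownames(lo_rc) <- DNA_BASES
  df <- region_df(regions)
  miss <- setdiff(unique(df$chrom), names(genome))
  if (length(miss)) stop("region chromosome(s) absent from genome: ",
                         paste(miss, collapse = ", "))
  hits <- vector("list", nrow(df) * 2L)
  hi <- 0L
  for (i in seq_len(nrow(df))) {
    seq_i <- substring(genome[[df$chrom[i]]], df$start[i] + 1L, df$end[i])
    code <- encode_dna(seq_i)
    for (str in c("+", "-")) {
      s <- score_windows(code, if (str == "+") lo else lo_rc)
      at <- which(!is.na(s) & s >= threshold - 1e-9)
      if (length(at)) {
        hi <- hi + 1L
        hits[[hi]] <- data.frame(
          motif = model$name, region_id = df$region_id[i],
          chrom = df$chrom[i],
          start = df$start[i] + at - 1L,
          end = df$start[i] + at - 1L + L,
          strand = str, score = s[at], stringsAsFactors = FALSE)
      }
    }
  }
  if (hi == 0L) {
    return(data.frame(motif = character(), region_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits[seq_len(hi)])
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

#' Motif enrichment in target vs background regions
#'
#' Fold = fraction of target regions with at least one occurrence divided by
#' the same fraction in background regions; p = one-sided binomial tail
#' probability of the target hit count at the background hit rate. When no
#' background region has a hit the fold is undefined (`Inf`) and the p-value
#' uses the rate floor `1 / (2 * n_background)`.
#'
#' @param target,background Region sets (`GRanges`).
#' @param occurrences Occurrence table from [scan_motif()] covering both sets.
#' @return list: `fold`, `p`, `target_hits`, `target_n`, `background_hits`,
#'   `background_n`.
#' @export
motif_enrichment <- function(target, background, occurrences) {
  if (!length(target)) stop("empty target region set")
  if (!length(background)) stop("empty background region set")
  hit_ids <- unique(occurrences$region_id)
  kt <- sum(names(target) %in% hit_ids)
  kb <- sum(names(background) %in% hit_ids)
  nt <- length(target)
  nb <- length(background)
  if (kb == 0) {
    rate <- 1 / (2 * nb)
    fold <- Inf
  } else {
    rate <- kb / nb
    fold <- (kt / nt) / rate
  }
  p <- pbinom(kt - 1, nt, rate, lower.tail = FALSE)
  list(fold = fold, p = p, target_hits = kt, target_n = nt,
       background_hits = kb, background_n = nb)
}

#' Per-sample mean accessibility over motif-bearing regions
#'
#' Averages each sample's accessibility across the distinct regions that
#' contain at least one occurrence of the motif; multiple occurrences in one
#' region count once.
#'
#' @param m region x sample accessibility matrix.
#' @param occurrences Occurrence table from [scan_motif()].
#' @return Named numeric vector, one mean per sample.
#' @export
motif_accessibility <- function(m, occurrences) {
  if (!nrow(occurrences)) stop("no motif occurrences")
  ids <- unique(occurrences$region_id)
  absent <- setdiff(ids, rownames(m))
  if (length(absent) == length(ids)) {
    stop("no occurrence region is present in the matrix")
  }
  if (length(absent)) {
    warning(length(absent), " occurrence region(s) absent from the matrix; dropped")
    ids <- setdiff(ids, absent)
  }
  colMeans(m[ids, , drop = FALSE])
}

#' Binned signal profile around anchor points
#'
#' For each anchor, the mean signal in `n_bins` equal bins across
#' `[center - half_window, center + half_window)`; minus-strand anchors are
#' reversed so bins read 5' to 3'. Column means ignore anchors whose whole
#' window carries no signal.
#'
#' @param track A `coverage_track`.
#' @param anchors data.frame with columns `chrom`, `center` (0-based) and
#'   optionally `strand`.
#' @param half_window Half window size in bp.
#' @param n_bins Number of bins; must divide `2 * half_window`.
#' @return list: `profile` (anchors x bins matrix), `column_means` (bins with
#'   no-signal anchors excluded), `n_used`.
#' @export
profile_matrix <- function(track, anchors, half_window, n_bins) {
  stopifnot(all(c("chrom", "center") %in% colnames(anchors)),
            (2 * half_window) %% n_bins == 0)
  if (any(anchors$center < half_window)) {
    stop("anchor window extends below position 0")
  }
  bw <- (2L * half_window) %/% n_bins
  na <- nrow(anchors)
  starts <- rep(anchors$center - half_window, each = n_bins) +
    rep(seq_len(n_bins) - 1L, na) * bw
  bins <- region_set(rep(anchors$chrom, each = n_bins), starts, starts + bw,
                     name = sprintf("b%08d", seq_len(na * n_bins)),
                     sort = FALSE)
  vals <- suppressWarnings(score_regions(bins, track))
  prof <- matrix(vals, nrow = na, ncol = n_bins, byrow = TRUE)
  if ("strand" %in% colnames(anchors)) {
    rev_i <- which(anchors$strand == "-")
    if (length(rev_i)) prof[rev_i, ] <- prof[rev_i, n_bins:1, drop = FALSE]
  }
  has_signal <- rowSums(prof != 0) > 0
  cm <- if (any(has_signal)) colMeans(prof[has_signal, , drop = FALSE]) else
    rep(NA_real_, n_bins)
  list(profile = prof, column_means = cm, n_used = sum(has_signal))
}
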