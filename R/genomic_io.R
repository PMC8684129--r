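#' @import GenomicRanges
#' @importFrom IRanges IRanges findOverlaps pintersect width
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
#' @importFrom stats cor kmeans p.adjust pbinom pnorm qnorm quantile rbinom
#'   rlnorm rnorm runif setNames t.test cor.test sd cmdscale dist
#' @importFrom utils read.delim write.table head tail
NULL

# All coordinates inside the package are 0-based half-open, carried in GRanges
# shifted to 1-based closed (the Bioconductor convention). `region_set()` and
# `write_bed()` are the only two places the conversion happens.

#' Construct a region set
#'
#' Builds the package's region container (a sorted [GenomicRanges::GRanges]
#' with unique region identifiers in `names()`) from 0-based half-open
#' coordinates, the convention of BED and of every coordinate this package
#' exposes.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; must satisfy `start < end`.
#' @param name Optional region identifiers; generated when `NULL` or not
#'   unique.
#' @param score Optional non-negative numeric scores.
#' @param strand Strand per region, `"+"`, `"-"` or `"."` (unstranded).
#' @param sort Sort by (chrom, start, end)? Region sets are sorted by
#'   contract; disable only for round-trip checks.
#' @return A `GRanges`; `names()` hold the region ids.
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       strand = NULL, sort = TRUE) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (!is.null(strand)) strand <- rep_len(strand, n)
  if (n == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("invalid interval at entry %d: start=%s end=%s (need 0 <= start < end)",
                 bad[1], format(start[bad[1]]), format(end[bad[1]])))
  }
  if (!is.null(score) && any(score < 0, na.rm = TRUE)) {
    stop("negative region score")
  }
  st <- if (is.null(strand)) "*" else ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = st
  )
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  if (sort) {
    ord <- order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr))
    gr <- gr[ord]
    if (!is.null(name)) name <- name[ord]
  }
  if (is.null(name) || anyDuplicated(name)) {
    name <- sprintf("region_%0*d", max(5L, nchar(n)), seq_len(length(gr)))
  }
  names(gr) <- name
  gr
}

#' 0-based half-open view of a region set
#'
#' @param regions A region set (`GRanges`).
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `region_id`, `strand`, and `score` when present.
#' @export
region_df <- function(regions) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    region_id = if (is.null(names(regions))) NA_character_ else names(regions),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(regions))),
    stringsAsFactors = FALSE
  )
  if (!is.null(mcols(regions)$score)) df$score <- mcols(regions)$score
  df
}

#' Read a BED file into a region set
#'
#' Accepts BED3 through BED6; columns beyond the sixth are ignored with a
#' warning. `track`/`browser`/`#` lines are skipped. Coordinates are 0-based
#' half-open as in the BED standard; empty intervals (`start >= end`) are a
#' parse error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return Sorted region set (`GRanges`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no BED records in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("%s line %d: fewer than 3 tab-separated fields",
                 path, idx[which(nf < 3L)[1]]))
  }
  if (any(nf > 6L)) {
    warning(sprintf("%s: %d record(s) have more than 6 columns; extras ignored",
                    path, sum(nf > 6L)))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-integer coordinates", path, idx[bad[1]]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: invalid interval [%d, %d)",
                 path, idx[bad[1]], start[bad[1]], end[bad[1]]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                  NA_real_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  nm <- if (all(nf >= 4L) && !anyDuplicated(name)) name else NULL
  sc <- if (all(nf >= 5L) && !anyNA(score)) score else NULL
  region_set(chrom, start, end, name = nm, score = sc, strand = strand)
}

#' Write a region set as BED
#'
#' Emits BED6 when strand or score information is present, BED4 otherwise,
#' converting back to 0-based half-open coordinates. Writing then re-reading a
#' sorted region set reproduces it exactly.
#'
#' @param regions Region set (`GRanges`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  df <- region_df(regions)
  if (is.null(df$score)) df$score <- 0
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                 df$chrom, df$start, df$end, df$region_id,
                 format(df$score, trim = TRUE, scientific = FALSE),
                 df$strand)
  writeLines(out, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value);
#'   whitespace-separated, 0-based half-open.
#' @return A `coverage_track`: data.frame of sorted, non-overlapping steps
#'   with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no bedGraph records in ", path)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  if (any(lengths(fields) < 4L)) {
    stop(sprintf("%s line %d: fewer than 4 fields",
                 path, idx[which(lengths(fields) < 4L)[1]]))
  }
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) | !is.finite(df$value))
  if (length(bad)) stop(sprintf("%s line %d: non-numeric field", path, idx[bad[1]]))
  coverage_track(df$chrom, df$start, df$end, df$value)
}

#' Construct a coverage track
#'
#' bedGraph semantics: per-chromosome steps, 0-based half-open, sorted and
#' non-overlapping (abutting steps are allowed and preserved).
#'
#' @param chrom,start,end,value Step fields, vectorized.
#' @return data.frame of class `coverage_track`.
#' @export
coverage_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start >= df$end | df$start < 0)) stop("invalid step interval")
    if (any(!is.finite(df$value))) stop("non-finite step value")
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    same <- c(FALSE, df$chrom[-1] == df$chrom[-nrow(df)])
    overl <- same & (df$start < c(0L, df$end[-nrow(df)]))
    if (any(overl)) {
      i <- which(overl)[1]
      stop(sprintf("overlapping bedGraph steps on %s at [%d, %d)",
                   df$chrom[i], df$start[i], df$end[i]))
    }
    rownames(df) <- NULL
  }
  class(df) <- c("coverage_track", "data.frame")
  df
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                 format(track$value, trim = TRUE, scientific = FALSE, digits = 10))
  writeLines(out, path)
  invisible(path)
}

#' Read a TSV matrix (accessibility or expression)
#'
#' Expects a header row of sample ids and a first column of row ids
#' (regions or genes). Values must be numeric and, for these assays,
#' non-negative. Duplicate row or column ids and ragged/missing cells are
#' errors.
#'
#' @param path Path to the TSV.
#' @param nonnegative Reject negative values (default `TRUE`).
#' @return Numeric matrix with row and column names.
#' @export
read_matrix <- function(path, nonnegative = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a row-id column plus >=1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in ", path)
  m <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  m <- matrix(m, nrow = nrow(df), dimnames = list(ids, colnames(df)[-1]))
  if (anyNA(m)) stop("missing or non-numeric cell in ", path)
  if (nonnegative && any(m < 0)) stop("negative values in ", path)
  m
}

#' Write a matrix as TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Header of the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA genome into a named character vector
#'
#' Sequences are upper-cased; duplicate headers and empty files are errors.
#' Only the first whitespace-delimited token of each header is used.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA: ", path)
  nm <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate FASTA header in ", path)
  setNames(toupper(as.character(set)), nm)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read tumor metadata
#'
#' Requires columns `sample_id`, `stage`, `pam50`, `ihc`; an optional `group`
#' column (chromatin group, integer) is kept when present.
#'
#' @param path Path to a TSV.
#' @return data.frame with validated columns.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "stage", "pam50", "ihc")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  bad <- setdiff(unique(df$stage), c("I", "II", "III", "IV", "unknown"))
  if (length(bad)) stop("invalid stage value(s): ", paste(bad, collapse = ", "))
  if ("group" %in% colnames(df) && !all(is.na(df$group))) {
    df$group <- as.integer(df$group)
  }
  df
}
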