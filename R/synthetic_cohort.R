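# Synthetic tumor cohort with planted chromatin structure.
#
# The generator emulates the statistical structure the analysis assumes in a
# real ATAC-seq cohort: latent tumor groups with group-private open
# ("signature") regions that are nearly closed in all other tumors; motif
# occurrences concentrated in signature regions but also present at a
# background rate genome-wide; a stage-graded additive accessibility increase
# at one motif family's regions; and a regulator gene whose expression is
# coupled (negatively, by default) to mean accessibility at that family's
# regions through a Gaussian copula on ranks.

#' Specification of a synthetic tumor cohort
#'
#' Defaults are the package's standard desk-scale study conditions: 3 groups
#' of 20 tumors, 5000 accessible regions, 200 group-private signature regions
#' per group opened 4-fold over baseline in the owning group and nearly closed
#' (10% of baseline) elsewhere, multiplicative lognormal noise, three motif
#' families (one per group, in 80% of the group's signature regions), a
#' stage-graded accessibility increase at family-2 motif regions, and a
#' regulator gene anticorrelated (r = -0.5) with family-2 motif accessibility.
#'
#' @param n_tumors Integer vector, tumors per latent group (length = k).
#' @param n_regions Total accessible regions.
#' @param n_signature_per_group Planted group-private open regions per group.
#' @param baseline_mean Mean accessibility of ordinary open regions.
#' @param signature_effect Fold lift of a signature region in its owning
#'   group.
#' @param closed_fraction Fraction of baseline a signature region keeps
#'   outside its owning group (near-closed chromatin).
#' @param noise_sd Lognormal sdlog of the multiplicative noise (0 = noise
#'   free).
#' @param motif_families List of families, each
#'   `list(name, consensus, group, signature_fraction, background_fraction)`:
#'   the owning group, the fraction of that group's signature regions
#'   carrying the motif, and the fraction of non-signature regions carrying
#'   it.
#' @param stage_effect Additive accessibility increment per stage step at the
#'   stage family's motif regions (stage I = 0, II = 1x, ...).
#' @param stage_family Index of the motif family carrying the stage trend.
#' @param regulator_coupling Target Pearson correlation (|r| < 1) between the
#'   regulator gene's expression and mean accessibility at the regulator
#'   family's motif regions.
#' @param regulator_gene,regulator_family Regulator gene id and coupled
#'   family index.
#' @param n_genes Total genes in the expression matrix (named marker genes
#'   included).
#' @param region_length,gap_length Length ranges (bp) for regions and
#'   inter-region gaps.
#' @param chrom_count Chromosomes in the synthetic genome.
#' @param genome_length Optional total genome length cap; the layout must fit
#'   or the cohort spec is rejected as infeasible.
#' @param peak_jitter Max per-sample jitter (bp) of emitted peak boundaries.
#' @param open_threshold Accessibility above which a region is included in a
#'   sample's emitted peak calls.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   byte-identically.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumors = c(20, 20, 20),
                        n_regions = 5000,
                        n_signature_per_group = 200,
                        baseline_mean = 10,
                        signature_effect = 4,
                        closed_fraction = 0.1,
                        noise_sd = 0.25,
                        motif_families = list(
                          list(name = "SOX", consensus = "AACAATGG", group = 1,
                               signature_fraction = 0.8, background_fraction = 0.05),
                          list(name = "FOX", consensus = "TGTTTACA", group = 2,
                               signature_fraction = 0.8, background_fraction = 0.39),
                          list(name = "CEBP", consensus = "TTGCGCAA", group = 3,
                               signature_fraction = 0.8, background_fraction = 0.05)),
                        stage_effect = 3,
                        stage_family = 2,
                        regulator_coupling = -0.5,
                        regulator_gene = "ANP32E",
                        regulator_family = 2,
                        n_genes = 200,
                        region_length = c(150, 400),
                        gap_length = c(100, 300),
                        chrom_count = 3,
                        genome_length = NULL,
                        peak_jitter = 5,
                        open_threshold = NULL,
                        seed = 1) {
  k <- length(n_tumors)
  stopifnot(k >= 2, all(n_tumors > 0), n_regions > 0,
            n_signature_per_group > 0, baseline_mean > 0, signature_effect > 0,
            closed_fraction >= 0, closed_fraction < 1, noise_sd >= 0,
            stage_effect >= 0, abs(regulator_coupling) < 1, n_genes >= 10,
            chrom_count >= 1, peak_jitter >= 0)
  if (k * n_signature_per_group > n_regions) {
    stop("infeasible spec: ", k * n_signature_per_group,
         " signature regions exceed ", n_regions, " total regions")
  }
  for (f in motif_families) {
    stopifnot(f$group >= 1, f$group <= k,
              f$signature_fraction >= 0, f$signature_fraction <= 1,
              f$background_fraction >= 0, f$background_fraction <= 1)
  }
  if (is.null(open_threshold)) open_threshold <- baseline_mean / 2
  structure(list(n_tumors = n_tumors, n_regions = n_regions,
                 n_signature_per_group = n_signature_per_group,
                 baseline_mean = baseline_mean,
                 signature_effect = signature_effect,
                 closed_fraction = closed_fraction, noise_sd = noise_sd,
                 motif_families = motif_families, stage_effect = stage_effect,
                 stage_family = stage_family,
                 regulator_coupling = regulator_coupling,
                 regulator_gene = regulator_gene,
                 regulator_family = regulator_family, n_genes = n_genes,
                 region_length = region_length, gap_length = gap_length,
                 chrom_count = chrom_count, genome_length = genome_length,
                 peak_jitter = peak_jitter, open_threshold = open_threshold,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic tumor cohort
#'
#' Draws the full cohort bundle from a [cohort_spec()]: the accessible region
#' set, the region x tumor accessibility matrix, a gene x tumor expression
#' matrix, tumor metadata (stage, PAM50, IHC), a genome with motif consensus
#' strings written into carrier regions, a TSS table, the motif models, and a
#' truth record of every planted assignment. All randomness flows from
#' `spec$seed`; the same spec yields byte-identical outputs.
#'
#' @param spec A [cohort_spec()].
#' @param emit Optional subset of `c("genome", "tracks", "peaks")` to
#'   generate; the matrix, expression, metadata and truth record are always
#'   produced. Skipping the genome also skips planted occurrences (carrier
#'   regions remain in the truth record).
#' @return list with elements `regions` (GRanges), `accessibility`,
#'   `expression` (matrices), `metadata` (data.frame), `genome` (named
#'   character or NULL), `tss` (data.frame), `motifs` (list of
#'   [motif_model()]s), `tracks`, `peaks` (named lists or NULL), and `truth`.
#' @export
generate_cohort <- function(spec, emit = c("genome", "tracks", "peaks")) {
  stopifnot(inherits(spec, "cohort_spec"))
  emit <- intersect(emit, c("genome", "tracks", "peaks"))
  set.seed(as.integer(spec$seed))
  k <- length(spec$n_tumors)
  n <- sum(spec$n_tumors)
  sample_ids <- sprintf("T%03d", seq_len(n))
  group <- rep(seq_len(k), spec$n_tumors)

  # stages cycled within each group so stage composition is group-balanced
  stage_levels <- c("I", "II", "III", "IV")
  stage_idx <- unlist(lapply(spec$n_tumors, function(ng) {
    rep_len(seq_along(stage_levels), ng)
  }))
  stage <- stage_levels[stage_idx]

  # --- region layout -------------------------------------------------------
  nr <- spec$n_regions
  lens <- round(runif(nr, spec$region_length[1], spec$region_length[2]))
  gaps <- round(runif(nr, spec$gap_length[1], spec$gap_length[2]))
  per_chrom <- rep(ceiling(nr / spec$chrom_count), spec$chrom_count)
  per_chrom[spec$chrom_count] <- nr - sum(per_chrom[-spec$chrom_count])
  chrom <- rep(paste0("chr", seq_len(spec$chrom_count)), per_chrom)
  start <- integer(nr)
  pos <- setNames(rep(0L, spec$chrom_count), unique(chrom))
  for (i in seq_len(nr)) {
    start[i] <- pos[chrom[i]] + gaps[i]
    pos[chrom[i]] <- start[i] + lens[i]
  }
  chrom_len <- pos + round(runif(spec$chrom_count, spec$gap_length[1],
                                 spec$gap_length[2]))
  if (!is.null(spec$genome_length) && sum(chrom_len) > spec$genome_length) {
    stop("infeasible spec: layout needs ", sum(chrom_len),
         " bp, genome_length caps it at ", spec$genome_length)
  }
  regions <- region_set(chrom, start, start + lens)
  region_ids <- names(regions)

  # --- planted structure ---------------------------------------------------
  sig_pool <- sample(nr, k * spec$n_signature_per_group)
  signature_idx <- split(sig_pool, rep(seq_len(k), each = spec$n_signature_per_group))
  background_idx <- setdiff(seq_len(nr), sig_pool)

  carrier_idx <- lapply(spec$motif_families, function(f) {
    sig <- signature_idx[[f$group]]
    from_sig <- sort(sample(sig, round(f$signature_fraction * length(sig))))
    n_bg <- round(f$background_fraction * length(background_idx))
    from_bg <- if (n_bg > 0) sort(sample(background_idx, n_bg)) else integer(0)
    sort(c(from_sig, from_bg))
  })
  names(carrier_idx) <- vapply(spec$motif_families, `[[`, "", "name")

  mu <- matrix(spec$baseline_mean, nrow = nr, ncol = n,
               dimnames = list(region_ids, sample_ids))
  for (g in seq_len(k)) {
    mu[signature_idx[[g]], group == g] <- spec$baseline_mean * spec$signature_effect
    mu[signature_idx[[g]], group != g] <- spec$baseline_mean * spec$closed_fraction
  }
  stage_regions <- carrier_idx[[spec$stage_family]]
  if (spec$stage_effect > 0 && length(stage_regions)) {
    mu[stage_regions, ] <- mu[stage_regions, ] +
      rep(spec$stage_effect * (stage_idx - 1), each = length(stage_regions))
  }
  access <- if (spec$noise_sd > 0) {
    mu * matrix(rlnorm(nr * n, meanlog = -spec$noise_sd^2 / 2,
                       sdlog = spec$noise_sd), nrow = nr)
  } else {
    mu
  }
  dimnames(access) <- list(region_ids, sample_ids)

  # --- expression ----------------------------------------------------------
  named_genes <- unique(c(spec$regulator_gene, "FOXA1", "GATA3", "KI67"))
  filler <- sprintf("gene%04d", seq_len(spec$n_genes - length(named_genes)))
  gene_ids <- c(named_genes, filler)

  reg_access <- colMeans(access[carrier_idx[[spec$regulator_family]], ,
                                drop = FALSE])
  # Gaussian copula on ranks: normal scores of the accessibility vector,
  # mixed with independent noise to hit the target correlation
  z <- qnorm((rank(reg_access, ties.method = "first") - 0.5) / n)
  rho <- spec$regulator_coupling
  zr <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  regulator_expr <- pmax(0, 100 + 20 * zr)

  luminal <- group != 1  # group 1 plays the Basal-like role
  marker_expr <- function(hi, lo, sdlog = 0.3) {
    rlnorm(n, meanlog = log(ifelse(luminal, hi, lo)), sdlog = sdlog)
  }
  expr <- matrix(0, nrow = length(gene_ids), ncol = n,
                 dimnames = list(gene_ids, sample_ids))
  expr[spec$regulator_gene, ] <- regulator_expr
  expr["FOXA1", ] <- marker_expr(120, 15)
  expr["GATA3", ] <- marker_expr(150, 20)
  expr["KI67", ] <- pmax(0, 40 + 0.3 * regulator_expr + rnorm(n, sd = 8))
  for (gname in filler) {
    expr[gname, ] <- rlnorm(n, meanlog = runif(1, 2, 5), sdlog = 0.5)
  }

  pam50_pool <- list(c("Basal-L"), c("Lum-B", "Lum-A", "HER2-enriched"),
                     c("Lum-A"))
  pam50 <- vapply(group, function(g) {
    pool <- pam50_pool[[min(g, length(pam50_pool))]]
    if (length(pool) == 1) pool else sample(pool, 1, prob = c(0.5, 0.35, 0.15))
  }, "")
  metadata <- data.frame(sample_id = sample_ids, stage = stage, pam50 = pam50,
                         ihc = ifelse(group == 1, "TNBC", "HR+/HER2-"),
                         stringsAsFactors = FALSE)

  # --- TSS table -----------------------------------------------------------
  tss_chrom <- sample(names(chrom_len), length(gene_ids), replace = TRUE)
  tss <- data.frame(gene_id = gene_ids, chrom = tss_chrom,
                    position = floor(runif(length(gene_ids)) *
                                       (chrom_len[tss_chrom] - 1)),
                    strand = sample(c("+", "-"), length(gene_ids), replace = TRUE),
                    stringsAsFactors = FALSE)

  motifs <- lapply(spec$motif_families, function(f) {
    motif_model(f$name, consensus = f$consensus)
  })
  names(motifs) <- names(carrier_idx)

  # --- genome + planted occurrences (drawn last so the statistical layers
  # above are identical whether or not a genome is emitted) ------------------
  genome <- NULL
  occurrences <- NULL
  if ("genome" %in% emit) {
    genome <- vapply(names(chrom_len), function(ch) {
      paste(sample(DNA_BASES, chrom_len[ch], replace = TRUE), collapse = "")
    }, "")
    rdf <- region_df(regions)
    occ <- vector("list", length(carrier_idx))
    occupied <- vector("list", nr)  # planted intervals per region, as offsets
    for (fi in seq_along(carrier_idx)) {
      f <- spec$motif_families[[fi]]
      L <- nchar(f$consensus)
      ids <- carrier_idx[[fi]]
      off <- integer(length(ids))
      strand <- character(length(ids))
      for (j in seq_along(ids)) {
        ri <- ids[j]
        len <- rdf$end[ri] - rdf$start[ri]
        for (try in 1:50) {
          o <- sample.int(len - L + 1L, 1L) - 1L
          clash <- any(vapply(occupied[[ri]], function(iv) {
            o < iv[2] && iv[1] < o + L
          }, TRUE))
          if (!clash) break
        }
        occupied[[ri]] <- c(occupied[[ri]], list(c(o, o + L)))
        off[j] <- o
        strand[j] <- sample(c("+", "-"), 1L)
        site <- if (strand[j] == "+") f$consensus else revcomp(f$consensus)
        ch <- rdf$chrom[ri]
        at <- rdf$start[ri] + o
        substr(genome[[ch]], at + 1L, at + L) <- site
      }
      occ[[fi]] <- data.frame(motif = f$name, region_id = region_ids[ids],
                              chrom = rdf$chrom[ids], start = rdf$start[ids] + off,
                              end = rdf$start[ids] + off + L, strand = strand,
                              stringsAsFactors = FALSE)
    }
    occurrences <- do.call(rbind, occ)
  }

  tracks <- NULL
  if ("tracks" %in% emit) {
    rdf <- region_df(regions)
    tracks <- lapply(seq_len(n), function(t) {
      keep <- access[, t] > 0
      coverage_track(rdf$chrom[keep], rdf$start[keep], rdf$end[keep],
                     access[keep, t])
    })
    names(tracks) <- sample_ids
  }

  peaks <- NULL
  if ("peaks" %in% emit) {
    rdf <- region_df(regions)
    j <- spec$peak_jitter
    peaks <- lapply(seq_len(n), function(t) {
      open <- which(access[, t] >= spec$open_threshold)
      s <- pmax(0L, rdf$start[open] + sample(seq(-j, j), length(open),
                                             replace = TRUE))
      e <- rdf$end[open] + sample(seq(-j, j), length(open), replace = TRUE)
      e <- pmax(e, s + 1L)
      region_set(rdf$chrom[open], s, e, score = access[open, t])
    })
    names(peaks) <- sample_ids
  }

  truth <- list(
    group = setNames(group, sample_ids),
    stage = setNames(stage, sample_ids),
    signature_regions = lapply(signature_idx, function(i) region_ids[i]),
    motif_carriers = lapply(carrier_idx, function(i) region_ids[i]),
    stage_family = names(carrier_idx)[spec$stage_family],
    regulator = list(gene = spec$regulator_gene,
                     family = names(carrier_idx)[spec$regulator_family],
                     target_r = spec$regulator_coupling),
    planted_occurrences = occurrences,
    seed = spec$seed
  )
  names(truth$signature_regions) <- as.character(seq_len(k))

  list(regions = regions, accessibility = access, expression = expr,
       metadata = metadata, genome = genome, tss = tss, motifs = motifs,
       tracks = tracks, peaks = peaks, truth = truth, spec = spec)
}

#' Write a cohort bundle to disk
#'
#' Writes `genome.fa`, `tss.tsv`, `peaks/<sample>.bed`,
#' `tracks/<sample>.bedgraph`, `accessibility.tsv`, `expression.tsv`,
#' `metadata.tsv`, `motifs.tsv` and `truth.json` under `outdir` (components
#' not generated are skipped).
#'
#' @param cohort Output of [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$accessibility, file.path(outdir, "accessibility.tsv"),
               id_col = "region_id")
  write_matrix(cohort$expression, file.path(outdir, "expression.tsv"),
               id_col = "gene_id")
  write.table(cohort$metadata, file.path(outdir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$tss, file.path(outdir, "tss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(cohort$regions, file.path(outdir, "regions.bed"))
  writeLines(c("name\tconsensus",
               vapply(cohort$motifs, function(m) {
                 paste(m$name, m$consensus, sep = "\t")
               }, "")),
             file.path(outdir, "motifs.tsv"))
  if (!is.null(cohort$genome)) {
    write_fasta(cohort$genome, file.path(outdir, "genome.fa"))
  }
  if (!is.null(cohort$peaks)) {
    dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
    for (s in names(cohort$peaks)) {
      write_bed(cohort$peaks[[s]], file.path(outdir, "peaks", paste0(s, ".bed")))
    }
  }
  if (!is.null(cohort$tracks)) {
    dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
    for (s in names(cohort$tracks)) {
      write_bedgraph(cohort$tracks[[s]],
                     file.path(outdir, "tracks", paste0(s, ".bedgraph")))
    }
  }
  truth <- cohort$truth
  truth$planted_occurrences <- NULL  # tabular; regenerate from seed if needed
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$truth$planted_occurrences)) {
    write.table(cohort$truth$planted_occurrences,
                file.path(outdir, "planted_occurrences.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
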