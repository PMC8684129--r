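# End-to-end pipeline: simulate/load -> union matrix -> rank -> stratify ->
# signatures -> motifs -> associations, with a written manifest.

default_pipeline_config <- function() {
  list(
    simulate = TRUE,          # generate a synthetic cohort (FALSE: read inputs)
    cohort = list(),          # overrides for cohort_spec()
    analysis = list(),        # overrides for analysis_config()
    inputs = list(),          # paths: accessibility, expression, metadata,
                              # genome, tss, motifs, peaks_dir, tracks_dir
    use_precomputed_matrix = TRUE,  # FALSE: rebuild from peaks + tracks
    embed_method = "umap",
    stage_direction = "increasing",
    seed = 1
  )
}

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; entries override the defaults and
#' unknown keys are rejected before anything runs. `cohort` entries are passed
#' to [cohort_spec()], `analysis` entries to [analysis_config()].
#'
#' @param config Path to a YAML mapping, a named list, or `NULL` for the
#'   defaults.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(base, config)
  bad <- setdiff(names(cfg$cohort), names(formals(cohort_spec)))
  if (length(bad)) stop("unknown cohort key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$analysis), names(formals(analysis_config)))
  if (length(bad)) stop("unknown analysis key(s): ", paste(bad, collapse = ", "))
  if (!cfg$simulate) {
    req <- c("accessibility", "expression", "metadata")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss)) {
      stop("simulate = FALSE but inputs missing: ", paste(miss, collapse = ", "))
    }
    gone <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
    if (length(gone)) stop("input file(s) not found: ", paste(gone, collapse = ", "))
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

load_inputs <- function(cfg) {
  ip <- cfg$inputs
  list(
    accessibility = read_matrix(ip$accessibility),
    expression = read_matrix(ip$expression),
    metadata = read_metadata(ip$metadata),
    genome = if (!is.null(ip$genome)) read_fasta(ip$genome),
    tss = if (!is.null(ip$tss)) read.delim(ip$tss, stringsAsFactors = FALSE),
    motifs = if (!is.null(ip$motifs)) read_motifs(ip$motifs),
    peaks = if (!is.null(ip$peaks_dir)) {
      fs <- list.files(ip$peaks_dir, "\\.bed$", full.names = TRUE)
      setNames(lapply(fs, read_bed), sub("\\.bed$", "", basename(fs)))
    },
    tracks = if (!is.null(ip$tracks_dir)) {
      fs <- list.files(ip$tracks_dir, "\\.bedgraph$", full.names = TRUE)
      setNames(lapply(fs, read_bedgraph),
               sub("\\.bedgraph$", "", basename(fs)))
    },
    truth = NULL
  )
}

#' Run the full stratification pipeline
#'
#' Chains every stage: simulate (or load) the cohort, build the union peak
#' accessibility matrix (or take the precomputed one), rank-normalize, embed
#' and assign chromatin groups, call per-group signatures, sample size-matched
#' background regions, scan and enrich motifs, and compute the downstream
#' associations (stage trends on motif accessibility, regulator correlations,
#' marker quartile filter, decile tables). Intermediate artifacts and a
#' manifest (file hashes, seeds, versions) are written when `outdir` is given;
#' a rerun with the same config is byte-identical for deterministic stages.
#'
#' @param config A [pipeline_config()], list, YAML path or `NULL`.
#' @param outdir Optional output directory for artifacts + manifest.
#' @param seed Overrides the config seed when non-`NULL`.
#' @return Report list with the cohort, groups, signatures, enrichment table,
#'   stage comparisons, correlations and filter results.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, seed = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  acfg <- do.call(analysis_config, c(cfg$analysis, list(seed = cfg$seed)))

  stage_msg <- function(...) message("[chromstrat] ", ...)

  if (cfg$simulate) {
    stage_msg("simulate: generating synthetic cohort (seed ", cfg$seed, ")")
    spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
    cohort <- generate_cohort(spec)
    cohort$truth_record <- cohort$truth
  } else {
    stage_msg("load: reading cohort inputs")
    cohort <- load_inputs(cfg)
  }

  if (cfg$use_precomputed_matrix || is.null(cohort$peaks) ||
      is.null(cohort$tracks)) {
    m <- cohort$accessibility
    regions <- cohort$regions
    if (is.null(regions)) {
      stop("no region set available for the precomputed matrix")
    }
  } else {
    stage_msg("build-matrix: union of ", length(cohort$peaks),
              " peak sets + track scoring")
    regions <- merge_peaks(cohort$peaks)
    m <- build_accessibility_matrix(regions, cohort$tracks)
  }

  stage_msg("rank: rank-normalizing ", nrow(m), " x ", ncol(m), " matrix")
  ranks <- rank_normalize(m)

  stage_msg("stratify: embedding (", cfg$embed_method, ", n_neighbors = ",
            acfg$n_neighbors, ") and assigning k = ", acfg$k_groups, " groups")
  strat <- stratify_tumors(ranks, n_neighbors = acfg$n_neighbors,
                           k = acfg$k_groups, seed = cfg$seed,
                           method = cfg$embed_method)
  groups <- strat$groups

  stage_msg("signatures: group-vs-rest log2FC > ", acfg$lfc_threshold)
  sigs <- call_signatures(m, groups, acfg)
  sig_regions <- lapply(sigs, function(s) regions[s$region_id])

  background <- sample_background(
    regions, do.call(c, unname(sig_regions[lengths(sig_regions) > 0])),
    n = min(acfg$background_n, length(regions)), seed = cfg$seed)

  annotation <- NULL
  if (!is.null(cohort$genome) && !is.null(cohort$tss)) {
    annotation <- lapply(sig_regions, function(rs) {
      if (!length(rs)) return(NULL)
      list(tss_distance = distance_to_tss(rs, cohort$tss),
           cpg = cpg_density(rs, cohort$genome))
    })
  }

  enrichment <- NULL
  occurrences <- NULL
  if (!is.null(cohort$genome) && length(cohort$motifs)) {
    stage_msg("motifs: scanning ", length(cohort$motifs), " motif(s) over ",
              length(regions), " regions")
    occurrences <- lapply(cohort$motifs, scan_motif, regions = regions,
                          genome = cohort$genome)
    enr <- list()
    for (mn in names(occurrences)) {
      for (gn in names(sig_regions)) {
        if (!length(sig_regions[[gn]])) next
        e <- motif_enrichment(sig_regions[[gn]], background, occurrences[[mn]])
        enr[[length(enr) + 1L]] <- data.frame(
          motif = mn, signature = gn, fold = e$fold, p = e$p,
          target_hits = e$target_hits, target_n = e$target_n,
          background_hits = e$background_hits, background_n = e$background_n,
          stringsAsFactors = FALSE)
      }
    }
    enrichment <- do.call(rbind, enr)
  }

  stage_msg("assoc: stage trends, correlations, marker filter")
  assoc <- list()
  motif_access <- NULL
  if (!is.null(occurrences)) {
    motif_access <- lapply(occurrences, function(occ) {
      if (nrow(occ)) motif_accessibility(m, occ) else NULL
    })
    assoc$stage_trend <- lapply(Filter(Negate(is.null), motif_access),
                                function(v) {
      by_stage <- split_by_stage(v, cohort$metadata)
      if (length(by_stage) >= 2 && all(lengths(by_stage) >= 2)) {
        stage_trend(by_stage, direction = cfg$stage_direction,
                    alpha_stars = acfg$alpha_stars)
      }
    })
  }
  # per-signature mean accessibility per tumor, and its regulator correlation
  sig_access <- lapply(sigs, function(s) {
    if (nrow(s)) colMeans(m[s$region_id, , drop = FALSE])
  })
  reg_gene <- intersect(c("ANP32E"), rownames(cohort$expression))
  if (length(reg_gene)) {
    reg <- cohort$expression[reg_gene[1], ]
    assoc$regulator_correlations <- lapply(
      Filter(Negate(is.null), c(sig_access,
                                if (!is.null(motif_access))
                                  setNames(motif_access,
                                           paste0("motif_", names(motif_access))))),
      function(v) tryCatch(pearson_cor(reg, v[names(reg)]),
                           error = function(e) NULL))
  }
  if (all(c("FOXA1", "GATA3") %in% rownames(cohort$expression))) {
    assoc$basal_filter <- basal_filter(cohort$expression,
                                       quartile = acfg$quartile)
  }
  if (length(reg_gene) && ncol(cohort$expression) * acfg$decile >= 1) {
    assoc$decile_tables <- decile_tables(cohort$expression, reg_gene[1],
                                         decile = acfg$decile)
  }

  report <- list(config = cfg, analysis_config = acfg, regions = regions,
                 accessibility = m, ranks = ranks, embedding = strat$embedding,
                 groups = groups, group_sizes = table(groups$group),
                 signatures = sigs, background = background,
                 annotation = annotation, enrichment = enrichment,
                 occurrences = occurrences, assoc = assoc,
                 metadata = cohort$metadata, expression = cohort$expression,
                 truth = cohort$truth)

  if (!is.null(outdir)) write_pipeline_outputs(report, cohort, outdir)
  report
}

write_pipeline_outputs <- function(report, cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(report$accessibility, file.path(outdir, "accessibility.tsv"),
               id_col = "region_id")
  write_matrix(report$ranks, file.path(outdir, "ranks.tsv"),
               id_col = "region_id")
  write.table(cbind(report$embedding, group = report$groups$group),
              file.path(outdir, "embedding.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$groups, file.path(outdir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in names(report$signatures)) {
    write.table(report$signatures[[g]],
                file.path(outdir, sprintf("signature_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bed(report$background, file.path(outdir, "background.bed"))
  if (!is.null(report$enrichment)) {
    write.table(report$enrichment, file.path(outdir, "motif_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    created = "chromstrat pipeline",
    package_version = as.character(utils::packageVersion("chromstrat")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = report$config$seed,
    embed_method = report$config$embed_method,
    hashes = as.list(tools::md5sum(files))
  )
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
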