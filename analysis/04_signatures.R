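#!/usr/bin/env Rscript
# Call each group's chromatin signature (group-vs-rest log2FC > 2.5 on the
# raw accessibility scale, pseudo-count 1), sample a size-matched background
# from the remaining union regions, and annotate signature regions with TSS
# distance, CpG density and genes within 1 Mb.

library(chromstrat)

seed <- 1
ind <- "data/cohort"
out <- "results"

m <- read_matrix(file.path(out, "accessibility_union.tsv"))
union <- read_bed(file.path(out, "union_regions.bed"))
groups <- read.delim(file.path(out, "groups.tsv"), stringsAsFactors = FALSE)
genome <- read_fasta(file.path(ind, "genome.fa"))
tss <- read.delim(file.path(ind, "tss.tsv"), stringsAsFactors = FALSE)

cfg <- analysis_config(seed = seed)
sigs <- call_signatures(m, groups, cfg)

annot_rows <- list()
for (g in names(sigs)) {
  write.table(sigs[[g]], file.path(out, sprintf("signature_group%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!nrow(sigs[[g]])) next
  rs <- union[sigs[[g]]$region_id]
  genes <- nearby_genes(rs, tss, window = cfg$gene_window)
  annot_rows[[g]] <- data.frame(
    group = g, region_id = names(rs),
    tss_distance = unname(distance_to_tss(rs, tss)),
    cpg_density = unname(cpg_density(rs, genome)),
    n_genes_1mb = lengths(genes)[names(rs)],
    stringsAsFactors = FALSE)
}
annot <- do.call(rbind, annot_rows)
write.table(annot, file.path(out, "signature_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

targets <- union[unlist(lapply(sigs, `[[`, "region_id"))]
pool <- union[setdiff(names(union), names(targets))]
background <- sample_background(pool, targets,
                                n = min(cfg$background_n, length(pool)),
                                seed = seed)
write_bed(background, file.path(out, "background.bed"))

message("signature sizes: ",
        paste(names(sigs), vapply(sigs, nrow, 0L), sep = "=", collapse = " "),
        "; background: ", length(background), " regions")
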