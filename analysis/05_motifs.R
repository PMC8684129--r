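#!/usr/bin/env Rscript
# Scan the motif families over all union regions (PWM log-odds, both strands,
# hits above 0.8 of the maximal score) and test each family's enrichment in
# each group signature against the size-matched background (binomial tail on
# region hit fractions).

library(chromstrat)

ind <- "data/cohort"
out <- "results"

union <- read_bed(file.path(out, "union_regions.bed"))
genome <- read_fasta(file.path(ind, "genome.fa"))
motifs <- read_motifs(file.path(ind, "motifs.tsv"))
background <- read_bed(file.path(out, "background.bed"))

sig_files <- list.files(out, "^signature_group[0-9]+\\.tsv$", full.names = TRUE)
sigs <- lapply(sig_files, read.delim, stringsAsFactors = FALSE)
names(sigs) <- sub("^signature_group([0-9]+)\\.tsv$", "\\1", basename(sig_files))

occ_all <- list()
enr <- list()
for (mn in names(motifs)) {
  occ <- scan_motif(motifs[[mn]], union, genome)
  occ_all[[mn]] <- cbind(motif = mn, occ)
  for (g in names(sigs)) {
    if (!nrow(sigs[[g]])) next
    e <- motif_enrichment(union[sigs[[g]]$region_id], background, occ)
    enr[[length(enr) + 1L]] <- data.frame(
      motif = mn, signature = g, fold = e$fold, p = e$p,
      stars = p_stars(e$p), target_hits = e$target_hits,
      target_n = e$target_n, background_hits = e$background_hits,
      background_n = e$background_n, stringsAsFactors = FALSE)
  }
}
occurrences <- do.call(rbind, occ_all)
enrichment <- do.call(rbind, enr)

write.table(occurrences, file.path(out, "motif_occurrences.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enrichment, file.path(out, "motif_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(nrow(occurrences), " motif occurrences; enrichment table:")
print(enrichment[, c("motif", "signature", "fold", "p", "stars")],
      row.names = FALSE)
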