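#!/usr/bin/env Rscript
# Rebuild the accessibility matrix from primary files: take the union of the
# per-tumor peak calls, score every union region against each tumor's
# coverage track (length-weighted mean), and rank-normalize within tumors.

library(chromstrat)

ind <- "data/cohort"
out <- "results"
dir.create(out, showWarnings = FALSE)

peak_files <- list.files(file.path(ind, "peaks"), "\\.bed$", full.names = TRUE)
track_files <- list.files(file.path(ind, "tracks"), "\\.bedgraph$",
                          full.names = TRUE)
peaks <- setNames(lapply(peak_files, read_bed),
                  sub("\\.bed$", "", basename(peak_files)))
tracks <- setNames(lapply(track_files, read_bedgraph),
                   sub("\\.bedgraph$", "", basename(track_files)))

union <- merge_peaks(peaks)
m <- build_accessibility_matrix(union, tracks)
ranks <- rank_normalize(m)

write_bed(union, file.path(out, "union_regions.bed"))
write_matrix(m, file.path(out, "accessibility_union.tsv"), id_col = "region_id")
write_matrix(ranks, file.path(out, "ranks.tsv"), id_col = "region_id")

message("union of ", length(peaks), " peak sets: ", length(union),
        " regions; matrix ", nrow(m), " x ", ncol(m))
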