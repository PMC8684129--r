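#!/usr/bin/env Rscript
# Simulate the study cohort: 60 tumors in three chromatin groups over 5,000
# accessible regions, with planted group signatures, motif families, a stage
# trend on the FOX family and an ANP32E-anticorrelated accessibility program.
# Writes the on-disk cohort (matrices, BED/bedGraph/FASTA, metadata, truth)
# that the later scripts consume.

library(chromstrat)

seed <- 1
out <- "data/cohort"

spec <- cohort_spec(seed = seed)
cohort <- generate_cohort(spec)
write_cohort(cohort, out)

message("cohort written to ", out, ": ",
        nrow(cohort$accessibility), " regions x ",
        ncol(cohort$accessibility), " tumors, ",
        length(cohort$peaks), " peak sets")
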