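#!/usr/bin/env Rscript
# Stratify the tumors: UMAP embedding (n_neighbors = 10) of the rank
# matrix, k-means into k = 3 chromatin groups (labels ordered by dim2
# separation), and a recovery check against the planted group labels.

library(chromstrat)

seed <- 1
out <- "results"

ranks <- read_matrix(file.path(out, "ranks.tsv"))
strat <- stratify_tumors(ranks, n_neighbors = 10, k = 3, seed = seed)

write.table(cbind(strat$embedding, group = strat$groups$group),
            file.path(out, "embedding.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(strat$groups, file.path(out, "groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# planted labels: truth.json stores the group vector in metadata sample order
truth <- jsonlite::read_json(file.path("data/cohort", "truth.json"),
                             simplifyVector = TRUE)
metadata <- read_metadata(file.path("data/cohort", "metadata.tsv"))
assigned <- setNames(strat$groups$group, strat$groups$sample_id)
ari <- adjusted_rand(assigned[metadata$sample_id], truth$group)

message("group sizes: ",
        paste(names(table(strat$groups$group)),
              as.integer(table(strat$groups$group)),
              sep = "=", collapse = " "),
        "; ARI vs planted groups: ", round(ari, 3))
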