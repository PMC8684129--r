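#!/usr/bin/env Rscript
# Downstream associations: stage trends of per-tumor motif accessibility
# (one-tailed Welch t-tests between adjacent stages and the extreme pair),
# ANP32E expression vs accessibility correlations, the FOXA1/GATA3 bottom
# quartile filter, and ANP32E top/bottom decile expression tables.

library(chromstrat)

ind <- "data/cohort"
out <- "results"

m <- read_matrix(file.path(out, "accessibility_union.tsv"))
expr <- read_matrix(file.path(ind, "expression.tsv"))
metadata <- read_metadata(file.path(ind, "metadata.tsv"))
occurrences <- read.delim(file.path(out, "motif_occurrences.tsv"),
                          stringsAsFactors = FALSE)

# stage trends per motif family
trend_rows <- list()
cors <- list()
for (mn in unique(occurrences$motif)) {
  v <- motif_accessibility(m, occurrences[occurrences$motif == mn, ])
  by_stage <- split_by_stage(v, metadata)
  if (length(by_stage) >= 2 && all(lengths(by_stage) >= 2)) {
    st <- stage_trend(by_stage, direction = "increasing")
    trend_rows[[mn]] <- cbind(motif = mn, st)
  }
  ct <- pearson_cor(expr["ANP32E", colnames(m)], v)
  cors[[mn]] <- data.frame(motif = mn, r = ct$r, p = ct$p,
                           stars = p_stars(ct$p), stringsAsFactors = FALSE)
}
trends <- do.call(rbind, trend_rows)
correlations <- do.call(rbind, cors)
write.table(trends, file.path(out, "stage_trends.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(correlations, file.path(out, "regulator_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# FOXA1/GATA3 bottom-quartile filter (depletes Basal-like tumors)
bf <- basal_filter(expr)
writeLines(bf$kept, file.path(out, "samples_after_basal_filter.txt"))

# ANP32E top/bottom decile expression tables (GSEA input)
dt <- decile_tables(expr, "ANP32E", decile = 0.10)
decile_tab <- data.frame(gene_id = names(dt$top$means),
                         top_decile_mean = unname(dt$top$means),
                         bottom_decile_mean = unname(dt$bottom$means))
write.table(decile_tab, file.path(out, "anp32e_decile_means.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("stage trends:")
print(trends, row.names = FALSE)
message("ANP32E correlations:")
print(correlations, row.names = FALSE)
message("basal filter removed ", length(bf$removed), "/", ncol(expr),
        " tumors; decile tables over ", dt$n_selected, " samples each")
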