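#!/usr/bin/env Rscript
# Stage 6: Convergent Functional Genomics scoring -- internal evidence from
# the three comparisons (with both-MAP and MAP-module bonuses), capped
# external evidence with the blood-psychosis weighting, prioritization at
# total score >= 3, and per-module enrichment in evidence-bearing genes.

suppressPackageStartupMessages(library(mapblood))
outdir <- "results"

read_de <- function(f) read.delim(file.path(outdir, f))
de1 <- read_de("de_control_vs_MAP.tsv")
de2 <- read_de("de_MA_vs_MAP.tsv")
de3 <- read_de("de_control_vs_MA.tsv")
part_df <- read.delim(file.path(outdir, "partition.tsv"))
partition <- setNames(part_df$module, part_df$gene)
map_modules <- as.integer(readLines(file.path(outdir, "map_modules.txt")))
evidence <- read.delim(file.path(outdir, "evidence_db.tsv"))

tab <- cfg_score_table(de1, de2, de3, partition, map_modules, evidence,
                       cfg_config(threshold = 3))
write.table(tab, file.path(outdir, "cfg_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# gene-disease edge list of the prioritized genes (network-figure input)
pri <- tab$gene[tab$prioritized]
edges <- evidence[evidence$gene %in% pri, c("gene", "disease", "evidence_type")]
write.table(edges, file.path(outdir, "cfg_gene_disease_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ev_genes <- unique(evidence$gene)
mods <- sort(unique(partition[partition > 0]))
enr <- do.call(rbind, lapply(mods, function(m) {
  cbind(data.frame(module = m),
        cfg_module_enrichment(names(partition)[partition == m], ev_genes,
                              length(partition)))
}))
write.table(enr, file.path(outdir, "cfg_module_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Scored", nrow(tab), "genes;", sum(tab$prioritized),
    "prioritized at total CFG score >= 3.\n")
cat("Top genes:\n")
print(head(tab[, c("gene", "internal", "external",
                   "blood_psychosis_bonus", "total")], 5), row.names = FALSE)
best <- enr[which.min(enr$p), ]
cat(sprintf("Module %d is most enriched in evidence-bearing genes (%d genes, p = %.2g)\n",
            best$module, best$overlap, best$p))
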