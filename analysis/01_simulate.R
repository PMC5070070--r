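#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 30-subject cohort (10 control / 10 MA /
# 10 MAP) with eight planted co-expression modules, group effects on the
# MAP-associated modules, a polysubstance confounder module, coupled
# phenotypes and a matched external evidence database.

suppressPackageStartupMessages(library(mapblood))
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)
seed <- 1L

config <- cohort_config() # 2000 genes, defaults documented in ?cohort_config
cohort <- generate_cohort(config, seed = seed)
evidence <- generate_evidence_db(cohort$truth, config, seed = seed + 1000L)

write_counts_tsv(cohort$counts, file.path(outdir, "counts.tsv"))
write.table(cohort$phenotypes, file.path(outdir, "phenotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(evidence, file.path(outdir, "evidence_db.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  seed = seed,
  module = as.list(cohort$truth$module),
  effects = as.data.frame(cohort$truth$effects),
  planted_de = cohort$truth$planted_de,
  confounder_module = cohort$truth$confounder_module
), file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)

cat("Simulated", nrow(cohort$counts), "genes x", ncol(cohort$counts),
    "subjects;", length(cohort$truth$planted_de),
    "genes carry planted group effects;",
    nrow(evidence), "external evidence records.\n")
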