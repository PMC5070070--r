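#!/usr/bin/env Rscript
# Stage 2: low-expression filter (>= 20 reads in >= 10 subjects), voom-style
# log-CPM normalization with precision weights, outlier screen.

suppressPackageStartupMessages(library(mapblood))
outdir <- "results"

counts <- read_counts_tsv(file.path(outdir, "counts.tsv"))
filtered <- filter_low_expression(counts, min_reads = 20, min_subjects = 10)
norm <- voom_normalize(filtered)
outliers <- detect_outliers(norm)

write.table(cbind(data.frame(gene = rownames(norm$E)), as.data.frame(norm$E)),
            file.path(outdir, "expr_normalized.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(data.frame(gene = rownames(norm$weights)),
                  as.data.frame(norm$weights)),
            file.path(outdir, "expr_weights.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  n_input = nrow(counts), n_retained = attr(filtered, "n_retained"),
  n_removed = attr(filtered, "n_removed"),
  outliers = as.character(outliers)
), file.path(outdir, "qc_report.json"), auto_unbox = TRUE, digits = NA)

cat("Retained", attr(filtered, "n_retained"), "of", nrow(counts),
    "genes after the low-expression filter.\n")
cat("Outlier screen (2 sd, correlation/PCA union):",
    if (length(outliers)) paste(outliers, collapse = ", ") else "none", "\n")
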