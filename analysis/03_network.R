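#!/usr/bin/env Rscript
# Stage 3: signed co-expression network (beta = 9), topological overlap,
# module detection (min size 15, deep split 2), eigengene merging at height
# 0.2, eigengenes, kME and hub genes.

suppressPackageStartupMessages(library(mapblood))
outdir <- "results"

df <- read.delim(file.path(outdir, "expr_normalized.tsv"), check.names = FALSE)
E <- as.matrix(df[, -1]); rownames(E) <- df$gene

cfg <- network_config() # beta 9, min size 15, deep split 2, merge height 0.2
adj <- signed_adjacency(E, cfg)
sft <- scale_free_fit(adj)
tom <- topological_overlap(adj)
part0 <- detect_modules(tom$diss, cfg)
partition <- merge_close_modules(E[names(part0), ], part0, cfg)
eg <- attr(partition, "eigengenes")
kme <- module_membership(E, eg, partition)

write.table(data.frame(gene = names(partition), module = as.integer(partition)),
            file.path(outdir, "partition.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(data.frame(module = rownames(eg$me)), as.data.frame(eg$me)),
            file.path(outdir, "eigengenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(data.frame(gene = rownames(kme$kme)), as.data.frame(kme$kme)),
            file.path(outdir, "kme.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(module = names(kme$hubs), hub_gene = kme$hubs),
            file.path(outdir, "hub_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sizes <- table(partition[partition > 0])
cat("Detected", length(sizes), "modules (sizes",
    paste(as.integer(sizes), collapse = ", "), ");",
    sum(partition == 0), "genes unassigned (grey).\n")
cat("Scale-free fit R^2:", round(sft, 3), "\n")
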