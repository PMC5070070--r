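#!/usr/bin/env Rscript
# Stage 5: moderated t-tests for the three group comparisons, exclusion of
# genes from polysubstance-associated modules, and diagnostic panel
# construction by RFE + DLDA (with SVM / nearest-centroid / 3-NN
# comparators) under LOOCV, with permutation p-values.

suppressPackageStartupMessages(library(mapblood))
outdir <- "results"
seed <- 1L
n_perm <- 100L # the published analysis used 1000; reduced for desk scale

df <- read.delim(file.path(outdir, "expr_normalized.tsv"), check.names = FALSE)
E <- as.matrix(df[, -1]); rownames(E) <- df$gene
phen <- read.delim(file.path(outdir, "phenotypes.tsv"), check.names = FALSE)
groups <- phen$group[match(colnames(E), phen$subject)]
part_df <- read.delim(file.path(outdir, "partition.tsv"))
partition <- setNames(part_df$module, part_df$gene)
trait_cor <- read.delim(file.path(outdir, "module_trait_cor.tsv"))

de1 <- moderated_ttest(E, groups, "control", "MAP")
de2 <- moderated_ttest(E, groups, "MA", "MAP")
de3 <- moderated_ttest(E, groups, "control", "MA")
for (de in list(de1, de2, de3)) {
  write.table(de, file.path(outdir, paste0("de_", de$comparison[1], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

conf_traits <- c("nicotine_use", "cannabis_use", "alcohol_use")
de_all <- exclude_confounded(rbind(de1, de2, de3), partition, trait_cor,
                             conf_traits)
candidates <- sort(unique(de_all$gene[de_all$p < 0.01]))
writeLines(candidates, file.path(outdir, "candidate_genes.txt"))
cat("Candidate pool (p < 0.01, polysubstance modules",
    paste(attr(de_all, "excluded_modules"), collapse = ","),
    "excluded):", length(candidates), "genes\n")

run_model <- function(label, E, y, perm_seed) {
  res <- rfe_loocv(E, y, candidates)
  write.table(res$accuracy, file.path(outdir, paste0("accuracy_", label, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- res$panel
  panel$module <- partition[panel$gene]
  write.table(panel, file.path(outdir, paste0("panel_", label, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- permutation_pvalue(E, y, candidates, n_perm = n_perm, seed = perm_seed)
  for (cl in names(res$best)) {
    cat(sprintf("  %s / %s: LOOCV accuracy %.2f at panel size %d\n",
                label, cl, res$best[[cl]]$accuracy, res$best[[cl]]$size))
  }
  cat(sprintf("  %s permutation p (DLDA, %d perms): %.4f\n", label, n_perm, pp$p))
  list(best = res$best, permutation_p = pp$p)
}

meth_labels <- ifelse(groups == "control", "control", "METH")
m1 <- run_model("control_vs_meth", E, meth_labels, seed + 2000L)
sub <- groups %in% c("MA", "MAP")
m2 <- run_model("ma_vs_map", E[, sub], groups[sub], seed + 2001L)

jsonlite::write_json(list(control_vs_meth = m1, ma_vs_map = m2),
                     file.path(outdir, "classifier_summary.json"),
                     auto_unbox = TRUE, digits = NA)
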