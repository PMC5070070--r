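#!/usr/bin/env Rscript
# Stage 4: Bayes-regularized ANOVA of module eigengenes across the three
# groups (conf = 12, window 5, Tukey post hoc) and module-trait Pearson
# correlations with asymptotic p-values; derive the MAP-associated and
# confounder-associated module lists.

suppressPackageStartupMessages(library(mapblood))
outdir <- "results"

me_df <- read.delim(file.path(outdir, "eigengenes.tsv"), check.names = FALSE)
me <- as.matrix(me_df[, -1]); rownames(me) <- me_df$module
phen <- read.delim(file.path(outdir, "phenotypes.tsv"), check.names = FALSE)
stopifnot(all(colnames(me) %in% phen$subject))
groups <- phen$group[match(colnames(me), phen$subject)]

me_test <- bayes_anova(me, groups, bayes_anova_config())
trait_cor <- correlate_traits(me, phen)

map_cols <- grep("^p_adj_.*MAP", names(me_test), value = TRUE)
map_modules <- as.integer(sub("^ME", "", me_test$feature[
  me_test$p < 0.05 & apply(me_test[, map_cols, drop = FALSE] < 0.05, 1, any)]))

conf_traits <- c("nicotine_use", "cannabis_use", "alcohol_use")
conf_modules <- unique(as.integer(sub("^ME", "", trait_cor$module[
  trait_cor$trait %in% conf_traits & !is.na(trait_cor$p) & trait_cor$p < 0.05])))

write.table(me_test, file.path(outdir, "me_group_test.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(trait_cor, file.path(outdir, "module_trait_cor.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(as.character(map_modules), file.path(outdir, "map_modules.txt"))
writeLines(as.character(conf_modules), file.path(outdir, "confounder_modules.txt"))

cat("MAP-associated modules (omnibus p < 0.05 + MAP pairwise Tukey p < 0.05):",
    if (length(map_modules)) paste(map_modules, collapse = ", ") else "none", "\n")
cat("Polysubstance-associated modules:",
    if (length(conf_modules)) paste(conf_modules, collapse = ", ") else "none", "\n")
cat("Bonferroni bar for the module-trait table:",
    signif(attr(trait_cor, "bonferroni_alpha"), 3), "\n")
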