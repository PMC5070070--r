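#' Adjusted Rand index between two partitions
#'
#' Permutation-model-corrected agreement between two labelings of the same
#' items; 1 for identical partitions, around 0 for independent ones. Used to
#' quantify recovery of planted modules.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

#' Run the full biomarker-discovery pipeline on a synthetic cohort
#'
#' Chains simulation, preprocessing, network construction, module statistics,
#' differential expression with confounder exclusion, diagnostic panel
#' construction and CFG scoring, and returns a machine-readable report. A
#' single global seed derives per-stage seeds by fixed offsets (cohort: seed;
#' evidence: seed + 1000; permutations: seed + 2000), so reruns with the same
#' configuration and seed reproduce the report exactly (timings aside).
#'
#' @param config a [cohort_config()]; its `seed` is overridden by `seed`.
#' @param seed global integer seed.
#' @param net_config a [network_config()].
#' @param anova_config a [bayes_anova_config()].
#' @param cfg a [cfg_config()].
#' @param min_reads,min_subjects low-expression filter settings.
#' @param de_alpha nominal DE threshold feeding the candidate pool.
#' @param confounder_traits trait names treated as polysubstance confounders.
#' @param n_perm permutations for the classifier p-value (0 skips the
#'   permutation test; the published analysis used 1000 -- reduce for
#'   desk-scale runs).
#' @param outdir optional directory; when given, all intermediate tables are
#'   written as TSV/JSON.
#' @return list of class `map_pipeline_report`; see the elements `cohort`,
#'   `preprocess`, `network`, `module_stats`, `classifier`, `cfg`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         net_config = network_config(),
                         anova_config = bayes_anova_config(),
                         cfg = cfg_config(),
                         min_reads = 20, min_subjects = 10,
                         de_alpha = 0.01,
                         confounder_traits = c("nicotine_use", "cannabis_use",
                                               "alcohol_use"),
                         n_perm = 100, outdir = NULL) {
  seed <- as.integer(seed)

  # --- simulate -------------------------------------------------------------
  cohort <- generate_cohort(config, seed = seed)
  evidence <- generate_evidence_db(cohort$truth, config, seed = seed + 1000L)
  groups <- cohort$phenotypes$group

  # --- preprocess -----------------------------------------------------------
  counts_f <- filter_low_expression(cohort$counts, min_reads, min_subjects)
  norm <- voom_normalize(counts_f)
  outliers <- detect_outliers(norm)

  # --- network --------------------------------------------------------------
  adj <- signed_adjacency(norm, net_config)
  tom <- topological_overlap(adj)
  part0 <- detect_modules(tom$diss, net_config)
  kept <- rownames(norm$E) %in% names(part0)
  partition <- merge_close_modules(norm$E[kept, , drop = FALSE], part0, net_config)
  eg <- attr(partition, "eigengenes")
  if (is.null(eg)) stop("no modules detected")
  kme <- module_membership(norm, eg, partition)
  sft <- scale_free_fit(adj)

  # --- module statistics ----------------------------------------------------
  me_test <- bayes_anova(eg$me, groups, anova_config)
  trait_cor <- correlate_traits(eg, cohort$phenotypes)
  map_modules <- .map_associated_modules(me_test)

  # --- differential expression + classifier ---------------------------------
  glev <- config$groups # control, MA, MAP
  de_map_ctrl <- moderated_ttest(norm, groups, glev[1], glev[3])
  de_map_ma <- moderated_ttest(norm, groups, glev[2], glev[3])
  de_ctrl_ma <- moderated_ttest(norm, groups, glev[1], glev[2])
  de_all <- rbind(de_map_ctrl, de_map_ma, de_ctrl_ma)
  de_clean <- exclude_confounded(de_all, partition, trait_cor, confounder_traits)
  candidates <- sort(unique(de_clean$gene[de_clean$p < de_alpha]))

  classifier <- list()
  if (length(candidates) >= 2) {
    meth_labels <- ifelse(groups == glev[1], "control", "METH")
    classifier$control_vs_meth <- rfe_loocv(norm, meth_labels, candidates)
    sub <- groups %in% glev[2:3]
    classifier$ma_vs_map <- rfe_loocv(
      list(E = norm$E[, sub, drop = FALSE]), groups[sub], candidates)
    if (n_perm > 0) {
      classifier$permutation <- list(
        control_vs_meth = permutation_pvalue(norm, meth_labels, candidates,
                                             n_perm = n_perm, seed = seed + 2000L),
        ma_vs_map = permutation_pvalue(list(E = norm$E[, sub, drop = FALSE]),
                                       groups[sub], candidates,
                                       n_perm = n_perm, seed = seed + 2001L)
      )
    }
  }

  # --- CFG ------------------------------------------------------------------
  score_table <- cfg_score_table(de_map_ctrl, de_map_ma, de_ctrl_ma,
                                 partition, map_modules, evidence, cfg)
  evidence_genes <- unique(evidence$gene)
  mods <- sort(unique(partition[partition > 0]))
  enr <- do.call(rbind, lapply(mods, function(m) {
    e <- cfg_module_enrichment(names(partition)[partition == m],
                               evidence_genes, nrow(norm$E))
    cbind(data.frame(module = m), e)
  }))

  report <- structure(list(
    seed = seed,
    cohort = list(n_genes = nrow(cohort$counts), n_subjects = ncol(cohort$counts),
                  groups = table(groups)),
    preprocess = list(n_retained = attr(counts_f, "n_retained"),
                      n_removed = attr(counts_f, "n_removed"),
                      outliers = as.character(outliers)),
    network = list(n_modules = length(mods),
                   module_sizes = as.integer(table(partition[partition > 0])),
                   n_grey = sum(partition == 0),
                   scale_free_r2 = sft,
                   partition = partition, eigengenes = eg, kme = kme),
    module_stats = list(me_test = me_test, trait_cor = trait_cor,
                        map_modules = map_modules),
    de = list(tables = list(map_vs_ctrl = de_map_ctrl, map_vs_ma = de_map_ma,
                            ctrl_vs_ma = de_ctrl_ma),
              excluded_modules = attr(de_clean, "excluded_modules"),
              n_candidates = length(candidates), candidates = candidates),
    classifier = classifier,
    cfg = list(table = score_table, module_enrichment = enr,
               n_prioritized = sum(score_table$prioritized)),
    truth = cohort$truth,
    evidence = evidence,
    phenotypes = cohort$phenotypes
  ), class = "map_pipeline_report")

  if (!is.null(outdir)) .write_report(report, outdir)
  report
}

# MAP-associated modules: omnibus group difference at p < 0.05 with a
# MAP-involving pairwise comparison surviving the Tukey correction.
.map_associated_modules <- function(me_test) {
  map_cols <- grep("^p_adj_.*MAP", names(me_test), value = TRUE)
  hit <- me_test$p < 0.05 &
    apply(me_test[, map_cols, drop = FALSE] < 0.05, 1, any)
  as.integer(sub("^ME", "", me_test$feature[hit]))
}

#' Headline summary of a pipeline report
#' @param x a `map_pipeline_report`.
#' @param ... unused.
#' @export
print.map_pipeline_report <- function(x, ...) {
  cat("MAP blood-biomarker pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  genes retained: ", x$preprocess$n_retained, " of ",
      x$cohort$n_genes, "; outliers: ",
      if (length(x$preprocess$outliers)) paste(x$preprocess$outliers, collapse = ", ")
      else "none", "\n", sep = "")
  cat("  modules: ", x$network$n_modules, " (grey genes: ", x$network$n_grey,
      "); scale-free R2: ", round(x$network$scale_free_r2, 3), "\n", sep = "")
  cat("  MAP-associated modules: ",
      if (length(x$module_stats$map_modules))
        paste(x$module_stats$map_modules, collapse = ", ") else "none", "\n", sep = "")
  cat("  DE candidates (p<0.01, confounder-cleaned): ", x$de$n_candidates, "\n", sep = "")
  for (m in intersect(names(x$classifier), c("control_vs_meth", "ma_vs_map"))) {
    b <- x$classifier[[m]]$best$dlda
    cat("  ", m, ": DLDA LOOCV accuracy ", round(b$accuracy, 3),
        " at panel size ", b$size, "\n", sep = "")
  }
  cat("  CFG-prioritized genes (threshold ", 3, "): ", x$cfg$n_prioritized,
      "\n", sep = "")
  invisible(x)
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(data.frame(gene = names(report$network$partition),
                module = as.integer(report$network$partition)), "partition.tsv")
  me <- report$network$eigengenes$me
  wt(cbind(data.frame(module = rownames(me)), as.data.frame(me)), "eigengenes.tsv")
  wt(report$module_stats$me_test, "me_group_test.tsv")
  wt(report$module_stats$trait_cor, "module_trait_cor.tsv")
  for (nm in names(report$de$tables)) wt(report$de$tables[[nm]], paste0("de_", nm, ".tsv"))
  wt(report$cfg$table, "cfg_scores.tsv")
  wt(report$cfg$module_enrichment, "cfg_module_enrichment.tsv")
  wt(report$evidence, "evidence_db.tsv")
  wt(report$phenotypes, "phenotypes.tsv")
  headline <- list(
    seed = report$seed,
    n_retained = report$preprocess$n_retained,
    n_modules = report$network$n_modules,
    map_modules = report$module_stats$map_modules,
    n_candidates = report$de$n_candidates,
    best_panels = lapply(report$classifier[intersect(names(report$classifier),
                                                     c("control_vs_meth", "ma_vs_map"))],
                         function(r) r$best$dlda),
    n_prioritized = report$cfg$n_prioritized
  )
  jsonlite::write_json(headline, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Write a count matrix as TSV
#' @param counts gene x subject matrix.
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(cbind(data.frame(gene = rownames(counts)),
                           as.data.frame(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix from TSV (first column = gene id)
#' @param path TSV file.
#' @return integer gene x subject matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
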