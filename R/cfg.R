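#' Convergent Functional Genomics scoring parameters
#'
#' The two-step CFG point system: internal evidence from the three group-wise
#' differential comparisons (1 point below p 0.001, 0.5 points in
#' \[0.001, 0.01), 0.2 points in \[0.01, 0.05), plus 0.5 when both MAP
#' comparisons pass p < 0.01 and 0.5 for membership in a MAP-associated
#' module, capping the internal score at 4), and external literature evidence
#' (1 point per distinct evidence-type x disease line, at most 5 lines, with
#' 1 extra point outside the cap when a peripheral-blood psychosis line
#' exists). The maximum total is 10 = 4 + 5 + 1.
#'
#' @param p_thresholds decreasing p-value thresholds of the point table.
#' @param points points awarded below each threshold.
#' @param both_map_bonus bonus when both MAP comparisons pass `both_map_p`.
#' @param both_map_p the p cutoff for the both-comparison bonus.
#' @param module_bonus bonus for MAP-associated module membership.
#' @param external_cap maximum number of counted external lines.
#' @param blood_psychosis_bonus extra points for blood evidence in psychosis.
#' @param threshold prioritization cutoff on the total score. The default 3
#'   is the stricter published bar; 2 is also used in the literature.
#' @return list of class `cfg_config`.
#' @export
cfg_config <- function(p_thresholds = c(0.001, 0.01, 0.05),
                       points = c(1, 0.5, 0.2),
                       both_map_bonus = 0.5, both_map_p = 0.01,
                       module_bonus = 0.5,
                       external_cap = 5, blood_psychosis_bonus = 1,
                       threshold = 3) {
  stopifnot(length(p_thresholds) == length(points),
            !is.unsorted(p_thresholds), all(diff(points) < 0))
  structure(list(p_thresholds = p_thresholds, points = points,
                 both_map_bonus = both_map_bonus, both_map_p = both_map_p,
                 module_bonus = module_bonus, external_cap = external_cap,
                 blood_psychosis_bonus = blood_psychosis_bonus,
                 threshold = threshold),
            class = "cfg_config")
}

.evidence_types <- c("blood_expression", "brain_expression", "genetic")
.evidence_diseases <- c("psychosis", "SCZ", "depression_stress", "neurocognitive")

.cfg_points <- function(p, config) {
  # half-open bins: p exactly at a threshold falls in the lower-scoring bin
  pts <- numeric(length(p))
  for (i in rev(seq_along(config$p_thresholds))) {
    pts[p < config$p_thresholds[i]] <- config$points[i]
  }
  pts
}

#' Internal CFG score of one gene
#'
#' Applies the threshold point table to the three comparison p-values
#' (MAP vs control, MAP vs MA, control vs MA) and adds the two 0.5-point
#' bonuses. A gene qualifies only if at least one p-value is below 0.05;
#' otherwise `NA` is returned (the gene is excluded from scoring).
#'
#' @param p_map_vs_ctrl,p_map_vs_ma,p_ctrl_vs_ma the three comparison
#'   p-values (`NA` allowed, treated as non-significant).
#' @param in_map_module is the gene a member of a MAP-associated module?
#' @param config a [cfg_config()].
#' @return internal score in \[0.2, 4\], or `NA` for excluded genes.
#' @export
internal_score <- function(p_map_vs_ctrl, p_map_vs_ma, p_ctrl_vs_ma,
                           in_map_module = FALSE, config = cfg_config()) {
  p3 <- c(p_map_vs_ctrl, p_map_vs_ma, p_ctrl_vs_ma)
  p3[is.na(p3)] <- 1
  if (min(p3) >= max(config$p_thresholds)) return(NA_real_)
  sc <- sum(.cfg_points(p3, config))
  both_map <- p3[1] < config$both_map_p && p3[2] < config$both_map_p
  sc <- sc + if (both_map) config$both_map_bonus else 0
  sc <- sc + if (isTRUE(in_map_module)) config$module_bonus else 0
  sc
}

#' External CFG score of one gene
#'
#' One external line of evidence is one distinct (evidence type, disease)
#' combination with at least one non-METH record; each line scores 1 point,
#' capped at `external_cap`. If a (blood_expression, psychosis) line exists,
#' the blood-psychosis weighting adds `blood_psychosis_bonus` outside the
#' cap. Records flagged `METH_study` are excluded; records with an unknown
#' evidence type or disease are rejected with a warning.
#'
#' @param gene gene id.
#' @param db evidence data.frame with columns `gene`, `evidence_type`,
#'   `disease` and optionally `METH_study`.
#' @param config a [cfg_config()].
#' @return list: `score` (capped line count), `bonus` (0 or the weighting),
#'   `lines` (data.frame of counted lines).
#' @export
external_score <- function(gene, db, config = cfg_config()) {
  db <- .validate_evidence(db)
  rec <- db[db$gene == gene, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(list(score = 0, bonus = 0,
                lines = rec[, c("evidence_type", "disease"), drop = FALSE]))
  }
  lines <- unique(rec[, c("evidence_type", "disease"), drop = FALSE])
  score <- min(nrow(lines), config$external_cap)
  has_bp <- any(lines$evidence_type == "blood_expression" &
                  lines$disease == "psychosis")
  bonus <- if (has_bp) config$blood_psychosis_bonus else 0
  list(score = score, bonus = bonus, lines = lines)
}

.validate_evidence <- function(db) {
  stopifnot(all(c("gene", "evidence_type", "disease") %in% names(db)))
  if ("METH_study" %in% names(db)) {
    db <- db[!db$METH_study %in% TRUE, , drop = FALSE]
  }
  bad <- !(db$evidence_type %in% .evidence_types) | !(db$disease %in% .evidence_diseases)
  if (any(bad)) {
    warning("rejecting ", sum(bad), " evidence record(s) with unknown type/disease")
    db <- db[!bad, , drop = FALSE]
  }
  db
}

#' Total CFG score
#'
#' @param internal internal score component.
#' @param external capped external line score.
#' @param bonus blood-psychosis weighting (0 or 1 by default).
#' @param config a [cfg_config()].
#' @return list: `total`, `prioritized` (total at or above the configured
#'   threshold).
#' @export
cfg_total <- function(internal, external, bonus, config = cfg_config()) {
  total <- internal + external + bonus
  list(total = total, prioritized = !is.na(total) & total >= config$threshold)
}

#' Score all genes and build the CFG prioritization table
#'
#' Combines the three comparison DE tables, the MAP-associated module list
#' and the external evidence database into a per-gene CFG score table, sorted
#' by decreasing total score (ties: higher internal score, then gene id).
#' Genes with all three p-values at or above 0.05 are excluded.
#'
#' @param de_map_vs_ctrl,de_map_vs_ma,de_ctrl_vs_ma DE tables from
#'   [moderated_ttest()] (columns `gene`, `p`).
#' @param partition named integer vector gene -> module.
#' @param map_modules integer vector of MAP-associated module labels.
#' @param db evidence data.frame (see [external_score()]).
#' @param config a [cfg_config()].
#' @return data.frame: `gene`, the three p-values, `internal`, `external`,
#'   `n_lines`, `blood_psychosis_bonus`, `total`, `prioritized`.
#' @export
cfg_score_table <- function(de_map_vs_ctrl, de_map_vs_ma, de_ctrl_vs_ma,
                            partition, map_modules, db,
                            config = cfg_config()) {
  db <- .validate_evidence(db)
  genes <- sort(unique(c(de_map_vs_ctrl$gene, de_map_vs_ma$gene, de_ctrl_vs_ma$gene)))
  p1 <- de_map_vs_ctrl$p[match(genes, de_map_vs_ctrl$gene)]
  p2 <- de_map_vs_ma$p[match(genes, de_map_vs_ma$gene)]
  p3 <- de_ctrl_vs_ma$p[match(genes, de_ctrl_vs_ma$gene)]
  in_map <- genes %in% names(partition)[partition %in% map_modules]

  rows <- lapply(seq_along(genes), function(i) {
    int <- internal_score(p1[i], p2[i], p3[i], in_map[i], config)
    if (is.na(int)) return(NULL)
    ext <- external_score(genes[i], db, config)
    tot <- cfg_total(int, ext$score, ext$bonus, config)
    data.frame(gene = genes[i], p_map_vs_ctrl = p1[i], p_map_vs_ma = p2[i],
               p_ctrl_vs_ma = p3[i], internal = int, external = ext$score,
               n_lines = nrow(ext$lines), blood_psychosis_bonus = ext$bonus,
               total = tot$total, prioritized = tot$prioritized,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene = character(), p_map_vs_ctrl = numeric(),
                      p_map_vs_ma = numeric(), p_ctrl_vs_ma = numeric(),
                      internal = numeric(), external = numeric(),
                      n_lines = integer(), blood_psychosis_bonus = numeric(),
                      total = numeric(), prioritized = logical()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$total, -out$internal, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of CFG-evidence genes within a module
#'
#' Upper-tail hypergeometric test of the overlap between a module's gene list
#' and the set of genes carrying CFG evidence, against the expressed
#' background. Zero overlaps are reported (p near 1), not skipped.
#'
#' @param module_genes character vector, the module's members.
#' @param evidence_genes character vector of evidence-bearing genes.
#' @param background_size expressed background universe size.
#' @return one-row data.frame `overlap`, `p`.
#' @export
cfg_module_enrichment <- function(module_genes, evidence_genes, background_size) {
  res <- hypergeometric_enrichment(unique(module_genes),
                                   list(evidence = unique(evidence_genes)),
                                   background_size, min_overlap = 0)
  data.frame(overlap = res$overlap, p = res$p)
}
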