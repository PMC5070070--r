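#' Bayes-regularized ANOVA parameters
#'
#' Defaults follow the analysis settings used for the module-eigengene group
#' tests: prior strength `conf = 12`, regularization on, window size 5.
#'
#' @param conf prior strength (pseudo-observations contributed by the
#'   background variance).
#' @param bayes logical; when `FALSE` the classical one-way ANOVA is used.
#' @param win_size odd positive window (number of features nearest in overall
#'   mean) over which the background variance is averaged.
#' @return list of class `bayes_anova_config`.
#' @export
bayes_anova_config <- function(conf = 12, bayes = TRUE, win_size = 5) {
  stopifnot(conf >= 0, win_size >= 1, win_size %% 2 == 1)
  structure(list(conf = conf, bayes = isTRUE(bayes), win_size = as.integer(win_size)),
            class = "bayes_anova_config")
}

#' Bayes-regularized one-way ANOVA across groups
#'
#' For each feature (eigengene, brain volume, ...) the within-group variances
#' are shrunk toward a local background: the mean sample variance of the
#' `win_size` features nearest in overall mean (window clipped at the edges).
#' The regularized variance for group g is
#' `s2_reg = (conf * s2_bg + (n_g - 1) * s2_g) / (conf + n_g - 1)` with
#' effective degrees of freedom `conf + n_g - 1`, so that as `conf -> 0` (or
#' with `bayes = FALSE`) the procedure reduces exactly to the classical
#' one-way ANOVA. The omnibus F uses the pooled regularized within-group
#' variance; pairwise post hoc comparisons use the same pooled variance with
#' a Tukey studentized-range family correction over the group pairs.
#'
#' @param values feature x subject numeric matrix.
#' @param groups group label per subject (length `ncol(values)`).
#' @param config a [bayes_anova_config()].
#' @return data.frame with one row per feature: per-group means and sds,
#'   omnibus `F` and `p`, and for each group pair the raw and Tukey-corrected
#'   p-values plus a direction label (e.g. `"control > MAP"`).
#' @export
bayes_anova <- function(values, groups, config = bayes_anova_config()) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(values))
  glev <- unique(groups)
  k <- length(glev)
  if (k < 2) stop("need at least 2 groups")
  n_g <- vapply(glev, function(g) sum(groups == g), integer(1))
  if (any(n_g < 2)) stop("every group needs at least 2 subjects")

  nf <- nrow(values)
  means <- sapply(glev, function(g) rowMeans(values[, groups == g, drop = FALSE]))
  vars <- sapply(glev, function(g) apply(values[, groups == g, drop = FALSE], 1, stats::var))
  means <- matrix(means, nf, k, dimnames = list(rownames(values), glev))
  vars <- matrix(vars, nf, k, dimnames = list(rownames(values), glev))

  # local background variance: window of win_size features nearest in overall mean
  overall <- rowMeans(values)
  ord <- order(overall, seq_len(nf)) # ties broken by feature order
  half <- (min(config$win_size, nf) - 1L) %/% 2L
  bg <- matrix(NA_real_, nf, k)
  pos <- match(seq_len(nf), ord)
  for (f in seq_len(nf)) {
    lo <- max(1L, min(pos[f] - half, nf - 2L * half))
    hi <- min(nf, lo + 2L * half)
    win <- ord[lo:hi]
    bg[f, ] <- colMeans(vars[win, , drop = FALSE])
  }

  conf <- if (config$bayes) config$conf else 0
  df_g <- conf + matrix(n_g, nf, k, byrow = TRUE) - 1
  s2_reg <- (conf * bg + sweep(vars, 2, n_g - 1, "*")) / df_g
  df_within <- rowSums(df_g)

  N <- sum(n_g)
  grand <- (means %*% n_g) / N
  msb <- rowSums(sweep((means - as.vector(grand))^2, 2, n_g, "*")) / (k - 1)
  msw <- rowSums(s2_reg * df_g) / df_within
  f_stat <- ifelse(msb == 0, 0, msb / msw)
  f_stat[msb > 0 & msw == 0] <- Inf
  p_omni <- ifelse(is.finite(f_stat),
                   stats::pf(f_stat, k - 1, df_within, lower.tail = FALSE),
                   0)
  p_omni[f_stat == 0] <- 1

  out <- data.frame(feature = rownames(values) %||% as.character(seq_len(nf)),
                    F = f_stat, p = p_omni, df_within = df_within,
                    stringsAsFactors = FALSE)
  for (g in glev) {
    out[[paste0("mean_", g)]] <- means[, g]
    out[[paste0("sd_", g)]] <- sqrt(vars[, g])
  }
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(msw * (1 / n_g[a] + 1 / n_g[b]))
    tt <- (means[, a] - means[, b]) / se
    tt[se == 0] <- 0
    praw <- 2 * stats::pt(-abs(tt), df_within)
    ptuk <- stats::ptukey(abs(tt) * sqrt(2), nmeans = k, df = df_within,
                          lower.tail = FALSE)
    dir <- ifelse(means[, a] >= means[, b], paste(a, ">", b), paste(b, ">", a))
    tag <- paste0(a, "_vs_", b)
    out[[paste0("p_", tag)]] <- praw
    out[[paste0("p_adj_", tag)]] <- pmax(ptuk, praw)
    out[[paste0("dir_", tag)]] <- dir
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Module-trait correlations with asymptotic p-values
#'
#' Pearson correlation between each module eigengene and each numeric trait
#' (pairwise-complete), with the two-sided Student asymptotic p-value
#' `p = 2 * P(T_{n-2} > |r| sqrt((n-2)/(1-r^2)))`. Group status is encoded as
#' one-vs-rest 0/1 indicator traits. The Bonferroni threshold across all
#' tested pairs is reported in the attribute `bonferroni_alpha`.
#'
#' @param eigengenes result of [module_eigengenes()] or a module x subject
#'   matrix.
#' @param phenotypes data.frame with columns `subject`, `group` and numeric
#'   traits; subjects must match the eigengene columns.
#' @return long-format data.frame: `module`, `trait`, `r`, `p`, `n`.
#' @export
correlate_traits <- function(eigengenes, phenotypes) {
  me <- if (is.list(eigengenes)) eigengenes$me else as.matrix(eigengenes)
  stopifnot(is.data.frame(phenotypes), "subject" %in% names(phenotypes))
  ph <- phenotypes[match(colnames(me), phenotypes$subject), , drop = FALSE]
  if (any(is.na(ph$subject))) stop("phenotype table is missing subjects present in eigengenes")

  traits <- ph[, setdiff(names(ph), c("subject", "group")), drop = FALSE]
  traits <- traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE]
  if ("group" %in% names(ph)) {
    for (g in unique(ph$group)) traits[[paste0("status_", g)]] <- as.numeric(ph$group == g)
  }

  rows <- list()
  for (m in rownames(me)) {
    for (tr in names(traits)) {
      x <- me[m, ]; y <- traits[[tr]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      sdy <- if (n >= 2) stats::sd(y[ok]) else NA_real_
      if (n < 3 || !is.finite(sdy) || sdy == 0) {
        if (isTRUE(sdy == 0)) warning("constant trait '", tr, "'; correlation undefined")
        rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr,
                                               r = NA_real_, p = NA_real_, n = n)
        next
      }
      r <- stats::cor(x[ok], y[ok])
      p <- cor_pvalue(r, n)
      rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr, r = r, p = p, n = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_alpha") <- 0.05 / sum(!is.na(out$p))
  out
}

#' Two-sided asymptotic p-value for a Pearson correlation
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations.
#' @return two-sided p-value.
#' @export
cor_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  r <- pmin(pmax(r, -1), 1)
  ifelse(abs(r) == 1, 0,
         2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
}

#' One-tailed hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability of observing an overlap at least as
#' large as the one seen between a query gene list and each gene set, against
#' a background of `background_size` genes, with Bonferroni correction across
#' the tested sets. Sets overlapping the query in fewer than `min_overlap`
#' genes are skipped (not tested, and not counted in the correction).
#'
#' @param query_genes character vector of query gene ids.
#' @param gene_sets named list of character vectors (or a single character
#'   vector, treated as one set named `"set1"`).
#' @param background_size integer background universe size; must be at least
#'   the size of the union of query and any set.
#' @param min_overlap minimum overlap for a set to be tested (default 2).
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `p_bonferroni`.
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets, background_size,
                                      min_overlap = 2) {
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  query_genes <- unique(query_genes)
  for (s in gene_sets) {
    if (length(union(query_genes, s)) > background_size) {
      stop("background_size smaller than the union of query and gene set")
    }
  }
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    ov <- length(intersect(query_genes, set))
    if (ov < min_overlap) return(NULL)
    p <- stats::phyper(ov - 1, length(set), background_size - length(set),
                       length(query_genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set = character(), set_size = integer(), overlap = integer(),
                      p = numeric(), p_bonferroni = numeric()))
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}
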