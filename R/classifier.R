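#' Moderated two-sample t-test with empirical-Bayes variance shrinkage
#'
#' Per-gene pooled two-sample variances are shrunk toward a common prior
#' estimated by method of moments on the log sample variances: with
#' `z_g = log(s2_g)` and residual df `d_g`, the prior df `d0` solves
#' `trigamma(d0/2) = var(e) - trigamma(d_g/2)` for
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, and the prior variance is
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The posterior variance
#' `(d0 s0^2 + d_g s2_g) / (d0 + d_g)` replaces the sample variance in the
#' t statistic, which gains `d0` degrees of freedom.
#'
#' @param expr gene x subject log2 expression matrix (or `voom_normalize()`
#'   list; weights are not used).
#' @param groups group label per subject.
#' @param group_a,group_b the two labels to compare (`group_b` minus
#'   `group_a` is the reported log-fold-change direction: positive logFC
#'   means higher in `group_b`).
#' @param prior_df optional override of the estimated prior df `d0` (useful
#'   for the `d0 -> 0` classical limit; `Inf` gives fully pooled variance).
#' @return data.frame `gene`, `comparison`, `logFC`, `t`, `p`, with
#'   attributes `d0` and `s02`.
#' @export
moderated_ttest <- function(expr, groups, group_a, group_b, prior_df = NULL) {
  E <- if (is.list(expr)) expr$E else as.matrix(expr)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(E))
  ia <- groups == group_a
  ib <- groups == group_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("need at least 2 subjects per group")
  st <- .moderated_t_stats(E, ia, ib, prior_df)
  out <- data.frame(gene = rownames(E) %||% as.character(seq_len(nrow(E))),
                    comparison = paste0(group_a, "_vs_", group_b),
                    logFC = st$logFC, t = st$t, p = st$p,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- st$d0
  attr(out, "s02") <- st$s02
  out
}

.moderated_t_stats <- function(E, ia, ib, prior_df = NULL) {
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(E[, ia, drop = FALSE])
  mb <- rowMeans(E[, ib, drop = FALSE])
  ssa <- rowSums((E[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((E[, ib, drop = FALSE] - mb)^2)
  d <- na + nb - 2
  if (d <= 0) stop("zero residual degrees of freedom")
  s2 <- (ssa + ssb) / d

  if (is.null(prior_df)) {
    hp <- .fit_log_variance_prior(s2, d)
  } else {
    s2_pos <- s2[s2 > 0]
    hp <- list(d0 = prior_df,
               s02 = if (is.finite(prior_df) && prior_df > 0)
                 .fit_log_variance_prior(s2, d)$s02 else stats::median(s2_pos))
  }
  d0 <- hp$d0; s02 <- hp$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  logFC <- mb - ma
  t <- ifelse(se > 0, logFC / se, 0)
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(t), df_total)
  list(logFC = logFC, t = t, p = p, d0 = d0, s02 = s02)
}

# Method-of-moments fit of the scaled inverse chi-square variance prior on
# the log scale (d0 may come back Inf when variances are underdispersed).
.fit_log_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (y = trigamma(x), solve for x).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Exclude genes from confounder-associated modules
#'
#' Removes from a differential-expression table every gene whose module is
#' significantly correlated (raw p < `alpha`) with any named confounder
#' trait, the polysubstance-adjustment strategy of the workflow.
#'
#' @param de data.frame from [moderated_ttest()] (or several comparisons row-bound).
#' @param partition named integer vector gene -> module.
#' @param trait_cor long-format table from [correlate_traits()].
#' @param confounder_traits character vector of trait names (e.g.
#'   `c("nicotine_use", "cannabis_use", "alcohol_use")`).
#' @param alpha association threshold on the raw correlation p-value.
#' @return the filtered DE table; attribute `excluded_modules` lists the
#'   dropped modules and `excluded_genes` the dropped genes.
#' @export
exclude_confounded <- function(de, partition, trait_cor, confounder_traits,
                               alpha = 0.05) {
  missing_tr <- setdiff(confounder_traits, unique(trait_cor$trait))
  if (length(missing_tr)) stop("unknown confounder trait(s): ",
                               paste(missing_tr, collapse = ", "))
  hits <- trait_cor[trait_cor$trait %in% confounder_traits &
                      !is.na(trait_cor$p) & trait_cor$p < alpha, , drop = FALSE]
  bad_mods <- unique(as.integer(sub("^ME", "", hits$module)))
  bad_genes <- names(partition)[partition %in% bad_mods]
  out <- de[!de$gene %in% bad_genes, , drop = FALSE]
  attr(out, "excluded_modules") <- bad_mods
  attr(out, "excluded_genes") <- intersect(unique(de$gene), bad_genes)
  attr(out, "d0") <- attr(de, "d0")
  out
}

#' Diagonal linear discriminant analysis
#'
#' Gaussian classifier with class-specific means and a shared diagonal
#' covariance: the pooled within-class variance per gene. A test sample is
#' assigned to the class minimizing `sum_j (x_j - mu_kj)^2 / s2_j`; ties are
#' broken by (sorted) class label order. Genes with zero pooled variance are
#' dropped with a warning.
#'
#' @param train_expr gene x subject training matrix.
#' @param train_labels class label per training subject.
#' @param test_expr gene x subject matrix of samples to classify.
#' @return character vector of predicted labels.
#' @export
dlda_fit_predict <- function(train_expr, train_labels, test_expr) {
  Etr <- as.matrix(train_expr)
  Ete <- as.matrix(test_expr)
  y <- as.character(train_labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  n_k <- vapply(classes, function(k) sum(y == k), integer(1))
  if (any(n_k < 2)) stop("every class needs at least 2 training subjects")

  mu <- sapply(classes, function(k) rowMeans(Etr[, y == k, drop = FALSE]))
  mu <- matrix(mu, nrow(Etr), length(classes), dimnames = list(rownames(Etr), classes))
  ss <- sapply(classes, function(k) rowSums((Etr[, y == k, drop = FALSE] - mu[, k])^2))
  s2 <- rowSums(matrix(ss, nrow(Etr))) / (length(y) - length(classes))
  if (any(s2 == 0)) {
    warning("dropping ", sum(s2 == 0), " zero-variance gene(s)")
    keep <- s2 > 0
    if (!any(keep)) stop("no genes with positive pooled variance")
    Ete <- Ete[keep, , drop = FALSE]
    mu <- mu[keep, , drop = FALSE]
    s2 <- s2[keep]
  }
  scores <- sapply(classes, function(k) colSums((Ete - mu[, k])^2 / s2))
  scores <- matrix(scores, ncol(Ete), length(classes))
  classes[apply(scores, 1, which.min)]
}

#' Nearest-centroid classifier (unshrunken)
#' @inheritParams dlda_fit_predict
#' @return predicted labels.
#' @export
nearest_centroid_predict <- function(train_expr, train_labels, test_expr) {
  Etr <- as.matrix(train_expr); Ete <- as.matrix(test_expr)
  y <- as.character(train_labels)
  classes <- sort(unique(y))
  mu <- sapply(classes, function(k) rowMeans(Etr[, y == k, drop = FALSE]))
  mu <- matrix(mu, nrow(Etr), length(classes))
  scores <- sapply(seq_along(classes), function(k) colSums((Ete - mu[, k])^2))
  scores <- matrix(scores, ncol(Ete), length(classes))
  classes[apply(scores, 1, which.min)]
}

#' k-nearest-neighbour classifier (Euclidean)
#'
#' Majority vote among the `k` nearest training subjects; vote ties are
#' broken in favour of the class of the nearest neighbour among the tied
#' classes.
#' @inheritParams dlda_fit_predict
#' @param k neighbourhood size (default 3).
#' @return predicted labels.
#' @export
knn_predict <- function(train_expr, train_labels, test_expr, k = 3) {
  Etr <- as.matrix(train_expr); Ete <- as.matrix(test_expr)
  y <- as.character(train_labels)
  k <- min(k, ncol(Etr))
  pred <- character(ncol(Ete))
  for (i in seq_len(ncol(Ete))) {
    dd <- colSums((Etr - Ete[, i])^2)
    nn <- order(dd)[seq_len(k)]
    votes <- table(y[nn])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else y[nn][y[nn] %in% top][1]
  }
  pred
}

#' Linear soft-margin support vector machine (binary)
#'
#' Deterministic full-batch subgradient descent on the primal hinge-loss
#' objective `lambda/2 ||w||^2 + mean(hinge)`, with `lambda = 1/(C n)` and
#' cost `C = 1`, on feature-standardized inputs. Intended as a comparator
#' classifier; only two classes are supported.
#' @inheritParams dlda_fit_predict
#' @param cost soft-margin cost parameter C.
#' @param n_iter number of full-batch subgradient steps.
#' @return predicted labels.
#' @export
svm_linear_predict <- function(train_expr, train_labels, test_expr,
                               cost = 1, n_iter = 200) {
  Etr <- as.matrix(train_expr); Ete <- as.matrix(test_expr)
  y <- as.character(train_labels)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("linear SVM comparator is binary only")
  yy <- ifelse(y == classes[2], 1, -1)
  mu <- rowMeans(Etr); sdv <- apply(Etr, 1, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- t((Etr - mu) / sdv)  # subjects x genes
  Xte <- t((Ete - mu) / sdv)
  n <- nrow(Xtr); p <- ncol(Xtr)
  lambda <- 1 / (cost * n)
  w <- numeric(p); b <- 0
  w_sum <- numeric(p); b_sum <- 0
  for (t in seq_len(n_iter)) {
    marg <- yy * (Xtr %*% w + b)
    viol <- as.vector(marg) < 1
    gw <- lambda * w - colSums(Xtr[viol, , drop = FALSE] * yy[viol]) / n
    gb <- -sum(yy[viol]) / n
    eta <- 1 / (lambda * (t + 1))
    w <- w - eta * gw
    b <- b - eta * gb
    w_sum <- w_sum + w; b_sum <- b_sum + b
  }
  w <- w_sum / n_iter; b <- b_sum / n_iter
  ifelse(as.vector(Xte %*% w + b) >= 0, classes[2], classes[1])
}

.classifier_fns <- list(
  dlda = dlda_fit_predict,
  svm = svm_linear_predict,
  centroid = nearest_centroid_predict,
  knn3 = function(tr, y, te) knn_predict(tr, y, te, k = 3)
)

# Nested panel sizes of the recursive elimination path: drop the
# lowest-ranked 10% (at least one gene) per step, down to a single gene.
.rfe_sizes <- function(n) {
  sizes <- n
  while (n > 1) {
    n <- n - max(1L, floor(0.1 * n))
    sizes <- c(sizes, n)
  }
  as.integer(sizes)
}

#' Recursive feature elimination under leave-one-out cross-validation
#'
#' For every held-out subject, candidate genes are re-ranked on the training
#' subjects only (absolute moderated t), the elimination path drops the
#' lowest-ranked 10% per step down to one gene, every panel size along the
#' path is evaluated by training each classifier on the training subjects and
#' predicting the held-out subject. Feature selection therefore happens
#' strictly inside each fold. The best panel size per classifier maximizes
#' LOOCV accuracy (ties: smallest panel); per-gene cross-validation support
#' is the percentage of folds whose selected panel (at the best size of the
#' reference classifier) contains the gene; the reported panel is the
#' ranking on all subjects truncated at the best size.
#'
#' @param expr gene x subject log2 expression matrix (or `voom_normalize()`
#'   list).
#' @param labels two-class label per subject.
#' @param candidate_genes character vector of candidate genes (typically the
#'   pooled DE lists at p < 0.01 after confounder exclusion).
#' @param classifiers subset of `c("dlda", "svm", "centroid", "knn3")`.
#' @param reference classifier whose best size defines the panel and CV
#'   support (default `"dlda"`).
#' @return list: `accuracy` (long data.frame classifier x panel size),
#'   `best` (per classifier: size, accuracy), `panel` (data.frame gene,
#'   rank, cv_support for the reference classifier), `sizes`, `cv_support`
#'   (all candidates), and `fold_ranks` (per-fold candidate ranking, useful
#'   for auditing that selection happened inside the fold).
#' @export
rfe_loocv <- function(expr, labels, candidate_genes,
                      classifiers = c("dlda", "svm", "centroid", "knn3"),
                      reference = "dlda") {
  E <- if (is.list(expr)) expr$E else as.matrix(expr)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(E), reference %in% classifiers)
  classifiers <- match.arg(classifiers, names(.classifier_fns), several.ok = TRUE)
  candidate_genes <- intersect(candidate_genes, rownames(E))
  if (length(candidate_genes) < 1) stop("no candidate genes present in the matrix")
  if (any(table(labels) < 2)) stop("each class needs at least 2 subjects for LOOCV")
  Ec <- E[candidate_genes, , drop = FALSE]
  n <- ncol(Ec)
  sizes <- .rfe_sizes(length(candidate_genes))
  classes <- sort(unique(labels))

  correct <- array(0, dim = c(length(classifiers), length(sizes)),
                   dimnames = list(classifiers, sizes))
  fold_panels <- vector("list", n)
  fold_ranks <- vector("list", n)

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    ia <- ytr == classes[1]; ib <- ytr == classes[2]
    st <- .moderated_t_stats(Ec[, tr, drop = FALSE], ia, ib)
    rk <- order(-abs(st$t), seq_along(candidate_genes)) # ties: gene order
    fold_ranks[[i]] <- rk
    for (ci in seq_along(classifiers)) {
      cl <- classifiers[ci]
      if (cl %in% c("dlda", "centroid")) {
        pred <- .nested_diag_predict(Ec[, tr, drop = FALSE], ytr,
                                     Ec[, i, drop = FALSE], rk, sizes,
                                     pooled_var = cl == "dlda")
      } else {
        pred <- vapply(sizes, function(s) {
          g <- rk[seq_len(s)]
          .classifier_fns[[cl]](Ec[g, tr, drop = FALSE], ytr,
                                Ec[g, i, drop = FALSE])
        }, character(1))
      }
      correct[ci, ] <- correct[ci, ] + (pred == labels[i])
    }
  }

  acc <- correct / n
  best <- lapply(classifiers, function(cl) {
    a <- acc[cl, ]
    # ties: smallest panel (sizes are stored decreasing, so pick the last max)
    j <- max(which(a == max(a)))
    list(size = sizes[j], accuracy = unname(a[j]))
  })
  names(best) <- classifiers

  ref_size <- best[[reference]]$size
  support <- stats::setNames(numeric(length(candidate_genes)), candidate_genes)
  for (i in seq_len(n)) {
    sel <- candidate_genes[fold_ranks[[i]][seq_len(ref_size)]]
    support[sel] <- support[sel] + 1
  }
  support <- 100 * support / n

  ia <- labels == classes[1]; ib <- labels == classes[2]
  st_all <- .moderated_t_stats(Ec, ia, ib)
  rk_all <- order(-abs(st_all$t), seq_along(candidate_genes))
  panel_genes <- candidate_genes[rk_all[seq_len(ref_size)]]
  panel <- data.frame(gene = panel_genes, rank = seq_along(panel_genes),
                      cv_support = unname(support[panel_genes]),
                      stringsAsFactors = FALSE)

  acc_long <- data.frame(
    classifier = rep(classifiers, times = length(sizes)),
    size = rep(sizes, each = length(classifiers)),
    accuracy = as.vector(acc[, as.character(sizes), drop = FALSE][classifiers, ]),
    stringsAsFactors = FALSE
  )
  list(accuracy = acc_long, best = best, panel = panel, sizes = sizes,
       cv_support = support, fold_ranks = fold_ranks, candidates = candidate_genes)
}

# Evaluate DLDA / nearest-centroid along a nested elimination path by
# accumulating per-gene score contributions in rank order (O(genes) per fold).
.nested_diag_predict <- function(Etr, ytr, ete, rk, sizes, pooled_var = TRUE) {
  classes <- sort(unique(ytr))
  mu <- sapply(classes, function(k) rowMeans(Etr[, ytr == k, drop = FALSE]))
  mu <- matrix(mu, nrow(Etr), length(classes))
  if (pooled_var) {
    ss <- sapply(seq_along(classes), function(k)
      rowSums((Etr[, ytr == classes[k], drop = FALSE] - mu[, k])^2))
    s2 <- rowSums(matrix(ss, nrow(Etr))) / (length(ytr) - length(classes))
    s2[s2 == 0] <- Inf # zero-variance gene contributes nothing
  } else {
    s2 <- rep(1, nrow(Etr))
  }
  contrib <- (as.vector(ete) - mu)^2 / s2     # gene x class
  cum <- apply(contrib[rk, , drop = FALSE], 2, cumsum)
  cum <- matrix(cum, length(rk), length(classes))
  vapply(sizes, function(s) classes[which.min(cum[s, ])], character(1))
}

#' Permutation p-value for a cross-validated classifier
#'
#' Repeats the full RFE + LOOCV pipeline (feature selection inside every
#' fold) on label permutations and reports
#' `p = (1 + #{perm error <= observed error}) / (n_perm + 1)` for the
#' reference classifier's best cross-validated misclassification rate.
#'
#' @inheritParams rfe_loocv
#' @param n_perm number of label permutations.
#' @param seed integer seed; results are deterministic given the seed.
#' @param classifier classifier family evaluated under permutation.
#' @return list: `p`, `observed_error`, `perm_errors`.
#' @export
permutation_pvalue <- function(expr, labels, candidate_genes, n_perm = 1000,
                               seed = 1, classifier = "dlda") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- rfe_loocv(expr, labels, candidate_genes, classifiers = classifier,
                   reference = classifier)
  obs_err <- 1 - obs$best[[classifier]]$accuracy
  set.seed(seed)
  perm_err <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(labels)
    # degenerate permutations (a class with < 2 subjects) cannot occur when
    # class counts are preserved by sample(); run the identical pipeline
    res <- rfe_loocv(expr, yp, candidate_genes, classifiers = classifier,
                     reference = classifier)
    perm_err[b] <- 1 - res$best[[classifier]]$accuracy
  }
  list(p = (1 + sum(perm_err <= obs_err)) / (n_perm + 1),
       observed_error = obs_err, perm_errors = perm_err)
}
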