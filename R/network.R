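#' Network construction parameters
#'
#' Defaults follow the published analysis: soft-threshold power 9, minimum
#' module size 15, deep split 2, eigengene merge height 0.2, signed network.
#'
#' @param beta soft-threshold power.
#' @param min_module_size smallest allowed module.
#' @param deep_split integer 0-4; larger values split the dendrogram more
#'   aggressively.
#' @param merge_cut_height eigengene dissimilarity (1 - cor) below which
#'   neighbouring modules are merged.
#' @param signed use the signed adjacency `((1 + r)/2)^beta`; if `FALSE`, the
#'   unsigned `|r|^beta` transform is used instead.
#' @return list of class `network_config`.
#' @export
network_config <- function(beta = 9, min_module_size = 15, deep_split = 2,
                           merge_cut_height = 0.2, signed = TRUE) {
  stopifnot(beta > 0, min_module_size >= 2,
            deep_split %in% 0:4,
            merge_cut_height > 0, merge_cut_height < 1)
  structure(list(beta = beta, min_module_size = as.integer(min_module_size),
                 deep_split = as.integer(deep_split),
                 merge_cut_height = merge_cut_height, signed = isTRUE(signed)),
            class = "network_config")
}

#' Signed (or unsigned) weighted adjacency
#'
#' Maps pairwise Pearson correlations to edge weights. In signed mode
#' `a_ij = ((1 + r_ij)/2)^beta`, so perfectly anti-correlated genes get
#' weight 0 and the map is strictly increasing in r; in unsigned mode
#' `a_ij = |r_ij|^beta`. The diagonal is 1. Zero-variance genes are dropped
#' with a warning before the correlation is computed; if a zero-variance gene
#' survives (e.g. supplied in a 1-gene matrix), an error names it.
#'
#' @param expr gene x subject expression matrix (or `voom_normalize()` list).
#' @param config a [network_config()].
#' @return symmetric gene x gene adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(expr, config = network_config()) {
  E <- if (is.list(expr)) expr$E else as.matrix(expr)
  stopifnot(ncol(E) >= 3)
  v <- apply(E, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(E)[v == 0]
    warning("dropping zero-variance gene(s): ", paste(bad, collapse = ", "))
    E <- E[v > 0, , drop = FALSE]
    if (nrow(E) == 0) stop("no genes with nonzero variance remain")
  }
  r <- stats::cor(t(E))
  if (any(!is.finite(r))) {
    bad <- rownames(E)[which(!is.finite(r), arr.ind = TRUE)[, 1]]
    stop("undefined correlation involving gene(s): ", paste(unique(bad), collapse = ", "))
  }
  a <- if (config$signed) ((1 + r) / 2)^config$beta else abs(r)^config$beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Computes the weighted connectivity `k_i = sum_{j != i} a_ij`, bins it,
#' and fits `log10(frequency)` against `log10(mean k)` by least squares.
#' Returns the R-squared of the fit, negated when the slope is positive
#' (an increasing degree distribution is not scale-free).
#'
#' @param adjacency symmetric adjacency matrix.
#' @param n_bins number of connectivity bins (reduced with a warning when
#'   there are fewer distinct connectivity values).
#' @return signed R-squared, or `NA` with a warning when the connectivities
#'   are all equal.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- rowSums(adjacency) - diag(adjacency)
  if (length(unique(round(k, 12))) < 2) {
    warning("all connectivities equal; scale-free fit undefined")
    return(NA_real_)
  }
  if (length(unique(k)) < n_bins) {
    n_bins <- max(2, length(unique(k)) - 1)
    warning("few distinct connectivity values; reducing to ", n_bins, " bins")
  }
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  x <- log10(mean_k[ok]); y <- log10(freq[ok] / length(k))
  if (length(x) < 3) {
    warning("too few populated bins for a fit")
    return(NA_real_)
  }
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` with `TOM_ii = 1`, where `k` is connectivity excluding the
#' diagonal. The returned list carries the TOM and its dissimilarity
#' `1 - TOM`, the standard clustering input for module detection.
#'
#' @param adjacency symmetric adjacency with unit diagonal.
#' @return list with `tom` and `diss` matrices.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  a_off <- a
  diag(a_off) <- 0
  k <- rowSums(a_off)
  num <- a_off %*% a_off + a_off
  den <- outer(k, k, pmin) + 1 - a_off
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2 # symmetrize numerical noise
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  list(tom = tom, diss = 1 - tom)
}

# Static-cut fraction of the maximum merge height per deep-split level.
# Larger deep_split cuts lower, producing more and smaller branches.
.cut_fraction <- c(`0` = 0.990, `1` = 0.985, `2` = 0.980, `3` = 0.975, `4` = 0.970)

#' Detect co-expression modules from a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of genes on the dissimilarity
#' (typically `1 - TOM`) followed by a simplified hybrid tree cut: the tree
#' is cut at a deep-split-dependent fraction of its maximum merge height;
#' branches of at least `min_module_size` genes become modules (numbered by
#' decreasing size); smaller branches are absorbed into the nearest module
#' when their average dissimilarity to it is below 0.8 and are otherwise left
#' unassigned (module 0, "grey"). The procedure is deterministic given its
#' input.
#'
#' @param diss square symmetric dissimilarity matrix.
#' @param config a [network_config()].
#' @param absorb_max small branches are absorbed into the nearest module only
#'   if the mean dissimilarity is below this value.
#' @return named integer vector gene -> module label (0 = unassigned), with
#'   the dendrogram in attribute `dendrogram`.
#' @export
detect_modules <- function(diss, config = network_config(), absorb_max = 0.8) {
  d <- as.matrix(diss)
  stopifnot(nrow(d) == ncol(d))
  genes <- rownames(d)
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(nrow(d)))
  if (nrow(d) < config$min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    out <- stats::setNames(integer(nrow(d)), genes)
    return(out)
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  frac <- .cut_fraction[[as.character(config$deep_split)]]
  cut_h <- frac * max(tree$height)
  cl <- stats::cutree(tree, h = cut_h)

  sizes <- table(cl)
  big <- names(sizes)[sizes >= config$min_module_size]
  # number surviving branches by decreasing size (ties: lower branch id first)
  big <- big[order(-sizes[big], as.integer(big))]
  lab <- integer(length(cl))
  for (i in seq_along(big)) lab[cl == as.integer(big[i])] <- i

  # absorb sub-threshold branches into the nearest module if close enough
  if (length(big)) {
    for (b in setdiff(names(sizes), big)) {
      members <- which(cl == as.integer(b))
      avg <- vapply(seq_along(big), function(m) {
        mean(d[members, lab == m, drop = FALSE])
      }, numeric(1))
      if (min(avg) < absorb_max) lab[members] <- which.min(avg)
    }
  }
  out <- stats::setNames(lab, genes)
  attr(out, "dendrogram") <- tree
  attr(out, "cut_height") <- cut_h
  out
}

#' Module eigengenes by singular value decomposition
#'
#' The eigengene of a module is the first right-singular vector of the
#' module's standardized (per-gene mean 0, sd 1 across subjects) expression
#' submatrix -- equivalently, the first principal component score profile
#' across subjects. Each eigengene has unit Euclidean norm and is oriented so
#' that the majority of member genes correlate positively with it.
#'
#' @param expr gene x subject expression matrix (or `voom_normalize()` list).
#' @param partition named integer vector gene -> module (0 ignored).
#' @return list with `me` (module x subject eigengene matrix, rows named
#'   `ME<label>`) and `var_explained` (first squared singular value over the
#'   total, per module).
#' @export
module_eigengenes <- function(expr, partition) {
  E <- if (is.list(expr)) expr$E else as.matrix(expr)
  mods <- sort(unique(partition[partition > 0]))
  if (!length(mods)) stop("no modules in partition")
  me <- matrix(NA_real_, length(mods), ncol(E),
               dimnames = list(paste0("ME", mods), colnames(E)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    m <- mods[i]
    genes <- names(partition)[partition == m]
    X <- E[genes, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) {
      stop("module ", m, " contains constant gene(s): ",
           paste(genes[sds == 0], collapse = ", "))
    }
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs)
    v1 <- sv$v[, 1]
    # orient: majority of member genes correlate positively with the ME
    if (sum(sign(stats::cor(t(Xs), v1))) < 0) v1 <- -v1
    me[i, ] <- v1
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(me = me, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules whose eigengenes are most
#' correlated while the eigengene dissimilarity `1 - cor` is below
#' `merge_cut_height`, recomputing eigengenes after every merge. On return no
#' pair of eigengenes has correlation above `1 - merge_cut_height`.
#'
#' @inheritParams module_eigengenes
#' @param config a [network_config()].
#' @return relabelled partition (consecutive labels, 0 preserved) with the
#'   final eigengene list in attribute `eigengenes`.
#' @export
merge_close_modules <- function(expr, partition, config = network_config()) {
  part <- partition
  attr(part, "dendrogram") <- NULL
  repeat {
    mods <- sort(unique(part[part > 0]))
    if (length(mods) < 2) break
    eg <- module_eigengenes(expr, part)
    cc <- stats::cor(t(eg$me))
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - config$merge_cut_height) break
    keep <- mods[min(top)]
    drop <- mods[max(top)]
    part[part == drop] <- keep
  }
  # relabel consecutively by decreasing size
  mods <- sort(unique(part[part > 0]))
  sizes <- vapply(mods, function(m) sum(part == m), integer(1))
  new_lab <- stats::setNames(seq_along(mods), mods[order(-sizes, mods)])
  out <- part
  out[part > 0] <- new_lab[as.character(part[part > 0])]
  attr(out, "eigengenes") <- if (any(out > 0)) module_eigengenes(expr, out) else NULL
  out
}

#' Module membership (kME) and hub genes
#'
#' kME of gene g in module m is the Pearson correlation between the gene's
#' expression profile and module m's eigengene. The hub gene of a module is
#' the member with maximal own-module kME (ties broken by row order).
#'
#' @param expr gene x subject expression matrix (or `voom_normalize()` list).
#' @param eigengenes result of [module_eigengenes()].
#' @param partition optional partition; when given, per-module hub genes are
#'   reported.
#' @return list with `kme` (gene x module matrix) and `hubs` (named character
#'   vector, module -> hub gene; `NULL` without a partition).
#' @export
module_membership <- function(expr, eigengenes, partition = NULL) {
  E <- if (is.list(expr)) expr$E else as.matrix(expr)
  kme <- stats::cor(t(E), t(eigengenes$me))
  hubs <- NULL
  if (!is.null(partition)) {
    mods <- sort(unique(partition[partition > 0]))
    hubs <- stats::setNames(character(length(mods)), paste0("ME", mods))
    for (i in seq_along(mods)) {
      members <- names(partition)[partition == mods[i]]
      km <- kme[members, paste0("ME", mods[i])]
      hubs[i] <- members[which.max(km)]
    }
  }
  list(kme = kme, hubs = hubs)
}
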