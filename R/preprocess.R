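#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_reads` reads in at least `min_subjects`
#' subjects, the unspecific low-expression filter applied before
#' normalization. The subject set is never changed and the filter is
#' idempotent.
#'
#' @param counts integer gene x subject matrix.
#' @param min_reads minimum read count per subject for a subject to "count".
#' @param min_subjects minimum number of subjects meeting `min_reads`.
#'
#' @return The filtered count matrix, with attributes `n_retained` and
#'   `n_removed`.
#' @export
filter_low_expression <- function(counts, min_reads = 20, min_subjects = 10) {
  counts <- .as_count_matrix(counts)
  stopifnot(min_reads >= 0, min_subjects <= ncol(counts))
  keep <- rowSums(counts >= min_reads) >= min_subjects
  if (!any(keep)) warning("no genes pass the low-expression filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

.as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("G%04d", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    stop("duplicate subject ids")
  }
  counts
}

#' Variance-stabilizing log-CPM normalization with precision weights
#'
#' Transforms counts to log2 counts-per-million with the standard half-count
#' offsets, `log2((count + 0.5) / (lib + 1) * 1e6)`, then fits a smooth
#' mean-variance trend -- a lowess of the square-root residual standard
#' deviation against the mean log2 count across genes -- and converts the
#' predicted per-observation standard deviation into inverse-variance
#' precision weights. This reproduces the contract of the voom-style
#' transformation used for bulk RNA-seq counts without importing it.
#'
#' @param counts filtered integer gene x subject count matrix.
#' @param span lowess span for the mean-variance trend.
#'
#' @return list with `E` (log2-CPM matrix), `weights` (same shape, > 0), and
#'   `trend` (data.frame of the fitted lowess curve: mean log2 count vs
#'   sqrt-sd).
#' @export
voom_normalize <- function(counts, span = 0.5) {
  counts <- .as_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for subject(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  E <- log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)

  # mean-variance trend on the gene level: sqrt(residual sd) vs mean log2 count
  mean_logcount <- rowMeans(E) + mean(log2(lib + 1)) - log2(1e6)
  resid_sd <- sqrt(apply(E, 1, stats::var))
  sqrt_sd <- sqrt(resid_sd)
  ok <- is.finite(mean_logcount) & is.finite(sqrt_sd)
  lo <- stats::lowess(mean_logcount[ok], sqrt_sd[ok], f = span)

  # per-observation predicted sqrt-sd at the fitted log2 count (gene mean
  # log-CPM plus the subject's library offset), linear interpolation,
  # clamped to the fitted range at the extremes
  fitted_logcount <- outer(rowMeans(E), log2(lib + 1) - log2(1e6), "+")
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_logcount), rule = 2,
                        ties = mean)$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(1 / pred^4, nrow(E), ncol(E), dimnames = dimnames(E))

  list(E = E, weights = w,
       trend = data.frame(mean_logcount = lo$x, sqrt_sd = lo$y))
}

#' Screen subjects for expression outliers
#'
#' Flags subjects that fall beyond `k_sd` standard deviations from the cohort
#' mean on either of two criteria: (a) the subject's mean inter-subject
#' Pearson correlation (the average-distance clustering criterion) or (b) the
#' subject's score on the first or second principal component of the
#' expression matrix. The union of the two criteria is used.
#'
#' @param expr normalized expression list from [voom_normalize()] or a plain
#'   gene x subject matrix.
#' @param k_sd flagging threshold in standard deviations.
#'
#' @return character vector of flagged subject ids (possibly empty), with the
#'   per-criterion detail in attribute `criteria`.
#' @export
detect_outliers <- function(expr, k_sd = 2.0) {
  E <- if (is.list(expr)) expr$E else as.matrix(expr)
  stopifnot(ncol(E) >= 3)
  subj <- colnames(E)
  if (is.null(subj)) subj <- sprintf("S%02d", seq_len(ncol(E)))

  sds <- apply(E, 2, stats::sd)
  flagged_const <- subj[sds == 0]
  if (length(flagged_const)) {
    warning("constant-expression subject(s): ", paste(flagged_const, collapse = ", "))
  }
  keep <- sds > 0
  flags <- character(0)
  crit <- list()
  if (sum(keep) >= 3) {
    cc <- stats::cor(E[, keep, drop = FALSE])
    mean_cor <- (rowSums(cc) - 1) / (sum(keep) - 1)
    z_cor <- .zscore(mean_cor)
    pc <- stats::prcomp(t(E[, keep, drop = FALSE]), center = TRUE, scale. = FALSE)
    z_pc1 <- .zscore(pc$x[, 1])
    z_pc2 <- if (ncol(pc$x) >= 2) .zscore(pc$x[, 2]) else rep(0, sum(keep))
    out <- abs(z_cor) > k_sd | abs(z_pc1) > k_sd | abs(z_pc2) > k_sd
    flags <- subj[keep][out]
    crit <- list(mean_correlation_z = z_cor, pc1_z = z_pc1, pc2_z = z_pc2)
  }
  res <- union(flagged_const, flags)
  attr(res, "criteria") <- crit
  res
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
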