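# Shared reduced-scale fixtures: planted structure identical to the package
# defaults, fewer background genes, so multi-seed experiments stay fast.

small_config <- function(...) {
  cohort_config(n_genes = 800,
                module_sizes = c(80, 60, 50, 50, 40, 40, 30, 30), ...)
}

null_config <- function(n_genes = 800) {
  cohort_config(n_genes = n_genes,
                module_sizes = c(80, 60, 50, 50, 40, 40, 30, 30),
                group_effects = list(), phenotype_couplings = list(),
                evidence_enrichment = c(), baseline_evidence_rate = 0.02)
}

# Toy expression matrix with two classes perfectly separable by a pair of
# marker genes. The markers share antithetic within-class noise, so each
# marker alone is ambiguous while any panel containing both separates the
# classes exactly (their sum is noise-free).
separable_data <- function(n_per_class = 10, n_genes = 40, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  E <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n))))
  y <- rep(c("A", "B"), each = n_per_class)
  cls <- as.numeric(y == "B")
  z <- rnorm(n)
  E[1, ] <- 3 * cls + 1.2 * z
  E[2, ] <- 3 * cls - 1.2 * z
  list(E = E, y = y, markers = rownames(E)[1:2])
}

# Exact upper-tail hypergeometric p by enumeration over all possible overlaps.
enum_hyper_p <- function(overlap, set_size, background, query_size) {
  ks <- 0:min(set_size, query_size)
  probs <- choose(set_size, ks) * choose(background - set_size, query_size - ks) /
    choose(background, query_size)
  sum(probs[ks >= overlap])
}
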