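#' Configuration for a synthetic MAP cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults describe a 30-subject cohort (10 healthy controls, 10
#' methamphetamine-dependent subjects without psychosis, MA, and 10 with
#' psychosis, MAP) with eight planted co-expression modules on a 2000-gene
#' background. Module co-expression is induced by a per-module latent factor
#' with gene-wise loadings; group effects act as log2-scale shifts of the
#' latent factor mean in the affected group; phenotypes are linear functions
#' of module factors plus Gaussian noise; counts are negative binomial around
#' library-size-scaled expected expression.
#'
#' @param n_genes total number of genes.
#' @param n_per_group subjects per group.
#' @param groups ordered group labels; first label is the reference group.
#' @param module_sizes planted module sizes (genes per module); the remaining
#'   genes form an unstructured background. All sizes must be >= 2 and sum to
#'   at most `n_genes`.
#' @param loading_mean,loading_sd mean and sd of gene loadings on the module
#'   latent factor. With residual sd `resid_sd`, the expected within-module
#'   gene-gene correlation is roughly `loading_mean^2 / (loading_mean^2 +
#'   resid_sd^2)` before counting noise.
#' @param group_effects named list mapping module index (as character) to a
#'   named numeric vector of per-group latent-factor mean shifts (log2 scale).
#'   Groups not named get shift 0.
#' @param nb_dispersion negative-binomial dispersion (1/size); must be > 0.
#' @param lib_size_mean,lib_size_cv mean and coefficient of variation of
#'   log-normal library sizes.
#' @param resid_sd residual log2-expression noise sd for module genes.
#' @param background_sd marginal log2-expression noise sd for background genes.
#' @param base_log2_mean,base_log2_sd parameters of the log-normal (base-2)
#'   gene abundance distribution.
#' @param phenotype_couplings named list mapping phenotype column to
#'   `list(module =, slope =, noise_sd =)`; the phenotype is
#'   `base + slope * factor + noise`. Bases for known clinical columns are
#'   built in (brain volumes in mm3, psychometric totals, use counts).
#' @param confounder_module module index whose latent factor drives the
#'   substance-use covariates (the polysubstance confounder).
#' @param evidence_enrichment named numeric vector mapping module index (as
#'   character) to the probability that a member gene carries external
#'   literature evidence; all entries in \[0, 1\].
#' @param baseline_evidence_rate evidence probability for all other genes.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   cohorts.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000,
                          n_per_group = 10,
                          groups = c("control", "MA", "MAP"),
                          module_sizes = c(150, 120, 100, 100, 80, 80, 60, 60),
                          loading_mean = 1.0,
                          loading_sd = 0.2,
                          group_effects = list(
                            "1" = c(MAP = -1.0),
                            "2" = c(MAP = 1.0),
                            "3" = c(MA = 0.8, MAP = 0.8)
                          ),
                          nb_dispersion = 0.1,
                          lib_size_mean = 1e6,
                          lib_size_cv = 0.1,
                          resid_sd = 0.5,
                          background_sd = 1.0,
                          base_log2_mean = 5,
                          base_log2_sd = 1.5,
                          phenotype_couplings = list(
                            hippocampus_L = list(module = 1, slope = 250, noise_sd = 200),
                            CC_anterior   = list(module = 1, slope = -60, noise_sd = 55),
                            EPQRS_psychoticism = list(module = 2, slope = 2.0, noise_sd = 2.0),
                            K10           = list(module = 2, slope = 3.0, noise_sd = 4.0),
                            nicotine_use  = list(module = 4, slope = 5, noise_sd = 3),
                            cannabis_use  = list(module = 4, slope = 4, noise_sd = 3),
                            alcohol_use   = list(module = 4, slope = 6, noise_sd = 4)
                          ),
                          confounder_module = 4,
                          evidence_enrichment = c("1" = 0.6, "2" = 0.5),
                          baseline_evidence_rate = 0.02,
                          seed = 1L) {
  stopifnot(n_genes >= 1, n_per_group >= 2, length(groups) >= 2)
  if (any(module_sizes < 2)) {
    stop("all module_sizes must be >= 2")
  }
  if (sum(module_sizes) > n_genes) {
    stop("module_sizes sum (", sum(module_sizes), ") exceeds n_genes (", n_genes, ")")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  n_modules <- length(module_sizes)
  bad_mod <- setdiff(names(group_effects), as.character(seq_len(n_modules)))
  if (length(bad_mod)) {
    stop("group_effects references unknown module(s): ", paste(bad_mod, collapse = ", "))
  }
  for (ge in group_effects) {
    if (!all(names(ge) %in% groups)) stop("group_effects names must be group labels")
  }
  if (length(evidence_enrichment)) {
    if (!all(names(evidence_enrichment) %in% as.character(seq_len(n_modules)))) {
      stop("evidence_enrichment references unknown module(s)")
    }
    if (any(evidence_enrichment < 0 | evidence_enrichment > 1)) {
      stop("evidence_enrichment probabilities must lie in [0, 1]")
    }
  }
  stopifnot(baseline_evidence_rate >= 0, baseline_evidence_rate <= 1)
  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    groups = groups, n_modules = n_modules, module_sizes = as.integer(module_sizes),
    loading_mean = loading_mean, loading_sd = loading_sd,
    group_effects = group_effects, nb_dispersion = nb_dispersion,
    lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
    resid_sd = resid_sd, background_sd = background_sd,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    phenotype_couplings = phenotype_couplings,
    confounder_module = as.integer(confounder_module),
    evidence_enrichment = evidence_enrichment,
    baseline_evidence_rate = baseline_evidence_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Baseline values (and noise scale) for the clinical phenotype columns.
# Volumes are in mm3, in the range of adult subcortical segmentations;
# psychometric entries are instrument totals; use covariates are counts.
.phenotype_bases <- function() {
  list(
    volumes = c(
      hippocampus_L = 4100, hippocampus_R = 4200,
      accumbens_L = 620, accumbens_R = 600,
      caudate_L = 3600, caudate_R = 3700,
      putamen_L = 5100, putamen_R = 5000,
      ventral_DC_L = 4000, ventral_DC_R = 4050,
      CC_anterior = 900, CC_posterior = 950
    ),
    psychometrics = c(
      EPQRS_psychoticism = 6, EPQRS_neuroticism = 10, EPQRS_extraversion = 14,
      BDI = 8, K10 = 18, BIS = 18, BAS = 38, LEQ = 6
    ),
    substance_use = c(nicotine_use = 10, cannabis_use = 6, alcohol_use = 8)
  )
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a count matrix, a phenotype table and a truth ledger from a
#' [cohort_config()]. Genes within a module share a per-subject latent factor;
#' group effects shift the factor mean in the affected groups; phenotypes are
#' linearly coupled to module factors; counts are negative binomial with
#' log-normal library sizes.
#'
#' @param config a `cohort_config`.
#' @param seed optional integer overriding `config$seed`.
#'
#' @return list with elements
#'   `counts` (integer gene x subject matrix with dimnames),
#'   `phenotypes` (data.frame, one row per subject), and
#'   `truth` (list: `module` gene assignment with 0 = background, `loadings`,
#'   `base_log2`, `effects` module x group shift matrix, `factors`
#'   module x subject latent factors, `planted_de` genes in modules with a
#'   nonzero group effect, `expected_group_means` gene x group expected log2
#'   expression, and the phenotype couplings).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(seed)

  n_sub <- config$n_per_group * length(config$groups)
  group <- rep(config$groups, each = config$n_per_group)
  subject <- sprintf("S%02d", seq_len(n_sub))
  gene <- sprintf("G%04d", seq_len(config$n_genes))

  module <- integer(config$n_genes)
  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    module[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }

  # module x group shift matrix (log2 scale)
  effects <- matrix(0, config$n_modules, length(config$groups),
                    dimnames = list(seq_len(config$n_modules), config$groups))
  for (m in names(config$group_effects)) {
    sh <- config$group_effects[[m]]
    effects[as.integer(m), names(sh)] <- sh
  }

  # latent factors: N(shift, 1) per subject
  factors <- matrix(stats::rnorm(config$n_modules * n_sub), config$n_modules, n_sub,
                    dimnames = list(seq_len(config$n_modules), subject))
  factors <- factors + effects[, group, drop = FALSE]

  base_log2 <- stats::rnorm(config$n_genes, config$base_log2_mean, config$base_log2_sd)
  loadings <- numeric(config$n_genes)
  in_mod <- module > 0L
  loadings[in_mod] <- stats::rnorm(sum(in_mod), config$loading_mean, config$loading_sd)

  x <- matrix(base_log2, config$n_genes, n_sub)
  x[in_mod, ] <- x[in_mod, ] + loadings[in_mod] * factors[module[in_mod], , drop = FALSE]
  noise_sd <- ifelse(in_mod, config$resid_sd, config$background_sd)
  x <- x + matrix(stats::rnorm(config$n_genes * n_sub, 0, noise_sd), config$n_genes, n_sub)

  lib_cv <- config$lib_size_cv
  sdlog <- sqrt(log(1 + lib_cv^2))
  lib <- stats::rlnorm(n_sub, log(config$lib_size_mean) - sdlog^2 / 2, sdlog)

  prop <- 2^x
  prop <- sweep(prop, 2, colSums(prop), "/")
  mu <- sweep(prop, 2, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   config$n_genes, n_sub, dimnames = list(gene, subject))
  storage.mode(counts) <- "integer"

  phenotypes <- .generate_phenotypes(config, group, subject, factors)

  expected_group_means <- matrix(base_log2, config$n_genes, length(config$groups),
                                 dimnames = list(gene, config$groups))
  shift_by_gene <- matrix(0, config$n_genes, length(config$groups))
  shift_by_gene[in_mod, ] <- effects[module[in_mod], , drop = FALSE]
  expected_group_means <- expected_group_means + loadings * shift_by_gene

  mod_has_effect <- apply(abs(effects), 1, max) > 0
  planted <- logical(config$n_genes)
  planted[in_mod] <- mod_has_effect[module[in_mod]]
  planted_de <- gene[planted]

  truth <- list(
    module = stats::setNames(module, gene),
    loadings = stats::setNames(loadings, gene),
    base_log2 = stats::setNames(base_log2, gene),
    effects = effects,
    factors = factors,
    planted_de = planted_de,
    expected_group_means = expected_group_means,
    phenotype_couplings = config$phenotype_couplings,
    confounder_module = config$confounder_module,
    seed = seed
  )
  list(counts = counts, phenotypes = phenotypes, truth = truth)
}

.generate_phenotypes <- function(config, group, subject, factors) {
  bases <- .phenotype_bases()
  n_sub <- length(subject)
  cols <- c(unlist(lapply(bases, names), use.names = FALSE))
  ph <- data.frame(subject = subject, group = group, stringsAsFactors = FALSE)
  for (nm in cols) {
    base <- unlist(bases, use.names = TRUE)
    base_val <- base[[grep(paste0("\\.", nm, "$"), names(base), value = TRUE)[1]]]
    # default noise: 6% of baseline for volumes, 30% for scores/counts
    is_vol <- nm %in% names(bases$volumes)
    noise_sd <- if (is_vol) 0.06 * base_val else 0.3 * base_val
    val <- base_val + stats::rnorm(n_sub, 0, noise_sd)
    cp <- config$phenotype_couplings[[nm]]
    if (!is.null(cp)) {
      val <- base_val + cp$slope * factors[cp$module, ] + stats::rnorm(n_sub, 0, cp$noise_sd)
    }
    if (is_vol) val <- pmax(val, 1) # volumes strictly positive
    if (nm %in% names(bases$substance_use)) val <- pmax(round(val), 0)
    ph[[nm]] <- as.numeric(val)
  }
  ph
}

#' Generate a synthetic external evidence database
#'
#' Emulates a curated literature database of gene-disease evidence. For each
#' gene, the probability of carrying any evidence is the module's configured
#' enrichment (or the baseline rate for background and unenriched modules);
#' evidence-bearing genes receive 1-3 distinct (evidence type, disease) lines
#' sampled from the three evidence types (blood expression, brain expression,
#' genetic) crossed with four disease categories (psychosis, SCZ,
#' depression/stress, neurocognitive impairment).
#'
#' @param truth truth ledger from [generate_cohort()].
#' @param config the `cohort_config` used for the cohort.
#' @param seed integer seed (default: cohort seed + 1000).
#'
#' @return data.frame with columns `gene`, `evidence_type`, `disease`,
#'   `source_id`, `METH_study` (all FALSE; the scorer drops flagged records).
#' @export
generate_evidence_db <- function(truth, config, seed = NULL) {
  stopifnot(is.list(truth), !is.null(truth$module))
  if (length(config$evidence_enrichment)) {
    bad <- setdiff(names(config$evidence_enrichment), as.character(seq_len(config$n_modules)))
    if (length(bad)) stop("evidence_enrichment references unknown module(s): ",
                          paste(bad, collapse = ", "))
  }
  seed <- if (is.null(seed)) truth$seed + 1000L else as.integer(seed)
  set.seed(seed)

  genes <- names(truth$module)
  prob <- rep(config$baseline_evidence_rate, length(genes))
  for (m in names(config$evidence_enrichment)) {
    prob[truth$module == as.integer(m)] <- config$evidence_enrichment[[m]]
  }
  has_ev <- stats::runif(length(genes)) < prob

  types <- c("blood_expression", "brain_expression", "genetic")
  diseases <- c("psychosis", "SCZ", "depression_stress", "neurocognitive")
  combos <- expand.grid(evidence_type = types, disease = diseases,
                        stringsAsFactors = FALSE)

  out <- vector("list", sum(has_ev))
  j <- 0L
  for (i in which(has_ev)) {
    n_lines <- 1L + stats::rbinom(1L, 2L, prob[i])
    pick <- sample.int(nrow(combos), n_lines)
    j <- j + 1L
    out[[j]] <- data.frame(
      gene = genes[i],
      evidence_type = combos$evidence_type[pick],
      disease = combos$disease[pick],
      source_id = sprintf("SYN_%s_%d", genes[i], seq_len(n_lines)),
      METH_study = FALSE,
      stringsAsFactors = FALSE
    )
  }
  if (j == 0L) {
    return(data.frame(gene = character(), evidence_type = character(),
                      disease = character(), source_id = character(),
                      METH_study = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(j)])
}
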