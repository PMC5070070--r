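test_that("moderated t reduces to the pooled two-sample t as d0 -> 0", {
  set.seed(30)
  E <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("G%03d", 1:100), NULL))
  gr <- rep(c("A", "B"), each = 10)
  de <- moderated_ttest(E, gr, "A", "B", prior_df = 1e-12)
  t_ref <- apply(E, 1, function(v) t.test(v[gr == "B"], v[gr == "A"],
                                          var.equal = TRUE)$statistic)
  expect_lt(max(abs(de$t - t_ref)), 1e-6)
  expect_true(all(de$p >= 0 & de$p <= 1))
})

test_that("moderated t agrees with the independent limma oracle", {
  skip_if_not_installed("limma")
  set.seed(31)
  E <- matrix(rnorm(400 * 20, sd = rep(runif(400, 0.5, 2), 20)), 400, 20,
              dimnames = list(sprintf("G%03d", 1:400), NULL))
  gr <- rep(c("A", "B"), each = 10)
  E[1:20, gr == "B"] <- E[1:20, gr == "B"] + 1
  de <- moderated_ttest(E, gr, "A", "B")
  design <- model.matrix(~ gr)
  fit <- limma::eBayes(limma::lmFit(E, design))
  expect_equal(unname(de$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(de$p), unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "s02"), fit$s2.prior, tolerance = 1e-4)
})

test_that("moderated t is calibrated on null data and ranks planted effects", {
  # null calibration: common true variance, fraction p < 0.01 in [0.005, 0.02]
  fr <- vapply(1:10, function(s) {
    set.seed(s)
    E <- matrix(rnorm(1000 * 20), 1000, 20)
    rownames(E) <- sprintf("G%04d", 1:1000)
    mean(moderated_ttest(E, rep(c("A", "B"), each = 10), "A", "B")$p < 0.01)
  }, numeric(1))
  expect_gte(mean(fr), 0.005)
  expect_lte(mean(fr), 0.02)

  # planted 1.5-sd effects: median planted rank in the top decile
  set.seed(32)
  E <- matrix(rnorm(1000 * 20), 1000, 20,
              dimnames = list(sprintf("G%04d", 1:1000), NULL))
  gr <- rep(c("A", "B"), each = 10)
  planted <- sample(rownames(E), 50)
  E[planted, gr == "B"] <- E[planted, gr == "B"] + 1.5
  de <- moderated_ttest(E, gr, "A", "B")
  rk <- rank(de$p)[match(planted, de$gene)]
  expect_lte(median(rk), 0.1 * nrow(E))
})

test_that("confounder-module genes are excluded from the DE pool", {
  ch <- generate_cohort(small_config(), seed = 5)
  v <- voom_normalize(filter_low_expression(ch$counts))
  part <- ch$truth$module[rownames(v$E)]
  eg <- module_eigengenes(v$E, part)
  tc <- correlate_traits(eg, ch$phenotypes)
  gr <- ch$phenotypes$group
  de <- moderated_ttest(v, gr, "control", "MAP")

  de_clean <- exclude_confounded(de, part, tc,
                                 c("nicotine_use", "cannabis_use", "alcohol_use"))
  conf_genes <- names(part)[part == ch$truth$confounder_module]
  expect_true(ch$truth$confounder_module %in% attr(de_clean, "excluded_modules"))
  expect_length(intersect(de_clean$gene, conf_genes), 0)

  # with no associated module nothing is removed
  tc_null <- tc
  tc_null$p[tc_null$trait %in% c("nicotine_use", "cannabis_use", "alcohol_use")] <- 0.9
  de_same <- exclude_confounded(de, part, tc_null,
                                c("nicotine_use", "cannabis_use", "alcohol_use"))
  expect_equal(nrow(de_same), nrow(de))
  expect_error(exclude_confounded(de, part, tc, "no_such_trait"), "unknown")
})

test_that("DLDA matches a brute-force scorer on random instances", {
  set.seed(33)
  for (rep_i in 1:5) {
    n_class <- sample(2:5, 1)
    n_genes <- sample(5:50, 1)
    n_tr <- n_class * sample(3:6, 1)
    y <- rep(paste0("C", seq_len(n_class)), length.out = n_tr)
    Etr <- matrix(rnorm(n_genes * n_tr), n_genes, n_tr,
                  dimnames = list(sprintf("g%02d", seq_len(n_genes)), NULL))
    Ete <- matrix(rnorm(n_genes * 7), n_genes, 7)
    pred <- dlda_fit_predict(Etr, y, Ete)

    classes <- sort(unique(y))
    mu <- sapply(classes, function(k) rowMeans(Etr[, y == k, drop = FALSE]))
    s2 <- numeric(n_genes)
    for (k in classes) {
      Ek <- Etr[, y == k, drop = FALSE]
      s2 <- s2 + rowSums((Ek - rowMeans(Ek))^2)
    }
    s2 <- s2 / (n_tr - n_class)
    ref <- apply(Ete, 2, function(x) {
      classes[which.min(vapply(classes, function(k)
        sum((x - mu[, k])^2 / s2), numeric(1)))]
    })
    expect_equal(pred, unname(ref))
  }
})

test_that("DLDA centroid and boundary behaviour", {
  # a test point at a class centroid is assigned to that class
  Etr <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), 1)
  y <- rep(c("low", "high"), each = 4)
  Etr <- rbind(Etr, Etr + rnorm(8, 0, 0.1))
  expect_equal(dlda_fit_predict(Etr, y, Etr[, c(1, 5), drop = FALSE]),
               c("low", "high"))
  # 1-gene symmetric problem: the decision boundary is the centroid midpoint
  Etr1 <- matrix(c(-1, -1.2, -0.8, 1, 1.2, 0.8), 1)
  y1 <- rep(c("neg", "pos"), each = 3)
  eps <- 0.01
  expect_equal(dlda_fit_predict(Etr1, y1, matrix(c(-eps, eps), 1)),
               c("neg", "pos"))
})

test_that("RFE+LOOCV reaches perfect accuracy on separable data with full support", {
  sd_ <- separable_data()
  res <- rfe_loocv(sd_$E, sd_$y, rownames(sd_$E))
  expect_equal(res$best$dlda$accuracy, 1.0)
  expect_true(all(res$cv_support[sd_$markers] == 100))
  expect_true(all(sd_$markers %in% res$panel$gene))
  expect_true(all(res$accuracy$accuracy >= 0 & res$accuracy$accuracy <= 1))
  # all four families are evaluated on the same fold structure
  expect_setequal(unique(res$accuracy$classifier),
                  c("dlda", "svm", "centroid", "knn3"))
  for (cl in c("svm", "centroid", "knn3")) {
    expect_equal(res$best[[cl]]$accuracy, 1.0)
  }
})

test_that("permuted labels drop accuracy to chance", {
  sd_ <- separable_data()
  set.seed(34)
  accs <- vapply(1:20, function(i) {
    yp <- sample(sd_$y)
    rfe_loocv(sd_$E, yp, rownames(sd_$E), classifiers = "dlda")$best$dlda$accuracy
  }, numeric(1))
  # best-over-sizes accuracy is optimistically biased; require the mean to sit
  # inside a generous binomial band around 0.5 for 20 balanced subjects
  expect_lt(mean(accs), 0.8)
  expect_gt(mean(accs), 0.3)
})

test_that("degenerate paths and leakage guards", {
  sd_ <- separable_data()
  # a single candidate gene: one panel size, equal to DLDA LOOCV on that gene
  res1 <- rfe_loocv(sd_$E, sd_$y, sd_$markers[1], classifiers = "dlda")
  expect_equal(res1$sizes, 1L)
  acc_manual <- mean(vapply(seq_along(sd_$y), function(i) {
    dlda_fit_predict(sd_$E[sd_$markers[1], -i, drop = FALSE], sd_$y[-i],
                     sd_$E[sd_$markers[1], i, drop = FALSE]) == sd_$y[i]
  }, logical(1)))
  expect_equal(res1$best$dlda$accuracy, acc_manual)

  # no leakage: corrupting the held-out subject's expression leaves the
  # ranking used for that fold untouched
  res <- rfe_loocv(sd_$E, sd_$y, rownames(sd_$E), classifiers = "dlda")
  E2 <- sd_$E
  E2[, 5] <- E2[, 5] + 100
  res2 <- rfe_loocv(E2, sd_$y, rownames(sd_$E), classifiers = "dlda")
  expect_identical(res$fold_ranks[[5]], res2$fold_ranks[[5]])

  # accuracy curves invariant to subject ordering
  p <- sample(length(sd_$y))
  res_p <- rfe_loocv(sd_$E[, p], sd_$y[p], rownames(sd_$E), classifiers = "dlda")
  expect_equal(res_p$accuracy$accuracy, res$accuracy$accuracy)

  expect_error(rfe_loocv(sd_$E, rep(c("A", "B"), c(19, 1)), rownames(sd_$E)),
               "2 subjects")
})

test_that("panel selection is reproducible bit-exact", {
  ch <- generate_cohort(small_config(), seed = 6)
  v <- voom_normalize(filter_low_expression(ch$counts))
  gr <- ifelse(ch$phenotypes$group == "control", "control", "METH")
  de <- moderated_ttest(v, ch$phenotypes$group, "control", "MAP")
  cand <- de$gene[de$p < 0.01]
  r1 <- rfe_loocv(v, gr, cand, classifiers = "dlda")
  r2 <- rfe_loocv(v, gr, cand, classifiers = "dlda")
  expect_identical(r1$panel, r2$panel)
})

test_that("permutation p-value follows the add-one rule and separates signal", {
  sd_ <- separable_data()
  # observed error 0 on separable data, 99 permutations: p at the floor
  pr <- permutation_pvalue(sd_$E, sd_$y, rownames(sd_$E), n_perm = 99, seed = 7)
  expect_equal(pr$observed_error, 0)
  expect_lte(pr$p, 0.05)
  expect_equal(pr$p, (1 + sum(pr$perm_errors <= 0)) / 100)

  # n_perm = 1 with a worse permutation: p = 1/2 by the add-one formula
  pr1 <- permutation_pvalue(sd_$E, sd_$y, rownames(sd_$E), n_perm = 1, seed = 8)
  if (pr1$perm_errors > pr1$observed_error) expect_equal(pr1$p, 0.5)
  expect_error(permutation_pvalue(sd_$E, sd_$y, rownames(sd_$E), n_perm = 0),
               "n_perm")

  # on already-random labels p is not spuriously tiny (reduced n_perm)
  set.seed(35)
  ps <- vapply(1:10, function(i) {
    y_null <- sample(sd_$y)
    permutation_pvalue(sd_$E[3:20, ], y_null, rownames(sd_$E)[3:20],
                       n_perm = 19, seed = i)$p
  }, numeric(1))
  expect_gt(min(ps), 0.001)
})
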