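test_that("signed adjacency matches the closed-form map", {
  # endpoints and the zero-correlation value at beta = 9
  r <- c(1, -1, 0)
  a <- ((1 + r) / 2)^9
  expect_equal(a, c(1, 0, 0.5^9))
  expect_equal(0.5^9, 0.001953125)

  # 4-gene toy: element-wise brute-force evaluation
  set.seed(5)
  E <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
  cfg <- network_config(beta = 9)
  adj <- signed_adjacency(E, cfg)
  cc <- cor(t(E))
  for (i in 1:4) for (j in 1:4) {
    expected <- if (i == j) 1 else ((1 + cc[i, j]) / 2)^9
    expect_equal(adj[i, j], expected, tolerance = 1e-12)
  }
  # unsigned option
  adj_u <- signed_adjacency(E, network_config(beta = 9, signed = FALSE))
  expect_equal(adj_u[1, 2], abs(cc[1, 2])^9, tolerance = 1e-12)

  # strictly increasing in correlation (signed mode)
  rs <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(((1 + rs) / 2)^9) > 0))

  # zero-variance gene dropped with a warning
  E2 <- rbind(E, flat = rep(1, 10))
  expect_warning(a2 <- signed_adjacency(E2, cfg), "flat")
  expect_equal(nrow(a2), 4)
})

test_that("topological overlap matches closed forms and a triple-loop oracle", {
  # 2-gene network, a12 = 0.5: no shared neighbours, k1 = k2 = a12, so
  # TOM12 = (0 + a) / (a + 1 - a) = a
  a <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  tom <- topological_overlap(a)$tom
  expect_equal(tom[1, 2], 0.5)

  # maximal overlap: identical binary neighbourhoods with a_ij = 1
  a3 <- matrix(0, 4, 4); diag(a3) <- 1
  a3[1, 2] <- a3[2, 1] <- 1
  a3[1, 3] <- a3[3, 1] <- 1
  a3[2, 3] <- a3[3, 2] <- 1
  expect_equal(topological_overlap(a3)$tom[1, 2], 1, tolerance = 1e-12)

  # 5-gene toy vs brute-force O(n^3) evaluation
  set.seed(6)
  E <- matrix(rnorm(5 * 12), 5, 12)
  adj <- signed_adjacency(E, network_config())
  tom5 <- topological_overlap(adj)$tom
  k <- rowSums(adj) - 1
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    num <- sum(vapply(setdiff(1:5, c(i, j)), function(u) adj[i, u] * adj[u, j],
                      numeric(1))) + adj[i, j]
    den <- min(k[i], k[j]) + 1 - adj[i, j]
    expect_equal(tom5[i, j], num / den, tolerance = 1e-12)
  }
  expect_true(all(tom5 >= 0 & tom5 <= 1))
  expect_equal(tom5, t(tom5))
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("adjacency and TOM are equivariant under gene permutation", {
  set.seed(7)
  E <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(sprintf("g%02d", 1:20), NULL))
  adj <- signed_adjacency(E, network_config())
  tom <- topological_overlap(adj)$tom
  p <- sample(20)
  adj_p <- signed_adjacency(E[p, ], network_config())
  expect_equal(adj_p, adj[p, p])
  expect_equal(topological_overlap(adj_p)$tom, tom[p, p])
})

test_that("scale-free fit ranks a power-law network above a correlation network", {
  expect_warning(r <- scale_free_fit(matrix(0.5, 10, 10)), "undefined")
  expect_true(is.na(r))

  # preferential-attachment-like weights: k_i proportional to a power law
  set.seed(8)
  n <- 300
  w <- sort((1:n)^-0.7, decreasing = TRUE)
  a_pl <- outer(w, w); diag(a_pl) <- 1
  r_pl <- scale_free_fit(a_pl)
  expect_gte(r_pl, 0.8)

  E <- matrix(rnorm(n * 20), n, 20)
  a_g <- signed_adjacency(E, network_config())
  expect_lt(scale_free_fit(a_g), r_pl)
})

test_that("module detection resolves separated blocks and documents small-branch handling", {
  d <- matrix(1, 40, 40)
  d[1:20, 1:20] <- 0; d[21:40, 21:40] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("g%02d", 1:40)
  part <- detect_modules(d, network_config(min_module_size = 15))
  expect_equal(length(unique(part)), 2)
  expect_true(all(part > 0))
  expect_equal(unname(table(part)), array(c(20L, 20L)))

  # blocks below the size threshold: no module can form, everything grey
  part25 <- detect_modules(d, network_config(min_module_size = 25))
  expect_true(all(part25 == 0))

  # fewer genes than min size: warning + all grey
  d5 <- d[1:5, 1:5]
  expect_warning(p5 <- detect_modules(d5, network_config(min_module_size = 15)),
                 "unassigned")
  expect_true(all(p5 == 0))
})

test_that("module detection recovers planted modules (ARI >= 0.7)", {
  ch <- generate_cohort(small_config(), seed = 1)
  v <- voom_normalize(filter_low_expression(ch$counts))
  adj <- signed_adjacency(v, network_config())
  part <- detect_modules(topological_overlap(adj)$diss, network_config())
  truth_mod <- ch$truth$module[names(part)]
  nb <- truth_mod > 0
  expect_gte(adjusted_rand_index(truth_mod[nb], part[nb]), 0.7)
})

test_that("eigengenes match a covariance-eigendecomposition PCA oracle", {
  set.seed(9)
  E <- matrix(rnorm(12 * 10), 12, 10, dimnames = list(sprintf("g%02d", 1:12), NULL))
  part <- setNames(rep(1L, 12), rownames(E))
  eg <- module_eigengenes(E, part)

  Xs <- t(scale(t(E)))
  ev <- eigen(crossprod(Xs)) # subjects x subjects covariance kernel
  v1 <- ev$vectors[, 1]
  if (sum(sign(cor(t(Xs), v1))) < 0) v1 <- -v1
  expect_lt(max(abs(eg$me[1, ] - v1)), 1e-8)
  expect_equal(sum(eg$me[1, ]^2), 1, tolerance = 1e-12)
  expect_equal(unname(eg$var_explained[1]), ev$values[1] / sum(ev$values),
               tolerance = 1e-12)

  # module of identical genes: rank one, variance explained 1
  E1 <- matrix(rep(rnorm(10), times = 10), 10, 10, byrow = TRUE)
  rownames(E1) <- sprintf("h%02d", 1:10)
  eg1 <- module_eigengenes(E1, setNames(rep(1L, 10), rownames(E1)))
  expect_equal(abs(cor(eg1$me[1, ], E1[1, ])), 1, tolerance = 1e-10)
  expect_equal(unname(eg1$var_explained[1]), 1, tolerance = 1e-10)

  # permuting subjects permutes the eigengene identically
  p <- sample(10)
  egp <- module_eigengenes(E[, p], part)
  expect_equal(abs(egp$me[1, ]), abs(eg$me[1, p]), tolerance = 1e-10)

  # constant gene inside a module is an error naming the module
  Ec <- E; Ec[3, ] <- 2
  expect_error(module_eigengenes(Ec, part), "module 1")
})

test_that("eigengene reproduces the planted latent factor", {
  ch <- generate_cohort(small_config(), seed = 2)
  v <- voom_normalize(filter_low_expression(ch$counts))
  truth_part <- ch$truth$module[rownames(v$E)]
  eg <- module_eigengenes(v$E, truth_part)
  for (m in 1:8) {
    expect_gte(abs(cor(eg$me[paste0("ME", m), ], ch$truth$factors[m, ])), 0.9)
  }
})

test_that("module merging honours the eigengene correlation cut", {
  set.seed(10)
  n_sub <- 30
  f <- rnorm(n_sub)
  make_block <- function(f, n, noise) {
    t(sapply(seq_len(n), function(i) f + rnorm(n_sub, 0, noise)))
  }
  # modules 1 and 2 share a factor (ME cor ~ 1): merged; module 3 independent
  E <- rbind(make_block(f, 20, 0.1), make_block(f, 20, 0.1),
             make_block(rnorm(n_sub), 20, 0.1))
  rownames(E) <- sprintf("g%02d", 1:60)
  part <- setNames(rep(1:3, each = 20), rownames(E))
  merged <- merge_close_modules(E, part, network_config(merge_cut_height = 0.2))
  expect_equal(length(unique(merged[merged > 0])), 2)
  expect_equal(length(unique(merged[1:40])), 1)

  # uncorrelated eigengenes are never merged
  E2 <- rbind(make_block(rnorm(n_sub), 20, 0.1), make_block(rnorm(n_sub), 20, 0.1))
  rownames(E2) <- sprintf("h%02d", 1:40)
  part2 <- setNames(rep(1:2, each = 20), rownames(E2))
  merged2 <- merge_close_modules(E2, part2, network_config())
  expect_equal(length(unique(merged2)), 2)

  # ME correlation ~0.85 (dissimilarity 0.15 < 0.2): merged
  # build f2 with exact sample correlation 0.85 against f
  zres <- residuals(lm(rnorm(n_sub) ~ f))
  f2 <- 0.85 * scale(f)[, 1] + sqrt(1 - 0.85^2) * scale(zres)[, 1]
  E3 <- rbind(make_block(f, 25, 0.05), make_block(f2, 25, 0.05))
  rownames(E3) <- sprintf("k%02d", 1:50)
  part3 <- setNames(rep(1:2, each = 25), rownames(E3))
  merged3 <- merge_close_modules(E3, part3, network_config())
  expect_equal(length(unique(merged3)), 1)

  # after merging no eigengene pair exceeds the cut correlation
  eg <- attr(merged, "eigengenes")
  cc <- cor(t(eg$me))
  expect_true(all(cc[upper.tri(cc)] <= 1 - 0.2))
})

test_that("kME is the gene-eigengene correlation and hubs maximize it", {
  set.seed(11)
  f <- rnorm(20)
  E <- rbind(t(sapply(1:10, function(i) f + rnorm(20, 0, 0.3))),
             matrix(rnorm(5 * 20), 5, 20))
  rownames(E) <- sprintf("g%02d", 1:15)
  part <- setNames(c(rep(1L, 10), rep(0L, 5)), rownames(E))
  eg <- module_eigengenes(E, part)
  km <- module_membership(E, eg, part)

  # gene equal to its ME: kME = 1; orthogonal gene: kME ~ 0
  E2 <- rbind(E, me_copy = eg$me[1, ])
  km2 <- module_membership(E2, eg)
  expect_equal(unname(km2$kme["me_copy", "ME1"]), 1, tolerance = 1e-10)

  ortho <- residuals(lm(rnorm(20) ~ eg$me[1, ]))
  E3 <- rbind(E, ortho = ortho)
  km3 <- module_membership(E3, eg)
  expect_lt(abs(km3$kme["ortho", "ME1"]), 1e-10)

  # hub gene attains the maximal own-module kME
  members <- names(part)[part == 1]
  expect_equal(unname(km$hubs["ME1"]),
               members[which.max(km$kme[members, "ME1"])])

  # kME > 0.5 membership filter equals the brute-force filter
  sel <- rownames(E)[km$kme[, "ME1"] > 0.5]
  expect_setequal(sel, rownames(E)[which(cor(t(E), eg$me[1, ]) > 0.5)])
})
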