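two_block_fixture <- function(seed = 5) {
  simulate_bulk_coexpression_dataset(
    n_samples = 60,
    modules = list(list(size = 25, within_correlation = 0.9),
                   list(size = 20, within_correlation = 0.9)),
    n_noise_genes = 30, trait_coupling = 0.8, seed = seed)
}

test_that("adjacency follows |S|^beta and TOM matches its closed forms", {
  # a_ij = |-0.5|^3 = 0.125 checked through a two-gene construction
  v <- rbind(c(1, 2, 3, 4, 5), c(5.2, 4, 3.1, 2, 0.9)) + 10
  em <- expression_matrix(v, c("g1", "g2"), paste0("s", 1:5),
                          layer = "normalized")
  m <- build_adjacency_tom(em, 3)
  expect_equal(m$A[1, 2], abs(m$S[1, 2])^3)
  S <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(abs(-0.5)^3, 0.125)

  # three perfectly correlated genes: TOM = 1 everywhere
  base <- abs(rnorm(10)) + 1
  v3 <- rbind(base, 2 * base, 0.5 * base + 1)
  em3 <- expression_matrix(v3, paste0("g", 1:3), paste0("s", 1:10),
                           layer = "normalized")
  m3 <- build_adjacency_tom(em3, 6)
  expect_equal(unname(m3$TOM), matrix(1, 3, 3))

  # genes uncorrelated with everything have TOM ~ 0 off-diagonal
  set.seed(47)
  v0 <- matrix(abs(rnorm(4 * 200, 5)), 4)
  em0 <- expression_matrix(v0, paste0("g", 1:4), paste0("s", 1:200),
                           layer = "normalized")
  m0 <- build_adjacency_tom(em0, 8)
  off <- m0$TOM[upper.tri(m0$TOM)]
  expect_lt(max(off), 0.05)
})

test_that("TOM is symmetric, bounded in [0,1], and beta-monotone", {
  set.seed(53)
  for (i in 1:100) {
    n_g <- sample(5:15, 1)
    n_s <- sample(8:20, 1)
    em <- random_em(n_g, n_s)
    m <- build_adjacency_tom(em, sample(1:10, 1))
    expect_lt(max(abs(m$TOM - t(m$TOM))), 1e-12)
    expect_lt(max(abs(m$A - t(m$A))), 1e-12)
    expect_true(all(m$TOM >= -1e-12 & m$TOM <= 1 + 1e-12))
    expect_true(all(m$A >= 0 & m$A <= 1))
  }
  em <- random_em(10, 12, seed = 59)
  a3 <- build_adjacency_tom(em, 3)$A
  a5 <- build_adjacency_tom(em, 5)$A
  off <- upper.tri(a3)
  expect_true(all(a5[off] <= a3[off] + 1e-14))
})

test_that("constant genes are dropped with a warning before correlation", {
  v <- rbind(matrix(abs(rnorm(40, 5)), 4), rep(2, 10))
  em <- expression_matrix(v, paste0("g", 1:5), paste0("s", 1:10),
                          layer = "normalized")
  expect_warning(m <- build_adjacency_tom(em, 2), "constant")
  expect_equal(length(m$gene_ids), 4L)
  expect_equal(m$dropped_genes, "g5")
})

test_that("soft threshold picking prefers the smallest adequate power", {
  set.seed(12)
  n <- 100; G <- 400
  w <- (runif(G) * 0.98 + 0.01)^(1 / 0.8)  # heavy-tailed factor loadings
  lam <- sqrt(w)
  X <- 6 + lam %o% rnorm(n) + sqrt(1 - lam^2) * matrix(rnorm(G * n), G)
  em <- expression_matrix(pmax(X, 0), sprintf("g%03d", 1:G),
                          sprintf("s%03d", 1:n), layer = "normalized")
  ps <- pick_soft_threshold(em, 1:12)
  expect_true(ps$reached_target)
  row <- ps$table[ps$table$power == ps$beta, ]
  expect_gte(row$r_squared, 0.8)
  expect_lt(row$slope, 0)       # decaying degree distribution
  expect_equal(ps$beta, 3)      # measured once at this seed

  # unreachable target falls back to the best fit
  ps2 <- pick_soft_threshold(em, c(3, 6), r2_target = 1.01)
  expect_false(ps2$reached_target)
  expect_true(ps2$beta %in% c(3, 6))
  # single candidate is returned as-is
  expect_equal(pick_soft_threshold(em, 7)$beta, 7)
})

test_that("degenerate connectivity reports a zero scale-free fit", {
  expect_equal(scale_free_fit(rep(3, 50))$r_squared, 0)
  expect_equal(scale_free_fit(numeric(0))$r_squared, 0)
})

test_that("planted two-block structure is recovered as two modules", {
  skip_if_not_installed("mclust")
  b <- two_block_fixture()
  model <- build_adjacency_tom(b$matrix, 6)
  model <- detect_modules(model, cut_height = 0.8, min_size = 5)
  found <- setdiff(unique(model$modules), "grey")
  expect_equal(length(found), 2L)
  keep <- b$truth$modules != "noise"
  ari <- mclust::adjustedRandIndex(model$modules[keep],
                                   b$truth$modules[keep])
  expect_gte(ari, 0.9)   # measured 1.0 at this seed
  # labels are assigned by decreasing size
  sizes <- table(model$modules)
  expect_gte(sizes[["turquoise"]], sizes[["blue"]])
})

test_that("tree-cut edge cases go grey", {
  em <- random_em(1, 10, seed = 61)
  model <- build_adjacency_tom(
    expression_matrix(rbind(em$values, em$values[1, ] * 0 + abs(rnorm(10))),
                      c("g1", "g2"), em$column_ids, layer = "normalized"), 2)
  out <- suppressWarnings(detect_modules(model, min_size = 5))
  expect_true(all(out$modules == "grey"))

  b <- two_block_fixture()
  model2 <- build_adjacency_tom(b$matrix, 6)
  out2 <- suppressWarnings(detect_modules(model2, cut_height = 0,
                                          min_size = 2))
  expect_true(all(out2$modules == "grey"))  # every gene its own cluster
})

test_that("eigengenes behave as signed first principal components", {
  # identical genes: eigengene equals each gene's z-score
  base <- abs(rnorm(12)) + 2
  v <- rbind(base, base, base)
  em <- expression_matrix(v, paste0("g", 1:3), paste0("s", 1:12),
                          layer = "normalized")
  model <- build_adjacency_tom(em, 2)
  model$modules <- stats::setNames(rep("turquoise", 3), model$gene_ids)
  model <- module_eigengenes(model)
  z <- as.numeric(scale(base))
  expect_equal(unname(model$eigengenes[, "turquoise"]), z, tolerance = 1e-10)
  expect_equal(attr(model$eigengenes, "var_explained")[["turquoise"]], 1)

  # flipping the module's values flips the eigengene
  b <- two_block_fixture()
  m1 <- detect_modules(build_adjacency_tom(b$matrix, 6))
  m1 <- module_eigengenes(m1)
  flipped <- b$matrix
  genes_t <- names(m1$modules)[m1$modules == "turquoise"]
  flipped$values[genes_t, ] <- max(flipped$values) -
    flipped$values[genes_t, ]
  m2 <- build_adjacency_tom(flipped, 6)
  m2$modules <- m1$modules
  m2 <- module_eigengenes(m2)
  expect_equal(unname(m2$eigengenes[, "turquoise"]),
               -unname(m1$eigengenes[, "turquoise"]), tolerance = 1e-8)

  # strong module: PC1 explains most variance (factor-model closed form)
  expect_gte(attr(m1$eigengenes, "var_explained")[["turquoise"]], 0.8)
})

test_that("module-trait correlation uses the exact t transform", {
  b <- two_block_fixture()
  model <- module_eigengenes(detect_modules(build_adjacency_tom(b$matrix, 6)))
  model <- module_trait_correlation(model, b$trait)
  mt <- model$module_trait
  # independent cross-check per module
  for (i in seq_len(nrow(mt))) {
    ref <- cor.test(model$eigengenes[, mt$module[i]], b$trait)
    expect_equal(mt$r[i], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mt$p[i], ref$p.value, tolerance = 1e-10)
  }
  # trait identical to an eigengene: r = 1, p ~ 0
  self <- module_trait_correlation(model$eigengenes,
                                   model$eigengenes[, 1])
  expect_equal(self$r[1], 1)
  expect_equal(self$p[1], 0)
  # r = 0.58 at n = 600 reproduces the t-formula p
  r <- 0.58; n <- 600
  p_formula <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  x <- rnorm(n)
  expect_equal(p_formula, 2 * pt(-abs(r / sqrt((1 - r^2) / (n - 2))), n - 2))
  expect_error(module_trait_correlation(model$eigengenes, rep(1, 60)),
               "zero variance")
})

test_that("trait correlation p-values are uniform under the null", {
  set.seed(67)
  n <- 100
  ps <- replicate(500, {
    eg <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "m"))
    module_trait_correlation(eg, rnorm(n))$p
  })
  expect_gte(mean(ps < 0.05), 0.035)
  expect_lte(mean(ps < 0.05), 0.065)
})
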