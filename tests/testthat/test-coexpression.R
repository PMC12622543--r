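test_that("adjacency is the soft-thresholded absolute correlation", {
  set.seed(14)
  x <- rnorm(50)
  expr <- cbind(g1 = x, g2 = x + rnorm(50, 0, 1e-8), g3 = rnorm(50))
  rownames(expr) <- sprintf("A%02d", 1:50)
  A <- adjacency_matrix(expr, beta = 6)
  expect_equal(A["g1", "g2"], 1, tolerance = 1e-6)
  A1 <- adjacency_matrix(expr, beta = 1)
  expect_equal(unname(A1), unname(abs(cor(expr))), tolerance = 1e-12)
  # r = 0.5 at beta = 6 gives 0.5^6 = 0.015625 (checked on an exact pair)
  n <- 16
  a <- scale(rnorm(n))[, 1]
  b <- scale(rnorm(n))[, 1]
  b <- scale(stats::residuals(lm(b ~ a)))[, 1]
  y <- 0.5 * a + sqrt(0.75) * b   # cor(a, y) = 0.5 exactly
  e2 <- cbind(g1 = a, g2 = y)
  rownames(e2) <- sprintf("A%02d", 1:n)
  expect_equal(adjacency_matrix(e2, 6)["g1", "g2"], 0.015625,
               tolerance = 1e-10)
  expect_error(adjacency_matrix(expr, beta = 0), "positive")
  expect_error(adjacency_matrix(cbind(expr, flat = rep(1, 50))), "flat")
})

test_that("TOM matches the closed forms and the brute-force oracle", {
  # 2 genes: TOM12 = a
  for (a in c(0.2, 0.7)) {
    A <- matrix(c(1, a, a, 1), 2)
    expect_equal(tom_similarity(A)[1, 2], a, tolerance = 1e-12)
  }
  # 3 genes, all a = 1: TOM = 1 everywhere
  A3 <- matrix(1, 3, 3)
  expect_true(all(abs(tom_similarity(A3) - 1) < 1e-12))
  # random adjacencies vs triple-loop oracle
  set.seed(15)
  for (n in c(5, 12, 20)) {
    R <- matrix(runif(n * n), n)
    A <- (R + t(R)) / 2
    diag(A) <- 1
    tom <- tom_similarity(A)
    expect_lt(max(abs(tom - tom_oracle(A))), 1e-12)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-14)
  }
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
})

test_that("planted modules are recovered with high purity", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 1,
                    n_variants_per_chrom = 50, chrom_length_bp = 1e7,
                    n_genes = 300, n_modules = 3, module_size = 50,
                    n_planted_eqtl = 0, n_trans_hotspots = 0,
                    transcriptome_subset_fraction = 1, seed = 67)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  A <- adjacency_matrix(ex$expression)
  assign <- detect_modules(tom_similarity(A))
  truth <- ex$truth$modules[assign$gene_id]
  found <- setdiff(unique(assign$module), "unassigned")
  expect_equal(length(found), 3)
  for (m in found) {
    members <- truth[assign$module == m]
    expect_gte(max(table(members)) / length(members), 0.9)
  }
  # gene-order invariance
  perm <- sample(ncol(ex$expression))
  A2 <- adjacency_matrix(ex$expression[, perm])
  assign2 <- detect_modules(tom_similarity(A2))
  merged <- merge(assign, assign2, by = "gene_id")
  expect_true(all(table(merged$module.x, merged$module.y) %in%
                    c(0, table(assign$module))))
  # affine per-gene rescaling leaves modules unchanged
  sc <- sweep(sweep(ex$expression, 2, runif(300, 0.5, 3), "*"),
              2, rnorm(300), "+")
  assign3 <- detect_modules(tom_similarity(adjacency_matrix(sc)))
  expect_equal(assign3$module, assign$module)
})

test_that("independent genes yield no module at the default cut", {
  set.seed(16)
  expr <- matrix(rnorm(100 * 100), 100, 100,
                 dimnames = list(sprintf("A%03d", 1:100),
                                 sprintf("g%03d", 1:100)))
  assign <- detect_modules(tom_similarity(adjacency_matrix(expr)))
  expect_true(all(assign$module == "unassigned"))
})

test_that("duplicated genes are always co-assigned", {
  cfg <- small_config(seed = 71, transcriptome_subset_fraction = 1)
  ex <- simulate_expression(simulate_genotypes(cfg), cfg)
  expr <- cbind(ex$expression, dup_gene = ex$expression[, 1])
  assign <- detect_modules(tom_similarity(adjacency_matrix(expr)))
  expect_equal(assign$module[assign$gene_id == "dup_gene"],
               assign$module[assign$gene_id == colnames(ex$expression)[1]])
})

test_that("eigengene matches the rank-1 and 2-gene closed forms", {
  set.seed(17)
  prof <- scale(rnorm(60))[, 1]
  expr <- matrix(rep(prof, 4), 60, 4,
                 dimnames = list(sprintf("A%02d", 1:60),
                                 paste0("g", 1:4)))
  expr <- sweep(expr, 2, c(1, 2, 3, 4), "*")  # same profile, scaled
  me <- module_eigengene(expr, paste0("g", 1:4))
  expect_equal(me$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$eigengene, prof)), 1, tolerance = 1e-12)
  expect_gte(mean(cor(me$eigengene, scale(expr))), 0)
  # sign equivariance with the orientation rule
  me_neg <- module_eigengene(-expr, paste0("g", 1:4))
  expect_equal(me_neg$eigengene, -me$eigengene, tolerance = 1e-10)
  # 2-gene module: variance explained = (1 + |r|) / 2
  x1 <- scale(rnorm(80))[, 1]
  x2 <- scale(0.6 * x1 + rnorm(80))[, 1]
  e2 <- cbind(a = x1, b = x2)
  rownames(e2) <- sprintf("A%02d", 1:80)
  r <- abs(cor(x1, x2))
  expect_equal(module_eigengene(e2, c("a", "b"))$var_explained,
               (1 + r) / 2, tolerance = 1e-10)
})

test_that("module-trait correlation flags planted drivers, not nulls", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 1,
                    n_variants_per_chrom = 50, chrom_length_bp = 1e7,
                    n_genes = 150, n_modules = 3, module_size = 40,
                    n_planted_eqtl = 0, n_trans_hotspots = 0,
                    transcriptome_subset_fraction = 1, seed = 73)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  assign <- detect_modules(tom_similarity(adjacency_matrix(ex$expression)))
  eg <- module_eigengenes(ex$expression, assign)
  # trait driven by module M1's latent factor
  set.seed(1)
  tr <- ex$module_factors[, 1] + rnorm(cfg$n_accessions, 0, 0.7)
  targets <- cbind(trait = tr)
  rownames(targets) <- rownames(ex$expression)
  mt <- module_trait_correlation(eg$eigengenes, targets, alpha = 0.01)
  driven <- mt$module[order(mt$p)][1]
  expect_true(mt$significant[mt$module == driven])
  # identity: a target equal to an eigengene correlates at r = 1
  targets2 <- cbind(self = eg$eigengenes[, 1])
  mt2 <- module_trait_correlation(eg$eigengenes, targets2)
  expect_equal(mt2$r[mt2$module == colnames(eg$eigengenes)[1]], 1,
               tolerance = 1e-12)
  # null targets flag at about the alpha rate
  set.seed(2)
  nulls <- matrix(rnorm(nrow(ex$expression) * 200), ncol = 200,
                  dimnames = list(rownames(ex$expression),
                                  sprintf("n%03d", 1:200)))
  mtn <- module_trait_correlation(eg$eigengenes, nulls, alpha = 0.05)
  expect_lt(mean(mtn$significant), 0.12)
})
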