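test_that("MAF filter applies the strict > rule on allele counts", {
  D <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 1), c(0, 2, 0))
  colnames(D) <- c("mono", "common", "rare")
  g <- toy_genotypes(D)
  # alt freq for "common" = 5/8, MAF = 0.375: kept; monomorphic removed
  kept <- maf_filter(g, 0.05)$map$variant_id
  expect_true("common" %in% kept)
  expect_false("mono" %in% kept)
  # boundary: MAF exactly at threshold is removed
  D2 <- matrix(c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0), ncol = 1,
               dimnames = list(NULL, "edge"))  # f = 0.1 at n = 10
  g2 <- toy_genotypes(D2)
  expect_equal(ncol(maf_filter(g2, 0.10)$dosage), 0)
  expect_equal(ncol(maf_filter(g2, 0.0999)$dosage), 1)
})

test_that("kinship matches the brute-force oracle and its symmetries", {
  set.seed(2)
  D <- matrix(sample(c(0L, 1L, 2L), 50 * 500, replace = TRUE), 50, 500)
  D[sample(length(D), 100)] <- NA
  g <- toy_genotypes(D)
  K <- compute_kinship(g)
  expect_lt(max(abs(K - kinship_oracle(D))), 1e-10)
  # duplicate accessions: off-diagonal equals the shared diagonal
  D2 <- rbind(D[1, ], D[1, ], D[2:10, ])
  rownames(D2) <- sprintf("ACC%03d", 1:11)
  K2 <- compute_kinship(toy_genotypes(D2))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  # permutation equivariance
  perm <- sample(nrow(D))
  Kp <- compute_kinship(toy_genotypes(D[perm, ]))
  expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-12)
})

test_that("null REML fit recovers heritability and maximizes the objective", {
  set.seed(5)
  cfg <- sim_config(n_accessions = 300, n_chromosomes = 2,
                    n_variants_per_chrom = 400, chrom_length_bp = 4e7,
                    missing_rate = 0, seed = 41)
  g <- simulate_genotypes(cfg)
  gf <- maf_filter(g)
  K <- compute_kinship(gf)
  eig <- kinship_eigen(K)
  # y with true h2 = 0.5 under K
  h2s <- replicate(20, {
    L <- eig$vectors %*% diag(sqrt(eig$values))
    gval <- L %*% rnorm(nrow(K))
    y <- sqrt(0.5) * gval / sd(gval) + rnorm(nrow(K)) * sqrt(0.5)
    fit_null_lmm(stats::setNames(y, rownames(K)), K, eig = eig)$h2
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.1)
  # i.i.d. y: boundary estimate near zero
  h2null <- replicate(10, fit_null_lmm(
    stats::setNames(rnorm(nrow(K)), rownames(K)), K, eig = eig)$h2)
  expect_lt(median(h2null), 0.1)
  # optimizer contract: the returned optimum beats every grid point
  y <- stats::setNames(rnorm(nrow(K)), rownames(K))
  nf <- fit_null_lmm(y, K, eig = eig)
  Xs <- crossprod(eig$vectors, matrix(1, nrow(K)))
  ys <- crossprod(eig$vectors, y)
  lds <- determinant(crossprod(matrix(1, nrow(K))), TRUE)$modulus
  grid_ll <- sapply(seq(log(1e-5), log(1e5), length.out = 61),
                    mqtlnet:::reml_ll, ys = ys, Xs = Xs,
                    lambda = eig$values, XtX_logdet = lds)
  expect_gte(nf$loglik, max(grid_ll) - 1e-8)
  expect_error(fit_null_lmm(stats::setNames(rep(1, nrow(K)),
                                            rownames(K)), K), "constant")
})

test_that("LMM with identity kinship reproduces OLS exactly", {
  set.seed(6)
  cfg <- sim_config(n_accessions = 120, n_chromosomes = 1,
                    n_variants_per_chrom = 300, chrom_length_bp = 3e7,
                    missing_rate = 0.01, seed = 43)
  g <- simulate_genotypes(cfg)
  gf <- maf_filter(g)
  y <- stats::setNames(rnorm(120), g$accessions)
  KI <- diag(120); dimnames(KI) <- list(g$accessions, g$accessions)
  scan <- lmm_scan(y, gf, KI)
  D <- mqtlnet:::impute_dosage(gf$dosage)
  for (j in sample(nrow(scan), 25)) {
    fit <- summary(lm(y ~ D[, scan$variant_id[j]]))$coefficients
    expect_lt(abs(log10(scan$p[j]) - log10(fit[2, 4])), 1e-6)
    expect_equal(scan$beta[j], fit[2, 1], tolerance = 1e-8)
  }
})

test_that("scan handles duplicated variants and permuted phenotypes", {
  set.seed(7)
  cfg <- small_config(seed = 47, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  gf <- maf_filter(g)
  # duplicated variant column: identical statistics
  gd <- gf
  gd$dosage <- cbind(gf$dosage, dup = gf$dosage[, 1])
  gd$map <- rbind(gf$map, within(gf$map[1, ], {
    variant_id <- "dup"; pos <- pos + 1L
  })[, names(gf$map)])
  colnames(gd$dosage)[ncol(gd$dosage)] <- "dup"
  K <- compute_kinship(gf)
  y <- stats::setNames(rnorm(cfg$n_accessions), g$accessions)
  sc <- lmm_scan(y, gd, K)
  a <- sc[sc$variant_id == gf$map$variant_id[1], c("beta", "se", "p")]
  b <- sc[sc$variant_id == "dup", c("beta", "se", "p")]
  expect_equal(unname(unlist(a)), unname(unlist(b)), tolerance = 1e-12)
  # permuting y breaks genotype linkage: p approximately uniform
  yp <- stats::setNames(sample(y), names(y))
  scp <- lmm_scan(yp, gf, K)
  expect_gt(stats::ks.test(scp$p, "punif")$p.value, 0.01)
})

test_that("scan is invariant under simultaneous accession permutation", {
  cfg <- small_config(seed = 53, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  gf <- maf_filter(g)
  K <- compute_kinship(gf)
  y <- stats::setNames(rnorm(cfg$n_accessions), g$accessions)
  s1 <- lmm_scan(y, gf, K)
  perm <- sample(g$accessions)
  g2 <- gf
  g2$dosage <- gf$dosage[perm, ]
  g2$accessions <- perm
  s2 <- lmm_scan(y[perm], g2, K[perm, perm])
  # eigendecomposition of the permuted kinship takes a different numeric
  # path; agreement is to floating-point accuracy, not bitwise
  expect_equal(s1$p, s2$p, tolerance = 1e-5)
})

test_that("OLS scan slope, significance and degenerate cases", {
  set.seed(9)
  n <- 100
  y <- rnorm(n)
  P <- cbind(self = y, neg = -y, noise = rnorm(n), flat = rep(1, n))
  rownames(P) <- sprintf("A%03d", 1:n)
  res <- ols_scan(stats::setNames(y, rownames(P)), P)
  expect_equal(res$beta[res$predictor == "self"], 1, tolerance = 1e-12)
  expect_lt(res$p[res$predictor == "self"], 1e-200)
  expect_equal(res$beta[res$predictor == "neg"], -1, tolerance = 1e-12)
  expect_false("flat" %in% res$predictor)  # constant predictor skipped
  # null predictors give uniform p at n = 274
  P2 <- matrix(rnorm(274 * 300), 274, 300,
               dimnames = list(sprintf("A%03d", 1:274), NULL))
  colnames(P2) <- sprintf("g%03d", 1:300)
  y2 <- stats::setNames(rnorm(274), rownames(P2))
  res2 <- ols_scan(y2, P2)
  expect_gt(stats::ks.test(res2$p, "punif")$p.value, 0.01)
})

test_that("significance threshold is the reciprocal of the test count", {
  expect_equal(significance_threshold(1), 1)
  expect_equal(signif(significance_threshold(8274830), 2), 1.2e-7)
  expect_equal(signif(significance_threshold(70781), 3), 1.41e-5)
  expect_equal(significance_threshold(100, "bonferroni05"), 5e-4)
  expect_error(significance_threshold(0), "positive")
})
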