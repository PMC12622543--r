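test_that("configuration invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(target_h2 = 1.2), "target_h2")
  expect_error(sim_config(n_variants_per_chrom = 100, chrom_length_bp = 50),
               "more variants")
  expect_error(sim_config(n_marker_metabolites = 99, n_metabolites = 10),
               "exceeds")
  expect_error(sim_config(n_genes = 100, n_modules = 4, module_size = 30,
                          n_planted_eqtl = 0, n_trans_hotspots = 0),
               "exceed")
})

test_that("genotype simulation is deterministic and respects its contract", {
  cfg <- small_config(seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  expect_true(all(g1$dosage %in% c(0L, 2L) | is.na(g1$dosage)))
  for (ch in unique(g1$map$chrom))
    expect_true(all(diff(g1$map$pos[g1$map$chrom == ch]) > 0))
  # degenerate MAF range: every variant generated at frequency one half
  cfg5 <- small_config(seed = 6, maf_range = c(0.5, 0.5),
                       mutation_rate = 0)
  g5 <- simulate_genotypes(cfg5)
  maf <- apply(g5$dosage, 2, function(d) {
    f <- mean(d, na.rm = TRUE) / 2; min(f, 1 - f)
  })
  # binomial tolerance: freq of a block founder at n = 150, sd ~ 0.04
  expect_gt(mean(maf), 0.5 - 3 * sqrt(0.25 / cfg5$n_accessions))
})

test_that("within-block LD exceeds between-block LD", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 2,
                    n_variants_per_chrom = 1000, chrom_length_bp = 2e7,
                    missing_rate = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  map <- g$map
  block <- paste(map$chrom, (map$pos - 1) %/% cfg$ld_block_bp)
  r2_within <- c(); r2_between <- c()
  set.seed(1)
  for (rep in 1:500) {
    i <- sample(ncol(g$dosage), 2)
    if (sd(g$dosage[, i[1]]) == 0 || sd(g$dosage[, i[2]]) == 0) next
    r2 <- cor(g$dosage[, i[1]], g$dosage[, i[2]])^2
    if (block[i[1]] == block[i[2]]) r2_within <- c(r2_within, r2)
    else r2_between <- c(r2_between, r2)
  }
  blocks <- split(seq_len(ncol(g$dosage)), block)
  blocks <- blocks[lengths(blocks) >= 2]
  for (b in blocks[1:200]) {
    i <- b[1:2]
    if (sd(g$dosage[, i[1]]) > 0 && sd(g$dosage[, i[2]]) > 0)
      r2_within <- c(r2_within, cor(g$dosage[, i[1]], g$dosage[, i[2]])^2)
  }
  expect_gt(mean(r2_within), mean(r2_between))
})

test_that("metabolome heritability and planted-variant effects are realized", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 2,
                    n_variants_per_chrom = 200, chrom_length_bp = 2e7,
                    n_metabolites = 30, n_marker_metabolites = 10,
                    n_planted_mqtl = 5, target_h2 = 0.67,
                    n_replicates = 6, n_years = 2,
                    effect_size_range = c(0.45, 0.55), seed = 21)
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  h2 <- estimate_heritability(met$replicates)
  expect_lt(abs(mean(h2$H2) - 0.67), 0.05)
  # planted variant at ~0.5 variance fraction: r^2 with accession means
  pm <- met$truth$planted_mqtls
  means2y <- (met$years[[1]] + met$years[[2]]) / 2
  for (i in seq_len(nrow(pm))) {
    z <- g$dosage[, pm$variant_id[i]]
    z[is.na(z)] <- mean(z, na.rm = TRUE)
    r2 <- cor(z, means2y[, pm$metabolite[i]])^2
    expect_lt(abs(r2 - pm$variance_fraction[i]), 0.12)
  }
  # causal variants clear the downstream MAF filter
  kept <- maf_filter(g)$map$variant_id
  expect_true(all(pm$variant_id %in% kept))
})

test_that("zero replicate noise gives heritability one", {
  cfg <- small_config(seed = 3, target_h2 = 1)
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  h2 <- estimate_heritability(met$replicates)
  expect_true(all(h2$H2 > 0.99))
})

test_that("expression has planted module structure and a subcohort", {
  cfg <- small_config(seed = 13)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  expect_equal(nrow(ex$expression),
               round(cfg$transcriptome_subset_fraction * cfg$n_accessions))
  mods <- ex$truth$modules
  m1 <- names(mods)[mods == "M1"]
  m2 <- names(mods)[mods == "M2"]
  C <- abs(cor(ex$expression))
  within <- c(C[m1, m1][upper.tri(C[m1, m1])],
              C[m2, m2][upper.tri(C[m2, m2])])
  between <- as.vector(C[m1, m2])
  expect_gt(mean(within), mean(between))
  # cis eQTLs land within the cis window of their gene
  eq <- ex$truth$planted_eqtls
  cis <- eq[eq$type == "cis", ]
  gm <- ex$gene_map[match(cis$gene_id, ex$gene_map$gene_id), ]
  vm <- g$map[match(cis$variant_id, g$map$variant_id), ]
  expect_true(all(gm$chrom == vm$chrom &
                    abs(vm$pos - gm$start) <= cfg$cis_window))
})

test_that("null expression gives uniform per-variant association p-values", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 2,
                    n_variants_per_chrom = 500, chrom_length_bp = 1e8,
                    n_genes = 30, n_modules = 1, module_size = 5,
                    n_planted_eqtl = 0, n_trans_hotspots = 0,
                    transcriptome_subset_fraction = 1, missing_rate = 0,
                    seed = 31)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  gf <- maf_filter(g)
  K <- compute_kinship(gf)
  # non-module genes carry no genetic signal: their scans are null
  free <- names(ex$truth$modules)[ex$truth$modules == "unassigned"][1:5]
  res <- lmm_scan_many(ex$expression[, free, drop = FALSE], gf, K)
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("trait construction respects planted marker signs", {
  cfg <- small_config(seed = 17)
  co <- simulate_cohort(cfg)
  mk <- co$truth$marker_metabolites
  for (t in 1:cfg$n_years) {
    tr <- co$trait$years[[t]]
    for (i in seq_len(nrow(mk))) {
      r <- cor(tr, co$metabolome$years[[t]][names(tr), mk$metabolite[i]])
      expect_equal(sign(r), mk$sign[i])
    }
  }
  # non-marker metabolite p-values are uniform across a null batch
  cfg0 <- small_config(seed = 19, n_metabolites = 200,
                       n_marker_metabolites = 5, n_planted_mqtl = 0)
  co0 <- simulate_cohort(cfg0)
  nulls <- setdiff(colnames(co0$metabolome$years[[1]]),
                   co0$truth$marker_metabolites$metabolite)
  tr <- co0$trait$years[[1]]
  ps <- sapply(nulls, function(m)
    cor.test(tr, co0$metabolome$years[[1]][names(tr), m])$p.value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("noise-free single-marker trait correlates perfectly", {
  cfg <- small_config(seed = 23, n_marker_metabolites = 1,
                      negative_marker_fraction = 0, target_h2 = 1,
                      n_planted_mqtl = 0, n_planted_triples = 0)
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  tr <- simulate_trait(met, cfg)
  r <- cor(tr$genetic_value,
           met$genetic_values[names(tr$genetic_value), "met001"])
  expect_equal(r, 1, tolerance = 1e-12)
})
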