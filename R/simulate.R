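#' Simulation configuration for the synthetic multi-omics cohort
#'
#' Builds and validates the parameter set controlling every stage of the
#' synthetic cohort generator.  Defaults emulate a rapeseed inbred-line
#' association panel: ~388 accessions scored over two years with six
#' replicates, metabolites with mean broad-sense heritability around 0.67,
#' a developing-seed transcriptome available for roughly 71% of the panel,
#' biallelic SNPs filtered at MAF > 5% with block-wise linkage
#' disequilibrium, and planted metabolite/expression QTLs of known effect.
#'
#' @param n_accessions number of inbred accessions.
#' @param n_chromosomes number of chromosomes.
#' @param n_variants_per_chrom SNPs per chromosome.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param maf_range length-2 numeric, range of founder allele frequencies in
#'   (0, 0.5]; every variant's generating minor-allele frequency is drawn
#'   from this interval.
#' @param ld_block_bp width of an LD block in bp; variants within one block
#'   are copies-with-mutation of a shared founder haplotype, variants in
#'   different blocks are independent.
#' @param mutation_rate per-accession flip probability used by the
#'   copy-with-mutation LD scheme (controls within-block r^2).
#' @param missing_rate fraction of genotype calls set to missing.
#' @param n_metabolites,n_marker_metabolites total metabolites and how many
#'   of them drive the trait (markers).
#' @param negative_marker_fraction fraction of markers with a negative trait
#'   weight.
#' @param target_h2 target broad-sense heritability of metabolites (and the
#'   trait), as the fraction of accession-level variance.
#' @param n_years,n_replicates study years and replicates per accession-year.
#' @param n_genes,n_modules,module_size transcriptome size and planted
#'   co-expression module layout.
#' @param n_planted_mqtl,n_planted_eqtl planted causal variants for
#'   metabolites and (cis) gene expression.
#' @param n_trans_hotspots,trans_hotspot_size trans-eQTL hotspots: each
#'   hotspot is one variant loading this many genes.
#' @param effect_size_range range of planted-effect variance fractions.
#' @param transcriptome_subset_fraction fraction of accessions carrying
#'   expression data (the transcriptome subcohort).
#' @param n_planted_triples metabolite-variant-gene triples in which a cis
#'   gene drives a metabolite that also maps to the same causal variant.
#' @param cis_window bp window defining a cis relationship.
#' @param seed integer seed; a fixed config (including seed) reproduces the
#'   cohort byte-for-byte.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_accessions = 388,
                       n_chromosomes = 2,
                       n_variants_per_chrom = 500,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.08, 0.5),
                       ld_block_bp = 1e5,
                       mutation_rate = 0.06,
                       missing_rate = 0.01,
                       n_metabolites = 60,
                       n_marker_metabolites = 20,
                       negative_marker_fraction = 1 / 3,
                       target_h2 = 0.67,
                       n_years = 2,
                       n_replicates = 6,
                       n_genes = 300,
                       n_modules = 3,
                       module_size = 50,
                       n_planted_mqtl = 10,
                       n_planted_eqtl = 10,
                       n_trans_hotspots = 1,
                       trans_hotspot_size = 120,
                       effect_size_range = c(0.08, 0.3),
                       transcriptome_subset_fraction = 274 / 388,
                       n_planted_triples = 1,
                       cis_window = 1e6,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_accessions", "n_chromosomes", "n_variants_per_chrom",
              "chrom_length_bp", "n_metabolites", "n_years", "n_replicates",
              "n_genes", "ld_block_bp")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1)
      stop("sim_config: '", nm, "' must be a positive count", call. = FALSE)
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("sim_config: maf_range must be an increasing pair in (0, 0.5]",
         call. = FALSE)
  for (nm in c("target_h2", "transcriptome_subset_fraction", "missing_rate",
               "negative_marker_fraction", "mutation_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("sim_config: '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (length(effect_size_range) != 2L || any(effect_size_range <= 0) ||
      any(effect_size_range >= 1) || effect_size_range[1] > effect_size_range[2])
    stop("sim_config: effect_size_range must be an increasing pair in (0, 1)",
         call. = FALSE)
  if (n_variants_per_chrom > chrom_length_bp)
    stop("sim_config: more variants than base pairs on a chromosome",
         call. = FALSE)
  if (n_marker_metabolites > n_metabolites)
    stop("sim_config: n_marker_metabolites exceeds n_metabolites",
         call. = FALSE)
  if (n_modules * module_size +
      n_planted_eqtl + n_trans_hotspots * trans_hotspot_size > n_genes)
    stop("sim_config: module, cis-eQTL and trans-hotspot gene allocations ",
         "exceed n_genes", call. = FALSE)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a block-LD genotype matrix of inbred accessions
#'
#' Chromosomes are tiled into fixed \code{ld_block_bp} windows.  Each block
#' draws a founder binary haplotype at a frequency sampled from
#' \code{maf_range}; every variant in the block copies the founder with
#' per-accession mutation probability \code{mutation_rate}, so within-block
#' r^2 is high and between-block variants are independent.  Accessions are
#' inbred: dosages are 0 or 2 (missing calls are NA at
#' \code{missing_rate}).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{genotype_matrix}: list with \code{dosage} (accession x
#'   variant matrix), \code{map} (data.frame variant_id, chrom, pos, ref,
#'   alt) and \code{accessions}.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  acc <- sprintf("ACC%04d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  dosage_cols <- vector("list", config$n_chromosomes)
  maps <- vector("list", config$n_chromosomes)
  for (chr in seq_len(config$n_chromosomes)) {
    m <- config$n_variants_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp, m, replace = FALSE))
    block <- (pos - 1L) %/% config$ld_block_bp
    X <- matrix(0L, nrow = n, ncol = m)
    for (b in unique(block)) {
      idx <- which(block == b)
      p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      founder <- stats::rbinom(n, 1L, p)
      for (j in idx) {
        flip <- stats::rbinom(n, 1L, config$mutation_rate)
        X[, j] <- ifelse(flip == 1L, 1L - founder, founder)
      }
    }
    D <- 2L * X
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      D[miss] <- NA_integer_
    }
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    maps[[chr]] <- data.frame(
      variant_id = sprintf("chr%02d_%09d", chr, pos),
      chrom = sprintf("chr%02d", chr),
      pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE, row.names = NULL)
    dosage_cols[[chr]] <- D
  }
  dosage <- do.call(cbind, dosage_cols)
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  dimnames(dosage) <- list(acc, map$variant_id)
  structure(list(dosage = dosage, map = map, accessions = acc),
            class = "genotype_matrix")
}

# empirical alt-allele frequencies and MAF of a dosage matrix
variant_maf <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

# standardize a dosage vector after mean imputation
std_dosage <- function(z) {
  z[is.na(z)] <- mean(z, na.rm = TRUE)
  s <- stats::sd(z)
  if (s == 0) return(rep(0, length(z)))
  (z - mean(z)) / s
}

#' Simulate the two-year replicated metabolome
#'
#' Each metabolite's accession-level genetic value is a standardized mix of
#' planted causal-variant effects and an independent polygenic accession
#' effect, scaled so the broad-sense heritability of the replicate-level
#' values matches \code{target_h2}.  Observed values add a shared year shift
#' and replicate noise.  Values are Gaussian on a log-like abundance scale.
#'
#' @param genotypes output of \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @param driver_signals optional accession x k matrix of external signals
#'   (e.g. latent gene expression) with column names naming the target
#'   metabolites; each target metabolite's genetic value gains a component
#'   proportional to its signal (used to plant metabolite-gene links).
#' @return list with \code{years} (list of accession x metabolite mean
#'   matrices, one per year), \code{replicates} (long data.frame accession,
#'   metabolite, year, replicate, value), \code{genetic_values} (accession x
#'   metabolite), and \code{truth} (planted mQTLs and marker designations).
#' @export
simulate_metabolome <- function(genotypes, config, driver_signals = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(genotypes$accessions)
  nm <- config$n_metabolites
  met_ids <- sprintf("met%03d", seq_len(nm))
  h2 <- config$target_h2

  # candidate causal variants must clear the downstream MAF > 5% filter
  maf <- variant_maf(genotypes$dosage)
  eligible <- which(maf > 0.10)
  n_q <- min(config$n_planted_mqtl, nm)
  causal <- if (n_q > 0) sample(eligible, n_q) else integer(0)
  frac <- stats::runif(n_q, config$effect_size_range[1],
                       config$effect_size_range[2])
  sgn <- sample(c(-1, 1), n_q, replace = TRUE)
  if (sum(frac) >= length(frac) && n_q > 0)  # per-metabolite: one effect each
    stop("planted effect variance fractions must each be < 1", call. = FALSE)

  G <- matrix(0, n, nm, dimnames = list(genotypes$accessions, met_ids))
  planted <- data.frame(metabolite = character(0), variant_id = character(0),
                        variance_fraction = numeric(0), sign = numeric(0))
  for (j in seq_len(nm)) {
    poly <- scale(stats::rnorm(n))[, 1]
    g <- poly
    if (j <= n_q) {
      z <- std_dosage(genotypes$dosage[, causal[j]])
      g <- sgn[j] * sqrt(frac[j]) * z + sqrt(1 - frac[j]) * poly
      planted <- rbind(planted, data.frame(
        metabolite = met_ids[j],
        variant_id = colnames(genotypes$dosage)[causal[j]],
        variance_fraction = frac[j], sign = sgn[j]))
    }
    if (!is.null(driver_signals) && met_ids[j] %in% colnames(driver_signals)) {
      d <- scale(driver_signals[genotypes$accessions, met_ids[j]])[, 1]
      g <- sqrt(0.5) * scale(g)[, 1] + sqrt(0.5) * d
    }
    G[, j] <- scale(g)[, 1] * sqrt(h2)
  }

  sd_year <- sqrt(0.005 * (1 - h2))
  sd_rep <- sqrt(0.995 * (1 - h2))
  reps <- vector("list", config$n_years)
  year_means <- vector("list", config$n_years)
  for (t in seq_len(config$n_years)) {
    yshift <- stats::rnorm(nm, 0, sd_year)
    per_rep <- vector("list", config$n_replicates)
    acc_sum <- matrix(0, n, nm)
    for (r in seq_len(config$n_replicates)) {
      noise <- matrix(stats::rnorm(n * nm, 0, sd_rep), n, nm)
      vals <- G + matrix(yshift, n, nm, byrow = TRUE) + noise
      acc_sum <- acc_sum + vals
      per_rep[[r]] <- data.frame(
        accession = rep(genotypes$accessions, nm),
        metabolite = rep(met_ids, each = n),
        year = t, replicate = r,
        value = as.vector(vals), stringsAsFactors = FALSE)
    }
    ym <- acc_sum / config$n_replicates
    dimnames(ym) <- list(genotypes$accessions, met_ids)
    year_means[[t]] <- ym
    reps[[t]] <- do.call(rbind, per_rep)
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL

  marker_ids <- met_ids[seq_len(config$n_marker_metabolites)]
  n_neg <- round(config$negative_marker_fraction *
                 config$n_marker_metabolites)
  marker_sign <- c(rep(-1, n_neg),
                   rep(1, config$n_marker_metabolites - n_neg))
  truth <- list(
    planted_mqtls = planted,
    marker_metabolites = data.frame(metabolite = marker_ids,
                                    sign = marker_sign,
                                    stringsAsFactors = FALSE))
  list(years = year_means, replicates = replicates,
       genetic_values = G, truth = truth)
}

#' Simulate the developing-seed transcriptome with planted structure
#'
#' Genes are laid along the simulated chromosomes.  Module genes share a
#' latent accession factor (high within-module correlation); planted cis
#' genes load on a variant within \code{cis_window} of the gene; each trans
#' hotspot is a single variant loading \code{trans_hotspot_size} genes.
#' Expression is reported only for the transcriptome subcohort, sampled
#' uniformly with the run seed.
#'
#' @inheritParams simulate_metabolome
#' @return list with \code{expression} (subcohort accession x gene matrix),
#'   \code{gene_map} (gene_id, chrom, start, end, strand), \code{subcohort},
#'   \code{latent} (full-cohort noise-free gene signals, for planting
#'   cross-omic links), \code{module_factors} (full-cohort accession x
#'   module latent factors) and \code{truth} (planted eQTLs, module map).
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (config$n_modules * config$module_size > config$n_genes)
    stop("module_size x n_modules exceeds n_genes", call. = FALSE)
  n <- length(genotypes$accessions)
  ng <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  chrom <- sample(sprintf("chr%02d", seq_len(config$n_chromosomes)), ng,
                  replace = TRUE)
  start <- sapply(chrom, function(ch)
    sample.int(config$chrom_length_bp - 3000L, 1L))
  gene_map <- data.frame(gene_id = gene_ids, chrom = chrom,
                         start = as.integer(start),
                         end = as.integer(start + 3000L),
                         strand = sample(c("+", "-"), ng, replace = TRUE),
                         stringsAsFactors = FALSE, row.names = NULL)

  maf <- variant_maf(genotypes$dosage)
  eligible <- which(maf > 0.10)

  # gene allocation: modules first, then cis genes, then trans-hotspot genes
  k_mod <- config$n_modules * config$module_size
  module_of <- rep("unassigned", ng)
  module_of[seq_len(k_mod)] <- rep(sprintf("M%d", seq_len(config$n_modules)),
                                   each = config$module_size)
  cis_genes <- k_mod + seq_len(config$n_planted_eqtl)
  trans_genes <- if (config$n_trans_hotspots > 0)
    k_mod + config$n_planted_eqtl +
      seq_len(config$n_trans_hotspots * config$trans_hotspot_size)
  else integer(0)

  factors <- matrix(stats::rnorm(n * config$n_modules), n, config$n_modules,
                    dimnames = list(genotypes$accessions,
                                    sprintf("M%d", seq_len(config$n_modules))))
  latent <- matrix(stats::rnorm(n * ng), n, ng,
                   dimnames = list(genotypes$accessions, gene_ids))
  eqtls <- data.frame(gene_id = character(0), variant_id = character(0),
                      type = character(0), variance_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  for (g in seq_len(k_mod)) {
    m <- (g - 1L) %/% config$module_size + 1L
    latent[, g] <- factors[, m] + 0.5 * latent[, g]
  }
  for (g in cis_genes) {
    same <- which(genotypes$map$chrom == gene_map$chrom[g] &
                  abs(genotypes$map$pos - gene_map$start[g]) <=
                    config$cis_window)
    same <- intersect(same, eligible)
    if (length(same) == 0) same <- eligible  # fallback: nearest eligible
    v <- same[which.min(abs(genotypes$map$pos[same] - gene_map$start[g]))]
    f <- stats::runif(1, config$effect_size_range[1],
                      config$effect_size_range[2])
    z <- std_dosage(genotypes$dosage[, v])
    latent[, g] <- sqrt(f) * z + sqrt(1 - f) * scale(latent[, g])[, 1]
    eqtls <- rbind(eqtls, data.frame(
      gene_id = gene_ids[g], variant_id = colnames(genotypes$dosage)[v],
      type = "cis", variance_fraction = f, stringsAsFactors = FALSE))
  }
  if (length(trans_genes) > 0) {
    hot_v <- sample(eligible, config$n_trans_hotspots)
    for (h in seq_len(config$n_trans_hotspots)) {
      z <- std_dosage(genotypes$dosage[, hot_v[h]])
      gg <- trans_genes[((h - 1L) * config$trans_hotspot_size + 1L):
                          (h * config$trans_hotspot_size)]
      f <- stats::runif(length(gg), max(config$effect_size_range[1], 0.12),
                        config$effect_size_range[2])
      for (k in seq_along(gg)) {
        g <- gg[k]
        latent[, g] <- sqrt(f[k]) * z +
          sqrt(1 - f[k]) * scale(latent[, g])[, 1]
        eqtls <- rbind(eqtls, data.frame(
          gene_id = gene_ids[g],
          variant_id = colnames(genotypes$dosage)[hot_v[h]],
          type = "trans", variance_fraction = f[k], stringsAsFactors = FALSE))
      }
    }
  }
  latent <- scale(latent)
  sub_n <- round(config$transcriptome_subset_fraction * n)
  subcohort <- sort(sample(genotypes$accessions, sub_n))
  expr <- latent[subcohort, , drop = FALSE] +
    matrix(stats::rnorm(sub_n * ng, 0, 0.3), sub_n, ng)
  truth <- list(planted_eqtls = eqtls,
                modules = stats::setNames(module_of, gene_ids))
  list(expression = expr, gene_map = gene_map, subcohort = subcohort,
       latent = latent, module_factors = factors, truth = truth)
}

#' Simulate the replicated trait from marker-metabolite genetic values
#'
#' The trait's accession-level genetic value is a signed, equally weighted
#' sum of the designated marker metabolites' genetic values (signs recorded
#' in the ground truth), rescaled to \code{target_h2} of the phenotypic
#' variance; observations add year shifts and replicate noise mirroring the
#' metabolome design.
#'
#' @param metabolome output of \code{\link{simulate_metabolome}}.
#' @param config the shared \code{\link{sim_config}}.
#' @return list with \code{replicates} (long accession, year, replicate,
#'   value), \code{years} (list of per-year accession mean vectors),
#'   \code{genetic_value}, and \code{truth$marker_metabolites}.
#' @export
simulate_trait <- function(metabolome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  mk <- metabolome$truth$marker_metabolites
  if (nrow(mk) > ncol(metabolome$genetic_values))
    stop("more marker metabolites than metabolites", call. = FALSE)
  gm <- metabolome$genetic_values[, mk$metabolite, drop = FALSE]
  g <- as.vector(gm %*% mk$sign)
  g <- scale(g)[, 1] * sqrt(config$target_h2)
  acc <- rownames(metabolome$genetic_values)
  n <- length(acc)
  sd_year <- sqrt(0.005 * (1 - config$target_h2))
  sd_rep <- sqrt(0.995 * (1 - config$target_h2))
  reps <- vector("list", config$n_years)
  years <- vector("list", config$n_years)
  for (t in seq_len(config$n_years)) {
    yshift <- stats::rnorm(1, 0, sd_year)
    vals <- matrix(g, n, config$n_replicates) + yshift +
      matrix(stats::rnorm(n * config$n_replicates, 0, sd_rep), n,
             config$n_replicates)
    years[[t]] <- stats::setNames(rowMeans(vals), acc)
    reps[[t]] <- data.frame(accession = rep(acc, config$n_replicates),
                            year = t,
                            replicate = rep(seq_len(config$n_replicates),
                                            each = n),
                            value = as.vector(vals), stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  list(replicates = replicates, years = years,
       genetic_value = stats::setNames(g, acc),
       truth = list(marker_metabolites = mk))
}

#' Simulate the full multi-omics cohort
#'
#' Runs the genotype, expression, metabolome and trait generators in order
#' and plants \code{n_planted_triples} metabolite-variant-gene triples: a
#' cis gene whose latent expression drives a marker metabolite that also
#' maps to the gene's causal variant, so the downstream ternary network
#' should recover a closed triangle.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes}, \code{expression}, \code{metabolome},
#'   \code{trait} and merged \code{truth} (including \code{triples}).
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  expr <- simulate_expression(geno, config)
  drivers <- NULL
  triples <- NULL
  n_tri <- min(config$n_planted_triples, config$n_planted_eqtl,
               config$n_marker_metabolites)
  if (n_tri > 0 && nrow(expr$truth$planted_eqtls) > 0) {
    cis <- expr$truth$planted_eqtls[expr$truth$planted_eqtls$type == "cis", ]
    cis <- cis[seq_len(min(n_tri, nrow(cis))), , drop = FALSE]
    # target the last marker metabolites, beyond those carrying their own mQTL
    targets <- rev(sprintf("met%03d",
                           seq_len(config$n_marker_metabolites)))[
                             seq_len(nrow(cis))]
    drivers <- expr$latent[, cis$gene_id, drop = FALSE]
    colnames(drivers) <- targets
    triples <- data.frame(metabolite = targets, gene_id = cis$gene_id,
                          variant_id = cis$variant_id,
                          stringsAsFactors = FALSE)
  }
  metab <- simulate_metabolome(geno, config, driver_signals = drivers)
  if (!is.null(triples)) {
    # the driven metabolite inherits half the gene's cis signal; record it
    cis_f <- expr$truth$planted_eqtls[
      match(triples$gene_id, expr$truth$planted_eqtls$gene_id),
      "variance_fraction"]
    metab$truth$planted_mqtls <- rbind(
      metab$truth$planted_mqtls,
      data.frame(metabolite = triples$metabolite,
                 variant_id = triples$variant_id,
                 variance_fraction = 0.5 * cis_f, sign = 1))
  }
  trait <- simulate_trait(metab, config)
  truth <- c(metab$truth, expr$truth["planted_eqtls"],
             list(modules = expr$truth$modules, triples = triples))
  list(genotypes = geno, expression = expr, metabolome = metab,
       trait = trait, truth = truth, config = config)
}
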