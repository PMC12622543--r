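# Shared fixtures built in code.

# small cohort config used by several module tests
small_config <- function(seed = 1, ...) {
  defaults <- list(n_accessions = 150, n_chromosomes = 2,
                   n_variants_per_chrom = 150, chrom_length_bp = 3e7,
                   n_metabolites = 12, n_marker_metabolites = 5,
                   n_planted_mqtl = 3, n_genes = 120, n_modules = 2,
                   module_size = 30, n_planted_eqtl = 3,
                   n_trans_hotspots = 1, trans_hotspot_size = 20,
                   transcriptome_subset_fraction = 0.8, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# genotype_matrix built directly from a dosage matrix (variants as columns)
toy_genotypes <- function(dosage, chrom = "chr01", pos = NULL,
                          ref = NULL, alt = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%03d", seq_len(m))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ACC%03d", seq_len(nrow(dosage)))
  structure(list(
    dosage = dosage,
    map = data.frame(variant_id = colnames(dosage),
                     chrom = rep(chrom, length.out = m), pos = pos,
                     ref = ref, alt = alt, stringsAsFactors = FALSE),
    accessions = rownames(dosage)), class = "genotype_matrix")
}

# hand-computed tripartite fixture: one metabolite (met1) with an mQTL at
# [1000, 2000], one gene (gA) with an eQTL whose distance to the mQTL is
# controlled by `gap_start`, and a significant mTWAS pair met1-gA
toy_network_inputs <- function(gap_start = 42000) {
  mq <- data.frame(kind = "mQTL", trait = "met1", block_id = "mQTL0001",
                   chrom = "chr01", start = 1000L, end = 2000L,
                   n_members = 2L, members = "v001,v002",
                   lead_variant = "v001", lead_p = 1e-8,
                   stringsAsFactors = FALSE)
  eq <- data.frame(kind = "eQTL", trait = "gA", block_id = "eQTL0001",
                   chrom = "chr01", start = gap_start,
                   end = gap_start + 10000L, n_members = 1L,
                   members = "v050", lead_variant = "v050", lead_p = 1e-9,
                   stringsAsFactors = FALSE)
  mt <- data.frame(trait = "met1", predictor = "gA", beta = 1.2, se = 0.1,
                   p = 1e-7, n = 100L, stringsAsFactors = FALSE)
  list(markers = "met1", mqtls = mq, eqtls = eq, mtwas = mt)
}

# brute-force TOM oracle: triple loop over the definition
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    tom[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# brute-force kinship oracle: double loop over accession pairs
kinship_oracle <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  D <- dosage
  idx <- which(is.na(D), arr.ind = TRUE)
  if (nrow(idx) > 0) D[idx] <- mu[idx[, 2]]
  sds <- apply(D, 2, sd)
  Z <- scale(D[, sds > 0, drop = FALSE])
  n <- nrow(Z); m <- ncol(Z)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sum(Z[i, ] * Z[j, ]) / m
  dimnames(K) <- list(rownames(dosage), rownames(dosage))
  K
}
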