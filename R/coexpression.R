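#' Soft-thresholded co-expression adjacency
#'
#' Unsigned weighted-network adjacency a_ij = |cor(x_i, x_j)|^beta with
#' unit diagonal.  beta = 6 follows the scale-free soft-thresholding power
#' used throughout the analysis.
#'
#' @param expr accession x gene matrix; zero-variance genes must be removed
#'   first (they are detected and rejected here).
#' @param beta soft-thresholding power (> 0, default 6).
#' @return gene x gene adjacency matrix in [0, 1].
#' @export
adjacency_matrix <- function(expr, beta = 6) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (nrow(expr) < 3 || ncol(expr) < 2)
    stop("need >= 3 accessions and >= 2 genes", call. = FALSE)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "), call. = FALSE)
  A <- abs(stats::cor(expr))^beta
  diag(A) <- 1
  A
}

#' Topological overlap from an adjacency matrix
#'
#' Unsigned TOM: TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij), with connectivity k_i = sum_{u != i} a_iu
#' and TOM_ii = 1.  Computed with matrix products; the numerator equals
#' (A^2)_ij - a_ii a_ij - a_ij a_jj + a_ij = (A^2)_ij - a_ij for a
#' unit-diagonal A.
#'
#' @param A symmetric adjacency with entries in [0, 1] and unit diagonal.
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tom_similarity <- function(A) {
  if (max(abs(A - t(A))) > 1e-10)
    stop("adjacency must be symmetric", call. = FALSE)
  if (min(A) < -1e-12 || max(A) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  k <- rowSums(A) - diag(A)
  num <- A %*% A - A          # sum_{u != i,j} a_iu a_uj + a_ij
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - A)
  tom <- (tom + t(tom)) / 2   # symmetrize numeric noise
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by static tree cut on TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of 1 - TOM, cut at a fixed
#' dissimilarity height; clusters below the minimum size fall into the
#' "unassigned" pool.  Module labels M1, M2, ... are assigned by
#' decreasing module size (ties by smallest member gene id), so the
#' result is independent of gene input order.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param min_module_size smallest gene count kept as a module (default 30).
#' @param cut_height dissimilarity cut (default 0.99).
#' @return data.frame: gene_id, module ("unassigned" for the pool).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  genes <- colnames(tom)
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  if (length(keep) == 0) {
    module <- rep("unassigned", length(genes))
  } else {
    first_gene <- vapply(keep, function(k) min(genes[cl == k]), character(1))
    ord <- keep[order(-sizes[keep], first_gene)]
    lab <- stats::setNames(sprintf("M%d", seq_along(ord)), ord)
    module <- ifelse(as.character(cl) %in% keep,
                     lab[as.character(cl)], "unassigned")
  }
  if (length(unique(cl)) == 1L)
    message("all genes fall in a single cluster at height ", cut_height)
  data.frame(gene_id = genes, module = unname(module),
             stringsAsFactors = FALSE)
}

#' Module eigengene (first principal component of member expression)
#'
#' The eigengene is the first PC of the standardized member-gene
#' submatrix, rescaled to unit variance and sign-oriented so that its mean
#' correlation with member expression is non-negative.
#'
#' @param expr accession x gene expression matrix.
#' @param genes member gene ids (>= 2).
#' @return list: eigengene (named vector, unit variance), var_explained.
#' @export
module_eigengene <- function(expr, genes) {
  if (length(genes) < 2) stop("a module needs >= 2 genes", call. = FALSE)
  if (nrow(expr) < 3) stop("need >= 3 accessions", call. = FALSE)
  X <- scale(expr[, genes, drop = FALSE])
  s <- svd(X, nu = 1, nv = 0)
  e <- s$u[, 1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(e, X)) < 0) e <- -e
  list(eigengene = stats::setNames(e, rownames(expr)),
       var_explained = s$d[1]^2 / sum(s$d^2))
}

#' Eigengenes for every detected module
#'
#' @param expr accession x gene matrix.
#' @param assignments \code{\link{detect_modules}} output.
#' @return list: eigengenes (accession x module matrix), var_explained.
#' @export
module_eigengenes <- function(expr, assignments) {
  mods <- setdiff(unique(assignments$module), "unassigned")
  mods <- mods[order(mods)]
  ev <- numeric(0)
  E <- NULL
  for (m in mods) {
    g <- assignments$gene_id[assignments$module == m]
    me <- module_eigengene(expr, g)
    E <- cbind(E, me$eigengene)
    ev <- c(ev, me$var_explained)
  }
  if (is.null(E))
    return(list(eigengenes = matrix(numeric(0), nrow(expr), 0,
                                    dimnames = list(rownames(expr), NULL)),
                var_explained = ev))
  dimnames(E) <- list(rownames(expr), mods)
  list(eigengenes = E, var_explained = stats::setNames(ev, mods))
}

#' Correlate module eigengenes with traits and metabolites
#'
#' Pearson correlation with two-sided t-test per (module, target) pair on
#' shared accessions; a pair is flagged significant iff p < alpha.
#'
#' @param eigengenes accession x module matrix.
#' @param targets accession x target matrix (traits and/or metabolites).
#' @param alpha significance level (default 0.01).
#' @return data.frame: module, target, r, p, n, significant.
#' @export
module_trait_correlation <- function(eigengenes, targets, alpha = 0.01) {
  shared <- intersect(rownames(eigengenes), rownames(targets))
  if (length(shared) < 3) stop("fewer than 3 shared accessions",
                               call. = FALSE)
  E <- eigengenes[shared, , drop = FALSE]
  targets <- as.matrix(targets)[shared, , drop = FALSE]
  out <- list()
  for (m in colnames(E)) {
    if (stats::sd(E[, m]) == 0)
      stop("constant eigengene '", m, "'", call. = FALSE)
    for (tg in colnames(targets)) {
      ok <- stats::complete.cases(E[, m], targets[, tg])
      ct <- stats::cor.test(E[ok, m], targets[ok, tg])
      out[[length(out) + 1L]] <- data.frame(
        module = m, target = tg, r = unname(ct$estimate), p = ct$p.value,
        n = sum(ok), significant = ct$p.value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
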