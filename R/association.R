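#' Filter variants by minor allele frequency
#'
#' Keeps a variant iff min(f, 1-f) > threshold, with f the alt-allele
#' frequency over non-missing dosages (strict inequality, matching a
#' "MAF > 5%" panel filter).  All-missing variants are removed with a
#' warning.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param threshold MAF threshold (default 0.05).
#' @return the filtered \code{genotype_matrix}.
#' @export
maf_filter <- function(genotypes, threshold = 0.05) {
  D <- genotypes$dosage
  nmiss <- colSums(!is.na(D))
  if (any(nmiss == 0))
    warning(sum(nmiss == 0), " variant(s) with all dosages missing removed")
  maf <- variant_maf(D)
  keep <- !is.na(maf) & maf > threshold & nmiss > 0
  genotypes$dosage <- D[, keep, drop = FALSE]
  genotypes$map <- genotypes$map[keep, , drop = FALSE]
  rownames(genotypes$map) <- NULL
  genotypes
}

# mean-impute missing dosages, column-wise
impute_dosage <- function(D) {
  if (!anyNA(D)) return(D)
  mu <- colMeans(D, na.rm = TRUE)
  idx <- which(is.na(D), arr.ind = TRUE)
  D[idx] <- mu[idx[, 2]]
  D
}

#' Centered-and-scaled genomic relationship matrix
#'
#' VanRaden-style kinship K = Z Z' / m from mean-imputed, per-variant
#' standardized dosages Z over m polymorphic variants.  Used as the
#' random-effect covariance of the mixed-model scans.
#'
#' @param genotypes a \code{genotype_matrix} (ideally MAF-filtered).
#' @return accession x accession kinship matrix.
#' @export
compute_kinship <- function(genotypes) {
  D <- impute_dosage(genotypes$dosage)
  if (nrow(D) < 2) stop("kinship needs at least 2 accessions", call. = FALSE)
  sds <- apply(D, 2, stats::sd)
  Z <- scale(D[, sds > 0, drop = FALSE])
  if (ncol(Z) < 2)
    stop("kinship needs at least 2 polymorphic variants", call. = FALSE)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(D), rownames(D))
  K
}

#' Eigendecomposition of a kinship matrix (cached spectral step)
#'
#' @param K symmetric kinship matrix.
#' @return list(values, vectors) with tiny negative eigenvalues clipped to 0.
#' @export
kinship_eigen <- function(K) {
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kinship matrix is not symmetric", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  if (min(e$values) < -1e-4 * max(abs(e$values)))
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         signif(min(e$values), 3), ")", call. = FALSE)
  e$values <- pmax(e$values, 0)
  e
}

# negative restricted log-likelihood profile in delta = sigma2_e / sigma2_g,
# in the rotated coordinates (single spectral decomposition)
reml_ll <- function(log_delta, ys, Xs, lambda, XtX_logdet) {
  delta <- exp(log_delta)
  w <- lambda + delta
  n <- length(ys)
  p <- ncol(Xs)
  Xw <- Xs / w
  A <- crossprod(Xs, Xw)                       # X' W^-1 X
  b <- crossprod(Xw, ys)
  beta <- solve(A, b)
  r <- ys - Xs %*% beta
  rss <- sum(r^2 / w)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(w)) +
            determinant(A, logarithm = TRUE)$modulus - XtX_logdet)
}

#' Fit the null linear mixed model by REML
#'
#' y = X beta + g + e with g ~ N(0, sigma2_g K) and e ~ N(0, sigma2_e I).
#' K is eigendecomposed once; the restricted likelihood is profiled to a
#' 1-D search over log(delta), delta = sigma2_e / sigma2_g, on a coarse
#' grid refined by bounded optimization.
#'
#' @param y named numeric vector of accession phenotypes.
#' @param K kinship matrix (rows/cols named by accession).
#' @param covariates optional accession x q matrix; an intercept is always
#'   included.
#' @param eig optional precomputed \code{\link{kinship_eigen}} of the
#'   aligned K (reused across phenotypes on the same panel).
#' @return list: delta, sigma2_g, sigma2_e, h2, loglik, eig (rotation),
#'   accessions, X (covariate design).
#' @export
fit_null_lmm <- function(y, K, covariates = NULL, eig = NULL) {
  if (is.null(eig)) y <- y[!is.na(y)]
  acc <- intersect(names(y), rownames(K))
  if (length(acc) < 3) stop("too few accessions shared with K", call. = FALSE)
  y <- y[acc]
  if (stats::sd(y) == 0) stop("phenotype is constant", call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, length(acc)))
  if (!is.null(covariates)) X <- cbind(X, covariates[acc, , drop = FALSE])
  if (is.null(eig)) eig <- kinship_eigen(K[acc, acc])
  U <- eig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  XtX_logdet <- determinant(crossprod(X), logarithm = TRUE)$modulus
  grid <- seq(log(1e-5), log(1e5), length.out = 61)
  ll <- vapply(grid, reml_ll, numeric(1), ys = ys, Xs = Xs,
               lambda = eig$values, XtX_logdet = XtX_logdet)
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, ys = ys,
                         Xs = Xs, lambda = eig$values,
                         XtX_logdet = XtX_logdet, tol = 1e-8)
  if (opt$objective >= ll[i]) {
    log_delta <- opt$maximum; ll_max <- opt$objective
  } else {
    log_delta <- grid[i]; ll_max <- ll[i]
  }
  delta <- exp(log_delta)
  w <- eig$values + delta
  Xw <- Xs / w
  A <- crossprod(Xs, Xw)
  beta <- solve(A, crossprod(Xw, ys))
  rss <- sum((ys - Xs %*% beta)^2 / w)
  s2g <- rss / (length(ys) - ncol(Xs))
  list(delta = delta, sigma2_g = s2g, sigma2_e = delta * s2g,
       h2 = 1 / (1 + delta), loglik = ll_max, eig = eig, accessions = acc,
       X = X, y = y)
}

#' Single-variant mixed-model association scan
#'
#' Generalized-least-squares effect and two-sided Wald p-value per variant
#' in the rotated coordinates, with the variance ratio delta fixed from the
#' null fit (the standard population-parameters-previously-determined
#' approximation).  With K = I the scan reduces exactly to per-variant OLS.
#'
#' @param y named phenotype vector (or NULL if \code{null_fit} given).
#' @param genotypes a \code{genotype_matrix}.
#' @param K kinship matrix; ignored when \code{null_fit} is supplied.
#' @param covariates optional covariate matrix.
#' @param null_fit optional \code{\link{fit_null_lmm}} result to reuse.
#' @param trait_id label written into the result (default "trait").
#' @return data.frame: trait, variant_id, chrom, pos, beta, se, p.  Variants
#'   constant after imputation are skipped (attribute "skipped").
#' @export
lmm_scan <- function(y = NULL, genotypes, K = NULL, covariates = NULL,
                     null_fit = NULL, trait_id = "trait") {
  if (is.null(null_fit)) null_fit <- fit_null_lmm(y, K, covariates)
  acc <- null_fit$accessions
  D <- impute_dosage(genotypes$dosage[acc, , drop = FALSE])
  U <- null_fit$eig$vectors
  Gs <- crossprod(U, D)
  ok <- apply(D, 2, stats::sd) > 0
  scan_core(null_fit, Gs, ok, genotypes$map, trait_id)
}

# Wald scan in rotated coordinates given a null fit and rotated dosages
scan_core <- function(null_fit, Gs, ok, map, trait_id) {
  U <- null_fit$eig$vectors
  w <- null_fit$eig$values + null_fit$delta
  ys <- crossprod(U, null_fit$y)
  Xs <- crossprod(U, null_fit$X)
  n <- length(null_fit$accessions)
  p0 <- ncol(Xs)
  if (p0 == 1L) {
    # fast closed form for the intercept-only design
    v <- 1 / w
    a <- Xs[, 1]
    A11 <- sum(v * a * a)
    r1 <- sum(v * a * ys)
    Sy <- sum(v * ys^2)
    A12 <- colSums(v * a * Gs)
    A22 <- colSums(v * Gs^2)
    r2 <- colSums(v * ys[, 1] * Gs)
    det <- A11 * A22 - A12^2
    beta2 <- (A11 * r2 - A12 * r1) / det
    beta1 <- (A22 * r1 - A12 * r2) / det
    rss <- Sy - beta1 * r1 - beta2 * r2
    s2 <- rss / (n - 2)
    se <- sqrt(s2 * A11 / det)
    tstat <- beta2 / se
    pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
    res <- data.frame(beta = beta2, se = se, p = pval)
  } else {
    res <- as.data.frame(t(vapply(seq_len(ncol(Gs)), function(j) {
      Xj <- cbind(Xs, Gs[, j])
      fit <- stats::lm.wfit(Xj, ys[, 1], 1 / w)
      cf <- fit$coefficients[p0 + 1L]
      XtWX <- crossprod(Xj / w, Xj)
      s2 <- sum(fit$residuals^2 / w) / (n - p0 - 1L)
      se <- sqrt(s2 * solve(XtWX)[p0 + 1L, p0 + 1L])
      tt <- cf / se
      c(cf, se, 2 * stats::pt(-abs(tt), df = n - p0 - 1L))
    }, numeric(3))))
    names(res) <- c("beta", "se", "p")
  }
  out <- data.frame(trait = trait_id,
                    variant_id = colnames(Gs),
                    chrom = map$chrom,
                    pos = map$pos,
                    res, stringsAsFactors = FALSE, row.names = NULL)
  skipped <- out$variant_id[!ok]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "null_fit") <- null_fit[c("delta", "sigma2_g", "sigma2_e",
                                      "h2", "loglik")]
  out
}

#' Mixed-model scans for many phenotypes on one panel
#'
#' Eigendecomposes the kinship once and rotates the dosage matrix once,
#' then fits the null model and runs the Wald scan per phenotype column.
#' This is the work-horse for mGWAS over many metabolites and eGWAS over
#' many genes.
#'
#' @param Y accession x phenotype matrix (rownames = accession ids).
#' @param genotypes a \code{genotype_matrix}.
#' @param K kinship matrix.
#' @param trait_prefix optional prefix prepended to column names in the
#'   output trait column (default "" = use column names as-is).
#' @return one data.frame of stacked \code{\link{lmm_scan}} results.
#' @export
lmm_scan_many <- function(Y, genotypes, K, trait_prefix = "") {
  acc <- intersect(rownames(Y), rownames(K))
  if (length(acc) < 3) stop("too few shared accessions", call. = FALSE)
  Ksub <- K[acc, acc]
  eig <- kinship_eigen(Ksub)
  D <- impute_dosage(genotypes$dosage[acc, , drop = FALSE])
  Gs <- crossprod(eig$vectors, D)
  ok <- apply(D, 2, stats::sd) > 0
  res <- lapply(colnames(Y), function(ph) {
    y <- stats::setNames(Y[acc, ph], acc)
    nf <- fit_null_lmm(y, Ksub, eig = eig)
    scan_core(nf, Gs, ok, genotypes$map, paste0(trait_prefix, ph))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-predictor ordinary least-squares scan (mTWAS)
#'
#' Simple linear regression of the target on each predictor column over
#' pairwise-complete accessions; slope, standard error and two-sided
#' t-test p-value (df = n - 2).  Constant predictors are skipped.
#'
#' @param target named numeric vector (e.g. a metabolite's accession means).
#' @param predictors accession x predictor matrix (e.g. gene expression).
#' @param target_id label for the output.
#' @return data.frame: trait, predictor, beta, se, p, n.
#' @export
ols_scan <- function(target, predictors, target_id = "trait") {
  shared <- intersect(names(target), rownames(predictors))
  if (length(shared) < 3)
    stop("fewer than 3 shared accessions", call. = FALSE)
  yv <- target[shared]
  M <- predictors[shared, , drop = FALSE]
  res <- lapply(colnames(M), function(j) {
    x <- M[, j]
    ok <- stats::complete.cases(yv, x)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0) return(NULL)
    xx <- x[ok] - mean(x[ok]); yy <- yv[ok] - mean(yv[ok])
    sxx <- sum(xx^2)
    b <- sum(xx * yy) / sxx
    rss <- sum((yy - b * xx)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    tt <- if (se == 0) Inf * sign(b) else b / se
    data.frame(trait = target_id, predictor = j, beta = b, se = se,
               p = 2 * stats::pt(-abs(tt), df = n - 2), n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reciprocal-of-tests significance threshold
#'
#' The scan convention used throughout: the genome-wide threshold is
#' 1 / (number of tests), compared strictly (p < threshold).  An
#' alpha-scaled Bonferroni cut (alpha / n) is available via \code{mode}.
#'
#' @param n_tests number of tests (>= 1).
#' @param mode "reciprocal" (default) or "bonferroni05".
#' @return the p-value threshold.
#' @export
significance_threshold <- function(n_tests, mode = c("reciprocal",
                                                     "bonferroni05")) {
  mode <- match.arg(mode)
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count", call. = FALSE)
  if (mode == "reciprocal") 1 / n_tests else 0.05 / n_tests
}
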