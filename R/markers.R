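#' Correlate a trait with every metabolite
#'
#' Pearson correlation (two-sided t-test on n-2 df) between an
#' accession-indexed trait vector and each column of a metabolite matrix,
#' on pairwise-complete accessions.  Constant vectors are flagged rather
#' than reported as zero.
#'
#' @param trait named numeric vector (names are accession ids).
#' @param metabolites accession x metabolite numeric matrix with rownames.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame: metabolite, r, p, n, flag ("" or a reason).
#' @export
correlate_trait <- function(trait, metabolites, method = "pearson") {
  shared <- intersect(names(trait), rownames(metabolites))
  if (length(shared) < 3)
    stop("fewer than 3 shared accessions between trait and metabolites",
         call. = FALSE)
  tr <- trait[shared]
  M <- metabolites[shared, , drop = FALSE]
  out <- lapply(colnames(M), function(j) {
    x <- M[, j]
    ok <- stats::complete.cases(tr, x)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(metabolite = j, r = NA_real_, p = NA_real_, n = n,
                        flag = "too_few_obs"))
    if (stats::sd(tr[ok]) == 0 || stats::sd(x[ok]) == 0)
      return(data.frame(metabolite = j, r = NA_real_, p = NA_real_, n = n,
                        flag = "constant"))
    ct <- stats::cor.test(tr[ok], x[ok], method = method, exact = FALSE)
    data.frame(metabolite = j, r = unname(ct$estimate), p = ct$p.value,
               n = n, flag = "")
  })
  do.call(rbind, out)
}

#' Build two-year marker records
#'
#' Joins per-year correlation tables into one record per metabolite with
#' r/p for each year and the shared sign (0 on disagreement or ties).
#'
#' @param trait_years list of per-year named trait vectors.
#' @param metabolite_years list of per-year accession x metabolite matrices.
#' @param method correlation type passed to \code{\link{correlate_trait}}.
#' @return data.frame: metabolite, r_year1, p_year1, r_year2, p_year2, ...,
#'   sign, flag.
#' @export
marker_records <- function(trait_years, metabolite_years,
                           method = "pearson") {
  if (length(trait_years) != length(metabolite_years))
    stop("trait and metabolite year lists differ in length", call. = FALSE)
  tabs <- lapply(seq_along(trait_years), function(t) {
    ct <- correlate_trait(trait_years[[t]], metabolite_years[[t]], method)
    names(ct)[names(ct) %in% c("r", "p", "n", "flag")] <-
      paste0(c("r", "p", "n", "flag"), "_year", t)
    ct
  })
  rec <- Reduce(function(a, b) merge(a, b, by = "metabolite", all = TRUE),
                tabs)
  rcols <- grep("^r_year", names(rec))
  signs <- sign(as.matrix(rec[, rcols, drop = FALSE]))
  same <- apply(signs, 1, function(s)
    if (anyNA(s) || any(s == 0) || length(unique(s)) > 1) 0 else s[1])
  rec$sign <- same
  fcols <- grep("^flag_year", names(rec))
  rec$flag <- apply(rec[, fcols, drop = FALSE], 1, function(f)
    paste(unique(f[f != "" & !is.na(f)]), collapse = ";"))
  rec[order(rec$metabolite), c(setdiff(names(rec), grep("^flag_year",
                                                        names(rec),
                                                        value = TRUE)))]
}

#' Select trait-marker metabolites by two-year consistent correlation
#'
#' A metabolite is a marker iff its correlation with the trait is
#' significant (p < alpha) in every year and all years agree on a nonzero
#' sign.  The selection is monotone in alpha.
#'
#' @param records output of \code{\link{marker_records}} (a missing year
#'   column is an error naming the metabolite set).
#' @param alpha per-year significance level (default 0.05).
#' @return \code{records} with a logical \code{selected} column; attribute
#'   \code{"partition"} holds the positive/negative marker id lists.
#' @export
select_markers <- function(records, alpha = 0.05) {
  pcols <- grep("^p_year", names(records), value = TRUE)
  if (length(pcols) < 2)
    stop("records must contain p-values for at least two years",
         call. = FALSE)
  P <- as.matrix(records[, pcols, drop = FALSE])
  if (anyNA(P) & any(records$flag == "")) {
    bad <- records$metabolite[apply(P, 1, anyNA) & records$flag == ""]
    if (length(bad) > 0)
      stop("missing year correlation for: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  sig <- apply(P, 1, function(p) all(!is.na(p) & p < alpha))
  records$selected <- sig & records$sign != 0
  attr(records, "partition") <- list(
    positive = records$metabolite[records$selected & records$sign > 0],
    negative = records$metabolite[records$selected & records$sign < 0])
  records
}

#' Broad-sense heritability from replicated observations
#'
#' One-way random-effects decomposition across accessions (years pooled as
#' replicates): H^2 = sigma2_accession / (sigma2_accession + sigma2_residual)
#' with sigma2_accession from the ANOVA expected mean squares
#' (MSB - MSW) / k0, k0 the effective replicate number for unbalanced
#' designs; negative estimates are truncated to 0.
#'
#' @param replicates long data.frame with columns accession, value, and a
#'   grouping column named by \code{by} (default "metabolite"; pass
#'   \code{by = NULL} for a single phenotype).
#' @param by name of the column splitting phenotypes, or NULL.
#' @return data.frame: phenotype id, H2, sigma2_a, sigma2_e, flag.
#' @export
estimate_heritability <- function(replicates, by = "metabolite") {
  one <- function(df, id) {
    df <- df[!is.na(df$value), ]
    ni <- table(df$accession)
    ni <- ni[ni > 0]
    a <- length(ni)
    N <- sum(ni)
    if (a < 2 || all(ni < 2))
      return(data.frame(id = id, H2 = NA_real_, sigma2_a = NA_real_,
                        sigma2_e = NA_real_, flag = "insufficient_replication"))
    mu_i <- tapply(df$value, df$accession, mean)[names(ni)]
    mu <- sum(df$value) / N
    ssb <- sum(ni * (mu_i - mu)^2)
    ssw <- sum((df$value - mu_i[as.character(df$accession)])^2)
    msb <- ssb / (a - 1)
    msw <- ssw / (N - a)
    k0 <- (N - sum(ni^2) / N) / (a - 1)
    s2a <- max((msb - msw) / k0, 0)
    data.frame(id = id, H2 = s2a / (s2a + msw), sigma2_a = s2a,
               sigma2_e = msw, flag = "")
  }
  if (is.null(by)) {
    out <- one(replicates, "phenotype")
  } else {
    out <- do.call(rbind, lapply(split(replicates, replicates[[by]]),
                                 function(d) one(d, d[[by]][1])))
  }
  names(out)[1] <- if (is.null(by)) "phenotype" else by
  rownames(out) <- NULL
  out
}
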