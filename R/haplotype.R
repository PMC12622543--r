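#' Group inbred accessions by haplotype at lead variants
#'
#' Concatenates the allele letter of each homozygous call across the lead
#' variants (dosage 0 -> ref letter, 2 -> alt letter) into a haplotype
#' string such as "TAGA".  Accessions heterozygous or missing at any lead
#' variant are dropped with a reason; groups below \code{min_group} are
#' excluded from testing.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param lead_variants character vector of 1-k variant ids.
#' @param min_group smallest group size kept (default 10).
#' @return list of class \code{haplotype_grouping}: \code{groups} (named
#'   list haplotype -> accession ids), \code{assignments} (accession,
#'   haplotype), \code{dropped} (accession, reason), \code{excluded}
#'   (haplotypes below min_group).
#' @export
group_haplotypes <- function(genotypes, lead_variants, min_group = 10) {
  missing_v <- setdiff(lead_variants, colnames(genotypes$dosage))
  if (length(missing_v) > 0)
    stop("lead variant(s) not in genotype matrix: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  D <- genotypes$dosage[, lead_variants, drop = FALSE]
  map <- genotypes$map[match(lead_variants, genotypes$map$variant_id), ]
  n <- nrow(D)
  hap <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    if (anyNA(d)) { reason[i] <- "missing"; next }
    if (any(d == 1)) { reason[i] <- "het"; next }
    hap[i] <- paste(ifelse(d == 0, map$ref, map$alt), collapse = "")
  }
  kept <- hap != ""
  assignments <- data.frame(accession = rownames(D)[kept],
                            haplotype = hap[kept], stringsAsFactors = FALSE)
  dropped <- data.frame(accession = rownames(D)[!kept],
                        reason = reason[!kept], stringsAsFactors = FALSE)
  groups <- split(assignments$accession, assignments$haplotype)
  small <- names(groups)[lengths(groups) < min_group]
  eligible <- groups[setdiff(names(groups), small)]
  if (length(eligible) == 0)
    stop("insufficient haplotype groups (none reaches min_group = ",
         min_group, ")", call. = FALSE)
  structure(list(lead_variants = lead_variants, groups = eligible,
                 assignments = assignments, dropped = dropped,
                 excluded = small),
            class = "haplotype_grouping")
}

#' Test a phenotype difference between haplotype groups
#'
#' Two eligible groups: Welch two-sample t-test (two-sided); more than two:
#' one-way ANOVA F-test.  Groups with no phenotype overlap are ignored;
#' identical values everywhere give p = 1 by convention.
#'
#' @param grouping a \code{\link{group_haplotypes}} result.
#' @param phenotype named numeric vector of accession values.
#' @return list: method, statistic, p, means (data.frame haplotype, n,
#'   mean).
#' @export
test_haplotype_effect <- function(grouping, phenotype) {
  vals <- lapply(grouping$groups, function(acc) {
    v <- phenotype[intersect(acc, names(phenotype))]
    v[!is.na(v)]
  })
  vals <- vals[lengths(vals) >= 2]
  if (length(vals) < 2)
    stop("need >= 2 haplotype groups with phenotype data", call. = FALSE)
  means <- data.frame(haplotype = names(vals),
                      n = lengths(vals),
                      mean = vapply(vals, mean, numeric(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
  allv <- unlist(vals)
  if (stats::sd(allv) == 0) {
    message("all phenotype values identical across groups; p = 1")
    return(list(method = "degenerate", statistic = 0, p = 1, means = means))
  }
  if (length(vals) == 2L) {
    tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = FALSE)
    list(method = "welch_t", statistic = unname(tt$statistic),
         p = tt$p.value, means = means)
  } else {
    grp <- factor(rep(names(vals), lengths(vals)))
    fit <- stats::oneway.test(allv ~ grp, var.equal = TRUE)
    list(method = "anova_f", statistic = unname(fit$statistic),
         p = fit$p.value, means = means)
  }
}
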