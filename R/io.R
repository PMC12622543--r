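#' Write a matrix as a TSV with an id column
#'
#' @param m matrix with rownames.
#' @param path output file.
#' @param id_col name of the rowname column (default "accession").
#' @export
write_matrix_tsv <- function(m, path, id_col = "accession") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  out <- cbind(dt, data.table::as.data.table(as.data.frame(m)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a TSV matrix written by \code{\link{write_matrix_tsv}}
#'
#' @param path input file.
#' @param id_col id column name (default: first column).
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path, id_col = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  if (is.null(id_col)) id_col <- names(dt)[1]
  ids <- as.character(dt[[id_col]])
  m <- as.matrix(dt[, setdiff(names(dt), id_col), with = FALSE])
  rownames(m) <- ids
  m
}

#' Write a genotype matrix (dosage TSV + variant position TSV)
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param dosage_path,map_path output files.
#' @export
write_genotypes_tsv <- function(genotypes, dosage_path, map_path) {
  write_matrix_tsv(genotypes$dosage, dosage_path)
  data.table::fwrite(genotypes$map, map_path, sep = "\t")
  invisible(dosage_path)
}

#' Read a genotype matrix from dosage + position TSVs
#'
#' @param dosage_path accession x variant dosage TSV (0/1/2, NA missing).
#' @param map_path variant table TSV (variant_id, chrom, pos, ref, alt).
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes_tsv <- function(dosage_path, map_path) {
  dosage <- read_matrix_tsv(dosage_path)
  map <- as.data.frame(data.table::fread(map_path, sep = "\t"))
  bad <- setdiff(colnames(dosage), map$variant_id)
  if (length(bad) > 0)
    stop("variants missing from the position table: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  map <- map[match(colnames(dosage), map$variant_id), ]
  rownames(map) <- NULL
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0/1/2 or missing", call. = FALSE)
  structure(list(dosage = dosage, map = map, accessions = rownames(dosage)),
            class = "genotype_matrix")
}

#' Write genotypes as a minimal VCF (v4.2, GT field, 1-based positions)
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output .vcf file (plain text).
#' @export
write_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mqtlnet",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", genotypes$accessions),
                     collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  D <- genotypes$dosage
  for (j in seq_len(ncol(D))) {
    g <- gt_code[as.character(D[, j])]
    g[is.na(g)] <- "./."
    writeLines(paste(c(genotypes$map$chrom[j], genotypes$map$pos[j],
                       genotypes$map$variant_id[j], genotypes$map$ref[j],
                       genotypes$map$alt[j], ".", "PASS", ".", "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (biallelic SNPs, GT field)
#'
#' Requires the \pkg{vcfR} package.  Heterozygous calls become dosage 1;
#' missing calls NA.
#'
#' @param path VCF file.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- sub("\\|", "/", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           ifelse(x == "0/0", 0L, ifelse(x %in% c("0/1", "1/0"), 1L, 2L)))
  }
  dosage <- t(apply(gt, 1, count_alt))
  dimnames(dosage) <- dimnames(gt)
  fix <- vcfR::getFIX(v)
  map <- data.frame(variant_id = unname(fix[, "ID"]),
                    chrom = unname(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
                    stringsAsFactors = FALSE)
  dosage <- t(dosage)
  colnames(dosage) <- map$variant_id
  structure(list(dosage = dosage, map = map, accessions = rownames(dosage)),
            class = "genotype_matrix")
}

#' Export QTL blocks as BED intervals
#'
#' The 1-based inclusive block intervals are converted to BED's 0-based
#' half-open convention at this writer boundary only.
#'
#' @param blocks \code{\link{cluster_signals}} output.
#' @param path output .bed file.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$chrom, start = blocks$start - 1L,
                    end = blocks$end,
                    name = paste(blocks$trait, blocks$block_id, sep = "|"))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write the simulated cohort to a directory of plain-text files
#'
#' Emits the genotype VCF and TSV pair, per-year metabolite matrices plus
#' the replicate-level long table, the expression matrix, trait tables,
#' variant/gene position tables and the ground-truth JSON.
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genotypes_tsv(cohort$genotypes, p("genotypes.tsv"),
                      p("variant_positions.tsv"))
  write_vcf(cohort$genotypes, p("genotypes.vcf"))
  for (t in seq_along(cohort$metabolome$years))
    write_matrix_tsv(cohort$metabolome$years[[t]],
                     p(sprintf("metabolites_year%d.tsv", t)))
  data.table::fwrite(cohort$metabolome$replicates,
                     p("metabolite_replicates.tsv"), sep = "\t")
  write_matrix_tsv(cohort$expression$expression, p("expression.tsv"))
  data.table::fwrite(cohort$expression$gene_map, p("gene_positions.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$trait$replicates, p("trait_replicates.tsv"),
                     sep = "\t")
  trait_years <- do.call(cbind, cohort$trait$years)
  colnames(trait_years) <- sprintf("year%d", seq_along(cohort$trait$years))
  write_matrix_tsv(trait_years, p("trait_means.tsv"))
  truth <- cohort$truth
  truth$modules <- as.list(truth$modules)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
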