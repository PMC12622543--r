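#' Pipeline parameter set
#'
#' Stage parameters shared across the end-to-end run, with the analysis
#' defaults: per-year marker alpha 0.05, MAF filter 0.05, 100-kb blocking
#' window and hotspot bin, hotspot thresholds > 30 signals / > 100 genes,
#' soft power beta = 6, module-trait alpha 0.01, 1-Mb cis window, minimum
#' haplotype group 10, reciprocal-of-tests significance thresholds.
#'
#' @param alpha per-year marker-selection significance level.
#' @param maf minor-allele-frequency filter threshold (strict >).
#' @param window QTL chaining / colocalization window in bp.
#' @param bin hotspot bin width in bp.
#' @param m_threshold,e_threshold hotspot count thresholds.
#' @param beta soft-thresholding power for co-expression adjacency.
#' @param min_module_size,cut_height module detection parameters.
#' @param module_alpha module-trait significance level.
#' @param cis_window cis classification window in bp.
#' @param min_group minimum haplotype group size.
#' @param threshold_mode "reciprocal" or "bonferroni05".
#' @param module_filter logical: restrict network genes to trait-significant
#'   modules.
#' @return a named list.
#' @export
pipeline_params <- function(alpha = 0.05, maf = 0.05, window = 1e5,
                            bin = 1e5, m_threshold = 30, e_threshold = 100,
                            beta = 6, min_module_size = 30,
                            cut_height = 0.99, module_alpha = 0.01,
                            cis_window = 1e6, min_group = 10,
                            threshold_mode = "reciprocal",
                            module_filter = FALSE) {
  as.list(environment())
}

read_inputs <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- c("genotypes.tsv", "variant_positions.tsv", "trait_means.tsv",
            "expression.tsv", "gene_positions.tsv",
            "metabolite_replicates.tsv")
  miss <- need[!file.exists(p(need))]
  if (length(miss) > 0)
    stop("missing input file(s) in ", dir, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  years <- sort(list.files(dir, pattern = "^metabolites_year[0-9]+\\.tsv$"))
  if (length(years) < 1) stop("no per-year metabolite matrices in ", dir,
                              call. = FALSE)
  trait_m <- read_matrix_tsv(p("trait_means.tsv"))
  list(genotypes = read_genotypes_tsv(p("genotypes.tsv"),
                                      p("variant_positions.tsv")),
       metab_years = lapply(years, function(f) read_matrix_tsv(p(f))),
       metab_reps = as.data.frame(
         data.table::fread(p("metabolite_replicates.tsv"))),
       expression = read_matrix_tsv(p("expression.tsv")),
       gene_map = as.data.frame(data.table::fread(p("gene_positions.tsv"))),
       trait_years = lapply(seq_len(ncol(trait_m)), function(t)
         stats::setNames(trait_m[, t], rownames(trait_m))))
}

#' Run the full marker-metabolite multi-omics pipeline
#'
#' Executes (optionally) simulate, then markers, mGWAS, mTWAS, eGWAS,
#' blocks, hotspots, co-expression, network and haplotype stages, writing
#' every inter-stage product as TSV under \code{out_dir} together with a
#' JSON run manifest (package version, parameters, config checksum, seed,
#' and row counts per output).  A stage failure halts the run naming the
#' stage; products of completed stages are retained.  Stages read their
#' inputs from the files earlier stages wrote, so a disabled prerequisite
#' stage makes the dependent stage fail fast naming the missing file.
#'
#' @param input_dir directory of input files as written by
#'   \code{\link{write_cohort}}; ignored when \code{sim} is given.
#' @param out_dir output directory.
#' @param sim optional \code{\link{sim_config}}: simulate the cohort first
#'   and use it as input.
#' @param params a \code{\link{pipeline_params}} list.
#' @param stages character vector of stages to run, in pipeline order.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(input_dir = NULL, out_dir, sim = NULL,
                         params = pipeline_params(),
                         stages = c("markers", "mgwas", "mtwas", "egwas",
                                    "blocks", "hotspots", "wgcna",
                                    "network", "haplotype")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(out_dir, f)
  logf <- o("run.log")
  counts <- list()
  t0 <- Sys.time()
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    if (!name %in% c("load", stages)) return(invisible(NULL))
    log_line("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wr <- function(df, f) {
    data.table::fwrite(df, o(f), sep = "\t")
    counts[[f]] <<- nrow(df)
  }
  wrm <- function(m, f) {
    write_matrix_tsv(m, o(f))
    counts[[f]] <<- nrow(m)
  }
  rd <- function(f, what) {
    if (!file.exists(o(f)))
      stop("missing ", what, " input '", f,
           "' (was its stage run?)", call. = FALSE)
    as.data.frame(data.table::fread(o(f), sep = "\t"))
  }

  if (!is.null(sim)) {
    input_dir <- o("simulated")
    stage("load", {
      cohort <- simulate_cohort(sim)
      write_cohort(cohort, input_dir)
      log_line("simulated cohort written to ", input_dir)
    })
  }
  inp <- stage("load", read_inputs(input_dir))

  stage("markers", {
    rec <- marker_records(inp$trait_years, inp$metab_years)
    rec <- select_markers(rec, alpha = params$alpha)
    h2 <- estimate_heritability(inp$metab_reps)
    rec <- merge(rec, h2[, c("metabolite", "H2")], by = "metabolite",
                 all.x = TRUE)
    wr(rec, "markers.tsv")
    log_line(sum(rec$selected), " marker metabolites selected")
  })

  geno_f <- if (any(c("mgwas", "egwas", "haplotype") %in% stages))
    maf_filter(inp$genotypes, params$maf) else NULL

  empty_scan <- data.frame(trait = character(0), variant_id = character(0),
                           chrom = character(0), pos = integer(0),
                           beta = numeric(0), se = numeric(0),
                           p = numeric(0), year = integer(0))

  stage("mgwas", {
    mk <- rd("markers.tsv", "marker table")
    sel <- mk$metabolite[mk$selected]
    if (length(sel) == 0) {
      wr(empty_scan, "mgwas_signals.tsv")
      log_line("no marker metabolites; mGWAS skipped with empty output")
    } else {
      K <- compute_kinship(geno_f)
      m <- ncol(geno_f$dosage)
      thr <- significance_threshold(m, params$threshold_mode)
      sig <- list()
      for (t in seq_along(inp$metab_years)) {
        Y <- inp$metab_years[[t]][, sel, drop = FALSE]
        res <- lmm_scan_many(Y, geno_f, K)
        res$year <- t
        sig[[t]] <- res[res$p < thr, , drop = FALSE]
      }
      sig <- do.call(rbind, sig)
      wr(sig, "mgwas_signals.tsv")
      log_line(nrow(sig), " significant mGWAS signals at p < ",
               signif(thr, 3))
    }
  })

  stage("mtwas", {
    mk <- rd("markers.tsv", "marker table")
    sel <- mk$metabolite[mk$selected]
    thr <- significance_threshold(ncol(inp$expression),
                                  params$threshold_mode)
    res <- do.call(rbind, lapply(sel, function(met)
      ols_scan(stats::setNames(inp$metab_years[[1]][, met],
                               rownames(inp$metab_years[[1]])),
               inp$expression, target_id = met)))
    if (is.null(res))
      res <- data.frame(trait = character(0), predictor = character(0),
                        beta = numeric(0), se = numeric(0), p = numeric(0),
                        n = integer(0))
    res$significant <- res$p < thr
    wr(res, "mtwas.tsv")
    log_line(sum(res$significant), " significant mTWAS pairs")
  })

  stage("egwas", {
    mt <- rd("mtwas.tsv", "mTWAS")
    genes <- sort(unique(mt$predictor[mt$significant]))
    if (length(genes) == 0) {
      wr(data.frame(trait = character(0), variant_id = character(0),
                    chrom = character(0), pos = integer(0),
                    beta = numeric(0), se = numeric(0), p = numeric(0)),
         "egwas_signals.tsv")
    } else {
      K <- compute_kinship(geno_f)
      thr <- significance_threshold(ncol(geno_f$dosage),
                                    params$threshold_mode)
      res <- lmm_scan_many(inp$expression[, genes, drop = FALSE], geno_f, K)
      sig <- res[res$p < thr, , drop = FALSE]
      wr(sig, "egwas_signals.tsv")
      log_line(nrow(sig), " significant eGWAS signals for ",
               length(genes), " genes")
    }
  })

  stage("blocks", {
    ms <- rd("mgwas_signals.tsv", "mGWAS signals")
    es <- rd("egwas_signals.tsv", "eGWAS signals")
    mq <- cluster_signals(ms, window = params$window, kind = "mQTL")
    eq <- cluster_signals(es, window = params$window, kind = "eQTL")
    if (nrow(eq) > 0) {
      eq$cis_trans <- vapply(seq_len(nrow(eq)), function(i) {
        gp <- inp$gene_map[inp$gene_map$gene_id == eq$trait[i], ]
        if (nrow(gp) == 0) return("unknown")
        classify_eqtl_cis_trans(eq[i, ], gp, params$cis_window)
      }, character(1))
    }
    wr(mq, "mqtl_blocks.tsv")
    wr(eq, "eqtl_blocks.tsv")
    write_blocks_bed(rbind(mq[, 1:10], eq[, 1:10]), o("blocks.bed"))
    log_line(nrow(mq), " mQTL and ", nrow(eq), " eQTL blocks")
  })

  stage("hotspots", {
    ms <- rd("mgwas_signals.tsv", "mGWAS signals")
    es <- rd("egwas_signals.tsv", "eGWAS signals")
    hm <- find_hotspots(ms, "mQTL", bin = params$bin,
                        m_threshold = params$m_threshold)
    he <- find_hotspots(es, "eQTL", bin = params$bin,
                        e_threshold = params$e_threshold)
    wr(rbind(hm, he), "hotspots.tsv")
  })

  stage("wgcna", {
    sds <- apply(inp$expression, 2, stats::sd)
    expr <- inp$expression[, sds > 0, drop = FALSE]
    A <- adjacency_matrix(expr, beta = params$beta)
    tom <- tom_similarity(A)
    assign <- detect_modules(tom, params$min_module_size, params$cut_height)
    eg <- module_eigengenes(expr, assign)
    wr(assign, "module_assignments.tsv")
    wrm(eg$eigengenes, "eigengenes.tsv")
    mk <- rd("markers.tsv", "marker table")
    sel <- mk$metabolite[mk$selected]
    targets <- cbind(trait = inp$trait_years[[1]][rownames(expr)],
                     inp$metab_years[[1]][rownames(expr), sel, drop = FALSE])
    if (ncol(eg$eigengenes) > 0) {
      mt <- module_trait_correlation(eg$eigengenes, targets,
                                     alpha = params$module_alpha)
      wr(mt, "module_trait.tsv")
    } else {
      wr(data.frame(module = character(0), target = character(0),
                    r = numeric(0), p = numeric(0), n = integer(0),
                    significant = logical(0)), "module_trait.tsv")
    }
  })

  stage("network", {
    mk <- rd("markers.tsv", "marker table")
    mq <- rd("mqtl_blocks.tsv", "mQTL blocks")
    eq <- rd("eqtl_blocks.tsv", "eQTL blocks")
    mt <- rd("mtwas.tsv", "mTWAS")
    mod <- NULL
    filt <- NULL
    if (isTRUE(params$module_filter)) {
      mod <- rd("module_assignments.tsv", "module assignments")
      mtc <- rd("module_trait.tsv", "module-trait correlations")
      filt <- unique(mtc$module[mtc$significant & mtc$target == "trait"])
    }
    net <- build_network(mk$metabolite[mk$selected], mq, eq,
                         mt[mt$significant, , drop = FALSE],
                         module_assignments = mod, module_filter = filt,
                         window = params$window)
    wr(net$nodes, "network_nodes.tsv")
    wr(net$edges, "network_edges.tsv")
    wr(candidate_genes(net), "candidate_genes.tsv")
    if (nrow(net$nodes) > 0) write_graphml(net, o("network.graphml"))
    log_line(nrow(net$nodes), " network nodes, ", nrow(net$edges),
             " edges")
  })

  stage("haplotype", {
    empty_hap <- data.frame(metabolite = character(0),
                            lead_variant = character(0),
                            method = character(0), statistic = numeric(0),
                            p = numeric(0), groups = character(0))
    mq <- rd("mqtl_blocks.tsv", "mQTL blocks")
    if (nrow(mq) == 0) {
      wr(empty_hap, "haplotype_tests.tsv")
    } else {
      top <- mq[order(mq$lead_p), ][1, ]
      res <- tryCatch({
        grp <- group_haplotypes(geno_f, top$lead_variant,
                                min_group = params$min_group)
        ph <- stats::setNames(inp$metab_years[[1]][, top$trait],
                              rownames(inp$metab_years[[1]]))
        tst <- test_haplotype_effect(grp, ph)
        cbind(data.frame(metabolite = top$trait,
                         lead_variant = top$lead_variant,
                         method = tst$method, statistic = tst$statistic,
                         p = tst$p),
              data.frame(groups = paste(sprintf("%s(n=%d,mean=%.3f)",
                                                tst$means$haplotype,
                                                tst$means$n,
                                                tst$means$mean),
                                        collapse = ";")))
      }, error = function(e) {
        log_line("haplotype test skipped: ", conditionMessage(e))
        empty_hap
      })
      wr(res, "haplotype_tests.tsv")
    }
  })

  cfg_json <- jsonlite::toJSON(list(params = params,
                                    sim = if (!is.null(sim))
                                      unclass(sim) else NULL),
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "mqtlnet",
    version = as.character(utils::packageVersion("mqtlnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = stages,
    params = params,
    sim_config = if (!is.null(sim)) unclass(sim) else NULL,
    seed = if (!is.null(sim)) sim$seed else NA,
    config_md5 = unname(tools::md5sum(tmp)),
    row_counts = counts,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  unlink(tmp)
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line("pipeline finished")
  invisible(manifest)
}
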