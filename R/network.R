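#' Colocalize mQTL and eQTL blocks into merged QTL nodes
#'
#' An mQTL and an eQTL colocalize iff they sit on the same chromosome and
#' the gap between their intervals is <= window (0 when overlapping).
#' Connected components of the colocalization relation are merged into
#' single QTL nodes spanning the union of member intervals, so chains like
#' m1-e1-m2 resolve to one node.
#'
#' @param mqtls,eqtls block tables from \code{\link{cluster_signals}}.
#' @param window colocalization distance in bp (default 100000).
#' @return list: \code{qtl_nodes} (qtl_id, chrom, start, end, n_mqtl,
#'   n_eqtl), \code{membership} (block_id, kind, trait, qtl_id),
#'   \code{pairs} (mqtl block_id, eqtl block_id, gap).
#' @export
colocalize <- function(mqtls, eqtls, window = 1e5) {
  empty <- list(
    qtl_nodes = data.frame(qtl_id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           n_mqtl = integer(0), n_eqtl = integer(0)),
    membership = data.frame(block_id = character(0), kind = character(0),
                            trait = character(0), qtl_id = character(0)),
    pairs = data.frame(mqtl = character(0), eqtl = character(0),
                       gap = numeric(0)))
  if (nrow(mqtls) == 0 || nrow(eqtls) == 0) return(empty)
  pairs <- list()
  for (ch in intersect(unique(mqtls$chrom), unique(eqtls$chrom))) {
    M <- mqtls[mqtls$chrom == ch, , drop = FALSE]
    E <- eqtls[eqtls$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(M))) {
      gap <- pmax(0, pmax(M$start[i], E$start) - pmin(M$end[i], E$end))
      hit <- which(gap <= window)
      if (length(hit) > 0)
        pairs[[length(pairs) + 1L]] <- data.frame(
          mqtl = M$block_id[i], eqtl = E$block_id[hit], gap = gap[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) return(empty)
  pairs <- do.call(rbind, pairs)
  g <- igraph::graph_from_data_frame(pairs[, c("mqtl", "eqtl")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  cols <- c("block_id", "kind", "trait", "chrom", "start", "end")
  blk <- rbind(mqtls[, cols], eqtls[, cols])
  member <- data.frame(block_id = names(comp$membership),
                       component = unname(comp$membership),
                       stringsAsFactors = FALSE)
  member <- merge(member, blk[, c("block_id", "kind", "trait", "chrom",
                                  "start", "end")], by = "block_id")
  # stable QTL ids ordered by genomic position of the merged span
  spans <- do.call(rbind, lapply(split(member, member$component),
    function(d) data.frame(component = d$component[1], chrom = d$chrom[1],
                           start = min(d$start), end = max(d$end),
                           n_mqtl = sum(d$kind == "mQTL"),
                           n_eqtl = sum(d$kind == "eQTL"))))
  spans <- spans[order(spans$chrom, spans$start, spans$end), ]
  spans$qtl_id <- sprintf("QTL%04d", seq_len(nrow(spans)))
  member$qtl_id <- spans$qtl_id[match(member$component, spans$component)]
  rownames(spans) <- NULL
  list(qtl_nodes = spans[, c("qtl_id", "chrom", "start", "end", "n_mqtl",
                             "n_eqtl")],
       membership = member[order(member$qtl_id, member$block_id),
                           c("block_id", "kind", "trait", "qtl_id")],
       pairs = pairs)
}

#' Assemble the ternary metabolite-QTL-gene network
#'
#' Nodes are marker metabolites, genes and merged QTLs; edges are typed
#' metabolite-QTL (from mQTL blocks), gene-QTL (from eQTL blocks) and
#' metabolite-gene (from threshold-passing mTWAS pairs).  QTL nodes exist
#' only where an mQTL and an eQTL colocalize within \code{window}, so each
#' carries at least one edge of both QTL edge types.  Gene membership can
#' optionally be restricted to genes of trait-significant co-expression
#' modules.
#'
#' @param markers character vector of marker metabolite ids.
#' @param mqtls,eqtls block tables (eQTL trait = gene id).
#' @param mtwas data.frame of significant mTWAS pairs with columns trait
#'   (metabolite), predictor (gene), p.
#' @param module_assignments optional \code{\link{detect_modules}} output.
#' @param module_filter optional character vector of module labels to keep;
#'   only genes in those modules enter the network when given.
#' @param window colocalization window in bp.
#' @return object of class \code{ternary_network}: list with \code{nodes}
#'   (id, type), \code{edges} (from, to, type, provenance columns),
#'   \code{qtl} (the \code{\link{colocalize}} result) and \code{graph}
#'   (an igraph object).
#' @export
build_network <- function(markers, mqtls, eqtls, mtwas,
                          module_assignments = NULL, module_filter = NULL,
                          window = 1e5) {
  gene_ok <- function(g) TRUE
  if (!is.null(module_filter)) {
    if (is.null(module_assignments))
      stop("module_filter requires module_assignments", call. = FALSE)
    allowed <- module_assignments$gene_id[
      module_assignments$module %in% module_filter]
    gene_ok <- function(g) g %in% allowed
  }
  mqtls <- mqtls[mqtls$trait %in% markers, , drop = FALSE]
  eqtls <- eqtls[gene_ok(eqtls$trait), , drop = FALSE]
  co <- colocalize(mqtls, eqtls, window)

  edges <- list()
  if (nrow(co$membership) > 0) {
    mm <- co$membership[co$membership$kind == "mQTL", , drop = FALSE]
    em <- co$membership[co$membership$kind == "eQTL", , drop = FALSE]
    lcols <- c("block_id", "lead_variant", "lead_p")
    lead <- rbind(mqtls[, lcols], eqtls[, lcols])
    lp <- lead$lead_p[match(mm$block_id, lead$block_id)]
    lv <- lead$lead_variant[match(mm$block_id, lead$block_id)]
    edges$mqtl <- data.frame(from = mm$trait, to = mm$qtl_id,
                             type = "mQTL", p = lp, lead_variant = lv,
                             block_id = mm$block_id, stringsAsFactors = FALSE)
    lp <- lead$lead_p[match(em$block_id, lead$block_id)]
    lv <- lead$lead_variant[match(em$block_id, lead$block_id)]
    edges$eqtl <- data.frame(from = em$trait, to = em$qtl_id,
                             type = "eQTL", p = lp, lead_variant = lv,
                             block_id = em$block_id, stringsAsFactors = FALSE)
  }
  if (!is.null(mtwas) && nrow(mtwas) > 0) {
    mt <- mtwas[mtwas$trait %in% markers & gene_ok(mtwas$predictor), ,
                drop = FALSE]
    if (nrow(mt) > 0)
      edges$mtwas <- data.frame(from = mt$trait, to = mt$predictor,
                                type = "mTWAS", p = mt$p,
                                lead_variant = NA_character_,
                                block_id = NA_character_,
                                stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               p = numeric(0), lead_variant = character(0),
               block_id = character(0))
  edges <- unique(edges[order(edges$type, edges$from, edges$to), ])
  rownames(edges) <- NULL

  met_nodes <- sort(unique(edges$from[edges$type %in% c("mQTL", "mTWAS")]))
  gene_nodes <- sort(unique(c(edges$from[edges$type == "eQTL"],
                              edges$to[edges$type == "mTWAS"])))
  qtl_nodes <- sort(unique(edges$to[edges$type %in% c("mQTL", "eQTL")]))
  nodes <- rbind(
    data.frame(id = met_nodes, type = rep("metabolite", length(met_nodes))),
    data.frame(id = gene_nodes, type = rep("gene", length(gene_nodes))),
    data.frame(id = qtl_nodes, type = rep("QTL", length(qtl_nodes))))
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "type", "p")], directed = FALSE,
    vertices = nodes)
  structure(list(nodes = nodes, edges = edges, qtl = co, graph = g),
            class = "ternary_network")
}

#' Candidate genes from closed metabolite-QTL-gene triangles
#'
#' A gene is a candidate iff it closes at least one triangle: its eQTL
#' colocalizes (same QTL node) with an mQTL of a metabolite the gene is
#' mTWAS-associated with.  Candidates are ranked by triangle count, then
#' best mTWAS p.
#'
#' @param network a \code{\link{build_network}} result.
#' @return data.frame: gene_id, n_triangles, best_mtwas_p, metabolites.
#' @export
candidate_genes <- function(network) {
  ed <- network$edges
  mq <- ed[ed$type == "mQTL", c("from", "to")]
  eq <- ed[ed$type == "eQTL", c("from", "to")]
  mt <- ed[ed$type == "mTWAS", c("from", "to", "p")]
  if (nrow(mq) == 0 || nrow(eq) == 0 || nrow(mt) == 0)
    return(data.frame(gene_id = character(0), n_triangles = integer(0),
                      best_mtwas_p = numeric(0), metabolites = character(0)))
  # (metabolite, gene) pairs sharing a QTL node
  shared <- merge(mq, eq, by = "to", suffixes = c("_met", "_gene"))
  tri <- merge(shared, mt,
               by.x = c("from_met", "from_gene"), by.y = c("from", "to"))
  if (nrow(tri) == 0)
    return(data.frame(gene_id = character(0), n_triangles = integer(0),
                      best_mtwas_p = numeric(0), metabolites = character(0)))
  out <- do.call(rbind, lapply(split(tri, tri$from_gene), function(d)
    data.frame(gene_id = d$from_gene[1], n_triangles = nrow(d),
               best_mtwas_p = min(d$p),
               metabolites = paste(sort(unique(d$from_met)), collapse = ","),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$n_triangles, out$best_mtwas_p, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Write a ternary network to GraphML
#'
#' @param network a \code{ternary_network}.
#' @param path output file.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
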