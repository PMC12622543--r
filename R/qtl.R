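#' Chain significant signals into positional QTL blocks
#'
#' Within each (trait, chromosome) group, signals are sorted by position
#' and chained: a signal joins the open block when its gap to the block's
#' last member is <= window, else it starts a new block.  The block spans
#' first-to-last member positions; the lead variant has the smallest p
#' (ties broken by smaller position).  This is the positional "LD threshold
#' of 100 kb" clustering that turns per-variant signals into mQTLs/eQTLs.
#'
#' @param signals data.frame of threshold-passing associations with columns
#'   trait, variant_id, chrom, pos, p.
#' @param window chaining gap in bp (default 100000).
#' @param kind "mQTL" or "eQTL" label written into the output.
#' @return data.frame of blocks: kind, trait, block_id, chrom, start, end,
#'   n_members, members (comma-joined variant ids), lead_variant, lead_p.
#' @export
cluster_signals <- function(signals, window = 1e5, kind = "mQTL") {
  need <- c("trait", "variant_id", "chrom", "pos", "p")
  if (!all(need %in% names(signals)))
    stop("signals must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(signals) == 0)
    return(data.frame(kind = character(0), trait = character(0),
                      block_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), members = character(0),
                      lead_variant = character(0), lead_p = numeric(0)))
  if (anyNA(signals$pos))
    stop("unknown position for variant(s): ",
         paste(signals$variant_id[is.na(signals$pos)], collapse = ", "),
         call. = FALSE)
  groups <- split(signals, list(signals$trait, signals$chrom), drop = TRUE)
  blocks <- lapply(groups, function(g) {
    g <- g[order(g$pos, g$variant_id), , drop = FALSE]
    newblk <- c(TRUE, diff(g$pos) > window)
    bid <- cumsum(newblk)
    do.call(rbind, lapply(split(g, bid), function(b) {
      lead <- b[order(b$p, b$pos), ][1, ]
      data.frame(kind = kind, trait = b$trait[1], chrom = b$chrom[1],
                 start = min(b$pos), end = max(b$pos),
                 n_members = nrow(b),
                 members = paste(b$variant_id, collapse = ","),
                 lead_variant = lead$variant_id, lead_p = lead$p,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$trait, out$chrom, out$start), , drop = FALSE]
  out$block_id <- sprintf("%s%04d", ifelse(out$kind == "mQTL", "mQTL",
                                           "eQTL"), seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("kind", "trait", "block_id", "chrom", "start", "end", "n_members",
          "members", "lead_variant", "lead_p")]
}

#' Detect signal/gene hotspots in fixed genomic bins
#'
#' The genome is tiled into non-overlapping \code{bin}-bp windows starting
#' at position 1.  In mQTL mode the count is the number of significant
#' signals in a bin (across traits); in eQTL mode it is the number of
#' distinct associated genes.  A bin is a hotspot iff its count strictly
#' exceeds the kind-specific threshold (> 30 signals / > 100 genes).
#'
#' @param signals data.frame with chrom, pos and (for eQTL mode) trait =
#'   the associated gene id.
#' @param kind "mQTL" or "eQTL".
#' @param bin bin width in bp (default 100000).
#' @param m_threshold,e_threshold hotspot count thresholds.
#' @return data.frame: kind, chrom, bin_start, bin_end, count, hotspot
#'   (all non-empty bins; filter on \code{hotspot} for the calls).
#' @export
find_hotspots <- function(signals, kind = c("mQTL", "eQTL"), bin = 1e5,
                          m_threshold = 30, e_threshold = 100) {
  kind <- match.arg(kind)
  if (nrow(signals) == 0)
    return(data.frame(kind = character(0), chrom = character(0),
                      bin_start = integer(0), bin_end = integer(0),
                      count = integer(0), hotspot = logical(0)))
  b <- (signals$pos - 1) %/% bin
  key <- paste(signals$chrom, b, sep = ":")
  cnt <- if (kind == "mQTL") {
    tapply(signals$pos, key, length)
  } else {
    tapply(signals$trait, key, function(x) length(unique(x)))
  }
  parts <- strsplit(names(cnt), ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  bi <- as.numeric(vapply(parts, `[`, character(1), 2))
  thr <- if (kind == "mQTL") m_threshold else e_threshold
  out <- data.frame(kind = kind, chrom = chrom,
                    bin_start = as.integer(bi * bin + 1),
                    bin_end = as.integer((bi + 1) * bin),
                    count = as.integer(cnt),
                    hotspot = as.integer(cnt) > thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$chrom, out$bin_start), ]
}

#' Classify an eQTL block as cis or trans relative to its gene
#'
#' cis iff the block and gene are on the same chromosome and the minimum
#' block-gene distance is <= cis_window (inclusive; overlap counts as
#' distance 0); otherwise trans.  Missing gene coordinates give "unknown".
#'
#' @param block one row of a \code{\link{cluster_signals}} result.
#' @param gene_pos list or one-row data.frame with chrom, start, end.
#' @param cis_window bp window (default 1e6).
#' @return "cis", "trans" or "unknown".
#' @export
classify_eqtl_cis_trans <- function(block, gene_pos, cis_window = 1e6) {
  if (is.null(gene_pos) || is.na(gene_pos$chrom[1]) ||
      is.na(gene_pos$start[1]) || is.na(gene_pos$end[1]))
    return("unknown")
  if (block$chrom[1] != gene_pos$chrom[1]) return("trans")
  gap <- interval_gap(block$start[1], block$end[1],
                      gene_pos$start[1], gene_pos$end[1])
  if (gap <= cis_window) "cis" else "trans"
}

# gap between two closed intervals; 0 when they overlap or touch
interval_gap <- function(s1, e1, s2, e2) {
  max(0, max(s1, s2) - min(e1, e2))
}
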