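# Host-gene scanning: count miRNAs whose genomic locus lies within CNV and
# non-CNV gene spans, per species, and summarise the per-species bias.

#' Scan miRNA coordinates against gene spans
#'
#' A miRNA is hosted by a gene iff its interval is fully contained within
#' the gene interval on the same chromosome (default; `mode = "any"` counts
#' any-base overlap instead). Strand-agnostic unless `strand = "match"`.
#' A miRNA inside genes of both strata is counted once in each stratum;
#' within a stratum a miRNA counts once no matter how many genes host it.
#'
#' @param mirnas data.frame with `mirna_id`, `chrom`, `start`, `end`
#'   (0-based half-open; rows with `NA` chrom are intergenic and never
#'   assigned).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `cnv_status` (and `strand` when `strand = "match"`).
#' @param mode `"within"` (containment, default) or `"any"` (overlap).
#' @param strand `"ignore"` (default) or `"match"`.
#' @return object of class `mircnv_hostscan`: list with `counts`
#'   (data.frame: stratum, n_mirnas, n_genes) and `assignments`
#'   (data.frame: mirna_id, gene_id, cnv_status).
#' @export
scan_hosts <- function(mirnas, genes, mode = c("within", "any"),
                       strand = c("ignore", "match")) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  m <- mirnas[!is.na(mirnas$chrom), , drop = FALSE]
  if (nrow(genes) > 0) check_intervals(genes, "gene_id", "gene table")
  if (nrow(m) > 0) check_intervals(m, "mirna_id", "miRNA table")
  only <- symdiff_chroms(m, genes)
  if (length(only) > 0) {
    warning("chromosome(s) present in only one input: ",
            paste(only, collapse = ", "), call. = FALSE)
  }
  if (nrow(m) > 0 && nrow(genes) > 0) {
    hits <- GenomicRanges::findOverlaps(
      intervals_to_granges(m), intervals_to_granges(genes),
      type = if (mode == "within") "within" else "any",
      minoverlap = 1L, ignore.strand = (strand == "ignore")
    )
    assignments <- data.frame(
      mirna_id = m$mirna_id[S4Vectors::queryHits(hits)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      cnv_status = genes$cnv_status[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
    assignments <- assignments[order(assignments$mirna_id,
                                     assignments$gene_id), ]
    rownames(assignments) <- NULL
  } else {
    assignments <- data.frame(mirna_id = character(0),
                              gene_id = character(0),
                              cnv_status = character(0),
                              stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, lapply(c("CNV", "nonCNV"), function(st) {
    data.frame(
      stratum = st,
      n_mirnas = length(unique(
        assignments$mirna_id[assignments$cnv_status == st])),
      n_genes = sum(genes$cnv_status == st),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(counts = counts, assignments = assignments),
            class = "mircnv_hostscan")
}

symdiff_chroms <- function(m, genes) {
  cm <- unique(as.character(m$chrom))
  cg <- unique(as.character(genes$chrom))
  if (length(cm) == 0 || length(cg) == 0) return(character(0))
  c(setdiff(cm, cg), setdiff(cg, cm))
}

#' @export
print.mircnv_hostscan <- function(x, ...) {
  cat("mircnv host scan\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Per-species host-miRNA bias summary
#'
#' Reports, per species, the hosted-miRNA counts and gene denominators of
#' both strata, the density ratio (CNV density / non-CNV density, each
#' density = hosted miRNAs / genes), and a three-way label: `cnv-biased`
#' when the ratio exceeds `similar_threshold`, `noncnv-biased` below its
#' reciprocal, `similar` in between.
#'
#' @param results named list (species -> [scan_hosts()] result).
#' @param similar_threshold ratio bound defining `similar` (default 1.2).
#' @return data.frame: species, cnv_mirnas, cnv_genes, noncnv_mirnas,
#'   noncnv_genes, cnv_density, noncnv_density, ratio, label.
#' @export
host_bias_summary <- function(results, similar_threshold = 1.2) {
  if (length(results) == 0) stop("no species results", call. = FALSE)
  rows <- lapply(names(results), function(sp) {
    cnt <- results[[sp]]$counts
    cn <- cnt[cnt$stratum == "CNV", ]
    nn <- cnt[cnt$stratum == "nonCNV", ]
    cd <- if (cn$n_genes > 0) cn$n_mirnas / cn$n_genes else NA_real_
    nd <- if (nn$n_genes > 0) nn$n_mirnas / nn$n_genes else NA_real_
    # all hosts in one stratum is a definite bias; no hosts at all is NA
    ratio <- if (is.na(cd) || is.na(nd) || (cd == 0 && nd == 0)) NA_real_
      else cd / nd
    label <- if (is.na(ratio)) NA_character_
      else if (ratio > similar_threshold) "cnv-biased"
      else if (ratio < 1 / similar_threshold) "noncnv-biased"
      else "similar"
    data.frame(species = sp,
               cnv_mirnas = cn$n_mirnas, cnv_genes = cn$n_genes,
               noncnv_mirnas = nn$n_mirnas, noncnv_genes = nn$n_genes,
               cnv_density = cd, noncnv_density = nd,
               ratio = ratio, label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
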