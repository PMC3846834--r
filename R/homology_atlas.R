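# Cross-species atlas of homologous CNV and non-CNV genes: a gene is CNV if
# its span overlaps >= 1 catalogued CNV region by >= 1 base; non-human
# species retain exactly the genes with a human homolog and carry their OWN
# species' CNV status.

#' Assign CNV / nonCNV status to genes by region overlap
#'
#' A gene is `CNV` iff its interval overlaps at least one CNV region by at
#' least one base (0-based half-open coordinates, strand-agnostic); all
#' others are `nonCNV`. Idempotent.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (additional columns are preserved).
#' @param cnv_regions data.frame with columns `chrom`, `start`, `end`.
#' @return `genes` with a `cnv_status` column set.
#' @export
assign_cnv_status <- function(genes, cnv_regions) {
  if (nrow(genes) == 0L) {
    genes$cnv_status <- character(0)
    return(genes)
  }
  check_intervals(genes, id_col = "gene_id", what = "gene table")
  if (nrow(cnv_regions) > 0L) {
    check_intervals(cnv_regions, what = "CNV region table")
    hits <- GenomicRanges::findOverlaps(
      intervals_to_granges(genes), intervals_to_granges(cnv_regions),
      minoverlap = 1L, ignore.strand = TRUE
    )
    is_cnv <- seq_len(nrow(genes)) %in% S4Vectors::queryHits(hits)
  } else {
    is_cnv <- rep(FALSE, nrow(genes))
  }
  genes$cnv_status <- ifelse(is_cnv, "CNV", "nonCNV")
  genes
}

#' Build the cross-species homolog atlas and its per-species summary
#'
#' Non-human species retain exactly those genes that belong to a homology
#' group with a human member; a retained gene's classification is its own
#' species' `cnv_status`. Genes referenced by the homology table but missing
#' from a species' gene table are dropped with a logged count; duplicated
#' gene ids within a species keep the first occurrence with a warning.
#'
#' @param human_genes data.frame of human genes carrying `cnv_status`.
#' @param homology data.frame with columns `group_id`, `species`, `gene_id`.
#' @param species_genes named list of per-species gene data.frames (each
#'   carrying `cnv_status`); human may be included or not.
#' @param inherit_human_status if `TRUE`, a retained gene is classified by
#'   its human homolog's status instead of its own species' CNV calls
#'   (fallback for species without CNV catalogues; off by default).
#' @return list with elements `atlas` (named list of per-species gene
#'   data.frames, rows sorted by `gene_id`) and `summary` (data.frame:
#'   species, n_cnv, n_noncnv, n_total).
#' @export
build_atlas <- function(human_genes, homology, species_genes = list(),
                        inherit_human_status = FALSE) {
  if (!"cnv_status" %in% names(human_genes)) {
    stop("human genes must carry cnv_status; run assign_cnv_status() first",
         call. = FALSE)
  }
  species_genes[["human"]] <- NULL
  hom_species <- setdiff(unique(homology$species), "human")
  missing_sp <- setdiff(hom_species, names(species_genes))
  if (length(missing_sp) > 0) {
    stop("species present in homology but lacking a gene table: ",
         paste(sort(missing_sp), collapse = ", "), call. = FALSE)
  }

  dedup <- function(g, sp) {
    dup <- duplicated(g$gene_id)
    if (any(dup)) {
      warning(sprintf("%d duplicated gene id(s) in %s; first occurrence kept",
                      sum(dup), sp), call. = FALSE)
      g <- g[!dup, ]
    }
    g
  }
  human_genes <- dedup(human_genes, "human")

  # groups usable for mapping must name a human member
  human_groups <- unique(homology$group_id[homology$species == "human" &
                          homology$gene_id %in% human_genes$gene_id])
  atlas <- list(human = human_genes[order(human_genes$gene_id), ])
  rownames(atlas$human) <- NULL
  for (sp in sort(names(species_genes))) {
    g <- dedup(species_genes[[sp]], sp)
    if (!"cnv_status" %in% names(g)) {
      stop("gene table for ", sp, " lacks cnv_status", call. = FALSE)
    }
    mapped_ids <- homology$gene_id[homology$species == sp &
                                     homology$group_id %in% human_groups]
    keep <- g[g$gene_id %in% mapped_ids, ]
    if (inherit_human_status && nrow(keep) > 0) {
      grp <- homology$group_id[match(keep$gene_id, homology$gene_id)]
      hum_id <- homology$gene_id[homology$species == "human"][
        match(grp, homology$group_id[homology$species == "human"])]
      keep$cnv_status <- human_genes$cnv_status[
        match(hum_id, human_genes$gene_id)]
    }
    n_lost <- length(setdiff(mapped_ids, g$gene_id))
    if (n_lost > 0) {
      message(sprintf(
        "[mircnv] %s: %d homology-mapped gene(s) lack coordinates; dropped",
        sp, n_lost))
    }
    keep <- keep[order(keep$gene_id), ]
    rownames(keep) <- NULL
    atlas[[sp]] <- keep
  }
  summary <- do.call(rbind, lapply(names(atlas), function(sp) {
    st <- atlas[[sp]]$cnv_status
    data.frame(species = sp, n_cnv = sum(st == "CNV"),
               n_noncnv = sum(st == "nonCNV"),
               n_total = length(st), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(atlas = atlas, summary = summary)
}

#' Flatten an atlas to a single data.frame
#'
#' @param atlas named list of per-species gene data.frames from
#'   [build_atlas()].
#' @return one data.frame with all species stacked.
#' @export
atlas_to_frame <- function(atlas) {
  out <- do.call(rbind, unname(atlas))
  rownames(out) <- NULL
  out
}
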