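# Per-gene interaction densities, per-unit (miRNA or family) target counts,
# overall means, the above/below-mean partition of units and their target
# gene lists, and the 3'UTR-length control.

#' Interactions per gene
#'
#' Total predicted pair count normalised by the number of genes scanned.
#'
#' @param pairs pair data.frame (one row per miRNA-gene pair) or an integer
#'   pair count.
#' @param n_genes number of genes in the stratum (>= 1).
#' @return interactions per gene (double).
#' @export
per_gene_density <- function(pairs, n_genes) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  total <- if (is.data.frame(pairs)) nrow(pairs) else as.numeric(pairs)
  total / n_genes
}

#' Mean number of targets per unit
#'
#' Total pair count divided by the number of units (miRNAs or families)
#' considered, at full precision; round to 2 decimals for display.
#'
#' @param pairs pair data.frame or an integer pair count.
#' @param n_units number of units in the denominator (>= 1), including
#'   units with zero targets.
#' @return mean targets per unit (double, full precision).
#' @export
overall_mean <- function(pairs, n_units) {
  if (n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  total <- if (is.data.frame(pairs)) nrow(pairs) else as.numeric(pairs)
  total / n_units
}

#' Partition units and their target genes by the overall mean
#'
#' Each unit with a target count strictly greater than `overall_mean` is
#' classed `above`; units at or below the mean (including ties, under the
#' default rule) are `below`. `above_genes` / `below_genes` are the unions
#' of the target genes of the corresponding units; the two gene lists may
#' overlap -- a gene can be targeted by units of both classes -- which is
#' deliberate, since enrichment is reported for both lists.
#'
#' @param pairs pair data.frame with a unit column and `gene_id`.
#' @param n_units total number of units considered (including zero-target
#'   units); used for the mean when `overall_mean` is `NULL`.
#' @param overall_mean the cut-off; defaults to `nrow(pairs) / n_units`.
#' @param level `"mirna"` (unit column `mirna_id`) or `"family"` (unit
#'   column `family_key`).
#' @param rule `"ties_below"` (default: count > mean is above) or
#'   `"ties_above"` (count >= mean is above).
#' @return object of class `mircnv_partition`: list with `species`, `level`,
#'   `n_units`, `total_pairs`, `overall_mean`, `units` (data.frame unit_id,
#'   target_count, class), `above_units`, `below_units`, `above_genes`,
#'   `below_genes`.
#' @export
partition_genes <- function(pairs, n_units, overall_mean = NULL,
                            level = c("mirna", "family"),
                            rule = c("ties_below", "ties_above")) {
  level <- match.arg(level)
  rule <- match.arg(rule)
  unit_col <- if (level == "mirna") "mirna_id" else "family_key"
  if (!unit_col %in% names(pairs)) {
    stop("pairs lack unit column: ", unit_col, call. = FALSE)
  }
  total <- nrow(pairs)
  if (is.null(overall_mean)) overall_mean <- total / n_units
  if (overall_mean < 0) stop("overall_mean must be >= 0", call. = FALSE)
  counts <- table(pairs[[unit_col]])
  units <- data.frame(unit_id = names(counts),
                      target_count = as.integer(counts),
                      stringsAsFactors = FALSE)
  units <- units[order(units$unit_id), ]
  rownames(units) <- NULL
  above <- if (rule == "ties_below") units$target_count > overall_mean else
    units$target_count >= overall_mean
  units$class <- ifelse(above, "above", "below")
  above_units <- units$unit_id[above]
  below_units <- units$unit_id[!above]
  species <- unique(pairs$species)
  structure(list(
    species = if (length(species) == 1) species else species,
    level = level,
    n_units = as.integer(n_units),
    total_pairs = as.integer(total),
    overall_mean = overall_mean,
    units = units,
    above_units = above_units,
    below_units = below_units,
    above_genes = sort(unique(pairs$gene_id[pairs[[unit_col]] %in%
                                              above_units])),
    below_genes = sort(unique(pairs$gene_id[pairs[[unit_col]] %in%
                                              below_units]))
  ), class = "mircnv_partition")
}

#' @export
print.mircnv_partition <- function(x, ...) {
  cat(sprintf(
    "mircnv partition (%s, level %s): %d pairs / %d units, mean %.2f\n",
    paste(x$species, collapse = ","), x$level, x$total_pairs, x$n_units,
    x$overall_mean))
  cat(sprintf("  above: %d units, %d genes; below: %d units, %d genes\n",
              length(x$above_units), length(x$above_genes),
              length(x$below_units), length(x$below_genes)))
  invisible(x)
}

#' Cross-species control for 3'UTR length
#'
#' Each species' CNV-gene UTR lengths are divided by that species' all-gene
#' mean UTR length; a Kruskal-Wallis omnibus test compares the normalised
#' CNV UTR lengths across species. Species contributing fewer than two CNV
#' UTRs are excluded with a warning.
#'
#' @param genes gene data.frame with `species`, `cnv_status` and `utr`
#'   sequences (lengths are taken as `nchar(utr)`).
#' @return list with `per_species` (data.frame: species, n, norm_mean_cnv),
#'   `p_value` (Kruskal-Wallis, NA when fewer than two species remain) and
#'   `method`.
#' @export
utr_length_comparison <- function(genes) {
  g <- genes[!is.na(genes$utr), , drop = FALSE]
  sp_all <- unique(g$species)
  vals <- list()
  per <- list()
  for (sp in sp_all) {
    gs <- g[g$species == sp, ]
    denom <- mean(nchar(gs$utr))
    cnv_len <- nchar(gs$utr[gs$cnv_status == "CNV"])
    if (length(cnv_len) < 2 || !is.finite(denom) || denom == 0) {
      warning(sprintf("species %s excluded from UTR-length control (%d CNV UTRs)",
                      sp, length(cnv_len)), call. = FALSE)
      next
    }
    norm <- cnv_len / denom
    vals[[sp]] <- norm
    per[[sp]] <- data.frame(species = sp, n = length(norm),
                            norm_mean_cnv = mean(norm),
                            stringsAsFactors = FALSE)
  }
  per_species <- if (length(per) > 0) do.call(rbind, per) else
    data.frame(species = character(0), n = integer(0),
               norm_mean_cnv = numeric(0), stringsAsFactors = FALSE)
  rownames(per_species) <- NULL
  if (length(vals) < 2) {
    warning("fewer than two species with >= 2 CNV UTRs; omnibus p is NA",
            call. = FALSE)
    return(list(per_species = per_species, p_value = NA_real_,
                method = "Kruskal-Wallis"))
  }
  x <- unlist(vals, use.names = FALSE)
  f <- factor(rep(names(vals), vapply(vals, length, integer(1))))
  kw <- kruskal.test(x, f)
  list(per_species = per_species, p_value = unname(kw$p.value),
       method = "Kruskal-Wallis")
}
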