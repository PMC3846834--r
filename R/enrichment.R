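# Gene-set enrichment of the above/below-mean gene lists (one-sided
# Fisher's exact test with Benjamini-Hochberg correction at 5%), curated
# gene-class tallies, and binding-site overrepresentation analysis.

#' One-sided Fisher's exact test for enrichment
#'
#' Hypergeometric upper-tail probability `P(X >= a)` with all margins fixed,
#' for the 2x2 table (a = in-list & in-set, b = in-list & not, c = not-list
#' & in-set, d = neither).
#'
#' @param a,b,c,d non-negative cell counts (vectorised).
#' @return raw p-value(s) in (0, 1].
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative counts", call. = FALSE)
  if (any(a + b + c + d < 1)) stop("empty table", call. = FALSE)
  # margins: list size a+b drawn from a population with K = a+c successes
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement (cumulative minimum from the
#' largest rank); output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Gene-set enrichment of a gene list against a background
#'
#' One result per set intersecting the background; `significant` flags
#' BH-adjusted p at or below `alpha`. The universe is either the supplied
#' background restricted to genes annotated to at least one set (default,
#' `"annotated"`) or the full background (`"all"`).
#'
#' @param gene_list character vector of genes of interest (subset of
#'   `background`; genes outside it are dropped with a warning).
#' @param background character vector: the candidate gene universe.
#' @param collection named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param universe `"annotated"` or `"all"` (see above).
#' @return data.frame with columns `set_id`, `a`, `b`, `c`, `d`, `p_raw`,
#'   `p_adj`, `significant`, ordered by `p_adj`; the number of significant
#'   sets is attached as attribute `n_significant`.
#' @export
pathway_enrichment <- function(gene_list, background, collection,
                               alpha = 0.05,
                               universe = c("annotated", "all")) {
  universe <- match.arg(universe)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  if (length(collection) == 0) stop("empty collection", call. = FALSE)
  background <- unique(background)
  bad <- setdiff(gene_list, background)
  if (length(bad) > 0) {
    warning(sprintf("%d gene(s) of the list are outside the background; dropped",
                    length(bad)), call. = FALSE)
  }
  if (universe == "annotated") {
    annotated <- unique(unlist(collection, use.names = FALSE))
    background <- intersect(background, annotated)
    if (length(background) == 0) stop("no background gene is annotated",
                                      call. = FALSE)
  }
  gene_list <- unique(intersect(gene_list, background))
  n_bg <- length(background)
  n_list <- length(gene_list)
  rows <- lapply(sort(names(collection)), function(set_id) {
    set_bg <- intersect(collection[[set_id]], background)
    if (length(set_bg) == 0) return(NULL)
    a <- length(intersect(gene_list, set_bg))
    b <- n_list - a
    c_ <- length(set_bg) - a
    d <- n_bg - a - b - c_
    data.frame(set_id = set_id, a = a, b = b, c = c_, d = d,
               p_raw = fisher_exact_greater(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(set_id = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_significant") <- 0L
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$set_id), ]
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  out
}

#' Significance matrix of gene sets across species
#'
#' Builds the set x species matrix over the union of significant sets, plus
#' the report of sets significant in the focal species and in no other.
#'
#' @param results_by_species named list (species -> [pathway_enrichment()]
#'   result).
#' @param value `"binary"` (0/1 significance indicators) or `"neglog10"`
#'   (-log10 adjusted p).
#' @param focal_species species for the specific-set report (default
#'   `"human"`; falls back to the first species).
#' @return list with `matrix` (sets x species) and `specific_sets`
#'   (character vector).
#' @export
heatmap_matrix <- function(results_by_species, value = c("binary",
                                                         "neglog10"),
                           focal_species = "human") {
  value <- match.arg(value)
  if (length(results_by_species) == 0) stop("no species results",
                                            call. = FALSE)
  if (!focal_species %in% names(results_by_species)) {
    focal_species <- names(results_by_species)[1]
  }
  sig_sets <- sort(unique(unlist(lapply(results_by_species, function(r) {
    r$set_id[r$significant]
  }), use.names = FALSE)))
  sp <- names(results_by_species)
  m <- matrix(0, nrow = length(sig_sets), ncol = length(sp),
              dimnames = list(sig_sets, sp))
  for (s in sp) {
    r <- results_by_species[[s]]
    idx <- match(sig_sets, r$set_id)
    if (value == "binary") {
      m[, s] <- as.numeric(!is.na(idx) & r$significant[idx])
    } else {
      padj <- ifelse(is.na(idx), 1, r$p_adj[idx])
      m[, s] <- -log10(pmax(padj, .Machine$double.xmin))
    }
  }
  sig_in <- lapply(results_by_species, function(r) r$set_id[r$significant])
  focal_sig <- sig_in[[focal_species]]
  others <- unlist(sig_in[setdiff(sp, focal_species)], use.names = FALSE)
  specific <- sort(setdiff(focal_sig, others))
  list(matrix = m, specific_sets = specific)
}

#' Tally CNV / non-CNV genes per curated class
#'
#' A gene belonging to several classes is counted once in each class
#' (multi-membership allowed, so class totals may exceed gene totals).
#' Class members absent from the atlas are skipped with a logged count.
#'
#' @param atlas_genes data.frame with `species`, `gene_id`, `cnv_status`
#'   (e.g. [atlas_to_frame()] output).
#' @param classes named list of gene-id vectors.
#' @return data.frame: `species`, `class`, `n_cnv`, `n_noncnv`.
#' @export
classify_genes <- function(atlas_genes, classes) {
  species <- unique(atlas_genes$species)
  known <- unique(atlas_genes$gene_id)
  unknown <- length(setdiff(unique(unlist(classes, use.names = FALSE)),
                            known))
  if (unknown > 0) {
    message(sprintf("[mircnv] %d class member id(s) not in atlas; skipped",
                    unknown))
  }
  rows <- list()
  for (sp in species) {
    g <- atlas_genes[atlas_genes$species == sp, ]
    for (cl in names(classes)) {
      members <- intersect(classes[[cl]], g$gene_id)
      st <- g$cnv_status[match(members, g$gene_id)]
      if (length(members) == 0) {
        warning(sprintf("class %s has no member in species %s", cl, sp),
                call. = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(species = sp, class = cl,
                   n_cnv = sum(st == "CNV"), n_noncnv = sum(st == "nonCNV"),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binding-site overrepresentation between two gene groups
#'
#' Compares per-gene binding-site density (site count / UTR length) between
#' member and non-member genes. The default variant is a one-sided
#' rank-sum test (members greater); `"fisher_threshold"` dichotomises
#' densities at the pooled median and applies [fisher_exact_greater()].
#'
#' @param sites site-level data.frame (`gene_id`, one row per site).
#' @param member_genes,nonmember_genes character vectors of gene ids; genes
#'   without sites count a density of zero.
#' @param utr_lengths named numeric vector of UTR lengths (nt) for all
#'   genes involved.
#' @param variant `"ranksum"` or `"fisher_threshold"`.
#' @return one-sided p-value (NA with a warning for degenerate groups).
#' @export
binding_site_ora <- function(sites, member_genes, nonmember_genes,
                             utr_lengths,
                             variant = c("ranksum", "fisher_threshold")) {
  variant <- match.arg(variant)
  if (length(member_genes) < 2 || length(nonmember_genes) < 2) {
    warning("group with fewer than 2 genes; ORA p is NA", call. = FALSE)
    return(NA_real_)
  }
  density_of <- function(g) {
    cnt <- table(factor(sites$gene_id[sites$gene_id %in% g], levels = g))
    len <- utr_lengths[g]
    as.numeric(cnt) / as.numeric(len)
  }
  dm <- density_of(member_genes)
  dn <- density_of(nonmember_genes)
  if (anyNA(c(dm, dn))) {
    warning("missing UTR length for some genes; ORA p is NA", call. = FALSE)
    return(NA_real_)
  }
  if (stats::var(c(dm, dn)) == 0) {
    warning("zero variance in binding-site densities; ORA p is NA",
            call. = FALSE)
    return(NA_real_)
  }
  if (variant == "ranksum") {
    suppressWarnings(
      wilcox.test(dm, dn, alternative = "greater", exact = FALSE)$p.value
    )
  } else {
    thr <- stats::median(c(dm, dn))
    a <- sum(dm > thr); b <- sum(dm <= thr)
    c_ <- sum(dn > thr); d <- sum(dn <= thr)
    fisher_exact_greater(a, b, c_, d)
  }
}

#' Binding-site overrepresentation across a gene-set collection
#'
#' Runs [binding_site_ora()] for every set (members = set genes within
#' `genes`, non-members = remaining `genes`) and BH-adjusts across sets.
#'
#' @param sites site-level data.frame (`gene_id`, one row per site).
#' @param genes character vector: the gene stratum analysed (typically the
#'   CNV genes of one species).
#' @param collection named list of gene-id vectors.
#' @param utr_lengths named numeric vector of UTR lengths for `genes`.
#' @param variant passed to [binding_site_ora()].
#' @return data.frame: `set_id`, `n_members`, `p_raw`, `p_adj`.
#' @export
ora_gene_sets <- function(sites, genes, collection, utr_lengths,
                          variant = c("ranksum", "fisher_threshold")) {
  variant <- match.arg(variant)
  rows <- lapply(sort(names(collection)), function(set_id) {
    members <- intersect(collection[[set_id]], genes)
    nonmembers <- setdiff(genes, members)
    p <- suppressWarnings(
      binding_site_ora(sites, members, nonmembers, utr_lengths,
                       variant = variant))
    data.frame(set_id = set_id, n_members = length(members), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # degenerate sets (NA p) do not count towards the number of tests
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adj[ok] <- bh_adjust(out$p_raw[ok])
  rownames(out) <- NULL
  out
}
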