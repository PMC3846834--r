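# miRNA binding-site prediction in 3'UTRs with two independent,
# deterministic algorithms, intersected at the (miRNA, gene) pair level.
#
# Predictor 1 ("seed"): canonical seed-match site types. With the seed
# defined as miRNA nucleotides 2-8, a site is
#   8mer     reverse-complement(positions 2-8) followed by A,
#   7mer-m8  reverse-complement(positions 2-8),
#   7mer-A1  reverse-complement(positions 2-7) followed by A,
# longest-type-wins at a locus (an 8mer suppresses the nested 7mers).
#
# Predictor 2 ("walk"): for each UTR locus, the longest run of consecutive
# Watson-Crick pairs (G:C, A:U only, no wobble) of the miRNA 5' end,
# anchored at miRNA position 1 or 2; a walk-k site is emitted when
# k >= min_len (default 7). Both are documented stand-ins for published
# web-resource predictors, which are external services; real prediction
# tables can be injected with read_predictions().

# starts of pattern `p` in each element of `utrs`, including overlapping
# occurrences (periodic sites can self-overlap); 1-based. Patterns are
# plain ACGU strings, so embedding them in a lookahead is safe.
match_starts <- function(p, utrs) {
  g <- gregexpr(paste0("(?=", p, ")"), utrs, perl = TRUE, useBytes = TRUE)
  n <- vapply(g, function(x) if (x[1] == -1L) 0L else length(x), integer(1))
  list(utr = rep(seq_along(utrs), n),
       start = as.integer(unlist(lapply(g, function(x) {
         if (x[1] == -1L) integer(0) else x
       }), use.names = FALSE)))
}

check_utrs <- function(utrs) {
  for (i in seq_along(utrs)) {
    bad <- first_non_acgu(utrs[i])
    if (bad > 0L) {
      stop(sprintf("non-ACGU character in UTR %s at offset %d",
                   if (!is.null(names(utrs))) names(utrs)[i] else i,
                   bad - 1L), call. = FALSE)
    }
  }
  invisible(utrs)
}

mature_of <- function(mirna) {
  if (is.character(mirna)) mirna[[1]] else mirna$mature_seq[[1]]
}

#' miRNA seed family key
#'
#' miRNAs sharing nucleotides 2-8 (1-based, inclusive) of the mature
#' sequence form one family; the key is independent of position 1.
#'
#' @param mature_seq mature miRNA sequence(s), 5'->3' RNA (vectorised).
#' @return 7-nt family key(s).
#' @export
mirna_family <- function(mature_seq) {
  if (any(nchar(mature_seq) < 8)) {
    stop("mature sequence shorter than 8 nt", call. = FALSE)
  }
  substr(mature_seq, 2, 8)
}

empty_sites <- function() {
  data.frame(utr = integer(0), utr_offset = integer(0),
             site_type = character(0), length = integer(0),
             source = character(0), stringsAsFactors = FALSE)
}

# Seed-type sites of one miRNA across a vector of UTRs (0-based offsets).
scan_seed <- function(mature, utrs) {
  seed7 <- substr(mature, 2, 8)
  rc7 <- rna_revcomp(seed7)
  p8 <- paste0(rc7, "A")
  p7a1 <- paste0(rna_revcomp(substr(mature, 2, 7)), "A")

  m8 <- match_starts(p8, utrs)
  k8 <- paste(m8$utr, m8$start)
  m7 <- match_starts(rc7, utrs)
  keep7 <- !(paste(m7$utr, m7$start) %in% k8)
  ma1 <- match_starts(p7a1, utrs)
  # the 7mer-A1 at s is nested in an 8mer starting one base 5' of it
  keepa1 <- !(paste(ma1$utr, ma1$start - 1L) %in% k8)

  out <- data.frame(
    utr = c(m8$utr, m7$utr[keep7], ma1$utr[keepa1]),
    utr_offset = c(m8$start - 1L, m7$start[keep7] - 1L,
                   ma1$start[keepa1] - 1L),
    site_type = c(rep("8mer", length(m8$utr)),
                  rep("7mer-m8", sum(keep7)),
                  rep("7mer-A1", sum(keepa1))),
    length = c(rep(8L, length(m8$utr)), rep(7L, sum(keep7)),
               rep(7L, sum(keepa1))),
    source = rep("seed", length(m8$utr) + sum(keep7) + sum(keepa1)),
    stringsAsFactors = FALSE
  )
  out[order(out$utr, out$utr_offset, out$site_type), , drop = FALSE]
}

# Walk sites of one miRNA across a vector of UTRs. Candidate loci are exact
# matches of the reverse complement of the miRNA's first `min_len` bases
# (anchor 1) or bases 2..(min_len+1) (anchor 2); each candidate is extended
# 5'-ward in the UTR to the maximal complementary run, and runs contained in
# a longer reported run collapse onto it.
scan_walk <- function(mature, utrs, min_len = 7L) {
  min_len <- as.integer(min_len)
  if (min_len < 5L) stop("min_len must be >= 5", call. = FALSE)
  n <- nchar(mature)
  mchars <- strsplit(mature, "", fixed = TRUE)[[1]]
  compchars <- chartr("ACGU", "UGCA", mchars)
  hits <- list()
  for (a in c(1L, 2L)) {
    if (n < a + min_len - 1L) next
    core <- rna_revcomp(substr(mature, a, a + min_len - 1L))
    m <- match_starts(core, utrs)
    if (length(m$utr) == 0L) next
    off <- integer(length(m$utr)); len <- integer(length(m$utr))
    for (j in seq_along(m$utr)) {
      s <- m$start[j]; k <- min_len
      utr <- utrs[[m$utr[j]]]
      while (s > 1L && a + k <= n &&
             substr(utr, s - 1L, s - 1L) == compchars[a + k]) {
        s <- s - 1L; k <- k + 1L
      }
      off[j] <- s - 1L; len[j] <- k
    }
    hits[[length(hits) + 1L]] <-
      data.frame(utr = m$utr, utr_offset = off, length = len,
                 stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty_sites())
  d <- unique(do.call(rbind, hits))
  # collapse runs strictly contained in a longer run of the same UTR
  d <- d[order(d$utr, -d$length, d$utr_offset), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    same <- which(d$utr == d$utr[i] & keep & seq_len(nrow(d)) > i)
    if (length(same) == 0L) next
    contained <- d$utr_offset[same] >= d$utr_offset[i] &
      (d$utr_offset[same] + d$length[same]) <=
        (d$utr_offset[i] + d$length[i]) &
      d$length[same] < d$length[i]
    keep[same[contained]] <- FALSE
  }
  d <- d[keep, , drop = FALSE]
  out <- data.frame(utr = d$utr, utr_offset = d$utr_offset,
                    site_type = paste0("walk-", d$length),
                    length = d$length, source = "walk",
                    stringsAsFactors = FALSE)
  out[order(out$utr, out$utr_offset), , drop = FALSE]
}

#' Predict canonical seed-match sites of one miRNA in one UTR
#'
#' Reports every 8mer, 7mer-m8 and 7mer-A1 occurrence (see the site-type
#' definitions in the package description); when an 8mer occurs, the nested
#' 7mers at the same locus are suppressed. Offsets are 0-based.
#'
#' @param mirna mature miRNA sequence (character) or a list/row with a
#'   `mature_seq` field; at least 8 nt.
#' @param utr UTR sequence, 5'->3' RNA.
#' @return data.frame with columns `utr_offset`, `site_type`, `length`,
#'   sorted by offset.
#' @export
predict_seed_sites <- function(mirna, utr) {
  mature <- mature_of(mirna)
  if (nchar(mature) < 8L) stop("mature sequence shorter than 8 nt",
                               call. = FALSE)
  stop_if_not_rna(mature, "miRNA sequence")
  check_utrs(utr)
  out <- scan_seed(mature, utr)
  out$utr <- NULL
  rownames(out) <- NULL
  out[, c("utr_offset", "site_type", "length")]
}

#' Predict longest-complementarity (walk) sites of one miRNA in one UTR
#'
#' For each UTR locus the longest run of consecutive Watson-Crick pairs
#' (G:C and A:U only) of the miRNA 5' end is computed, anchored at miRNA
#' position 1 or 2; a `walk-k` site is reported when the run length `k` is
#' at least `min_len`, and runs contained in a longer reported run collapse
#' onto it. Offsets are 0-based.
#'
#' @inheritParams predict_seed_sites
#' @param min_len minimum run length reported (default 7, the published
#'   default of the algorithm this stands in for; must be >= 5).
#' @return data.frame with columns `utr_offset`, `site_type`, `length`.
#' @export
predict_walk_sites <- function(mirna, utr, min_len = 7L) {
  mature <- mature_of(mirna)
  stop_if_not_rna(mature, "miRNA sequence")
  check_utrs(utr)
  out <- scan_walk(mature, utr, min_len = min_len)
  out$utr <- NULL
  rownames(out) <- NULL
  out[, c("utr_offset", "site_type", "length")]
}

pair_key <- function(df) paste(df$mirna_id, df$gene_id, df$species,
                               sep = "\r")

#' Intersect the predictions of the two algorithms at pair level
#'
#' Returns exactly the (miRNA, gene, species) pairs present in both inputs;
#' each retained pair carries the union of its binding sites from both
#' predictors (deduplicated on offset and site type) and
#' `predicted_by = "walk+seed"`.
#'
#' @param walk_sites,seed_sites site-level data.frames with columns
#'   `mirna_id`, `gene_id`, `species`, `utr_offset`, `site_type`, `length`
#'   (a `source` column is added/overwritten).
#' @return list with `pairs` (data.frame: mirna_id, gene_id, species,
#'   n_sites, predicted_by) and `sites` (site rows of retained pairs).
#' @export
intersect_predictions <- function(walk_sites, seed_sites) {
  sw <- unique(walk_sites$species)
  ss <- unique(seed_sites$species)
  if (length(sw) > 0 && length(ss) > 0 &&
      !setequal(sw, ss)) {
    stop("species mismatch between prediction lists: ",
         paste(sort(sw), collapse = ","), " vs ",
         paste(sort(ss), collapse = ","), call. = FALSE)
  }
  walk_sites$source <- rep("walk", nrow(walk_sites))
  seed_sites$source <- rep("seed", nrow(seed_sites))
  common <- intersect(unique(pair_key(walk_sites)),
                      unique(pair_key(seed_sites)))
  cols <- c("mirna_id", "gene_id", "species", "utr_offset", "site_type",
            "length", "source")
  sites <- rbind(walk_sites[pair_key(walk_sites) %in% common, cols],
                 seed_sites[pair_key(seed_sites) %in% common, cols])
  sites <- sites[!duplicated(sites[, c("mirna_id", "gene_id", "species",
                                       "utr_offset", "site_type")]), ]
  sites <- sites[order(sites$species, sites$gene_id, sites$mirna_id,
                       sites$utr_offset, sites$site_type), ]
  rownames(sites) <- NULL
  if (length(common) > 0) {
    key <- pair_key(sites)
    cnt <- table(key)
    parts <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    pairs <- data.frame(mirna_id = parts[, 1], gene_id = parts[, 2],
                        species = parts[, 3],
                        n_sites = as.integer(cnt),
                        predicted_by = "walk+seed",
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$species, pairs$gene_id, pairs$mirna_id), ]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(mirna_id = character(0), gene_id = character(0),
                        species = character(0), n_sites = integer(0),
                        predicted_by = character(0),
                        stringsAsFactors = FALSE)
  }
  list(pairs = pairs, sites = sites)
}

#' Collapse miRNA-level pairs to family-level pairs
#'
#' A family targets a gene iff at least one member miRNA does.
#'
#' @param pairs pair data.frame with `mirna_id`, `gene_id`, `species`.
#' @param mirnas miRNA catalog with `mirna_id` and `family_key` (or
#'   `mature_seq`, from which families are derived).
#' @return data.frame with `family_key`, `gene_id`, `species`.
#' @export
collapse_families <- function(pairs, mirnas) {
  if (!"family_key" %in% names(mirnas)) {
    mirnas$family_key <- mirna_family(mirnas$mature_seq)
  }
  fam <- mirnas$family_key[match(pairs$mirna_id, mirnas$mirna_id)]
  out <- unique(data.frame(family_key = fam, gene_id = pairs$gene_id,
                           species = pairs$species,
                           stringsAsFactors = FALSE))
  out <- out[order(out$species, out$gene_id, out$family_key), ]
  rownames(out) <- NULL
  out
}

#' Run both predictors over a gene stratum and intersect
#'
#' Scans every (miRNA, gene) combination for the requested species and CNV
#' stratum with the seed and walk predictors, intersects at pair level, and
#' additionally collapses miRNA-level pairs to family-level pairs.
#'
#' @param mirnas miRNA catalog data.frame (`mirna_id`, `mature_seq`, and
#'   optionally `family_key`).
#' @param genes gene data.frame with `gene_id`, `species`, `cnv_status`,
#'   `utr`.
#' @param species species to scan (default: all present in `genes`).
#' @param stratum `"CNV"`, `"nonCNV"` or `"all"` (default `"CNV"`, the
#'   stratum the downstream analysis consumes).
#' @param min_len minimum walk run length.
#' @return list with `pairs`, `sites`, `family_pairs`, `n_mirnas`, and
#'   `genes_scanned` (data.frame: species, n_genes).
#' @export
predict_all <- function(mirnas, genes, species = NULL, stratum = "CNV",
                        min_len = 7L) {
  if (is.null(species)) species <- unique(genes$species)
  keep <- genes$species %in% species
  if (stratum != "all") keep <- keep & genes$cnv_status == stratum
  g <- genes[keep & !is.na(genes$utr), , drop = FALSE]
  all_sites <- vector("list", length(species) * max(1L, nrow(mirnas)))
  k <- 0L
  for (sp in species) {
    gs <- g[g$species == sp, , drop = FALSE]
    if (nrow(gs) == 0L) next
    utrs <- gs$utr
    check_utrs(setNames(utrs, gs$gene_id))
    for (i in seq_len(nrow(mirnas))) {
      s1 <- scan_seed(mirnas$mature_seq[i], utrs)
      s2 <- scan_walk(mirnas$mature_seq[i], utrs, min_len = min_len)
      s <- rbind(s1, s2)
      if (nrow(s) == 0L) next
      s$mirna_id <- mirnas$mirna_id[i]
      s$gene_id <- gs$gene_id[s$utr]
      s$species <- sp
      k <- k + 1L
      all_sites[[k]] <- s[, c("mirna_id", "gene_id", "species",
                              "utr_offset", "site_type", "length",
                              "source")]
    }
  }
  sites <- if (k > 0) do.call(rbind, all_sites[seq_len(k)]) else
    cbind(data.frame(mirna_id = character(0), gene_id = character(0),
                     species = character(0), stringsAsFactors = FALSE),
          empty_sites()[, c("utr_offset", "site_type", "length", "source")])
  # intersect within each species: a predictor finding nothing for one
  # species is an empty list there, not a species mismatch
  if (length(species) == 0L) {
    e <- sites[0, , drop = FALSE]
    per_sp <- list(intersect_predictions(e, e))
  } else per_sp <- lapply(species, function(sp) {
    s <- sites[sites$species == sp, , drop = FALSE]
    intersect_predictions(s[s$source == "walk", , drop = FALSE],
                          s[s$source == "seed", , drop = FALSE])
  })
  res <- list(
    pairs = do.call(rbind, c(lapply(per_sp, `[[`, "pairs"),
                             list(make.row.names = FALSE))),
    sites = do.call(rbind, c(lapply(per_sp, `[[`, "sites"),
                             list(make.row.names = FALSE)))
  )
  # canonical order, independent of the species scan order
  res$pairs <- res$pairs[order(res$pairs$species, res$pairs$gene_id,
                               res$pairs$mirna_id), ]
  rownames(res$pairs) <- NULL
  res$sites <- res$sites[order(res$sites$species, res$sites$gene_id,
                               res$sites$mirna_id, res$sites$utr_offset,
                               res$sites$site_type), ]
  rownames(res$sites) <- NULL
  fam <- collapse_families(res$pairs, mirnas)
  scanned <- do.call(rbind, lapply(species, function(sp) {
    data.frame(species = sp, n_genes = sum(g$species == sp),
               stringsAsFactors = FALSE)
  }))
  list(pairs = res$pairs, sites = res$sites, family_pairs = fam,
       n_mirnas = nrow(mirnas), genes_scanned = scanned)
}
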