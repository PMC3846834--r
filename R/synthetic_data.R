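# Synthetic multi-species cohort generator. Emulates the data regime the
# analysis assumes -- homologous gene groups across species, per-species CNV
# region assignment, random-nucleotide 3'UTRs with canonical 8mer seed sites
# planted at configurable per-(species, CNV-status) rates, a miRNA catalog
# with seed families and genomic placement, and pathway / gene-class
# collections with planted enrichment -- together with a complete truth
# record, so every downstream stage is testable without external databases.

CANONICAL_SPECIES <- c("human", "chimpanzee", "macaque", "mouse", "rat",
                       "chicken", "dog", "cow")

GENE_CLASS_NAMES <- c("cell_differentiation", "cytokines_growth_factors",
                      "homeodomain", "oncogene", "kinases",
                      "transcription_factors")

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the package's simulations run
#' under: eight species, homologous gene groups anchored on human, a human
#' CNV planted-site excess, a small set of prolific miRNAs that carry most
#' of the planted-site mass (this is what couples planted pathways to the
#' realized above-mean partition), pathways with a planted "above"
#' enrichment, and a CNV bias for intragenic miRNA placement.
#'
#' `planted_site_rate` is a named numeric vector of expected planted 8mer
#' sites per gene; names are `"<species>.<CNV|nonCNV>"` with a `"default"`
#' fallback for unnamed cells.
#'
#' @param n_species number of species (first `n` of human, chimpanzee,
#'   macaque, mouse, rat, chicken, dog, cow).
#' @param n_homology_groups number of homologous gene groups (all present in
#'   human).
#' @param cnv_fraction_per_species fraction of each species' genes placed in
#'   CNV regions (scalar, recycled, or named by species).
#' @param n_mirnas number of miRNAs in the catalog.
#' @param utr_length_mean,utr_length_sd 3'UTR length distribution in nt
#'   (normal, truncated at 30).
#' @param planted_site_rate named numeric vector of Poisson rates (see
#'   Details).
#' @param n_prolific_mirnas number of miRNAs carrying most planted sites.
#' @param prolific_site_share probability a planted site is assigned to a
#'   prolific miRNA.
#' @param n_pathways number of pathway gene sets (including planted ones).
#' @param pathway_size_range integer range of pathway sizes.
#' @param planted_enriched_pathways data.frame with columns `pathway_id`,
#'   `target` (`"above"` or `"below"`) and `excess` (fraction of members
#'   drawn from the expected target gene pool).
#' @param n_gene_classes number of curated gene classes.
#' @param class_size_range integer range of class sizes.
#' @param host_mirna_cnv_bias probability an intragenic miRNA is placed in a
#'   CNV gene.
#' @param intragenic_fraction fraction of miRNAs placed inside a gene span.
#' @param mirna_length_range mature miRNA length range in nt.
#' @param ortholog_presence probability a non-human species carries a given
#'   homology group.
#' @param rng_seed integer seed; fixes the cohort byte-for-byte.
#' @param species optional explicit species names (overrides the canonical
#'   list; length must equal `n_species`).
#' @return an object of class `mircnv_config` (a validated list).
#' @export
synthetic_config <- function(n_species = 8L,
                             n_homology_groups = 300L,
                             cnv_fraction_per_species = 0.5,
                             n_mirnas = 30L,
                             utr_length_mean = 250,
                             utr_length_sd = 50,
                             planted_site_rate = c(human.CNV = 1.0,
                                                   default = 0.3),
                             n_prolific_mirnas = 3L,
                             prolific_site_share = 0.7,
                             n_pathways = 20L,
                             pathway_size_range = c(20L, 40L),
                             planted_enriched_pathways = data.frame(
                               pathway_id = paste0("PWP", 1:3),
                               target = "above",
                               excess = 0.9,
                               stringsAsFactors = FALSE),
                             n_gene_classes = 6L,
                             class_size_range = c(30L, 60L),
                             host_mirna_cnv_bias = 0.8,
                             intragenic_fraction = 0.6,
                             mirna_length_range = c(21L, 25L),
                             ortholog_presence = 0.92,
                             rng_seed = 1L,
                             species = NULL) {
  if (is.null(species)) {
    if (n_species > length(CANONICAL_SPECIES)) {
      species <- c(CANONICAL_SPECIES,
                   paste0("species",
                          seq_len(n_species - length(CANONICAL_SPECIES)) +
                            length(CANONICAL_SPECIES)))
    } else {
      species <- CANONICAL_SPECIES[seq_len(n_species)]
    }
  } else {
    species <- as.character(species)
    if (length(species) != n_species) {
      stop("length(species) must equal n_species", call. = FALSE)
    }
  }
  frac <- cnv_fraction_per_species
  if (is.null(names(frac))) {
    frac <- setNames(rep_len(frac, n_species), species)
  } else {
    miss <- setdiff(species, names(frac))
    if (length(miss) > 0) {
      stop("cnv_fraction_per_species lacks species: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    frac <- frac[species]
  }
  cfg <- structure(list(
    n_species = as.integer(n_species),
    species = species,
    n_homology_groups = as.integer(n_homology_groups),
    cnv_fraction_per_species = frac,
    n_mirnas = as.integer(n_mirnas),
    utr_length_mean = as.numeric(utr_length_mean),
    utr_length_sd = as.numeric(utr_length_sd),
    planted_site_rate = planted_site_rate,
    n_prolific_mirnas = as.integer(n_prolific_mirnas),
    prolific_site_share = as.numeric(prolific_site_share),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    planted_enriched_pathways = planted_enriched_pathways,
    n_gene_classes = as.integer(n_gene_classes),
    class_size_range = as.integer(class_size_range),
    host_mirna_cnv_bias = as.numeric(host_mirna_cnv_bias),
    intragenic_fraction = as.numeric(intragenic_fraction),
    mirna_length_range = as.integer(mirna_length_range),
    ortholog_presence = as.numeric(ortholog_presence),
    rng_seed = as.integer(rng_seed)
  ), class = "mircnv_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_species, cfg$n_homology_groups, cfg$n_mirnas,
              cfg$n_pathways, cfg$n_gene_classes)
  if (any(counts < 1L)) stop("all counts must be >= 1", call. = FALSE)
  fracs <- c(cfg$cnv_fraction_per_species, cfg$prolific_site_share,
             cfg$host_mirna_cnv_bias, cfg$intragenic_fraction,
             cfg$ortholog_presence)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must be in [0, 1]", call. = FALSE)
  }
  if (cfg$utr_length_mean < 30) {
    stop("utr_length_mean must be >= 30", call. = FALSE)
  }
  if (any(cfg$planted_site_rate < 0)) {
    stop("planted_site_rate values must be >= 0", call. = FALSE)
  }
  if (8 * max(cfg$planted_site_rate) > cfg$utr_length_mean) {
    stop("planted site length x expected sites exceeds UTR length; ",
         "cannot place sites without overlap", call. = FALSE)
  }
  if (cfg$n_prolific_mirnas > cfg$n_mirnas) {
    stop("n_prolific_mirnas must not exceed n_mirnas", call. = FALSE)
  }
  pep <- cfg$planted_enriched_pathways
  if (nrow(pep) > 0) {
    if (!all(pep$target %in% c("above", "below"))) {
      stop("planted pathway target must be 'above' or 'below'", call. = FALSE)
    }
    if (any(pep$excess < 0 | pep$excess > 1)) {
      stop("planted pathway excess must be in [0, 1]", call. = FALSE)
    }
    if (nrow(pep) > cfg$n_pathways) {
      stop("more planted pathways than n_pathways", call. = FALSE)
    }
  }
  invisible(cfg)
}

# Planted-site Poisson rate for one (species, status) cell.
rate_for <- function(cfg, species, status) {
  key <- paste0(species, ".", status)
  r <- cfg$planted_site_rate
  if (key %in% names(r)) return(unname(r[[key]]))
  if ("default" %in% names(r)) return(unname(r[["default"]]))
  0
}

# Uniformly choose `n` non-overlapping 0-based offsets for length-`w` sites
# within a sequence of length `len` (stars-and-bars bijection).
place_nonoverlapping <- function(n, w, len) {
  if (n == 0L) return(integer(0))
  slack <- len - n * w + n
  u <- sort(sample.int(slack, n))
  u + (seq_len(n) - 1L) * (w - 1L) - 1L
}

#' Generate a synthetic multi-species cohort
#'
#' Deterministic for a fixed `rng_seed`. UTRs are i.i.d. uniform A/C/G/U with
#' exact 8mer seed matches of catalog miRNAs overwritten at non-overlapping
#' offsets; per-gene planted-site counts are Poisson with the configured
#' per-(species, CNV status) rate. The returned `truth` element records every
#' planted site, the per-species CNV gene sets, the prolific miRNAs, the
#' planted pathways and the miRNA host-gene placements.
#'
#' @param config a [synthetic_config()] object.
#' @return an object of class `mircnv_cohort`: a list with elements `genes`
#'   (data.frame: gene_id, species, chrom, start, end, strand, cnv_status,
#'   utr), `homology`, `cnv_regions`, `mirnas`, `pathways`, `gene_classes`,
#'   `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$rng_seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  species <- config$species
  G <- config$n_homology_groups

  ## miRNA catalog
  mirna_ids <- sprintf("syn-miR-%03d", seq_len(config$n_mirnas))
  mirna_len <- sample(seq(config$mirna_length_range[1],
                          config$mirna_length_range[2]),
                      config$n_mirnas, replace = TRUE)
  mature <- random_rna(mirna_len)
  prolific <- sort(sample(mirna_ids, config$n_prolific_mirnas))
  mirnas <- data.frame(
    mirna_id = mirna_ids,
    mature_seq = mature,
    family_key = substr(mature, 2, 8),
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_,
    stringsAsFactors = FALSE
  )

  ## homology groups and per-species gene tables
  group_ids <- sprintf("HG%04d", seq_len(G))
  genes_list <- list()
  homology_list <- list()
  regions_list <- list()
  for (sp in species) {
    present <- if (sp == "human") rep(TRUE, G) else
      runif(G) < config$ortholog_presence
    gid <- sprintf("%s_%s", group_ids[present], sp)
    n <- length(gid)
    glen <- sample(2000:5000, n, replace = TRUE)
    gap <- sample(500:1500, n, replace = TRUE)
    start <- cumsum(c(0L, glen[-n] + gap[-n])) + gap[1]
    end <- start + glen
    n_cnv <- round(config$cnv_fraction_per_species[[sp]] * n)
    cnv_idx <- sort(sample.int(n, n_cnv))
    status <- rep("nonCNV", n)
    status[cnv_idx] <- "CNV"
    utr_len <- pmax(30L, as.integer(round(rnorm(n, config$utr_length_mean,
                                                config$utr_length_sd))))
    genes_list[[sp]] <- data.frame(
      gene_id = gid, species = sp, chrom = paste0("chr1_", sp),
      start = as.integer(start), end = as.integer(end),
      strand = sample(c("+", "-"), n, replace = TRUE),
      cnv_status = status,
      utr = random_rna(utr_len),
      stringsAsFactors = FALSE
    )
    homology_list[[sp]] <- data.frame(
      group_id = group_ids[present], species = sp, gene_id = gid,
      stringsAsFactors = FALSE
    )
    regions_list[[sp]] <- data.frame(
      species = sp, chrom = paste0("chr1_", sp),
      start = as.integer(start[cnv_idx] - 100L),
      end = as.integer(end[cnv_idx] + 100L),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL
  homology <- do.call(rbind, homology_list)
  rownames(homology) <- NULL
  cnv_regions <- do.call(rbind, regions_list)
  rownames(cnv_regions) <- NULL

  ## plant 8mer seed sites
  nonprolific <- setdiff(mirna_ids, prolific)
  rate <- mapply(function(sp, st) rate_for(config, sp, st),
                 genes$species, genes$cnv_status, USE.NAMES = FALSE)
  n_sites <- rpois(nrow(genes), rate)
  utr_len <- nchar(genes$utr)
  n_sites <- pmin(n_sites, utr_len %/% 8L)
  planted <- vector("list", sum(n_sites > 0))
  k <- 0L
  for (i in which(n_sites > 0L)) {
    c_i <- n_sites[i]
    offs <- place_nonoverlapping(c_i, 8L, utr_len[i])
    use_prolific <- runif(c_i) < config$prolific_site_share
    mids <- character(c_i)
    if (length(prolific) > 0) {
      mids[use_prolific] <- sample(prolific, sum(use_prolific), replace = TRUE)
    } else {
      use_prolific[] <- FALSE
    }
    mids[!use_prolific] <- sample(nonprolific, sum(!use_prolific),
                                  replace = TRUE)
    seed7 <- substr(mirnas$mature_seq[match(mids, mirnas$mirna_id)], 2, 8)
    site <- paste0(rna_revcomp(seed7), "A")
    utr <- genes$utr[i]
    for (j in seq_len(c_i)) {
      substr(utr, offs[j] + 1L, offs[j] + 8L) <- site[j]
    }
    genes$utr[i] <- utr
    k <- k + 1L
    planted[[k]] <- data.frame(
      species = genes$species[i], gene_id = genes$gene_id[i],
      mirna_id = mids, offset = as.integer(offs),
      stringsAsFactors = FALSE
    )
  }
  planted_sites <- if (k > 0) do.call(rbind, planted) else
    data.frame(species = character(0), gene_id = character(0),
               mirna_id = character(0), offset = integer(0),
               stringsAsFactors = FALSE)
  rownames(planted_sites) <- NULL

  ## pathways: planted ones draw `excess` of members from human genes
  ## expected to land on the above-mean side (>= 1 prolific planted site)
  human <- genes[genes$species == "human", ]
  human_cnv <- human$gene_id[human$cnv_status == "CNV"]
  prolific_hits <- unique(planted_sites$gene_id[
    planted_sites$species == "human" &
      planted_sites$mirna_id %in% prolific])
  above_pool <- intersect(human_cnv, prolific_hits)
  below_pool <- setdiff(human_cnv, above_pool)
  pep <- config$planted_enriched_pathways
  pathways <- list()
  if (nrow(pep) > 0) {
    for (i in seq_len(nrow(pep))) {
      size <- sample_range(config$pathway_size_range[1],
                           config$pathway_size_range[2])
      pool <- if (pep$target[i] == "above") above_pool else below_pool
      rest <- setdiff(human_cnv, pool)
      n_pool <- min(length(pool), round(pep$excess[i] * size))
      n_rest <- min(length(rest), size - n_pool)
      pathways[[pep$pathway_id[i]]] <-
        sort(c(sample(pool, n_pool), sample(rest, n_rest)))
    }
  }
  n_null <- config$n_pathways - nrow(pep)
  if (n_null > 0) {
    for (i in seq_len(n_null)) {
      size <- sample_range(config$pathway_size_range[1],
                           config$pathway_size_range[2])
      pathways[[sprintf("PW%03d", i)]] <-
        sort(sample(human$gene_id, min(size, nrow(human))))
    }
  }

  ## curated gene classes
  gene_classes <- list()
  class_names <- rep_len(GENE_CLASS_NAMES, config$n_gene_classes)
  if (config$n_gene_classes > length(GENE_CLASS_NAMES)) {
    class_names <- make.unique(class_names)
  }
  for (i in seq_len(config$n_gene_classes)) {
    size <- sample_range(config$class_size_range[1],
                         config$class_size_range[2])
    gene_classes[[class_names[i]]] <-
      sort(sample(human$gene_id, min(size, nrow(human))))
  }

  ## miRNA genomic placement on the human chromosome
  n_intra <- round(config$intragenic_fraction * config$n_mirnas)
  intra_idx <- sort(sample.int(config$n_mirnas, n_intra))
  hosted <- vector("list", n_intra)
  human_noncnv <- human$gene_id[human$cnv_status == "nonCNV"]
  for (j in seq_along(intra_idx)) {
    i <- intra_idx[j]
    in_cnv <- runif(1) < config$host_mirna_cnv_bias
    pool <- if (in_cnv) human_cnv else human_noncnv
    if (length(pool) == 0) pool <- if (in_cnv) human_noncnv else human_cnv
    if (length(pool) == 0) next
    host <- sample1(pool)
    h <- human[human$gene_id == host, ]
    mstart <- h$start + sample.int(h$end - h$start - 80L, 1)
    mirnas$chrom[i] <- h$chrom
    mirnas$start[i] <- as.integer(mstart)
    mirnas$end[i] <- as.integer(mstart + 80L)
    mirnas$strand[i] <- sample(c("+", "-"), 1)
    hosted[[j]] <- data.frame(
      mirna_id = mirnas$mirna_id[i], host_gene_id = host,
      host_cnv_status = h$cnv_status, stringsAsFactors = FALSE
    )
  }
  # intergenic miRNAs sit in inter-gene gaps, clear of the +/-100 nt CNV
  # region margins
  inter_idx <- setdiff(seq_len(config$n_mirnas), intra_idx)
  if (length(inter_idx) > 0) {
    hgenes <- human[order(human$start), ]
    gap_after <- which(c(hgenes$start[-1], Inf) - hgenes$end > 400)
    for (i in inter_idx) {
      g <- sample1(gap_after)
      mstart <- hgenes$end[g] + 200L
      mirnas$chrom[i] <- hgenes$chrom[1]
      mirnas$start[i] <- as.integer(mstart)
      mirnas$end[i] <- as.integer(mstart + 80L)
      mirnas$strand[i] <- sample(c("+", "-"), 1)
    }
  }
  hosted_mirnas <- if (n_intra > 0) do.call(rbind, hosted) else
    data.frame(mirna_id = character(0), host_gene_id = character(0),
               host_cnv_status = character(0), stringsAsFactors = FALSE)
  rownames(hosted_mirnas) <- NULL

  truth <- list(
    planted_sites = planted_sites,
    cnv_genes = data.frame(species = genes$species[genes$cnv_status == "CNV"],
                           gene_id = genes$gene_id[genes$cnv_status == "CNV"],
                           stringsAsFactors = FALSE),
    prolific_mirnas = prolific,
    planted_pathways = pep,
    above_pool = sort(above_pool),
    hosted_mirnas = hosted_mirnas
  )
  structure(list(genes = genes, homology = homology,
                 cnv_regions = cnv_regions, mirnas = mirnas,
                 pathways = pathways, gene_classes = gene_classes,
                 truth = truth, config = config),
            class = "mircnv_cohort")
}

#' @export
print.mircnv_cohort <- function(x, ...) {
  cat("mircnv synthetic cohort\n")
  cat(sprintf("  species: %s\n", paste(x$config$species, collapse = ", ")))
  cat(sprintf("  genes: %d   miRNAs: %d   pathways: %d   classes: %d\n",
              nrow(x$genes), nrow(x$mirnas), length(x$pathways),
              length(x$gene_classes)))
  cat(sprintf("  planted sites: %d\n", nrow(x$truth$planted_sites)))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits UTRs and mature miRNAs as FASTA, gene / miRNA / CNV-region
#' coordinates as BED6, the homology table as TSV, pathways and gene classes
#' as GMT, and the truth record plus generator configuration as JSON. The
#' files round-trip losslessly through [read_cohort()].
#'
#' @param cohort a `mircnv_cohort`.
#' @param out_dir output directory (created if missing).
#' @return data.frame manifest (file, md5), invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  genes <- cohort$genes
  utrs <- setNames(genes$utr, paste(genes$gene_id, genes$species))
  write_fasta(utrs, file.path(out_dir, "utrs.fasta"))
  mseqs <- setNames(cohort$mirnas$mature_seq,
                    paste(cohort$mirnas$mirna_id, "synthetic"))
  write_fasta(mseqs, file.path(out_dir, "mirnas.fasta"))
  for (sp in cohort$config$species) {
    g <- genes[genes$species == sp, ]
    write_bed(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                         name = g$gene_id, strand = g$strand,
                         stringsAsFactors = FALSE),
              file.path(out_dir, sprintf("genes_%s.bed", sp)))
    r <- cohort$cnv_regions[cohort$cnv_regions$species == sp, ]
    write_bed(data.frame(chrom = r$chrom, start = r$start, end = r$end,
                         name = sprintf("cnv_%s_%04d", sp, seq_len(nrow(r))),
                         strand = rep("*", nrow(r)),
                         stringsAsFactors = FALSE),
              file.path(out_dir, sprintf("cnv_regions_%s.bed", sp)))
  }
  m <- cohort$mirnas[!is.na(cohort$mirnas$chrom), ]
  write_bed(data.frame(chrom = m$chrom, start = m$start, end = m$end,
                       name = m$mirna_id, strand = m$strand,
                       stringsAsFactors = FALSE),
            file.path(out_dir, "mirnas.bed"))
  write_homology(cohort$homology, file.path(out_dir, "homology.tsv"))
  write_gmt(cohort$pathways, file.path(out_dir, "pathways.gmt"))
  write_gmt(cohort$gene_classes, file.path(out_dir, "gene_classes.gmt"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_lst <- unclass(cohort$config)
  # named atomic vectors serialise as bare arrays; keep the names
  cfg_lst$planted_site_rate <- as.list(cfg_lst$planted_site_rate)
  cfg_lst$cnv_fraction_per_species <-
    as.list(cfg_lst$cnv_fraction_per_species)
  jsonlite::write_json(cfg_lst, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}

config_from_list <- function(lst) {
  pep <- as.data.frame(lst$planted_enriched_pathways,
                       stringsAsFactors = FALSE)
  if (nrow(pep) == 0) {
    pep <- data.frame(pathway_id = character(0), target = character(0),
                      excess = numeric(0), stringsAsFactors = FALSE)
  }
  synthetic_config(
    n_species = lst$n_species,
    n_homology_groups = lst$n_homology_groups,
    cnv_fraction_per_species = unlist(lst$cnv_fraction_per_species),
    n_mirnas = lst$n_mirnas,
    utr_length_mean = lst$utr_length_mean,
    utr_length_sd = lst$utr_length_sd,
    planted_site_rate = unlist(lst$planted_site_rate),
    n_prolific_mirnas = lst$n_prolific_mirnas,
    prolific_site_share = lst$prolific_site_share,
    n_pathways = lst$n_pathways,
    pathway_size_range = unlist(lst$pathway_size_range),
    planted_enriched_pathways = pep,
    n_gene_classes = lst$n_gene_classes,
    class_size_range = unlist(lst$class_size_range),
    host_mirna_cnv_bias = lst$host_mirna_cnv_bias,
    intragenic_fraction = lst$intragenic_fraction,
    mirna_length_range = unlist(lst$mirna_length_range),
    ortholog_presence = lst$ortholog_presence,
    rng_seed = lst$rng_seed,
    species = lst$species
  )
}

empty_truth_df <- function(nm) {
  switch(nm,
    planted_sites = data.frame(species = character(0),
                               gene_id = character(0),
                               mirna_id = character(0), offset = integer(0),
                               stringsAsFactors = FALSE),
    cnv_genes = data.frame(species = character(0), gene_id = character(0),
                           stringsAsFactors = FALSE),
    planted_pathways = data.frame(pathway_id = character(0),
                                  target = character(0), excess = numeric(0),
                                  stringsAsFactors = FALSE),
    hosted_mirnas = data.frame(mirna_id = character(0),
                               host_gene_id = character(0),
                               host_cnv_status = character(0),
                               stringsAsFactors = FALSE)
  )
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `mircnv_cohort` equal field-by-field to the written one.
#' @export
read_cohort <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) {
    stop("not a cohort directory (config.json missing): ", dir,
         call. = FALSE)
  }
  config <- config_from_list(jsonlite::read_json(cfg_path,
                                                 simplifyVector = TRUE))
  utrs <- read_fasta(file.path(dir, "utrs.fasta"))
  utr_tab <- data.frame(
    gene_id = sub(" .*$", "", names(utrs)),
    utr = unname(utrs), stringsAsFactors = FALSE
  )
  genes_list <- list()
  regions_list <- list()
  for (sp in config$species) {
    b <- read_bed(file.path(dir, sprintf("genes_%s.bed", sp)))
    r <- read_bed(file.path(dir, sprintf("cnv_regions_%s.bed", sp)))
    g <- data.frame(gene_id = b$name, species = rep(sp, nrow(b)),
                    chrom = b$chrom, start = b$start, end = b$end,
                    strand = b$strand, stringsAsFactors = FALSE)
    reg <- data.frame(species = rep(sp, nrow(r)), chrom = r$chrom,
                      start = r$start, end = r$end, stringsAsFactors = FALSE)
    g <- assign_cnv_status(g, reg)
    g$utr <- utr_tab$utr[match(g$gene_id, utr_tab$gene_id)]
    genes_list[[sp]] <- g
    regions_list[[sp]] <- reg
  }
  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "species", "chrom", "start", "end", "strand",
                     "cnv_status", "utr")]
  cnv_regions <- do.call(rbind, regions_list)
  rownames(cnv_regions) <- NULL

  mseqs <- read_fasta(file.path(dir, "mirnas.fasta"))
  mirnas <- data.frame(
    mirna_id = sub(" .*$", "", names(mseqs)),
    mature_seq = unname(mseqs), stringsAsFactors = FALSE
  )
  mirnas$family_key <- substr(mirnas$mature_seq, 2, 8)
  mb <- read_bed(file.path(dir, "mirnas.bed"))
  idx <- match(mirnas$mirna_id, mb$name)
  mirnas$chrom <- mb$chrom[idx]
  mirnas$start <- mb$start[idx]
  mirnas$end <- mb$end[idx]
  mirnas$strand <- mb$strand[idx]

  homology <- read_homology(file.path(dir, "homology.tsv"))
  pathways <- read_gmt(file.path(dir, "pathways.gmt"))
  gene_classes <- read_gmt(file.path(dir, "gene_classes.gmt"))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  for (nm in c("planted_sites", "cnv_genes", "planted_pathways",
               "hosted_mirnas")) {
    t_df <- truth[[nm]]
    if (is.null(t_df) || length(t_df) == 0 ||
        (is.data.frame(t_df) && nrow(t_df) == 0)) {
      truth[[nm]] <- empty_truth_df(nm)
    } else {
      truth[[nm]] <- as.data.frame(t_df, stringsAsFactors = FALSE)
      if ("offset" %in% names(truth[[nm]])) {
        truth[[nm]]$offset <- as.integer(truth[[nm]]$offset)
      }
    }
  }
  truth$prolific_mirnas <- as.character(truth$prolific_mirnas)
  truth$above_pool <- as.character(truth$above_pool)

  structure(list(genes = genes, homology = homology,
                 cnv_regions = cnv_regions, mirnas = mirnas,
                 pathways = pathways, gene_classes = gene_classes,
                 truth = truth, config = config),
            class = "mircnv_cohort")
}
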