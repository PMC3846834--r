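# End-to-end orchestration. Stages communicate through plain-text files
# inside the run directory (TSV as the inter-stage contract, FASTA/BED/GMT
# for the cohort inputs), so each stage can also be run on its own -- and
# externally computed prediction tables can replace the built-in
# predictors. All randomness flows from the single pipeline seed.

PIPELINE_STAGES <- c("generate", "atlas", "predict", "partition", "enrich",
                     "scan", "report")

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read the
#'   formats listed under `paths`).
#' @param out_dir run directory; all stage outputs land here.
#' @param synthetic a [synthetic_config()]; its `rng_seed` is overridden by
#'   `rng_seed` so one seed drives the whole run.
#' @param paths named list for files mode: `utr_fasta`, `mirna_fasta`,
#'   `homology_tsv`, `pathways_gmt`, `classes_gmt`, and named vectors
#'   `genes_bed` / `cnv_bed` (one path per species); optional `mirna_bed`
#'   and `predictions` (pre-computed site TSV replacing the built-in
#'   predictors).
#' @param focal_species species for enrichment detail, ORA and the
#'   specific-set report (default `"human"`).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param universe enrichment universe rule (`"annotated"` or `"all"`).
#' @param partition_rule `"ties_below"` or `"ties_above"`.
#' @param ora_variant `"ranksum"` or `"fisher_threshold"`.
#' @param scan_mode `"within"` or `"any"`; `scan_strand` `"ignore"` or
#'   `"match"`.
#' @param min_walk_len minimum walk-site run length (default 7).
#' @param rng_seed integer seed for the run.
#' @return object of class `mircnv_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            out_dir,
                            synthetic = synthetic_config(),
                            paths = list(),
                            focal_species = "human",
                            alpha = 0.05,
                            universe = c("annotated", "all"),
                            partition_rule = c("ties_below", "ties_above"),
                            ora_variant = c("ranksum", "fisher_threshold"),
                            scan_mode = c("within", "any"),
                            scan_strand = c("ignore", "match"),
                            min_walk_len = 7L,
                            rng_seed = 1L) {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)",
                                      call. = FALSE)
  if (mode == "files") {
    req <- c("utr_fasta", "mirna_fasta", "homology_tsv", "pathways_gmt")
    miss <- setdiff(req, names(paths))
    if (length(miss) > 0) {
      stop("files mode lacks path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    flat <- unlist(paths, use.names = TRUE)
    absent <- flat[!file.exists(flat)]
    if (length(absent) > 0) {
      stop("configured path(s) do not exist: ",
           paste(sprintf("%s (%s)", names(absent), absent), collapse = "; "),
           call. = FALSE)
    }
    if (is.null(names(paths$genes_bed)) || is.null(names(paths$cnv_bed))) {
      stop("genes_bed and cnv_bed must be named by species", call. = FALSE)
    }
  } else {
    synthetic$rng_seed <- as.integer(rng_seed)
  }
  structure(list(
    mode = mode, out_dir = out_dir, synthetic = synthetic, paths = paths,
    focal_species = focal_species, alpha = alpha,
    universe = match.arg(universe),
    partition_rule = match.arg(partition_rule),
    ora_variant = match.arg(ora_variant),
    scan_mode = match.arg(scan_mode),
    scan_strand = match.arg(scan_strand),
    min_walk_len = as.integer(min_walk_len),
    rng_seed = as.integer(rng_seed)
  ), class = "mircnv_pipeline_config")
}

rbind_rows <- function(rows, proto) {
  if (length(rows) == 0) return(proto)
  do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
}

pl_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

pl_need <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop(sprintf("stage '%s' is missing input(s): %s -- run the earlier stages first",
                 stage, paste(basename(missing), collapse = ", ")),
         call. = FALSE)
  }
  invisible(paths)
}

stage_generate <- function(config) {
  inputs <- pl_dir(config, "inputs")
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$synthetic)
  } else {
    cohort <- ingest_files(config)
  }
  write_cohort(cohort, inputs)
  invisible(cohort)
}

# Assemble a cohort object from user-supplied files (files mode).
ingest_files <- function(config) {
  p <- config$paths
  sps <- names(p$genes_bed)
  utrs <- read_fasta(p$utr_fasta)
  utr_tab <- data.frame(gene_id = sub(" .*$", "", names(utrs)),
                        utr = unname(utrs), stringsAsFactors = FALSE)
  genes_list <- list(); regions_list <- list()
  for (sp in sps) {
    b <- read_bed(p$genes_bed[[sp]])
    r <- if (!is.null(p$cnv_bed[[sp]])) read_bed(p$cnv_bed[[sp]]) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    g <- data.frame(gene_id = b$name, species = rep(sp, nrow(b)),
                    chrom = b$chrom, start = b$start, end = b$end,
                    strand = b$strand, stringsAsFactors = FALSE)
    g <- assign_cnv_status(g, r)
    g$utr <- utr_tab$utr[match(g$gene_id, utr_tab$gene_id)]
    genes_list[[sp]] <- g
    regions_list[[sp]] <- data.frame(species = rep(sp, nrow(r)),
                                     chrom = r$chrom, start = r$start,
                                     end = r$end, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_list); rownames(genes) <- NULL
  cnv_regions <- do.call(rbind, regions_list); rownames(cnv_regions) <- NULL
  mseqs <- read_fasta(p$mirna_fasta)
  mirnas <- data.frame(mirna_id = sub(" .*$", "", names(mseqs)),
                       mature_seq = unname(mseqs), stringsAsFactors = FALSE)
  mirnas$family_key <- mirna_family(mirnas$mature_seq)
  mirnas$chrom <- NA_character_; mirnas$start <- NA_integer_
  mirnas$end <- NA_integer_; mirnas$strand <- NA_character_
  if (!is.null(p$mirna_bed)) {
    mb <- read_bed(p$mirna_bed)
    idx <- match(mirnas$mirna_id, mb$name)
    mirnas$chrom <- mb$chrom[idx]; mirnas$start <- mb$start[idx]
    mirnas$end <- mb$end[idx]; mirnas$strand <- mb$strand[idx]
  }
  classes <- if (!is.null(p$classes_gmt)) read_gmt(p$classes_gmt) else
    setNames(list(), character(0))
  cfg <- synthetic_config(n_species = length(sps), species = sps,
                          rng_seed = config$rng_seed)
  truth <- list(planted_sites = empty_truth_df("planted_sites"),
                cnv_genes = data.frame(
                  species = genes$species[genes$cnv_status == "CNV"],
                  gene_id = genes$gene_id[genes$cnv_status == "CNV"],
                  stringsAsFactors = FALSE),
                prolific_mirnas = character(0),
                planted_pathways = empty_truth_df("planted_pathways"),
                above_pool = character(0),
                hosted_mirnas = empty_truth_df("hosted_mirnas"))
  structure(list(genes = genes, homology = read_homology(p$homology_tsv),
                 cnv_regions = cnv_regions, mirnas = mirnas,
                 pathways = read_gmt(p$pathways_gmt), gene_classes = classes,
                 truth = truth, config = cfg),
            class = "mircnv_cohort")
}

stage_atlas <- function(config) {
  pl_need(file.path(config$out_dir, "inputs", "config.json"), "atlas")
  cohort <- read_cohort(file.path(config$out_dir, "inputs"))
  d <- pl_dir(config, "atlas")
  sps <- cohort$config$species
  human <- cohort$genes[cohort$genes$species == "human", ]
  others <- lapply(setdiff(sps, "human"), function(sp) {
    cohort$genes[cohort$genes$species == sp, ]
  })
  names(others) <- setdiff(sps, "human")
  res <- build_atlas(human, cohort$homology, others)
  for (sp in names(res$atlas)) {
    write_tsv(res$atlas[[sp]][, c("gene_id", "chrom", "start", "end",
                                  "strand", "cnv_status")],
              file.path(d, sprintf("atlas_%s.tsv", sp)))
  }
  write_tsv(res$summary, file.path(d, "summary.tsv"))
  invisible(res)
}

stage_predict <- function(config) {
  pl_need(file.path(config$out_dir, "inputs", "config.json"), "predict")
  cohort <- read_cohort(file.path(config$out_dir, "inputs"))
  d <- pl_dir(config, "predict")
  if (!is.null(config$paths$predictions)) {
    ext <- read_predictions(config$paths$predictions)
    res <- intersect_predictions(ext[ext$source == "walk", , drop = FALSE],
                                 ext[ext$source == "seed", , drop = FALSE])
    out <- list(pairs = res$pairs, sites = res$sites,
                family_pairs = collapse_families(res$pairs, cohort$mirnas),
                n_mirnas = nrow(cohort$mirnas),
                genes_scanned = data.frame(
                  species = unique(res$pairs$species),
                  n_genes = NA_integer_, stringsAsFactors = FALSE))
  } else {
    out <- predict_all(cohort$mirnas, cohort$genes,
                       species = cohort$config$species, stratum = "CNV",
                       min_len = config$min_walk_len)
  }
  write_tsv(out$sites, file.path(d, "sites.tsv"))
  write_tsv(out$pairs, file.path(d, "pairs.tsv"))
  write_tsv(out$family_pairs, file.path(d, "family_pairs.tsv"))
  write_tsv(data.frame(n_mirnas = out$n_mirnas,
                       n_families = length(unique(
                         cohort$mirnas$family_key))),
            file.path(d, "units.tsv"))
  write_tsv(out$genes_scanned, file.path(d, "genes_scanned.tsv"))
  invisible(out)
}

stage_partition <- function(config) {
  pd <- file.path(config$out_dir, "predict")
  pl_need(file.path(pd, c("pairs.tsv", "family_pairs.tsv", "units.tsv")),
          "partition")
  cohort <- read_cohort(file.path(config$out_dir, "inputs"))
  d <- pl_dir(config, "partition")
  pairs <- read_tsv(file.path(pd, "pairs.tsv"))
  fam_pairs <- read_tsv(file.path(pd, "family_pairs.tsv"))
  units <- read_tsv(file.path(pd, "units.tsv"))
  scanned <- read_tsv(file.path(pd, "genes_scanned.tsv"))
  sps <- cohort$config$species

  unit_rows <- list(); list_rows <- list(); mean_rows <- list()
  dens_rows <- list()
  for (sp in sps) {
    for (level in c("mirna", "family")) {
      p <- if (level == "mirna") pairs[pairs$species == sp, , drop = FALSE]
        else fam_pairs[fam_pairs$species == sp, , drop = FALSE]
      n_units <- if (level == "mirna") units$n_mirnas else units$n_families
      part <- partition_genes(p, n_units = n_units, level = level,
                              rule = config$partition_rule)
      u <- part$units
      if (nrow(u) > 0) {
        unit_rows[[length(unit_rows) + 1L]] <-
          cbind(data.frame(species = sp, level = level,
                           stringsAsFactors = FALSE), u)
      }
      for (cl in c("above", "below")) {
        gl <- if (cl == "above") part$above_genes else part$below_genes
        if (length(gl) > 0) {
          list_rows[[length(list_rows) + 1L]] <-
            data.frame(species = sp, level = level, class = cl,
                       gene_id = gl, stringsAsFactors = FALSE)
        }
      }
      mean_rows[[length(mean_rows) + 1L]] <-
        data.frame(species = sp, level = level, n_units = part$n_units,
                   total_pairs = part$total_pairs,
                   overall_mean = part$overall_mean,
                   overall_mean_2dp = round(part$overall_mean, 2),
                   stringsAsFactors = FALSE)
    }
    n_genes <- scanned$n_genes[scanned$species == sp]
    if (length(n_genes) == 1 && !is.na(n_genes) && n_genes >= 1) {
      dens_rows[[length(dens_rows) + 1L]] <- data.frame(
        species = sp, n_pairs = sum(pairs$species == sp),
        n_genes = n_genes,
        density = per_gene_density(sum(pairs$species == sp), n_genes),
        stringsAsFactors = FALSE)
    }
  }
  write_tsv(rbind_rows(unit_rows, data.frame(
    species = character(0), level = character(0), unit_id = character(0),
    target_count = integer(0), class = character(0))),
    file.path(d, "partition_units.tsv"))
  write_tsv(rbind_rows(list_rows, data.frame(
    species = character(0), level = character(0), class = character(0),
    gene_id = character(0))), file.path(d, "gene_lists.tsv"))
  write_tsv(do.call(rbind, mean_rows), file.path(d, "means.tsv"))
  write_tsv(rbind_rows(dens_rows, data.frame(
    species = character(0), n_pairs = integer(0), n_genes = integer(0),
    density = numeric(0))), file.path(d, "density.tsv"))
  ctrl <- withCallingHandlers(
    utr_length_comparison(cohort$genes),
    warning = function(w) invokeRestart("muffleWarning"))
  write_tsv(ctrl$per_species, file.path(d, "utr_control.tsv"))
  write_tsv(data.frame(method = ctrl$method, p_value = ctrl$p_value),
            file.path(d, "utr_control_p.tsv"))
  invisible(NULL)
}

stage_enrich <- function(config) {
  pd <- file.path(config$out_dir, "partition")
  pl_need(file.path(pd, c("gene_lists.tsv", "partition_units.tsv")),
          "enrich")
  cohort <- read_cohort(file.path(config$out_dir, "inputs"))
  d <- pl_dir(config, "enrich")
  gene_lists <- read_tsv(file.path(pd, "gene_lists.tsv"))
  units <- read_tsv(file.path(pd, "partition_units.tsv"))
  sites <- read_tsv(file.path(config$out_dir, "predict", "sites.tsv"))
  sps <- cohort$config$species

  res_rows <- list(); summary_rows <- list()
  above_mirna <- list()
  for (sp in sps) {
    bg <- cohort$genes$gene_id[cohort$genes$species == sp &
                                 cohort$genes$cnv_status == "CNV"]
    for (level in c("mirna", "family")) {
      for (cl in c("above", "below")) {
        gl <- gene_lists$gene_id[gene_lists$species == sp &
                                   gene_lists$level == level &
                                   gene_lists$class == cl]
        r <- tryCatch(
          suppressWarnings(
            pathway_enrichment(gl, bg, cohort$pathways,
                               alpha = config$alpha,
                               universe = config$universe)),
          error = function(e) NULL)
        n_sig <- if (is.null(r)) 0L else attr(r, "n_significant")
        if (!is.null(r) && nrow(r) > 0) {
          res_rows[[length(res_rows) + 1L]] <-
            cbind(data.frame(species = sp, level = level, list_class = cl,
                             stringsAsFactors = FALSE), r)
        }
        summary_rows[[length(summary_rows) + 1L]] <-
          data.frame(species = sp, level = level, list_class = cl,
                     n_significant = n_sig, stringsAsFactors = FALSE)
        if (level == "mirna" && cl == "above" && !is.null(r)) {
          above_mirna[[sp]] <- r
        }
      }
    }
  }
  write_tsv(rbind_rows(res_rows, data.frame(
    species = character(0), level = character(0), list_class = character(0),
    set_id = character(0), a = integer(0), b = integer(0), c = integer(0),
    d = integer(0), p_raw = numeric(0), p_adj = numeric(0),
    significant = logical(0))), file.path(d, "enrichment_results.tsv"))
  write_tsv(do.call(rbind, summary_rows),
            file.path(d, "enrichment_summary.tsv"))
  if (length(above_mirna) > 0) {
    hm <- heatmap_matrix(above_mirna, value = "binary",
                         focal_species = config$focal_species)
    hm_df <- data.frame(set_id = rownames(hm$matrix),
                        as.data.frame(hm$matrix), check.names = FALSE,
                        stringsAsFactors = FALSE)
    write_tsv(hm_df, file.path(d, "heatmap_above_mirna.tsv"))
    write_tsv(data.frame(set_id = hm$specific_sets),
              file.path(d, "specific_sets.tsv"))
  }

  atlas_genes <- cohort$genes[, c("species", "gene_id", "cnv_status")]
  if (length(cohort$gene_classes) > 0) {
    cls <- withCallingHandlers(
      classify_genes(atlas_genes, cohort$gene_classes),
      warning = function(w) invokeRestart("muffleWarning"))
    write_tsv(cls, file.path(d, "classes_summary.tsv"))
  }

  ## binding-site ORA on the focal species' CNV genes
  fsp <- config$focal_species
  focal <- cohort$genes[cohort$genes$species == fsp &
                          cohort$genes$cnv_status == "CNV", ]
  utr_len <- setNames(nchar(focal$utr), focal$gene_id)
  fsites <- sites[sites$species == fsp, , drop = FALSE]
  ora_rows <- list()
  for (cl in c("above", "below")) {
    uids <- units$unit_id[units$species == fsp & units$level == "mirna" &
                            units$class == cl]
    s <- fsites[fsites$mirna_id %in% uids, , drop = FALSE]
    r <- ora_gene_sets(s, focal$gene_id, cohort$pathways, utr_len,
                       variant = config$ora_variant)
    r$unit_class <- cl
    ora_rows[[cl]] <- r
  }
  write_tsv(do.call(rbind, ora_rows), file.path(d, "ora_pathways.tsv"))
  if (length(cohort$gene_classes) > 0) {
    fam_sites <- fsites[!duplicated(data.frame(
      fam = cohort$mirnas$family_key[match(fsites$mirna_id,
                                           cohort$mirnas$mirna_id)],
      fsites$gene_id, fsites$utr_offset, fsites$site_type)), , drop = FALSE]
    rc1 <- ora_gene_sets(fsites, focal$gene_id, cohort$gene_classes,
                         utr_len, variant = config$ora_variant)
    rc1$level <- "mirna"
    rc2 <- ora_gene_sets(fam_sites, focal$gene_id, cohort$gene_classes,
                         utr_len, variant = config$ora_variant)
    rc2$level <- "family"
    write_tsv(rbind(rc1, rc2), file.path(d, "ora_classes.tsv"))
  }
  invisible(NULL)
}

stage_scan <- function(config) {
  pl_need(file.path(config$out_dir, "inputs", "config.json"), "scan")
  cohort <- read_cohort(file.path(config$out_dir, "inputs"))
  d <- pl_dir(config, "scan")
  m <- cohort$mirnas[!is.na(cohort$mirnas$chrom), , drop = FALSE]
  count_rows <- list(); assign_rows <- list(); results <- list()
  for (sp in cohort$config$species) {
    g <- cohort$genes[cohort$genes$species == sp, , drop = FALSE]
    msp <- m[m$chrom %in% unique(g$chrom), , drop = FALSE]
    if (nrow(msp) == 0) next
    res <- suppressWarnings(
      scan_hosts(msp, g, mode = config$scan_mode,
                 strand = config$scan_strand))
    results[[sp]] <- res
    count_rows[[sp]] <- cbind(data.frame(species = sp,
                                         stringsAsFactors = FALSE),
                              res$counts)
    if (nrow(res$assignments) > 0) {
      assign_rows[[sp]] <- cbind(data.frame(species = sp,
                                            stringsAsFactors = FALSE),
                                 res$assignments)
    }
  }
  if (length(results) == 0) {
    message("[mircnv] no species has miRNA coordinates; host scan skipped")
    write_tsv(data.frame(species = character(0), stratum = character(0),
                         n_mirnas = integer(0), n_genes = integer(0)),
              file.path(d, "host_counts.tsv"))
    return(invisible(NULL))
  }
  write_tsv(do.call(rbind, c(unname(count_rows),
                             list(make.row.names = FALSE))),
            file.path(d, "host_counts.tsv"))
  write_tsv(do.call(rbind, c(unname(assign_rows),
                             list(make.row.names = FALSE))),
            file.path(d, "assignments.tsv"))
  write_tsv(host_bias_summary(results), file.path(d, "bias.tsv"))
  invisible(NULL)
}

stage_report <- function(config) {
  d <- config$out_dir
  expected <- c("inputs/config.json", "atlas/summary.tsv",
                "predict/pairs.tsv", "partition/means.tsv",
                "enrich/enrichment_summary.tsv", "scan/host_counts.tsv")
  missing <- expected[!file.exists(file.path(d, expected))]
  if (length(missing) > 0) {
    stop("report: missing stage output(s): ",
         paste(missing, collapse = ", "),
         " -- run the corresponding stages first", call. = FALSE)
  }
  files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "mircnv",
    version = as.character(utils::packageVersion("mircnv")),
    mode = config$mode,
    rng_seed = config$rng_seed,
    alpha = config$alpha,
    universe = config$universe,
    partition_rule = config$partition_rule,
    ora_variant = config$ora_variant,
    scan_mode = config$scan_mode,
    files = data.frame(file = sub(paste0("^", d, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' @param stage one of `generate`, `atlas`, `predict`, `partition`,
#'   `enrich`, `scan`, `report`.
#' @param config a [pipeline_config()].
#' @return the stage's value, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  switch(stage,
         generate = stage_generate(config),
         atlas = stage_atlas(config),
         predict = stage_predict(config),
         partition = stage_partition(config),
         enrich = stage_enrich(config),
         scan = stage_scan(config),
         report = stage_report(config))
}

#' Run the full pipeline
#'
#' Executes generate/ingest -> atlas -> predict+intersect -> partition ->
#' enrichment + ORA + classes -> host scan -> report. Re-running with an
#' identical configuration and seed reproduces byte-identical TSVs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  manifest <- NULL
  for (stage in PIPELINE_STAGES) {
    manifest <- tryCatch(
      run_stage(stage, config),
      error = function(e) {
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE)
      })
  }
  invisible(manifest)
}
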