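# Replicate-level evaluation of the pipeline against the generator's truth
# record: planted-pathway recovery (sensitivity / empirical FDR), the
# cross-species per-gene density pattern, planted-site recovery through the
# prediction intersection, host-miRNA bias labelling, and the no-effect
# null control. These drive both the test suite and scripts/acceptance.R.

rep_seeds <- function(n_reps, seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  sample.int(2^31 - 2, n_reps)
}

# Evaluate one cohort end-to-end; internal worker.
planted_eval_rep <- function(config, alpha = 0.05) {
  cohort <- generate_cohort(config)
  pred <- predict_all(cohort$mirnas, cohort$genes, stratum = "CNV")
  genes <- cohort$genes
  sps <- config$species

  ## per-species density over CNV genes
  dens <- vapply(sps, function(sp) {
    n <- sum(genes$species == sp & genes$cnv_status == "CNV")
    if (n == 0) return(NA_real_)
    per_gene_density(sum(pred$pairs$species == sp), n)
  }, numeric(1))
  density_top <- !is.na(dens[["human"]]) &&
    all(dens[["human"]] > dens[setdiff(sps, "human")], na.rm = TRUE)

  ## planted 8mer recovery through the intersection (CNV stratum)
  ps <- cohort$truth$planted_sites
  cnv_key <- paste(genes$species, genes$gene_id)[genes$cnv_status == "CNV"]
  ps <- ps[paste(ps$species, ps$gene_id) %in% cnv_key, , drop = FALSE]
  s8 <- pred$sites[pred$sites$site_type == "8mer", ]
  found <- paste(ps$species, ps$gene_id, ps$mirna_id, ps$offset) %in%
    paste(s8$species, s8$gene_id, s8$mirna_id, s8$utr_offset)
  site_recovery <- if (nrow(ps) > 0) mean(found) else NA_real_

  ## human above-mean partition and pathway enrichment vs planted truth
  hp <- pred$pairs[pred$pairs$species == "human", , drop = FALSE]
  part <- partition_genes(hp, n_units = nrow(cohort$mirnas),
                          level = "mirna")
  bg <- genes$gene_id[genes$species == "human" & genes$cnv_status == "CNV"]
  enr <- suppressWarnings(
    pathway_enrichment(part$above_genes, bg, cohort$pathways,
                       alpha = alpha, universe = "annotated"))
  planted_ids <- cohort$truth$planted_pathways$pathway_id
  sig <- enr$set_id[enr$significant]
  n_planted <- length(planted_ids)
  n_recovered <- length(intersect(sig, planted_ids))
  n_false <- length(setdiff(sig, planted_ids))

  ## host-miRNA bias on human
  hg <- genes[genes$species == "human", ]
  hs <- suppressWarnings(scan_hosts(cohort$mirnas, hg))
  bias <- host_bias_summary(list(human = hs))

  data.frame(
    n_planted = n_planted, n_recovered = n_recovered,
    n_discoveries = length(sig), n_false = n_false,
    density_top = density_top, site_recovery = site_recovery,
    n_planted_sites = nrow(ps),
    host_label = bias$label[1],
    stringsAsFactors = FALSE
  )
}

#' Planted-effect recovery simulation
#'
#' Runs the full analysis on `n_reps` independently seeded default cohorts
#' and measures, against the generator's truth record: pooled sensitivity
#' and per-replicate empirical FDR for the planted enriched pathways (BH at
#' `alpha` on the above-mean human gene list), the fraction of replicates
#' in which human CNV genes have the strictly highest per-gene interaction
#' density, the fraction labelled `cnv-biased` by the host-miRNA scan, and
#' the pooled recovery of planted 8mer sites through the prediction
#' intersection.
#'
#' @param n_reps number of replicates.
#' @param seed master seed (per-replicate seeds are drawn from it).
#' @param config generator configuration (default [synthetic_config()]).
#' @param alpha BH significance level.
#' @return list with `per_rep` (data.frame) and `summary` (list:
#'   sensitivity, fdr, density_top_fraction, cnv_biased_fraction,
#'   site_recovery).
#' @export
simulate_planted_recovery <- function(n_reps = 100, seed = 1,
                                      config = synthetic_config(),
                                      alpha = 0.05) {
  seeds <- rep_seeds(n_reps, seed)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$rng_seed <- seeds[i]
    rows[[i]] <- cbind(data.frame(rep = i, seed = seeds[i]),
                       planted_eval_rep(cfg, alpha = alpha))
  }
  per_rep <- do.call(rbind, rows)
  fdp <- per_rep$n_false / pmax(1, per_rep$n_discoveries)
  summary <- list(
    sensitivity = sum(per_rep$n_recovered) / sum(per_rep$n_planted),
    fdr = mean(fdp),
    density_top_fraction = mean(per_rep$density_top),
    cnv_biased_fraction = mean(per_rep$host_label == "cnv-biased",
                               na.rm = TRUE),
    site_recovery = sum(per_rep$site_recovery * per_rep$n_planted_sites) /
      sum(per_rep$n_planted_sites)
  )
  list(per_rep = per_rep, summary = summary)
}

#' Null configuration: no planted effects
#'
#' The default generator configuration with all planted-site rates at zero
#' and no planted pathways; everything else unchanged.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @return a `mircnv_config`.
#' @export
null_config <- function(...) {
  synthetic_config(
    planted_site_rate = c(default = 0),
    planted_enriched_pathways = data.frame(pathway_id = character(0),
                                           target = character(0),
                                           excess = numeric(0),
                                           stringsAsFactors = FALSE),
    ...)
}

#' Null-control simulation for the enrichment stage
#'
#' With no planted effects, each replicate runs prediction on human CNV
#' genes, partitions by the overall mean, and tests pathway enrichment of
#' the above-mean gene list (BH at `alpha`); the replicate "fires" when at
#' least one set is called significant. Under the null this fraction stays
#' near the BH level.
#'
#' @inheritParams simulate_planted_recovery
#' @return list with `per_rep` (data.frame: rep, seed, n_significant) and
#'   `any_significant_fraction`.
#' @export
simulate_null_enrichment <- function(n_reps = 200, seed = 1,
                                     config = null_config(),
                                     alpha = 0.05) {
  seeds <- rep_seeds(n_reps, seed)
  n_sig <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$rng_seed <- seeds[i]
    cohort <- generate_cohort(cfg)
    pred <- predict_all(cohort$mirnas, cohort$genes, species = "human",
                        stratum = "CNV")
    part <- partition_genes(pred$pairs, n_units = nrow(cohort$mirnas),
                            level = "mirna")
    bg <- cohort$genes$gene_id[cohort$genes$species == "human" &
                                 cohort$genes$cnv_status == "CNV"]
    enr <- suppressWarnings(
      pathway_enrichment(part$above_genes, bg, cohort$pathways,
                         alpha = alpha, universe = "annotated"))
    n_sig[i] <- attr(enr, "n_significant")
  }
  list(per_rep = data.frame(rep = seq_len(n_reps), seed = seeds,
                            n_significant = n_sig),
       any_significant_fraction = mean(n_sig > 0))
}
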