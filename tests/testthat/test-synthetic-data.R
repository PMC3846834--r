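test_that("generation is deterministic for a fixed seed", {
  c1 <- generate_cohort(tiny_config())
  c2 <- generate_cohort(tiny_config())
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(tiny_config(rng_seed = 12L))
  expect_false(identical(c1$genes$utr, c3$genes$utr))
})

test_that("zero planted rate yields an empty truth and clean UTRs", {
  cohort <- generate_cohort(tiny_config(
    planted_site_rate = c(default = 0)))
  expect_identical(nrow(cohort$truth$planted_sites), 0L)
})

test_that("planted-site totals follow the configured Poisson rate", {
  # one species, all genes CNV, rate 2 per gene over 2000 genes: the total
  # is a Poisson(4000) sum; require it within 3 SDs
  cohort <- generate_cohort(synthetic_config(
    n_species = 1L, n_homology_groups = 2000L,
    cnv_fraction_per_species = 1.0,
    planted_site_rate = c(human.CNV = 2.0, default = 0),
    rng_seed = 99L))
  total <- nrow(cohort$truth$planted_sites)
  expect_gt(total, 4000 - 3 * sqrt(4000))
  expect_lt(total, 4000 + 3 * sqrt(4000))
})

test_that("every truth-recorded planted site is literally in its UTR", {
  cohort <- generate_cohort(tiny_config())
  ps <- cohort$truth$planted_sites
  expect_gt(nrow(ps), 0)
  key <- paste(cohort$genes$species, cohort$genes$gene_id)
  seed7 <- substr(cohort$mirnas$mature_seq[
    match(ps$mirna_id, cohort$mirnas$mirna_id)], 2, 8)
  expected <- paste0(vapply(seed7, oracle_rc, character(1),
                            USE.NAMES = FALSE), "A")
  utr <- cohort$genes$utr[match(paste(ps$species, ps$gene_id), key)]
  observed <- substr(utr, ps$offset + 1L, ps$offset + 8L)
  expect_identical(observed, expected)
})

test_that("cohort structural invariants hold", {
  cohort <- generate_cohort(tiny_config())
  # gene intervals within a species do not overlap
  for (sp in cohort$config$species) {
    g <- cohort$genes[cohort$genes$species == sp, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # homology groups name at most one gene per species, human always present
  tab <- table(cohort$homology$group_id, cohort$homology$species)
  expect_true(all(tab <= 1))
  expect_true(all(tab[, "human"] == 1))
  # intergenic miRNAs have no coordinates or sit outside every gene span
  m <- cohort$mirnas[!cohort$mirnas$mirna_id %in%
                       cohort$truth$hosted_mirnas$mirna_id, ]
  m <- m[!is.na(m$chrom), ]
  if (nrow(m) > 0) {
    human <- cohort$genes[cohort$genes$species == "human", ]
    inside <- oracle_within(m, human)
    expect_null(inside)
  }
})

test_that("scanning recovers planted 8mer sites exactly (100%)", {
  cohort <- generate_cohort(tiny_config())
  pred <- predict_all(cohort$mirnas, cohort$genes, stratum = "all")
  ps <- cohort$truth$planted_sites
  s8 <- pred$sites[pred$sites$site_type == "8mer", ]
  found <- paste(ps$species, ps$gene_id, ps$mirna_id, ps$offset) %in%
    paste(s8$species, s8$gene_id, s8$mirna_id, s8$utr_offset)
  expect_identical(mean(found), 1)
})

test_that("unplaceable configurations are rejected", {
  expect_error(synthetic_config(utr_length_mean = 40,
                                planted_site_rate = c(default = 6)),
               "exceeds UTR length")
  expect_error(synthetic_config(n_mirnas = 0), "counts")
  expect_error(synthetic_config(host_mirna_cnv_bias = 1.3), "fractions")
  expect_error(synthetic_config(utr_length_mean = 20), "utr_length_mean")
})

test_that("write_cohort round-trips losslessly through read_cohort", {
  cohort <- generate_cohort(tiny_config())
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  expect_true(all(c("utrs.fasta", "mirnas.fasta", "homology.tsv",
                    "pathways.gmt", "truth.json", "config.json") %in%
                    manifest$file))
  back <- read_cohort(dir)
  expect_equal(back$genes, cohort$genes)
  expect_equal(back$mirnas, cohort$mirnas)
  expect_equal(back$homology, cohort$homology)
  expect_equal(back$cnv_regions, cohort$cnv_regions)
  expect_equal(back$pathways, cohort$pathways)
  expect_equal(back$gene_classes, cohort$gene_classes)
  expect_equal(back$truth, cohort$truth)
  expect_equal(unclass(back$config), unclass(cohort$config))
})

test_that("degenerate cohorts write well-formed files", {
  cohort <- generate_cohort(tiny_config())
  # zero genes
  empty <- cohort
  empty$genes <- empty$genes[0, ]
  empty$cnv_regions <- empty$cnv_regions[0, ]
  empty$homology <- empty$homology[0, ]
  dir <- withr::local_tempdir()
  expect_no_error(write_cohort(empty, dir))
  back <- read_cohort(dir)
  expect_identical(nrow(back$genes), 0L)
  # one gene, one positioned miRNA: exactly two coordinate lines in total
  one <- cohort
  one$genes <- one$genes[1, ]
  one$cnv_regions <- one$cnv_regions[0, ]
  one$mirnas <- one$mirnas[!is.na(one$mirnas$chrom), ][1, ]
  dir2 <- withr::local_tempdir()
  write_cohort(one, dir2)
  beds <- list.files(dir2, pattern = "^(genes_.*|mirnas)\\.bed$",
                     full.names = TRUE)
  n_lines <- sum(vapply(beds, function(f) length(readLines(f)), integer(1)))
  expect_identical(n_lines, 2L)
})
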