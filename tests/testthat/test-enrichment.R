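test_that("Fisher upper tail matches combinatorial enumeration", {
  expect_equal(fisher_exact_greater(3, 1, 1, 3), 17 / 70, tolerance = 1e-12)
  # a at the minimum of the support puts the whole mass in the tail
  expect_identical(fisher_exact_greater(0, 5, 3, 10), 1)
  expect_error(fisher_exact_greater(-1, 1, 1, 1), "negative")
  set.seed(51)
  for (i in 1:300) {
    n <- sample.int(40, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c_ <- cuts[3] - cuts[2]
    d <- n - cuts[3]
    if (a + b + c_ + d < 1) next
    expect_equal(fisher_exact_greater(a, b, c_, d),
                 oracle_fisher_tail(a, b, c_, d), tolerance = 1e-10,
                 info = paste(a, b, c_, d))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(52)
  for (i in 1:50) {
    p <- runif(sample.int(60, 1))
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-12)
    # monotone non-decreasing in raw-p rank order
    expect_true(all(diff(got[order(p)]) >= -1e-15))
  }
})

test_that("enrichment of the full background is never significant", {
  sets <- list(s1 = paste0("g", 1:5), s2 = paste0("g", 6:12))
  bg <- paste0("g", 1:20)
  res <- pathway_enrichment(bg, bg, sets, universe = "all")
  expect_true(all(res$p_raw == 1))
  expect_identical(attr(res, "n_significant"), 0L)
})

test_that("enrichment p-values equal Fisher on hand-built tables", {
  bg <- paste0("g", 1:6)
  gl <- c("g1", "g2", "g3")
  sets <- list(s1 = c("g1", "g2", "g4"), s2 = c("g5", "g6"))
  res <- pathway_enrichment(gl, bg, sets, universe = "all")
  # s1: a=2 (g1,g2), b=1, c=1 (g4), d=2; s2: a=0, b=3, c=2, d=1
  expect_equal(res$p_raw[res$set_id == "s1"],
               fisher_exact_greater(2, 1, 1, 2), tolerance = 1e-12)
  expect_equal(res$p_raw[res$set_id == "s2"],
               fisher_exact_greater(0, 3, 2, 1), tolerance = 1e-12)
})

test_that("enrichment results are order invariant and carry valid tables", {
  cohort <- generate_cohort(tiny_config())
  bg <- cohort$genes$gene_id[cohort$genes$species == "human" &
                               cohort$genes$cnv_status == "CNV"]
  gl <- sample(bg, 12)
  r1 <- pathway_enrichment(gl, bg, cohort$pathways)
  r2 <- pathway_enrichment(rev(gl), sample(bg), cohort$pathways[
    sample(names(cohort$pathways))])
  expect_equal(r1, r2, ignore_attr = TRUE)
  # 2x2 cells always sum to the universe size
  expect_true(all(rowSums(r1[, c("a", "b", "c", "d")]) ==
                    r1$a[1] + r1$b[1] + r1$c[1] + r1$d[1]))
  expect_true(all(r1$p_adj >= r1$p_raw))
})

test_that("planted pathways are recovered on a default cohort", {
  cohort <- generate_cohort(synthetic_config(rng_seed = 1L))
  pred <- predict_all(cohort$mirnas, cohort$genes, species = "human",
                      stratum = "CNV")
  part <- partition_genes(pred$pairs, n_units = nrow(cohort$mirnas))
  bg <- cohort$genes$gene_id[cohort$genes$species == "human" &
                               cohort$genes$cnv_status == "CNV"]
  enr <- pathway_enrichment(part$above_genes, bg, cohort$pathways)
  planted <- cohort$truth$planted_pathways$pathway_id
  expect_true(all(planted %in% enr$set_id[enr$significant]))
})

test_that("species-specific sets are read off the significance matrix", {
  r_hs <- data.frame(set_id = c("a", "b"), p_adj = c(0.01, 0.2),
                     significant = c(TRUE, FALSE))
  r_mm <- data.frame(set_id = c("a", "b"), p_adj = c(0.03, 0.3),
                     significant = c(TRUE, FALSE))
  hm <- heatmap_matrix(list(human = r_hs, mouse = r_mm))
  expect_identical(dim(hm$matrix), c(1L, 2L))
  expect_length(hm$specific_sets, 0)
  # one species: everything significant is specific
  hm1 <- heatmap_matrix(list(human = r_hs))
  expect_identical(hm1$specific_sets, "a")
  # a set significant only in the focal species is reported
  r_mm2 <- data.frame(set_id = "a", p_adj = 0.5, significant = FALSE)
  hm2 <- heatmap_matrix(list(human = r_hs, mouse = r_mm2))
  expect_identical(hm2$specific_sets, "a")
})

test_that("gene classes tally CNV and non-CNV members per species", {
  atlas_genes <- data.frame(
    species = "human", gene_id = paste0("g", 1:4),
    cnv_status = c("CNV", "CNV", "nonCNV", "CNV"),
    stringsAsFactors = FALSE)
  res <- classify_genes(atlas_genes, list(k = c("g1", "g2", "g3")))
  expect_identical(res$n_cnv, 2L)
  expect_identical(res$n_noncnv, 1L)
  expect_warning(res0 <- classify_genes(atlas_genes, list(none = "zz")),
                 "no member")
  expect_identical(res0$n_cnv + res0$n_noncnv, 0L)
})

test_that("binding-site ORA is uniform under the null and powered", {
  set.seed(53)
  ps <- replicate(500, {
    genes <- paste0("g", 1:60)
    len <- pmax(50, round(rnorm(60, 250, 50)))
    names(len) <- genes
    sites <- data.frame(gene_id = rep(genes, rpois(60, 2)),
                        stringsAsFactors = FALSE)
    suppressWarnings(
      binding_site_ora(sites, genes[1:30], genes[31:60], len))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # members with 3x the site rate: p <= 0.05 in >= 90% of replicates
  pw <- replicate(100, {
    genes <- paste0("g", 1:100)
    len <- pmax(50, round(rnorm(100, 250, 50)))
    names(len) <- genes
    sites <- data.frame(gene_id = rep(genes, c(rpois(50, 6), rpois(50, 2))),
                        stringsAsFactors = FALSE)
    suppressWarnings(
      binding_site_ora(sites, genes[1:50], genes[51:100], len))
  })
  expect_gte(mean(pw <= 0.05), 0.9)
})

test_that("degenerate ORA inputs return NA without crashing", {
  genes <- paste0("g", 1:10)
  len <- setNames(rep(100, 10), genes)
  sites <- data.frame(gene_id = rep(genes, 2), stringsAsFactors = FALSE)
  expect_warning(p <- binding_site_ora(sites, genes[1:5], genes[6:10], len),
                 "zero variance")
  expect_true(is.na(p))
  expect_warning(p2 <- binding_site_ora(sites, genes[1], genes[2:10], len),
                 "fewer than 2")
  expect_true(is.na(p2))
  # fisher-threshold variant runs on ordinary input
  set.seed(54)
  sites2 <- data.frame(gene_id = rep(genes, rpois(10, 3)),
                       stringsAsFactors = FALSE)
  p3 <- binding_site_ora(sites2, genes[1:5], genes[6:10], len,
                         variant = "fisher_threshold")
  expect_true(p3 >= 0 && p3 <= 1)
})

test_that("ORA across a collection BH-adjusts per set", {
  set.seed(55)
  genes <- paste0("g", 1:40)
  len <- setNames(pmax(50, round(rnorm(40, 250, 50))), genes)
  sites <- data.frame(gene_id = rep(genes, rpois(40, 2)),
                      stringsAsFactors = FALSE)
  coll <- list(s1 = genes[1:10], s2 = genes[11:30], s3 = paste0("x", 1:4))
  res <- suppressWarnings(ora_gene_sets(sites, genes, coll, len))
  expect_identical(res$set_id, c("s1", "s2", "s3"))
  expect_true(is.na(res$p_raw[res$set_id == "s3"]))
  ok <- !is.na(res$p_raw)
  expect_equal(res$p_adj[ok], oracle_bh(res$p_raw[ok]), tolerance = 1e-12)
})
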