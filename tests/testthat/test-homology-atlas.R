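mk_genes <- function(starts, ends, chrom = "chr1",
                     ids = sprintf("g%02d", seq_along(starts))) {
  data.frame(gene_id = ids, species = "human", chrom = chrom,
             start = starts, end = ends, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("CNV status follows any-base overlap with half-open boundaries", {
  genes <- mk_genes(c(100L, 100L), c(200L, 200L), ids = c("a", "b"))
  overlap <- data.frame(chrom = "chr1", start = 150L, end = 400L)
  abut <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  expect_identical(assign_cnv_status(genes[1, ], overlap)$cnv_status, "CNV")
  expect_identical(assign_cnv_status(genes[2, ], abut)$cnv_status, "nonCNV")
  # idempotent
  once <- assign_cnv_status(genes, overlap)
  expect_identical(assign_cnv_status(once, overlap), once)
})

test_that("CNV assignment matches all-pairs brute force on random input", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 50; m <- 10
    gs <- sample.int(5000, n)
    genes <- mk_genes(gs, gs + sample.int(300, n),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    rs <- sample.int(5000, m)
    regions <- data.frame(chrom = sample(c("chr1", "chr2"), m,
                                         replace = TRUE),
                          start = rs, end = rs + sample.int(400, m))
    got <- assign_cnv_status(genes, regions)$cnv_status
    want <- ifelse(oracle_overlaps(genes, regions), "CNV", "nonCNV")
    expect_identical(got, want)
  }
})

test_that("malformed intervals are rejected naming the record", {
  genes <- mk_genes(c(10L, 50L), c(20L, 40L), ids = c("ok", "bad"))
  expect_error(assign_cnv_status(genes, data.frame(chrom = "chr1",
                                                   start = 1L, end = 5L)),
               "bad")
})

test_that("atlas maps non-human genes through human homologs with own status", {
  human <- data.frame(gene_id = "g1", species = "human", chrom = "chr1",
                      start = 0L, end = 100L, strand = "+",
                      cnv_status = "CNV", stringsAsFactors = FALSE)
  mouse <- data.frame(gene_id = c("m1", "m2"), species = "mouse",
                      chrom = "chr1m", start = c(0L, 500L),
                      end = c(100L, 600L), strand = "+",
                      cnv_status = c("CNV", "nonCNV"),
                      stringsAsFactors = FALSE)
  homology <- data.frame(group_id = c("HG1", "HG1"),
                         species = c("human", "mouse"),
                         gene_id = c("g1", "m1"), stringsAsFactors = FALSE)
  res <- build_atlas(human, homology, list(mouse = mouse))
  expect_identical(res$atlas$mouse$gene_id, "m1")
  s <- res$summary
  expect_identical(s$n_cnv[s$species == "mouse"], 1L)
  expect_identical(s$n_noncnv[s$species == "mouse"], 0L)
  # m2 has no human homolog and is not retained
  expect_false("m2" %in% res$atlas$mouse$gene_id)
  # inherit-human-status fallback reclassifies by the human homolog
  mouse2 <- mouse
  mouse2$cnv_status <- "nonCNV"
  res2 <- build_atlas(human, homology, list(mouse = mouse2),
                      inherit_human_status = TRUE)
  expect_identical(res2$atlas$mouse$cnv_status, "CNV")
})

test_that("atlas summary equals the generator truth tallies", {
  cohort <- generate_cohort(tiny_config())
  human <- cohort$genes[cohort$genes$species == "human", ]
  others <- split(cohort$genes[cohort$genes$species != "human", ],
                  cohort$genes$species[cohort$genes$species != "human"])
  res <- build_atlas(human, cohort$homology, others)
  truth_cnv <- table(cohort$truth$cnv_genes$species)
  totals <- table(cohort$genes$species)
  for (sp in cohort$config$species) {
    s <- res$summary[res$summary$species == sp, ]
    expect_identical(s$n_cnv, as.integer(truth_cnv[[sp]]))
    expect_identical(s$n_total, as.integer(totals[[sp]]))
  }
})

test_that("atlas output is invariant to input row order", {
  cohort <- generate_cohort(tiny_config())
  human <- cohort$genes[cohort$genes$species == "human", ]
  others <- split(cohort$genes[cohort$genes$species != "human", ],
                  cohort$genes$species[cohort$genes$species != "human"])
  res1 <- build_atlas(human, cohort$homology, others)
  set.seed(3)
  human_shuf <- human[sample.int(nrow(human)), ]
  others_shuf <- lapply(others, function(g) g[sample.int(nrow(g)), ])
  hom_shuf <- cohort$homology[sample.int(nrow(cohort$homology)), ]
  res2 <- build_atlas(human_shuf, hom_shuf, others_shuf)
  expect_equal(res2$summary, res1$summary)
  for (sp in names(res1$atlas)) {
    expect_identical(res2$atlas[[sp]]$gene_id, res1$atlas[[sp]]$gene_id)
  }
})

test_that("a species in homology without a gene table is a hard error", {
  human <- data.frame(gene_id = "g1", species = "human", chrom = "chr1",
                      start = 0L, end = 10L, strand = "+",
                      cnv_status = "CNV", stringsAsFactors = FALSE)
  homology <- data.frame(group_id = c("HG1", "HG1"),
                         species = c("human", "rat"),
                         gene_id = c("g1", "r1"), stringsAsFactors = FALSE)
  expect_error(build_atlas(human, homology, list()), "rat")
})

test_that("duplicate gene ids keep the first occurrence with a warning", {
  human <- data.frame(gene_id = c("g1", "g1"), species = "human",
                      chrom = "chr1", start = c(0L, 5L), end = c(10L, 20L),
                      strand = "+", cnv_status = c("CNV", "nonCNV"),
                      stringsAsFactors = FALSE)
  homology <- data.frame(group_id = "HG1", species = "human",
                         gene_id = "g1", stringsAsFactors = FALSE)
  expect_warning(res <- build_atlas(human, homology, list()), "duplicated")
  expect_identical(res$summary$n_cnv[res$summary$species == "human"], 1L)
})
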