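let7a <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("family key is mature positions 2-8, independent of position 1", {
  expect_identical(mirna_family(let7a), "GAGGUAG")
  expect_identical(mirna_family("AAAAAAAA"), "AAAAAAA")
  expect_identical(mirna_family("ACGUACGUA"), mirna_family("GCGUACGUA"))
  expect_error(mirna_family("ACGUACG"), "shorter than 8")
})

test_that("seed predictor reports canonical site types with 8mer priority", {
  expect_equal(predict_seed_sites(let7a, "AAACUACCUCAAA"),
               data.frame(utr_offset = 3L, site_type = "8mer", length = 8L))
  expect_equal(predict_seed_sites(let7a, "CUACCUCG"),
               data.frame(utr_offset = 0L, site_type = "7mer-m8",
                          length = 7L))
  # seed complement contains non-G bases, so an all-G UTR has no site
  expect_identical(nrow(predict_seed_sites(let7a,
                                           strrep("G", 50))), 0L)
  expect_error(predict_seed_sites(let7a, "ACGTACGUACG"), "offset 3")
})

test_that("walk predictor finds maximal 5' complementary runs", {
  expect_equal(predict_walk_sites("UGAGGUAG", "CUACCUCA"),
               data.frame(utr_offset = 0L, site_type = "walk-8",
                          length = 8L))
  expect_equal(predict_walk_sites("UGAGGUAG", "CUACCUC"),
               data.frame(utr_offset = 0L, site_type = "walk-7",
                          length = 7L))
  expect_identical(nrow(predict_walk_sites("UGAGGUAG", "CUACCUC",
                                           min_len = 8)), 0L)
  expect_error(predict_walk_sites("UGAGGUAG", "CUACCUCA", min_len = 4),
               "min_len")
})

test_that("both predictors match brute-force scanning on random instances", {
  set.seed(31)
  for (i in 1:200) {
    m <- oracle_random_rna(sample(18:25, 1))
    utr <- oracle_random_rna(sample(30:200, 1))
    expect_equal(predict_seed_sites(m, utr), oracle_seed_sites(m, utr),
                 info = paste(m, utr))
    expect_equal(predict_walk_sites(m, utr), oracle_walk_sites(m, utr),
                 info = paste(m, utr))
  }
})

test_that("an 8mer locus is always covered by a walk site of length >= 7", {
  set.seed(32)
  for (i in 1:100) {
    m <- oracle_random_rna(22)
    utr <- paste0(oracle_random_rna(40),
                  paste0(oracle_rc(substr(m, 2, 8)), "A"),
                  oracle_random_rna(40))
    seeds <- predict_seed_sites(m, utr)
    e8 <- seeds[seeds$site_type == "8mer", ]
    expect_gt(nrow(e8), 0)
    walks <- predict_walk_sites(m, utr)
    for (j in seq_len(nrow(e8))) {
      covered <- any(walks$utr_offset <= e8$utr_offset[j] &
                       walks$utr_offset + walks$length >=
                         e8$utr_offset[j] + 7L)
      expect_true(covered)
    }
  }
})

test_that("background 7mer-m8 counts match the analytic expectation", {
  # uniform UTRs of length L: E[count] = (L-6) * 4^-7 per (miRNA, UTR)
  set.seed(33)
  L <- 60; trials <- 10000
  utrs <- vapply(seq_len(trials), function(i) oracle_random_rna(L),
                 character(1))
  m <- oracle_random_rna(22)
  total <- 0L
  for (u in utrs) {
    s <- predict_seed_sites(m, u)
    total <- total + sum(s$site_type %in% c("7mer-m8", "8mer"))
  }
  expected <- trials * (L - 6) * 4^-7
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("intersection keeps exactly the pairs seen by both predictors", {
  w <- data.frame(mirna_id = "m1", gene_id = "g1", species = "human",
                  utr_offset = 5L, site_type = "walk-7", length = 7L,
                  stringsAsFactors = FALSE)
  s <- data.frame(mirna_id = c("m1", "m1"), gene_id = c("g1", "g2"),
                  species = "human", utr_offset = c(5L, 9L),
                  site_type = "7mer-m8", length = 7L,
                  stringsAsFactors = FALSE)
  res <- intersect_predictions(w, s)
  expect_identical(res$pairs$gene_id, "g1")
  expect_identical(res$pairs$predicted_by, "walk+seed")
  # disjoint inputs -> empty
  s2 <- s; s2$gene_id <- "g9"
  expect_identical(nrow(intersect_predictions(w, s2)$pairs), 0L)
  # species mismatch is an error
  s3 <- s; s3$species <- "mouse"
  expect_error(intersect_predictions(w, s3), "species mismatch")
})

test_that("intersection equals brute-force double-loop on random tables", {
  set.seed(34)
  w <- random_site_table(1000)
  s <- random_site_table(1000)
  res <- intersect_predictions(w, s)
  wk <- unique(paste(w$mirna_id, w$gene_id))
  sk <- unique(paste(s$mirna_id, s$gene_id))
  want <- character(0)
  for (k in wk) for (j in sk) if (k == j) want <- c(want, k)
  got <- paste(res$pairs$mirna_id, res$pairs$gene_id)
  expect_setequal(got, want)
  # intersected pairs are a subset of each input's pairs
  expect_true(all(got %in% wk) && all(got %in% sk))
  # site lists are deduplicated on (offset, site_type)
  expect_false(any(duplicated(res$sites[, c("mirna_id", "gene_id",
                                            "species", "utr_offset",
                                            "site_type")])))
})

test_that("family collapse is a surjection from miRNA pairs", {
  mirnas <- data.frame(
    mirna_id = c("mA", "mB", "mC"),
    mature_seq = c("AACGUACGUACGUACGUACGU", "GACGUACGUACGUACGUACGU",
                   "CCCCCCCCCCCCCCCCCCCCC"),
    stringsAsFactors = FALSE)
  pairs <- data.frame(mirna_id = c("mA", "mB", "mC"),
                      gene_id = c("g1", "g1", "g1"), species = "human",
                      stringsAsFactors = FALSE)
  fam <- collapse_families(pairs, mirnas)
  # mA and mB share the seed; three miRNA pairs collapse to two family pairs
  expect_identical(nrow(fam), 2L)
  expect_lte(nrow(fam), nrow(pairs))
})

test_that("predict_all recovers planted pairs and handles empty catalogs", {
  cohort <- generate_cohort(tiny_config())
  pred <- predict_all(cohort$mirnas, cohort$genes, stratum = "all")
  ps <- cohort$truth$planted_sites
  got <- paste(ps$species, ps$gene_id, ps$mirna_id) %in%
    paste(pred$pairs$species, pred$pairs$gene_id, pred$pairs$mirna_id)
  expect_true(all(got))
  # family pair count never exceeds miRNA pair count per (species, gene)
  mp <- table(paste(pred$pairs$species, pred$pairs$gene_id))
  fp <- table(paste(pred$family_pairs$species, pred$family_pairs$gene_id))
  expect_true(all(fp[names(fp)] <= mp[names(fp)]))
  # zero miRNAs -> empty output
  none <- predict_all(cohort$mirnas[0, ], cohort$genes)
  expect_identical(nrow(none$pairs), 0L)
})
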