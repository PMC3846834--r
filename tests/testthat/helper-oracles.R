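# Independent brute-force oracles and small fixtures used across the suite.
# Each oracle is written from the definition, not by calling the package
# code paths it checks.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A")

oracle_rc <- function(s) {
  paste(rev(unname(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1]]])),
        collapse = "")
}

oracle_random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# exhaustive substring scan for canonical seed sites
oracle_seed_sites <- function(mature, utr) {
  L <- nchar(utr)
  s8 <- paste0(oracle_rc(substr(mature, 2, 8)), "A")
  s7m8 <- oracle_rc(substr(mature, 2, 8))
  s7a1 <- paste0(oracle_rc(substr(mature, 2, 7)), "A")
  rows <- list()
  starts8 <- integer(0)
  for (i in seq_len(max(0L, L - 7L))) {
    if (substr(utr, i, i + 7L) == s8) {
      starts8 <- c(starts8, i)
      rows[[length(rows) + 1L]] <- list(i - 1L, "8mer", 8L)
    }
  }
  for (i in seq_len(max(0L, L - 6L))) {
    if (substr(utr, i, i + 6L) == s7m8 && !(i %in% starts8)) {
      rows[[length(rows) + 1L]] <- list(i - 1L, "7mer-m8", 7L)
    }
    if (substr(utr, i, i + 6L) == s7a1 && !((i - 1L) %in% starts8)) {
      rows[[length(rows) + 1L]] <- list(i - 1L, "7mer-A1", 7L)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(utr_offset = integer(0), site_type = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(utr_offset = vapply(rows, function(r) r[[1]], integer(1)),
                    site_type = vapply(rows, function(r) r[[2]], character(1)),
                    length = vapply(rows, function(r) r[[3]], integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$utr_offset, out$site_type), ]
  rownames(out) <- NULL
  out
}

# brute-force antiparallel pairing scan: for each anchor (miRNA position 1
# or 2) and each rightmost UTR base, the maximal consecutive Watson-Crick
# run, then containment collapse
oracle_walk_sites <- function(mature, utr, min_len = 7L) {
  L <- nchar(utr)
  n <- nchar(mature)
  uc <- strsplit(utr, "", fixed = TRUE)[[1]]
  mc <- strsplit(mature, "", fixed = TRUE)[[1]]
  found <- list()
  for (a in c(1L, 2L)) {
    for (r in seq_len(L)) {
      k <- 0L
      while (a + k <= n && r - k >= 1L &&
             uc[r - k] == ORACLE_COMP[[mc[a + k]]]) {
        k <- k + 1L
      }
      if (k >= min_len) {
        found[[length(found) + 1L]] <- c(offset = r - k, len = k)
      }
    }
  }
  if (length(found) == 0L) {
    return(data.frame(utr_offset = integer(0), site_type = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  d <- unique(do.call(rbind, found))
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (i == j) next
      if (d[i, "offset"] >= d[j, "offset"] &&
          d[i, "offset"] + d[i, "len"] <= d[j, "offset"] + d[j, "len"] &&
          d[i, "len"] < d[j, "len"]) {
        keep[i] <- FALSE
      }
    }
  }
  d <- d[keep, , drop = FALSE]
  out <- data.frame(utr_offset = as.integer(d[, "offset"]),
                    site_type = paste0("walk-", d[, "len"]),
                    length = as.integer(d[, "len"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$utr_offset), ]
  rownames(out) <- NULL
  out
}

# all-pairs interval overlap (any base, half-open)
oracle_overlaps <- function(genes, regions) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(regions$chrom == genes$chrom[i] &
          regions$start < genes$end[i] &
          regions$end > genes$start[i])
  }, logical(1))
}

# all-pairs containment (miRNA fully inside gene, same chrom)
oracle_within <- function(mirnas, genes) {
  do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i) {
    hit <- which(genes$chrom == mirnas$chrom[i] &
                   genes$start <= mirnas$start[i] &
                   genes$end >= mirnas$end[i])
    if (length(hit) == 0) return(NULL)
    data.frame(mirna_id = mirnas$mirna_id[i], gene_id = genes$gene_id[hit],
               stringsAsFactors = FALSE)
  }))
}

# exact hypergeometric upper tail by direct combinatorial enumeration
oracle_fisher_tail <- function(a, b, c, d) {
  R1 <- a + b; C1 <- a + c; N <- a + b + c + d
  lo <- max(0L, R1 - (N - C1)); hi <- min(R1, C1)
  xs <- lo:hi
  probs <- choose(C1, xs) * choose(N - C1, R1 - xs) / choose(N, R1)
  sum(probs[xs >= a])
}

# independent step-up BH from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# small, fast generator configuration for structural tests
tiny_config <- function(rng_seed = 11L, ...) {
  synthetic_config(n_species = 3L, n_homology_groups = 40L, n_mirnas = 10L,
                   n_prolific_mirnas = 2L, n_pathways = 8L,
                   pathway_size_range = c(8L, 15L),
                   n_gene_classes = 3L, class_size_range = c(8L, 15L),
                   utr_length_mean = 120, utr_length_sd = 20,
                   rng_seed = rng_seed, ...)
}

random_site_table <- function(n, n_mirnas = 20, n_genes = 30,
                              species = "human") {
  data.frame(
    mirna_id = paste0("m", sample.int(n_mirnas, n, replace = TRUE)),
    gene_id = paste0("g", sample.int(n_genes, n, replace = TRUE)),
    species = species,
    utr_offset = sample.int(200, n, replace = TRUE) - 1L,
    site_type = sample(c("7mer-m8", "8mer", "walk-7"), n, replace = TRUE),
    length = 7L,
    stringsAsFactors = FALSE
  )
}
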