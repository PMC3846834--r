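#' @keywords internal
"_PACKAGE"

#' @importFrom stats kruskal.test p.adjust phyper rnorm rpois runif wilcox.test
#' @importFrom utils read.delim write.table
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

# Watson-Crick complement of an RNA string (no wobble).
rna_complement <- function(x) chartr("ACGU", "UGCA", x)

# Reverse complement, vectorised over character strings.
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(rna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate an RNA string; returns the 1-based offset of the first bad
# character, or 0L when clean.
first_non_acgu <- function(x) {
  m <- regexpr("[^ACGU]", x)
  if (m > 0) as.integer(m) else 0L
}

stop_if_not_rna <- function(x, what = "sequence") {
  bad <- first_non_acgu(x)
  if (bad > 0L) {
    stop(sprintf("non-ACGU character in %s at position %d", what, bad),
         call. = FALSE)
  }
  invisible(x)
}

# DNA (T) to RNA (U) transliteration used by FASTA readers; logs once per
# call when a T was seen.
dna_to_rna <- function(x, label = "input FASTA") {
  if (any(grepl("T", x, fixed = TRUE))) {
    message(sprintf("[mircnv] transliterating T -> U in %s", label))
    x <- chartr("Tt", "Uu", x)
  }
  toupper(x)
}

# sample() treats a length-1 numeric as 1:n; these avoid that trap
sample1 <- function(x) x[sample.int(length(x), 1L)]
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Uniform random RNA strings of the given lengths (vectorised).
random_rna <- function(lengths) {
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  chars <- sample(RNA_ALPHABET, total, replace = TRUE)
  idx <- rep.int(seq_along(lengths), lengths)
  vapply(split(chars, idx), paste, character(1), collapse = "", USE.NAMES = FALSE)
}

# Validate an interval data.frame (chrom, start, end in 0-based half-open
# coordinates); names the first offending record.
check_intervals <- function(df, id_col = NULL, what = "interval table") {
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0) {
    lab <- if (!is.null(id_col) && id_col %in% names(df)) {
      as.character(df[[id_col]][bad[1]])
    } else {
      sprintf("row %d", bad[1])
    }
    stop(sprintf("malformed interval (start >= end) in %s: %s", what, lab),
         call. = FALSE)
  }
  invisible(df)
}

# Convert a 0-based half-open interval data.frame to GRanges.
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df) && length(df$strand) > 0) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else {
    rep("*", nrow(df))
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# Deterministic TSV writer shared by all stages (byte-stable output).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
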