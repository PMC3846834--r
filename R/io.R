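# Readers and writers for the plain-text interchange formats used between
# pipeline stages: FASTA (Biostrings), BED6 (rtracklayer), TSV, GMT (fgsea
# reader, hand-written writer as no installed package provides one) and the
# JSON truth sidecar.

#' Write sequences to FASTA
#'
#' @param seqs named character vector of RNA sequences (names become FASTA
#'   headers).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::RNAStringSet(unlist(as.character(seqs), use.names = TRUE))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' DNA input (containing T) is transliterated to RNA and a message is logged
#' once. Headers are kept verbatim as names.
#'
#' @param path FASTA file path.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- dna_to_rna(as.character(x), label = basename(path))
  names(out) <- names(x)
  out
}

#' Write genomic intervals as BED6
#'
#' Intervals are 0-based half-open internally, matching BED natively.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, a `name` column
#'   (identified by `name_col`) and optionally `strand`.
#' @param path output file path.
#' @param name_col column holding the feature name (default `"name"`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name_col = "name") {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- intervals_to_granges(df)
  names(gr) <- as.character(df[[name_col]])
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval data.frame
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write a gene-set collection in GMT format
#'
#' One line per set: set id, description, then tab-separated gene ids.
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param description single description string or vector (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0L) return(setNames(list(), character(0)))
  fgsea::gmtPathways(path)
}

#' Write a homology table (group_id, species, gene_id) as TSV
#'
#' @param homology data.frame with columns `group_id`, `species`, `gene_id`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_homology <- function(homology, path) {
  write_tsv(homology[, c("group_id", "species", "gene_id")], path)
}

#' Read a homology table TSV
#'
#' @param path TSV with columns `group_id`, `species`, `gene_id`.
#' @return data.frame.
#' @export
read_homology <- function(path) {
  df <- read_tsv(path)
  req <- c("group_id", "species", "gene_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("homology table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df[req] <- lapply(df[req], as.character)
  df
}

#' Read an externally computed miRNA target prediction table
#'
#' Allows real prediction exports to replace the built-in predictors. The
#' table must carry one row per binding site.
#'
#' @param path TSV with columns `mirna_id`, `gene_id`, `species`,
#'   `utr_offset`, `site_type`, `source` (`source` in `walk`/`seed`).
#' @return site-level data.frame as produced by the built-in predictors.
#' @export
read_predictions <- function(path) {
  df <- read_tsv(path)
  req <- c("mirna_id", "gene_id", "species", "utr_offset", "site_type",
           "source")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("prediction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$source), c("walk", "seed"))
  if (length(bad) > 0) {
    stop("unknown prediction source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$utr_offset <- as.integer(df$utr_offset)
  if (!"length" %in% names(df)) {
    df$length <- ifelse(df$site_type == "8mer", 8L,
                        ifelse(grepl("^walk-", df$site_type),
                               as.integer(sub("^walk-", "", df$site_type)), 7L))
  }
  df
}
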