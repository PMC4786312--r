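# Readers/writers for the standard interchange formats: FASTA via
# Biostrings, GFF3 via rtracklayer/GenomicRanges (internal coordinates are
# 0-based half-open; GFF3 is 1-based inclusive), trees via ape, tables as
# TSV.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(unlist(seqs))
  else Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write gene loci as GFF3
#'
#' Internal 0-based half-open loci are converted to the 1-based inclusive
#' GFF3 convention.
#'
#' @param loci data.frame: scaffold, start, end, strand, id, plus optional
#'   `status` and `subfamily` columns carried into the attributes.
#' @param path Output path.
#' @param source Source tag for column 2.
#' @export
write_gff3 <- function(loci, path, source = "taarevol") {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$scaffold,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$ID <- loci$id
  if (!is.null(loci$status)) S4Vectors::mcols(gr)$status <- loci$status
  if (!is.null(loci$subfamily))
    S4Vectors::mcols(gr)$subfamily <- loci$subfamily
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene loci from GFF3 into internal coordinates
#'
#' @param path GFF3 path.
#' @return data.frame: scaffold, start, end (0-based half-open), strand,
#'   id (+status/subfamily attributes when present).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = S4Vectors::mcols(gr)$ID)
  for (col in c("status", "subfamily"))
    if (col %in% names(S4Vectors::mcols(gr)))
      out[[col]] <- S4Vectors::mcols(gr)[[col]]
  out
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D Symmetric matrix with row names.
#' @param path Output path.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Input path.
#' @return Symmetric matrix with dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  labs <- character(n)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    labs[i] <- parts[1L]
    D[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(D) <- list(labs, labs)
  D
}

#' Write a tab-separated table
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
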