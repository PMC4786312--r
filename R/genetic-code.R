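# Genetic-code and residue machinery shared across the package. The codon
# state space follows the GY94/PAML convention: the standard nuclear code with
# the three stop codons removed, leaving 61 sense codons.

NUCS <- c("T", "C", "A", "G")

AA_ALPHABET1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  codons64 <- names(gc)
  sense <- codons64[gc != "*"]
  stopifnot(length(sense) == 61L)
  aa_of <- gc[sense]
  # codon index 1..61 in fixed (alphabetical) order of the sense codons
  idx <- seq_along(sense)
  names(idx) <- sense
  # single-nucleotide neighbor structure among sense codons
  nb <- vector("list", 61L)
  splt <- do.call(rbind, strsplit(sense, ""))
  for (i in idx) {
    hits <- which(rowSums(splt != matrix(splt[i, ], 61L, 3L, byrow = TRUE)) == 1L)
    pos <- integer(0); ts <- logical(0)
    for (j in hits) {
      p <- which(splt[i, ] != splt[j, ])
      pos <- c(pos, p)
      pair <- sort(c(splt[i, p], splt[j, p]))
      ts <- c(ts, identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
    }
    nb[[i]] <- list(to = hits, pos = pos, transition = ts,
                    synonymous = aa_of[hits] == aa_of[i])
  }
  # flat edge arrays of the single-nucleotide-change graph (for vectorized
  # rate-matrix construction)
  ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
  for (i in idx) {
    nbi <- nb[[i]]
    ii <- c(ii, rep.int(i, length(nbi$to)))
    jj <- c(jj, nbi$to)
    ts <- c(ts, nbi$transition)
    syn <- c(syn, nbi$synonymous)
  }
  .codon_env$tab <- list(codons = sense, aa = aa_of, index = idx,
                         split = splt, neighbors = nb,
                         stops = codons64[gc == "*"],
                         edge_i = ii, edge_j = jj, edge_ts = ts,
                         edge_syn = syn)
  .codon_env$tab
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in the fixed package order
#'   (alphabetical), the order used by every 61-vector and 61 x 61 matrix in
#'   the codon-model machinery.
#' @export
sense_codons <- function() .codon_tables()$codons

#' Amino acid encoded by each sense codon
#'
#' @return Named character vector over [sense_codons()].
#' @export
codon_aa <- function() .codon_tables()$aa

codon_index <- function(codons) {
  idx <- .codon_tables()$index[codons]
  as.integer(idx)
}

#' Reverse complement of a nucleotide string
#'
#' Ambiguity characters other than N are left as N.
#'
#' @param x Single nucleotide string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string
#'
#' Translation runs codon-by-codon from the first position; trailing bases
#' that do not fill a codon are dropped. Stop codons become `*` and any codon
#' containing a non-ACGT character becomes `X`.
#'
#' @param x Nucleotide string.
#' @return Amino-acid string (may contain `*` and `X`).
#' @export
translate_nt <- function(x) {
  n <- nchar(x)
  if (n < 3L) return("")
  n <- n - n %% 3L
  codons <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Random nucleotide string (uniform ACGT) using the session RNG.
random_nt <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Split a CDS into codon strings.
codon_split <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
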