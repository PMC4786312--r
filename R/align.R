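# Protein alignment container and a deterministic progressive aligner:
# k-mer distances -> UPGMA guide tree -> profile-profile merges with affine
# gaps under BLOSUM62. Precomputed alignments can be supplied instead
# anywhere a protein_alignment is accepted.

#' Protein alignment container
#'
#' @param seqs Named character vector/list of equal-length aligned rows
#'   (gap `-`).
#' @return A `protein_alignment`: `ids`, `seqs` (named list), `n_col`.
#' @export
protein_alignment <- function(seqs) {
  seqs <- as.list(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("rows must have unique ids")
  L <- unique(nchar(unlist(seqs)))
  if (length(L) != 1L) stop("rows differ in length")
  structure(list(ids = names(seqs), seqs = seqs, n_col = L),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein alignment:", length(x$ids), "rows x", x$n_col, "columns\n")
  invisible(x)
}

kmer_counts <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

# Fractional-common-k-mer distance between unaligned sequences.
kmer_distance <- function(a, b, k = 3L) {
  ca <- kmer_counts(a, k); cb <- kmer_counts(b, k)
  shared <- sum(pmin(ca[names(cb)], cb)[!is.na(ca[names(cb)])])
  1 - shared / max(1L, min(sum(ca), sum(cb)))
}

# Deterministic UPGMA with smallest-index tie-breaking; returns the merge
# order as a list of (left member ids, right member ids).
upgma_merge_order <- function(D, ids) {
  n <- length(ids)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  Dm <- D
  merges <- list()
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bestd <- Inf
    idx <- which(active)
    for (ii in seq_along(idx)) for (jj in seq_len(ii - 1L)) {
      i <- idx[jj]; j <- idx[ii]
      if (Dm[i, j] < bestd - 1e-12) { bestd <- Dm[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    merges[[step]] <- list(left = clusters[[i]], right = clusters[[j]])
    # average-linkage update onto slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      Dm[i, k] <- Dm[k, i] <- (sizes[i] * Dm[i, k] + sizes[j] * Dm[j, k]) /
        (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  merges
}

profile_freqs <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  F <- matrix(0, 20L, L, dimnames = list(AA_ALPHABET1, NULL))
  for (a in AA_ALPHABET1) F[a, ] <- colSums(m == a)
  F / nrow(m)
}

# Merge two profiles (lists of aligned rows) with the affine DP kernel.
merge_profiles <- function(rows1, rows2, sub20, gap_open = 11,
                           gap_extend = 1) {
  F1 <- profile_freqs(rows1); F2 <- profile_freqs(rows2)
  S <- t(F1) %*% sub20 %*% F2
  path <- gotoh_global_cpp(S, gap_open, gap_extend)
  expand <- function(rows, idx) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(m), length(idx))
    out[, idx > 0L] <- m[, idx[idx > 0L], drop = FALSE]
    apply(out, 1L, paste0, collapse = "")
  }
  c(setNames(expand(rows1, path$idx1), names(rows1)),
    setNames(expand(rows2, path$idx2), names(rows2)))
}

#' Progressive multiple alignment of proteins
#'
#' Guide tree from fractional-common-k-mer distances (UPGMA,
#' smallest-index tie rule); profiles merged leaf-to-root with an affine
#' global DP over average-of-pairs BLOSUM62 column scores. Input order
#' does not affect the result (sequences are sorted by id first).
#'
#' @param sequences Named character vector of unaligned proteins (>= 2).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param k k-mer size for the guide distances.
#' @return A [protein_alignment()] (rows in sorted-id order).
#' @export
progressive_align <- function(sequences, gap_open = 11, gap_extend = 1,
                              k = 3L) {
  if (length(sequences) < 2L) stop("need >= 2 sequences")
  bad <- vapply(sequences, function(s)
    !all(split1(s) %in% AA_ALPHABET1), TRUE)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  sequences <- unlist(sequences)[order(names(sequences))]
  n <- length(sequences)
  if (n == 2L) {
    m <- blosum62_encoded()
    sub20 <- m[AA_ALPHABET1, AA_ALPHABET1]
    merged <- merge_profiles(sequences[1L], sequences[2L], sub20,
                             gap_open, gap_extend)
    return(protein_alignment(merged))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    D[i, j] <- D[j, i] <- kmer_distance(sequences[i], sequences[j], k)
  }
  merges <- upgma_merge_order(D, names(sequences))
  m <- blosum62_encoded()
  sub20 <- m[AA_ALPHABET1, AA_ALPHABET1]
  profiles <- lapply(seq_len(n), function(i) sequences[i])
  for (mg in merges) {
    i <- mg$left[1L]; j <- mg$right[1L]
    profiles[[i]] <- merge_profiles(profiles[[i]], profiles[[j]], sub20,
                                    gap_open, gap_extend)
    profiles[j] <- list(NULL)  # keep slot so indices stay stable
  }
  rows <- profiles[[merges[[length(merges)]]$left[1L]]]
  protein_alignment(rows[order(names(rows))])
}

#' Percent-identity between two rows of an alignment
#'
#' @param alignment A [protein_alignment()].
#' @param id1,id2 Row ids.
#' @return Fraction of identical residues over shared ungapped columns.
#' @export
pairwise_identity <- function(alignment, id1, id2) {
  a <- split1(alignment$seqs[[id1]])
  b <- split1(alignment$seqs[[id2]])
  ok <- a != "-" & b != "-"
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}
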