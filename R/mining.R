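# Translated homology mining of genome scaffolds: six-frame translation,
# affine-gap local alignment against protein queries, Karlin-Altschul
# E-values with a fixed effective database length (so E-values are
# comparable across genomes of different sizes), recursive re-searching
# with newly found candidates, reciprocal verification against a labelled
# reference set, and a log-odds profile search for divergent subfamilies.

#' Search parameters
#'
#' @param evalue_threshold Maximum E-value of a reported hit
#'   (default 1e-30).
#' @param effective_db_length Effective database length (nucleotides) used
#'   in the E-value formula (default 1.1e10).
#' @param gap_open,gap_extend Affine gap penalties (BLAST-style: a gap of
#'   length L costs open + L * extend).
#' @param karlin_k,karlin_lambda Calibration constants of the E-value
#'   formula `E = K m n exp(-lambda S)`; defaults are the published
#'   ungapped BLOSUM62 values.
#' @param max_chain_gap Maximum nucleotide gap when chaining collinear
#'   same-strand hits into one locus (frameshift/pseudogene evidence).
#' @return A `search_params` list.
#' @export
search_params <- function(evalue_threshold = 1e-30,
                          effective_db_length = 1.1e10,
                          gap_open = 11L, gap_extend = 1L,
                          karlin_k = 0.134, karlin_lambda = 0.3176,
                          max_chain_gap = 1000L) {
  stopifnot(evalue_threshold > 0, effective_db_length > 0)
  list(evalue_threshold = evalue_threshold,
       effective_db_length = effective_db_length,
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
       karlin_k = karlin_k, karlin_lambda = karlin_lambda,
       max_chain_gap = as.integer(max_chain_gap))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n_eff * exp(-lambda * S)` with m the query length and
#' n_eff the effective database length.
#'
#' @param score Raw alignment score.
#' @param query_length Query length (residues).
#' @param params A [search_params()].
#' @return E-value.
#' @export
karlin_evalue <- function(score, query_length, params) {
  params$karlin_k * query_length * params$effective_db_length *
    exp(-params$karlin_lambda * score)
}

.blosum_env <- new.env(parent = emptyenv())

# BLOSUM62 over the extended alphabet (incl. X and *), integer-encoded.
blosum62_encoded <- function() {
  if (!is.null(.blosum_env$mat)) return(.blosum_env$mat)
  data("BLOSUM62", package = "Biostrings", envir = .blosum_env)
  m <- .blosum_env$BLOSUM62
  alpha <- colnames(m)
  .blosum_env$alpha <- alpha
  .blosum_env$mat <- m
  m
}

encode_aa <- function(x, strict = FALSE) {
  blosum62_encoded()
  alpha <- .blosum_env$alpha
  v <- match(split1(x), alpha)
  if (anyNA(v)) {
    if (strict) stop("non-amino-acid character in protein sequence")
    v[is.na(v)] <- match("X", alpha)
  }
  v - 1L
}

# Best local alignment of query protein vs subject protein (both character
# strings); thin wrapper over the C++ kernel.
local_align <- function(query, subject, params = search_params()) {
  m <- blosum62_encoded()
  r <- sw_align_cpp(encode_aa(query), encode_aa(subject), unname(m),
                    params$gap_open, params$gap_extend)
  r$identity_fraction <- if (r$aligned_length > 0)
    r$matches / r$aligned_length else 0
  r
}

# Six-frame translations of one scaffold. Returns a data.frame of frames
# with the translated sequence and coordinate conversion parameters.
six_frames <- function(scaffold_seq) {
  L <- nchar(scaffold_seq)
  rc <- revcomp(scaffold_seq)
  out <- list()
  for (f in 0:2) {
    out[[length(out) + 1L]] <- list(strand = "+", frame = f,
                                    aa = translate_nt(substring(scaffold_seq,
                                                                f + 1L)))
    out[[length(out) + 1L]] <- list(strand = "-", frame = f,
                                    aa = translate_nt(substring(rc, f + 1L)))
  }
  out
}

# Map an aa interval [s,e) on a frame translation to 0-based half-open
# scaffold nucleotide coordinates.
frame_to_nt <- function(aa_start, aa_end, strand, frame, L) {
  nt_start <- frame + 3L * aa_start
  nt_end <- frame + 3L * aa_end
  if (strand == "+") c(nt_start, nt_end) else c(L - nt_end, L - nt_start)
}

#' Six-frame translated search of scaffolds with a protein query
#'
#' Every scaffold is translated in all six frames (translations run to the
#' frame boundary, ambiguous codons become X) and locally aligned to the
#' query with affine gaps under BLOSUM62. Within each frame,
#' non-overlapping hits are peeled off iteratively (best first, matched
#' region masked) until the E-value threshold is passed.
#'
#' @param scaffolds Named character vector of nucleotide scaffolds.
#' @param query_protein Amino-acid query (>= 30 residues).
#' @param params A [search_params()].
#' @param query_id Id recorded in the hits.
#' @return data.frame of hits sorted by E-value: scaffold, start, end
#'   (0-based half-open nucleotide coords), strand, frame, raw_score,
#'   evalue, query, identity_fraction.
#' @export
translated_search <- function(scaffolds, query_protein,
                              params = search_params(), query_id = "query") {
  if (length(scaffolds) == 0L) return(empty_hits())
  if (nchar(query_protein) < 30L) stop("query shorter than 30 aa")
  if (any(is.na(match(split1(query_protein), .blosum_env$alpha %||%
                      colnames(blosum62_encoded())))))
    stop("query contains non-amino-acid characters")
  qenc <- encode_aa(query_protein, strict = TRUE)
  qlen <- nchar(query_protein)
  mat <- unname(blosum62_encoded())
  # minimum raw score that can reach the threshold
  min_score <- ceiling(log(params$karlin_k * qlen *
                             params$effective_db_length /
                             params$evalue_threshold) /
                         params$karlin_lambda)
  hits <- list()
  for (sc in names(scaffolds)) {
    L <- nchar(scaffolds[[sc]])
    for (fr in six_frames(scaffolds[[sc]])) {
      senc <- encode_aa(fr$aa)
      repeat {
        r <- sw_align_cpp(qenc, senc, mat, params$gap_open, params$gap_extend)
        if (r$score < min_score) break
        nt <- frame_to_nt(r$s_start, r$s_end, fr$strand, fr$frame, L)
        hits[[length(hits) + 1L]] <- data.frame(
          scaffold = sc, start = nt[1L], end = nt[2L], strand = fr$strand,
          frame = fr$frame, raw_score = r$score,
          evalue = karlin_evalue(r$score, qlen, params), query = query_id,
          identity_fraction = if (r$aligned_length > 0)
            r$matches / r$aligned_length else 0)
        # mask the matched subject region and look for further hits
        senc[(r$s_start + 1L):r$s_end] <- match("*", .blosum_env$alpha) - 1L
      }
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$evalue, out$scaffold, out$start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0),
             raw_score = numeric(0), evalue = numeric(0),
             query = character(0), identity_fraction = numeric(0))
}

# Merge/chain hits into candidate loci. Same-strand hits overlapping by
# >= 50% of the shorter are merged; same-strand collinear hits separated by
# <= max_chain_gap nt are chained (frameshift/pseudogene fragments).
merge_hits <- function(hits, params = search_params()) {
  if (nrow(hits) == 0L)
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_frames = integer(0), best_query = character(0),
                      best_score = numeric(0)))
  loci <- list()
  for (grp in split(hits, paste(hits$scaffold, hits$strand))) {
    grp <- grp[order(grp$start, -grp$end), , drop = FALSE]
    cur <- grp[1L, ]
    frames <- cur$frame
    for (i in seq_len(nrow(grp))[-1L]) {
      h <- grp[i, ]
      ov <- min(cur$end, h$end) - max(cur$start, h$start)
      shorter <- min(cur$end - cur$start, h$end - h$start)
      # hits are sorted by start, so h$start - cur$end is the gap (negative
      # when fragments overlap, as frameshift pieces around a lesion do)
      if (ov >= 0.5 * shorter || h$start - cur$end <= params$max_chain_gap) {
        if (h$raw_score > cur$raw_score) {
          cur$raw_score <- h$raw_score; cur$query <- h$query
          cur$evalue <- h$evalue
        }
        cur$start <- min(cur$start, h$start)
        cur$end <- max(cur$end, h$end)
        frames <- union(frames, h$frame)
      } else {
        loci[[length(loci) + 1L]] <- cbind(cur, n_frames = length(frames))
        cur <- h; frames <- h$frame
      }
    }
    loci[[length(loci) + 1L]] <- cbind(cur, n_frames = length(frames))
  }
  out <- do.call(rbind, loci)
  data.frame(scaffold = out$scaffold, start = out$start, end = out$end,
             strand = out$strand, n_frames = out$n_frames,
             best_query = out$query, best_score = out$raw_score,
             row.names = NULL)
}

#' Verify a candidate against a labelled reference set
#'
#' The candidate is locally aligned to every reference protein; it passes
#' iff the best-scoring reference is in-family. Ties break by higher
#' identity fraction, then lexicographically smaller reference id.
#'
#' @param candidate_protein Amino-acid string.
#' @param reference_db data.frame with columns `id`, `sequence`,
#'   `in_family` (logical) and optionally `family`.
#' @param params A [search_params()].
#' @return List: `verified` (logical), `best_hit` (reference id),
#'   `family` label when present.
#' @export
reciprocal_verify <- function(candidate_protein, reference_db,
                              params = search_params()) {
  if (nrow(reference_db) == 0L) stop("empty reference database")
  scores <- lapply(reference_db$sequence, function(s)
    local_align(candidate_protein, s, params))
  sc <- vapply(scores, `[[`, 0, "score")
  idf <- vapply(scores, `[[`, 0, "identity_fraction")
  ord <- order(-sc, -idf, reference_db$id)
  best <- ord[1L]
  list(verified = isTRUE(reference_db$in_family[best]),
       best_hit = reference_db$id[best],
       family = if ("family" %in% names(reference_db))
         reference_db$family[best] else NA_character_)
}

# Extract the translated protein over a candidate locus (frame 0 of the
# locus on its strand, stops as '*').
locus_protein <- function(scaffold_seq, start, end, strand) {
  s <- substr(scaffold_seq, start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  translate_nt(s)
}

#' Recursive mining of receptor loci
#'
#' Runs [translated_search()] with the seed queries, merges hits into
#' candidate loci, keeps loci whose translation passes
#' [reciprocal_verify()], then re-runs the search using the newly found
#' candidates as queries, until no new locus is found (the candidate set
#' is monotone non-decreasing; a 20-iteration cap guards the loop).
#'
#' @param genomes Named character vector of scaffolds.
#' @param seed_queries Named character vector of seed proteins.
#' @param reference_db Reference set for [reciprocal_verify()].
#' @param params A [search_params()].
#' @return data.frame of candidate loci: scaffold, start, end, strand,
#'   n_frames, best_query, verified family label, protein.
#' @export
recursive_mine <- function(genomes, seed_queries, reference_db,
                           params = search_params()) {
  if (length(seed_queries) == 0L) stop("seed_queries must be non-empty")
  loci <- NULL
  queries <- seed_queries
  for (round in seq_len(20L)) {
    hits <- do.call(rbind, lapply(names(queries), function(qid)
      translated_search(genomes, queries[[qid]], params, query_id = qid)))
    hits <- hits[hits$evalue <= params$evalue_threshold, , drop = FALSE]
    cand <- merge_hits(hits, params)
    new_rows <- list()
    for (i in seq_len(nrow(cand))) {
      if (!is.null(loci)) {
        same <- loci$scaffold == cand$scaffold[i] &
          loci$strand == cand$strand[i]
        if (any(same)) {
          ov <- pmin(loci$end[same], cand$end[i]) -
            pmax(loci$start[same], cand$start[i])
          shorter <- pmin(loci$end[same] - loci$start[same],
                          cand$end[i] - cand$start[i])
          if (any(ov >= 0.5 * shorter)) next  # already known locus
        }
      }
      prot <- locus_protein(genomes[[cand$scaffold[i]]], cand$start[i],
                            cand$end[i], cand$strand[i])
      rv <- reciprocal_verify(gsub("[*]", "X", prot), reference_db, params)
      if (!rv$verified) next
      row <- cand[i, , drop = FALSE]
      row$family <- rv$family
      row$protein <- prot
      new_rows[[length(new_rows) + 1L]] <- row
    }
    if (!length(new_rows)) break
    new_df <- do.call(rbind, new_rows)
    loci <- rbind(loci, new_df)
    queries <- setNames(gsub("[*]", "X", new_df$protein),
                        sprintf("cand_r%d_%d", round, seq_len(nrow(new_df))))
  }
  if (is.null(loci))
    return(cbind(merge_hits(empty_hits()), family = character(0),
                 protein = character(0)))
  loci[order(loci$scaffold, loci$start), , drop = FALSE]
}

#' Build a log-odds sequence profile from aligned proteins
#'
#' Columns with a gap majority are removed; per-column scores are
#' log2((count + pseudocount * bg) / (n + pseudocount) / bg) against
#' uniform background.
#'
#' @param alignment A [protein_alignment()] of >= 2 sequences.
#' @param pseudocount Pseudocount weight (default 1).
#' @return A `sequence_profile`: 20 x L score matrix.
#' @export
sequence_profile <- function(alignment, pseudocount = 1) {
  if (length(alignment$ids) < 2L) stop("profile needs >= 2 sequences")
  rows <- do.call(rbind, strsplit(unlist(alignment$seqs), ""))
  keep <- colSums(rows == "-") < nrow(rows) / 2
  rows <- rows[, keep, drop = FALSE]
  bg <- 1 / 20
  scores <- apply(rows, 2L, function(col) {
    col <- col[col %in% AA_ALPHABET1]
    cnt <- table(factor(col, levels = AA_ALPHABET1))
    log2((as.numeric(cnt) + pseudocount * bg) /
           (length(col) + pseudocount) / bg)
  })
  rownames(scores) <- AA_ALPHABET1
  structure(list(scores = scores, length = ncol(scores)),
            class = "sequence_profile")
}

#' Scan a proteome with a log-odds profile
#'
#' Each protein is scanned ungapped at every offset; a protein's score is
#' its best window, normalized to bits per profile column.
#'
#' @param profile A [sequence_profile()].
#' @param proteome Named character vector of proteins.
#' @param threshold Minimum bits per column to report (default 0.5).
#' @return data.frame sorted by descending score: id, bits_per_column,
#'   offset (0-based best window start).
#' @export
profile_search <- function(profile, proteome, threshold = 0.5) {
  out <- list()
  L <- profile$length
  for (id in names(proteome)) {
    chars <- split1(proteome[[id]])
    if (!all(chars %in% c(AA_ALPHABET1, "X", "*")))
      stop("proteome sequence '", id, "' has unexpected characters")
    idx <- match(chars, AA_ALPHABET1)
    n <- length(idx)
    if (n < L) next
    best <- -Inf; best_off <- 0L
    for (off in 0:(n - L)) {
      cols <- idx[(off + 1L):(off + L)]
      sc <- sum(profile$scores[cbind(cols, seq_len(L))], na.rm = TRUE)
      if (sc > best) { best <- sc; best_off <- off }
    }
    bpc <- best / L
    if (bpc >= threshold)
      out[[length(out) + 1L]] <- data.frame(id = id, bits_per_column = bpc,
                                            offset = best_off)
  }
  if (!length(out))
    return(data.frame(id = character(0), bits_per_column = numeric(0),
                      offset = integer(0)))
  res <- do.call(rbind, out)
  res[order(-res$bits_per_column), , drop = FALSE]
}
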