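# Gene-model classification. A mined locus becomes a classified gene
# candidate: intact (full-length ORF, seven complete TM regions),
# incomplete (ambiguity runs, contig ends, TM/ORF shortfall without a
# lesion, or exon2-only matches to two-exon references), or pseudogene
# (premature stop codons or frame-shifting indels). Decision order:
# ambiguity is checked first, but an unambiguous disrupting lesion
# overrides it; completeness is judged last.

#' Gene candidate constructor
#'
#' @param locus List or one-row data.frame: scaffold, start, end (0-based
#'   half-open), strand.
#' @param cds Nucleotide sequence of the locus (plus-strand of the gene).
#' @param protein Conceptual translation.
#' @param status `"intact"`, `"incomplete"` or `"pseudogene"`.
#' @param defects List of defect records (`type` in premature_stop,
#'   frameshift, n_run, contig_end, tm_deficit, exon2_only; plus position
#'   evidence).
#' @param subfamily Subfamily label or `"unassigned"`.
#' @return A `gene_candidate` object.
#' @export
gene_candidate <- function(locus, cds, protein, status, defects = list(),
                           subfamily = "unassigned") {
  types <- vapply(defects, `[[`, "", "type")
  if (status == "pseudogene" &&
      !any(types %in% c("premature_stop", "frameshift")))
    stop("pseudogene status requires a premature_stop or frameshift defect")
  if (status == "incomplete" &&
      !any(types %in% c("n_run", "contig_end", "tm_deficit", "exon2_only")))
    stop("incomplete status requires ambiguity/TM-deficit evidence")
  if (status == "intact" && length(defects))
    stop("intact status requires an empty defect list")
  structure(list(locus = locus, cds = cds, protein = protein,
                 status = status, defects = defects, subfamily = subfamily),
            class = "gene_candidate")
}

#' @export
print.gene_candidate <- function(x, ...) {
  cat(sprintf("gene candidate %s:%d-%d(%s) status=%s subfamily=%s\n",
              x$locus$scaffold, x$locus$start, x$locus$end, x$locus$strand,
              x$status, x$subfamily))
  if (length(x$defects))
    cat(" defects:", paste(vapply(x$defects, `[[`, "", "type"),
                           collapse = ", "), "\n")
  invisible(x)
}

# Best reading frame of a locus sequence against a reference protein.
# Returns frame, the frame translation, and its local alignment.
best_frame <- function(locus_seq, reference_protein,
                       params = search_params()) {
  best <- NULL
  for (f in 0:2) {
    aa <- translate_nt(substring(locus_seq, f + 1L))
    if (nchar(aa) == 0L) next
    al <- local_align(gsub("[*]", "X", aa), reference_protein, params)
    if (is.null(best) || al$score > best$al$score)
      best <- list(frame = f, aa = aa, al = al)
  }
  best
}

#' Detect frame-shifting indels against a reference protein
#'
#' The three frame translations of the genomic CDS are locally aligned to
#' the reference; alignments are chained along the reference and the
#' nucleotide offset at every junction is inspected. Junction offsets that
#' are not a multiple of 3 are reported as frameshifts.
#'
#' @param genomic_cds Nucleotide sequence (gene on its plus strand).
#' @param reference_protein Reference amino-acid sequence.
#' @param params A [search_params()].
#' @param min_segment_score Minimum alignment score for a frame segment to
#'   enter the chain (default 50).
#' @return data.frame of records (ref_codon, nt_offset) with attribute
#'   `"low_confidence"` when no frame aligns at >= 20% identity.
#' @export
detect_frameshift <- function(genomic_cds, reference_protein,
                              params = search_params(),
                              min_segment_score = 50) {
  if (!nchar(genomic_cds) || !nchar(reference_protein))
    stop("empty input sequence")
  segs <- list()
  best_idf <- 0
  for (f in 0:2) {
    aa <- translate_nt(substring(genomic_cds, f + 1L))
    if (nchar(aa) < 10L) next
    al <- local_align(gsub("[*]", "X", aa), reference_protein, params)
    best_idf <- max(best_idf, al$identity_fraction)
    if (al$score < min_segment_score) next
    segs[[length(segs) + 1L]] <- data.frame(
      frame = f, score = al$score,
      ref_start = al$s_start, ref_end = al$s_end,
      nt_start = f + 3L * al$q_start, nt_end = f + 3L * al$q_end)
  }
  empty <- data.frame(ref_codon = integer(0), nt_offset = integer(0))
  if (!length(segs) || best_idf < 0.2) {
    attr(empty, "low_confidence") <- TRUE
    return(empty)
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs$ref_start, -segs$score), , drop = FALSE]
  # drop segments mostly contained in a better-scoring one
  keep <- rep(TRUE, nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(segs))) {
      if (i == j || !keep[j]) next
      ov <- min(segs$ref_end[i], segs$ref_end[j]) -
        max(segs$ref_start[i], segs$ref_start[j])
      len_j <- segs$ref_end[j] - segs$ref_start[j]
      if (ov > 0.6 * len_j && segs$score[j] <= segs$score[i]) keep[j] <- FALSE
    }
  }
  segs <- segs[keep, , drop = FALSE]
  segs <- segs[order(segs$ref_start), , drop = FALSE]
  out <- list()
  if (nrow(segs) > 1L) {
    for (i in seq_len(nrow(segs) - 1L)) {
      nt_gap <- segs$nt_start[i + 1L] - segs$nt_end[i]
      if (nt_gap %% 3L != 0L)
        out[[length(out) + 1L]] <- data.frame(
          ref_codon = segs$ref_end[i], nt_offset = nt_gap %% 3L)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "low_confidence") <- FALSE
  res
}

#' Classify a mined locus into a gene model
#'
#' Decision order: (1) ambiguity — an N-run of >= `n_run_min` inside the
#' locus, or a locus within `contig_end_margin` nt of a contig end, makes
#' the model incomplete unless an unambiguous disrupting lesion is found;
#' (2) lesion — a premature stop codon in unambiguous sequence or a
#' frame-shifting indel makes it a pseudogene; (3) completeness — intact
#' requires the alignment to cover >= `orf_coverage` of the reference and
#' exactly seven predicted TM segments, otherwise the model is incomplete
#' with TM-deficit evidence.
#'
#' @param hit_locus List/row: scaffold, start, end (0-based half-open),
#'   strand.
#' @param scaffold Scaffold nucleotide sequence (single string).
#' @param reference_protein Reference receptor protein (>= 100 aa
#'   recommended; shorter emits a warning).
#' @param params [search_params()] for the guided alignments.
#' @param n_run_min Minimum ambiguity-run length (default 10).
#' @param contig_end_margin Contig-end proximity in nt (default 50).
#' @param orf_coverage Minimum reference coverage for "full-length"
#'   (default 0.9).
#' @param reference_two_exon Set TRUE when the reference is a two-exon
#'   gene represented by its long exon only; matches are then classified
#'   incomplete with an `exon2_only` note.
#' @return A [gene_candidate()].
#' @export
classify_gene <- function(hit_locus, scaffold, reference_protein,
                          params = search_params(), n_run_min = 10L,
                          contig_end_margin = 50L, orf_coverage = 0.9,
                          reference_two_exon = FALSE) {
  L <- nchar(scaffold)
  if (hit_locus$start < 0L || hit_locus$end > L)
    stop("locus outside scaffold bounds")
  if (nchar(reference_protein) < 100L)
    warning("reference protein shorter than 100 aa")
  locus_seq <- substr(scaffold, hit_locus$start + 1L, hit_locus$end)
  if (hit_locus$strand == "-") locus_seq <- revcomp(locus_seq)
  defects <- list()

  ambiguous <- FALSE
  m <- regexpr(sprintf("N{%d,}", n_run_min), locus_seq)
  if (m > 0) {
    ambiguous <- TRUE
    defects <- c(defects, list(list(type = "n_run", position = as.integer(m),
                                    length = attr(m, "match.length"))))
  }
  if (hit_locus$start < contig_end_margin ||
      L - hit_locus$end < contig_end_margin) {
    ambiguous <- TRUE
    defects <- c(defects, list(list(type = "contig_end",
                                    position = if (hit_locus$start <
                                                   contig_end_margin)
                                      "start" else "end")))
  }

  # lesion scan; ambiguous codons translate to X, so stop/frameshift calls
  # can only come from unambiguous sequence
  lesions <- list()
  bf <- best_frame(locus_seq, reference_protein, params)
  if (!is.null(bf) && bf$al$score >= 50) {
    aa_chars <- split1(bf$aa)
    span <- (bf$al$q_start + 1L):bf$al$q_end
    stops <- span[aa_chars[span] == "*"]
    # a stop at the very end of the aligned region is the natural terminator
    stops <- stops[stops < bf$al$q_end - 1L]
    for (s in stops)
      lesions <- c(lesions, list(list(
        type = "premature_stop",
        codon = bf$al$s_start + (s - bf$al$q_start),
        frame = bf$frame)))
    fs <- detect_frameshift(locus_seq, reference_protein, params)
    if (nrow(fs))
      for (i in seq_len(nrow(fs)))
        lesions <- c(lesions, list(list(type = "frameshift",
                                        codon = fs$ref_codon[i],
                                        nt_offset = fs$nt_offset[i])))
  }

  protein <- if (!is.null(bf)) {
    sub_aa <- substr(bf$aa, bf$al$q_start + 1L, bf$al$q_end)
    gsub("[*]", "X", sub_aa)
  } else ""
  # in-frame CDS of the translated region (translates to `protein` when
  # stop-free)
  orf_cds <- if (!is.null(bf))
    substr(locus_seq, bf$frame + 3L * bf$al$q_start + 1L,
           bf$frame + 3L * bf$al$q_end) else ""

  finish <- function(status, defs) {
    g <- gene_candidate(hit_locus, locus_seq, protein, status, defs)
    g$orf_cds <- orf_cds
    g
  }
  if (length(lesions))
    return(finish("pseudogene", c(defects, lesions)))
  if (ambiguous)
    return(finish("incomplete", defects))
  if (reference_two_exon)
    return(finish("incomplete",
                  list(list(type = "exon2_only",
                            note = "matches long exon of a two-exon reference"))))
  coverage <- if (!is.null(bf))
    (bf$al$s_end - bf$al$s_start) / nchar(reference_protein) else 0
  topo <- if (nchar(protein) >= 100L) predict_tm_topology(protein) else
    list(n_tm = 0L)
  if (coverage >= orf_coverage && topo$n_tm == 7L)
    return(finish("intact", list()))
  finish("incomplete",
         list(list(type = "tm_deficit", n_tm = topo$n_tm,
                   coverage = coverage)))
}
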