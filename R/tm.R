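# Transmembrane topology from sliding-window hydropathy, and
# Ballesteros-Weinstein residue numbering for seven-TM receptors.

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Predict transmembrane topology by sliding-window hydropathy
#'
#' Window-averaged hydropathy is computed at every full-window center;
#' maximal runs of centers above the threshold become TM segments, runs
#' closer than `min_gap` residues are merged, and segments are labelled
#' TM1..TMk from the N-terminus. Loops alternate sides under the GPCR
#' convention of an extracellular N-terminus (N-term, IC1, EC1, IC2, EC2,
#' IC3, EC3, C-term for a 7-TM receptor).
#'
#' @param protein Amino-acid string (residues outside the 20-letter alphabet
#'   score 0).
#' @param window Sliding-window width (odd; default 19).
#' @param threshold Hydropathy call threshold (default 1.6).
#' @param min_gap Minimum separation between segments; closer runs merge.
#' @param scale Hydropathy scale, default [kyte_doolittle()].
#' @return List with `segments` (data.frame start, end, label; 1-based
#'   inclusive protein coordinates), `loops` (data.frame of loop labels),
#'   and `n_tm`.
#' @export
predict_tm_topology <- function(protein, window = 19L, threshold = 1.6,
                                min_gap = 5L, scale = kyte_doolittle()) {
  chars <- split1(protein)
  L <- length(chars)
  half <- (window - 1L) %/% 2L
  empty <- list(segments = data.frame(start = integer(0), end = integer(0),
                                      label = character(0)),
                loops = data.frame(start = integer(0), end = integer(0),
                                   label = character(0)),
                n_tm = 0L)
  if (L < window) return(empty)
  h <- unname(scale[chars])
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  centers <- (half + 1L):(L - half)
  win_mean <- (cs[centers + half + 1L] - cs[centers - half]) / window
  above <- win_mean > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = centers[starts[r$values]],
                    end = centers[ends[r$values]])
  # merge segments separated by fewer than min_gap residues
  if (nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (i in 2L:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$start[i] - last$end - 1L < min_gap) {
        keep[[length(keep)]]$end <- seg$end[i]
      } else keep[[length(keep) + 1L]] <- seg[i, ]
    }
    seg <- do.call(rbind, keep)
  }
  seg$label <- paste0("TM", seq_len(nrow(seg)))
  rownames(seg) <- NULL
  k <- nrow(seg)
  loops <- data.frame(start = c(1L, seg$end + 1L),
                      end = c(seg$start - 1L, L),
                      label = c("N-term",
                                if (k > 1L) vapply(seq_len(k - 1L), function(t)
                                  if (t %% 2L == 1L) paste0("IC", (t + 1L) %/% 2L)
                                  else paste0("EC", t %/% 2L), ""),
                                "C-term"))
  loops <- loops[loops$start <= loops$end, , drop = FALSE]
  rownames(loops) <- NULL
  list(segments = seg, loops = loops, n_tm = k)
}

#' Ballesteros-Weinstein reference annotation
#'
#' @param tm_spans 7 x 2 matrix or data.frame of TM start/end positions
#'   (1-based inclusive, reference protein coordinates).
#' @param index50 Integer vector of length 7: per TM, the position of the
#'   most conserved residue, which carries index 50.
#' @return A `bw_reference` object.
#' @export
bw_reference <- function(tm_spans, index50) {
  tm_spans <- as.matrix(tm_spans)
  stopifnot(nrow(tm_spans) == 7L, length(index50) == 7L)
  if (any(index50 < tm_spans[, 1L] | index50 > tm_spans[, 2L]))
    stop("each index-50 residue must lie inside its TM span")
  structure(list(tm_spans = tm_spans, index50 = as.integer(index50)),
            class = "bw_reference")
}

# Loop label for a reference position outside all TMs.
bw_loop_label <- function(ref_pos, bw_ref) {
  starts <- bw_ref$tm_spans[, 1L]; ends <- bw_ref$tm_spans[, 2L]
  if (ref_pos < starts[1L]) return("N-term")
  if (ref_pos > ends[7L]) return("C-term")
  t <- max(which(ends < ref_pos))
  if (t %% 2L == 1L) paste0("IC", (t + 1L) %/% 2L) else paste0("EC", t %/% 2L)
}

#' Ballesteros-Weinstein number of an aligned query residue
#'
#' A residue aligned to reference TM t with index-50 residue at r50 gets
#' `"t.(50 + pos - r50)"`; residues aligned outside the TMs get the loop
#' label; residues aligned to a reference gap get `"unmapped"`.
#'
#' @param column_map Integer vector, one entry per query residue, giving the
#'   aligned reference position (NA where the query residue is inserted
#'   relative to the reference). See [alignment_column_map()].
#' @param bw_ref A [bw_reference()].
#' @param query_position 1-based query residue index.
#' @return BW string such as `"5.42"`, a loop label, or `"unmapped"`.
#' @export
bw_number <- function(column_map, bw_ref, query_position) {
  if (query_position < 1L || query_position > length(column_map))
    stop("query_position outside the query")
  ref_pos <- column_map[query_position]
  if (is.na(ref_pos)) return("unmapped")
  inside <- ref_pos >= bw_ref$tm_spans[, 1L] & ref_pos <= bw_ref$tm_spans[, 2L]
  if (!any(inside)) return(bw_loop_label(ref_pos, bw_ref))
  t <- which(inside)[1L]
  paste0(t, ".", 50L + ref_pos - bw_ref$index50[t])
}

#' Query-to-reference residue map from an alignment
#'
#' @param alignment A [protein_alignment()].
#' @param query_id,ref_id Row ids.
#' @return Integer vector over query residues giving the aligned reference
#'   residue index (NA at reference gaps).
#' @export
alignment_column_map <- function(alignment, query_id, ref_id) {
  q <- split1(alignment$seqs[[query_id]])
  r <- split1(alignment$seqs[[ref_id]])
  stopifnot(length(q) == length(r))
  rpos <- cumsum(r != "-")
  map <- ifelse(r == "-", NA_integer_, rpos)[q != "-"]
  as.integer(map)
}
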