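# Degenerate peptide-motif grammars. TAAR proteins carry a family-diagnostic
# motif in TM7 that is absent from other GPCRs; the strict form is
# NSx(2)NPx(2)[YH]x(3)YxWF, and divergent (lamprey-like / TAAR V-like)
# receptors carry only weakened variants. Grammars are ordered element lists:
# fixed residues, alternative sets, and fixed-length wildcards.

#' Construct a peptide motif grammar
#'
#' The pattern string uses one-letter residues for fixed positions,
#' `[AB]` for an alternative set, and `X` or `X<n>` for a wildcard of
#' length 1 or n (case-sensitive; only `X` is a wildcard).
#'
#' @param pattern Compact pattern string, e.g. `"NSX2NPX2[YH]X3YXWF"`.
#' @param name Grammar name used in scan reports.
#' @return A `motif_grammar` object.
#' @examples
#' motif_grammar("NSX2NPX2[YH]X3YXWF", "strict")
#' @export
motif_grammar <- function(pattern, name = pattern) {
  chars <- split1(pattern)
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated alternative set in pattern: ", pattern)
      aas <- chars[(i + 1L):(j - 1L)]
      if (!all(aas %in% AA_ALPHABET1)) stop("non-amino-acid in set: ", pattern)
      elements[[length(elements) + 1L]] <- list(type = "set", aas = aas)
      i <- j + 1L
    } else if (ch == "X") {
      j <- i + 1L
      digits <- character(0)
      while (j <= n && grepl("[0-9]", chars[j])) { digits <- c(digits, chars[j]); j <- j + 1L }
      len <- if (length(digits)) as.integer(paste0(digits, collapse = "")) else 1L
      elements[[length(elements) + 1L]] <- list(type = "any", n = len)
      i <- j
    } else if (ch %in% AA_ALPHABET1) {
      elements[[length(elements) + 1L]] <- list(type = "fixed", aa = ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in pattern: ", pattern)
    }
  }
  span <- sum(vapply(elements, function(e) if (e$type == "any") e$n else 1L, 1L))
  structure(list(name = name, elements = elements, span = span),
            class = "motif_grammar")
}

#' @export
print.motif_grammar <- function(x, ...) {
  cat("motif grammar '", x$name, "' (span ", x$span, "): ",
      motif_to_regex(x), "\n", sep = "")
  invisible(x)
}

#' Mechanical regular-expression form of a grammar
#'
#' @param grammar A [motif_grammar()].
#' @return A regex string matching exactly the sequences the grammar accepts.
#' @export
motif_to_regex <- function(grammar) {
  paste0(vapply(grammar$elements, function(e) {
    switch(e$type,
           fixed = e$aa,
           set = paste0("[", paste0(e$aas, collapse = ""), "]"),
           any = if (e$n == 1L) "." else paste0(".{", e$n, "}"))
  }, ""), collapse = "")
}

#' Default TAAR signature-motif grammars
#'
#' The strict tetrapod motif plus the two weakly conserved variants seen in
#' lamprey TAAR-like and TAAR V receptors.
#'
#' @return Named list of [motif_grammar()] objects; the first is the strict
#'   grammar, the remainder weak variants in precedence order.
#' @export
taar_motif_grammars <- function() {
  list(strict = motif_grammar("NSX2NPX2[YH]X3YXWF", "strict"),
       weak_lamprey = motif_grammar("XSX2NPX2[YF]X6F", "weak_lamprey"),
       weak_taarv = motif_grammar("NSX2NPX2YX3[HN]XS[YF]", "weak_taarv"))
}

grammar_match_at <- function(chars, grammar, pos) {
  i <- pos
  for (e in grammar$elements) {
    if (e$type == "any") { i <- i + e$n; next }
    ch <- chars[i]
    ok <- switch(e$type, fixed = ch == e$aa, set = ch %in% e$aas)
    if (!ok) return(FALSE)
    i <- i + 1L
  }
  TRUE
}

#' Scan a protein for the signature motif
#'
#' All start positions are scanned; the strict grammar takes precedence over
#' weak variants (in list order), and within a grammar the leftmost match
#' wins. When a TM topology is supplied the scan is restricted to a window of
#' +/- `window` residues around the TM7 segment.
#'
#' @param protein Amino-acid string.
#' @param grammars Named list of grammars, strict first
#'   (default [taar_motif_grammars()]).
#' @param topology Optional [predict_tm_topology()] result used to restrict
#'   the scan to TM7.
#' @param window Residues of slack around TM7 when `topology` is given.
#' @return List with `grammar` (name), `position` (0-based motif start) —
#'   or `NULL` when no grammar matches.
#' @export
scan_signature_motif <- function(protein, grammars = taar_motif_grammars(),
                                 topology = NULL, window = 10L) {
  chars <- split1(protein)
  L <- length(chars)
  lo <- 1L; hi <- L
  if (!is.null(topology) && nrow(topology$segments) >= 7L) {
    tm7 <- topology$segments[7L, ]
    lo <- max(1L, tm7$start - window)
    hi <- min(L, tm7$end + window)
  }
  for (g in grammars) {
    last <- hi - g$span + 1L
    if (last < lo) next
    for (p in lo:last) {
      if (grammar_match_at(chars, g, p)) {
        return(list(grammar = g$name, position = p - 1L))
      }
    }
  }
  NULL
}
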