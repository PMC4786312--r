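# Nei-Gojobori (1986) counting estimator of dN/dS: an independent,
# likelihood-free cross-check for the M0 fits.

# Synonymous/nonsynonymous site counts of one codon (index 1..61).
# Each position contributes the fraction of its single-nucleotide changes
# (to sense codons only) that are synonymous.
ng86_site_counts <- function(ci) {
  tab <- .codon_tables()
  nb <- tab$neighbors[[ci]]
  syn <- 0
  for (p in 1:3) {
    at <- nb$pos == p
    n_at <- sum(at)
    if (n_at > 0) syn <- syn + sum(nb$synonymous[at]) / n_at
  }
  c(S = syn, N = 3 - syn)
}

# Average syn/nonsyn difference counts between two codons over all
# substitution orders (paths through sense codons only).
ng86_diff_counts <- function(ci, cj) {
  tab <- .codon_tables()
  if (ci == cj) return(c(Sd = 0, Nd = 0))
  a <- tab$split[ci, ]; b <- tab$split[cj, ]
  pos <- which(a != b)
  paths <- permn(pos)
  acc <- c(Sd = 0, Nd = 0); nvalid <- 0
  for (ord in paths) {
    cur <- a; steps <- c(Sd = 0, Nd = 0); ok <- TRUE
    from_idx <- ci
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      key <- paste0(nxt, collapse = "")
      to_idx <- .codon_tables()$index[key]
      if (is.na(to_idx)) { ok <- FALSE; break }  # path through a stop codon
      if (tab$aa[to_idx] == tab$aa[from_idx]) steps["Sd"] <- steps["Sd"] + 1
      else steps["Nd"] <- steps["Nd"] + 1
      cur <- nxt; from_idx <- to_idx
    }
    if (ok) { acc <- acc + steps; nvalid <- nvalid + 1 }
  }
  if (nvalid == 0) {
    # all paths blocked by stops: count positions as nonsynonymous
    return(c(Sd = 0, Nd = length(pos)))
  }
  acc / nvalid
}

# All permutations of a small vector (n <= 3 here).
permn <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permn(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Nei-Gojobori dN and dS for a pair of coding sequences
#'
#' Counting method with equal weighting of substitution pathways (pathways
#' through stop codons excluded) and Jukes-Cantor multiple-hit correction.
#'
#' @param cds_i,cds_j In-frame coding sequences of equal length, no stops.
#' @return List: `dN`, `dS`, `omega`, counts (`S`, `N`, `Sd`, `Nd`), and
#'   `undefined` flag (TRUE when pS or pN >= 3/4 or dS = 0, in which case
#'   omega is NA).
#' @export
ng86_dnds <- function(cds_i, cds_j) {
  if (nchar(cds_i) != nchar(cds_j)) stop("sequences differ in length")
  ci <- codon_index(codon_split(cds_i))
  cj <- codon_index(codon_split(cds_j))
  if (anyNA(ci) || anyNA(cj)) stop("stop codon or ambiguity in input")
  sites_i <- vapply(ci, ng86_site_counts, c(S = 0, N = 0))
  sites_j <- vapply(cj, ng86_site_counts, c(S = 0, N = 0))
  S <- (sum(sites_i["S", ]) + sum(sites_j["S", ])) / 2
  N <- (sum(sites_i["N", ]) + sum(sites_j["N", ])) / 2
  diffs <- mapply(function(a, b) ng86_diff_counts(a, b), ci, cj)
  Sd <- sum(diffs["Sd", ]); Nd <- sum(diffs["Nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  undefined <- is.na(dS) || is.na(dN) || !is.finite(dS) || dS == 0
  list(dN = dN, dS = dS,
       omega = if (undefined) NA_real_ else dN / dS,
       S = S, N = N, Sd = Sd, Nd = Nd, undefined = undefined)
}
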