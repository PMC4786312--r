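# Destabilizing-selection analysis on amino-acid physicochemical
# properties: Fitch-parsimony ancestral reconstruction on a fixed tree,
# 8-category magnitude binning of each inferred replacement, and z-tests
# of the radical categories (6-8, z > 3.09) against a neutral expectation
# built from single-nucleotide nonsynonymous codon changes.

#' Default physicochemical property table
#'
#' Four packaged properties: Kyte-Doolittle hydropathy, side-chain volume
#' (Zamyatnin), Grantham polarity, and isoelectric point (charge proxy).
#' Any table with 20 finite values per property can be supplied instead
#' (rows = one-letter amino acids).
#'
#' @return data.frame, rownames the 20 amino acids, one column per
#'   property.
#' @export
default_property_table <- function() {
  data.frame(
    hydropathy = unname(kyte_doolittle()[AA_ALPHABET1]),
    volume = c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6,
               V = 140.0)[AA_ALPHABET1],
    polarity = c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
                 E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
                 M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4,
                 Y = 6.2, V = 5.9)[AA_ALPHABET1],
    isoelectric_point = c(A = 6.00, R = 10.76, N = 5.41, D = 2.77,
                          C = 5.07, Q = 5.65, E = 3.22, G = 5.97,
                          H = 7.59, I = 6.02, L = 5.98, K = 9.74,
                          M = 5.74, F = 5.48, P = 6.30, S = 5.68,
                          T = 5.60, W = 5.89, Y = 5.66,
                          V = 5.96)[AA_ALPHABET1],
    row.names = AA_ALPHABET1)
}

#' Read a property table from TSV
#'
#' @param path TSV with an `aa` column (one-letter codes) and one numeric
#'   column per property.
#' @return data.frame in [default_property_table()] layout.
#' @export
read_property_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"aa" %in% names(d)) stop("property TSV needs an 'aa' column")
  rownames(d) <- d$aa
  d$aa <- NULL
  miss <- setdiff(AA_ALPHABET1, rownames(d))
  if (length(miss)) stop("missing amino acids: ", paste(miss, collapse = ","))
  d <- d[AA_ALPHABET1, , drop = FALSE]
  if (!all(vapply(d, function(x) all(is.finite(x)), TRUE)))
    stop("property values must be finite")
  d
}

#' Magnitude bins for property changes
#'
#' Eight equal-width categories spanning `[0, max |delta|]` over all 190
#' unordered amino-acid pairs, per property. Bins are left-closed,
#' right-open, except bin 8 which is right-closed; a boundary value falls
#' in the lower bin.
#'
#' @param properties Property table (default
#'   [default_property_table()]).
#' @return A `magnitude_bins` object: per-property bin width and maximum.
#' @export
magnitude_bins <- function(properties = default_property_table()) {
  out <- lapply(properties, function(v) {
    names(v) <- rownames(properties)
    d <- abs(outer(v, v, "-"))
    mx <- max(d)
    list(max = mx, width = mx / 8)
  })
  structure(out, class = "magnitude_bins")
}

#' Magnitude category (1-8) of an amino-acid replacement
#'
#' @param from,to One-letter amino acids.
#' @param bins A [magnitude_bins()].
#' @param property Property name.
#' @param properties The property table the bins were built from.
#' @return Integer category 1..8 (1 most conservative, 8 most radical).
#' @export
categorize <- function(from, to, bins, property,
                       properties = default_property_table()) {
  if (!from %in% AA_ALPHABET1 || !to %in% AA_ALPHABET1)
    stop("unknown residue: ", from, "/", to)
  d <- abs(properties[to, property] - properties[from, property])
  b <- bins[[property]]
  # boundary values go to the lower bin: ceiling(d/width), with d = 0 -> 1
  cat <- if (d <= 0) 1L else as.integer(ceiling(d / b$width - 1e-12))
  min(max(cat, 1L), 8L)
}

# ---------------------------------------------------------------------------
# Fitch parsimony

#' Fitch-parsimony ancestral states per alignment column
#'
#' Bottom-up Fitch sets followed by a top-down pass that prefers the
#' parent's state and otherwise the lexicographically smallest member of
#' the node's set. Unrooted input is rooted at the first internal node
#' (noted in the result). Gaps/unknowns at leaves are treated as
#' uninformative (full set).
#'
#' @param tree `phylo`; leaves must match alignment rows.
#' @param alignment A [protein_alignment()].
#' @return List: `states` (character matrix, rows = all nodes in ape
#'   numbering, columns = alignment columns; leaf rows echo the data),
#'   `score` (Fitch parsimony count per column), `rooted_at`.
#' @export
reconstruct_ancestral <- function(tree, alignment) {
  miss <- setdiff(tree$tip.label, alignment$ids)
  if (length(miss)) stop("tree leaves absent from alignment: ", miss[1L])
  # Fitch needs a rooted binary tree: unrooted input is rooted on the edge
  # to its first tip (documented convention), multifurcations resolved
  # deterministically with zero-length edges
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L],
                      resolve.root = TRUE)
  if (!ape::is.binary.phylo(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  pt <- stats::reorder(tree, "postorder")
  ntip <- length(pt$tip.label)
  nnode <- ntip + pt$Nnode
  L <- alignment$n_col
  chars <- do.call(rbind, strsplit(unlist(alignment$seqs[pt$tip.label]), ""))
  rownames(chars) <- pt$tip.label
  root <- pt$edge[nrow(pt$edge), 1L]
  aa_bit <- setNames(seq_along(AA_ALPHABET1), AA_ALPHABET1)
  full <- rep(TRUE, 20L)

  states <- matrix(NA_character_, nnode, L)
  states[seq_len(ntip), ] <- chars
  score <- integer(L)
  # per column: sets as logical 20-vectors
  kids <- split(pt$edge[, 2L], pt$edge[, 1L])
  postorder_nodes <- unique(pt$edge[, 1L])  # postorder parents
  sets <- array(FALSE, dim = c(nnode, 20L))
  for (col in seq_len(L)) {
    sets[] <- FALSE
    for (i in seq_len(ntip)) {
      ch <- chars[i, col]
      if (ch %in% AA_ALPHABET1) sets[i, aa_bit[ch]] <- TRUE
      else sets[i, ] <- TRUE
    }
    sc <- 0L
    for (nd in postorder_nodes) {
      ks <- kids[[as.character(nd)]]
      cur <- NULL
      for (k in ks) {
        if (is.null(cur)) { cur <- sets[k, ]; next }
        inter <- cur & sets[k, ]
        if (any(inter)) cur <- inter
        else { cur <- cur | sets[k, ]; sc <- sc + 1L }
      }
      sets[nd, ] <- cur
    }
    score[col] <- sc
    # top-down resolution
    rootset <- which(sets[root, ])
    states[root, col] <- AA_ALPHABET1[rootset[1L]]
    for (e in rev(seq_len(nrow(pt$edge)))) {
      parent <- pt$edge[e, 1L]; child <- pt$edge[e, 2L]
      if (child <= ntip) next
      ps <- states[parent, col]
      if (sets[child, aa_bit[ps]]) states[child, col] <- ps
      else states[child, col] <- AA_ALPHABET1[which(sets[child, ])[1L]]
    }
  }
  # leaves with missing data take their parent's state for change counting
  for (i in seq_len(ntip)) {
    bad <- !(states[i, ] %in% AA_ALPHABET1)
    if (any(bad)) {
      par <- pt$edge[match(i, pt$edge[, 2L]), 1L]
      states[i, bad] <- states[par, bad]
    }
  }
  list(states = states, score = score, rooted_at = root, tree = pt)
}

#' Enumerate inferred amino-acid replacements
#'
#' @param recon Result of [reconstruct_ancestral()].
#' @return data.frame: edge index, child node, column, from_aa, to_aa.
#' @export
enumerate_changes <- function(recon) {
  pt <- recon$tree
  out <- list()
  for (e in seq_len(nrow(pt$edge))) {
    parent <- pt$edge[e, 1L]; child <- pt$edge[e, 2L]
    diff <- which(recon$states[parent, ] != recon$states[child, ])
    if (length(diff))
      out[[length(out) + 1L]] <- data.frame(
        edge = e, child = child, column = diff,
        from_aa = recon$states[parent, diff],
        to_aa = recon$states[child, diff])
  }
  if (!length(out))
    return(data.frame(edge = integer(0), child = integer(0),
                      column = integer(0), from_aa = character(0),
                      to_aa = character(0)))
  do.call(rbind, out)
}

# Per-amino-acid neutral category distribution for one property: pool all
# single-nucleotide nonsynonymous changes from all codons of the residue,
# uniformly over changes.
.aa_neighbor_cats <- function(property, bins,
                              properties = default_property_table()) {
  tab <- .codon_tables()
  out <- matrix(0, 20L, 8L, dimnames = list(AA_ALPHABET1, NULL))
  for (a in AA_ALPHABET1) {
    cods <- which(tab$aa == a)
    cats <- integer(0)
    for (ci in cods) {
      nb <- tab$neighbors[[ci]]
      tos <- nb$to[!nb$synonymous]
      for (tj in tos)
        cats <- c(cats, categorize(a, tab$aa[tj], bins, property,
                                   properties))
    }
    if (length(cats))
      out[a, ] <- tabulate(cats, 8L) / length(cats)
  }
  out
}

#' Test for positive-destabilizing selection on a property
#'
#' Observed category counts of the inferred replacements are compared to
#' the neutral expectation: the category distribution of all
#' single-nucleotide nonsynonymous codon changes reachable from the
#' ancestral residues (pooled over every branch-column, uniform over
#' changes). `z = (o - n p) / sqrt(n p (1 - p))`; categories 6-8 with
#' z strictly greater than 3.09 (P < 0.001) are called
#' positive-destabilizing.
#'
#' @param changes data.frame from [enumerate_changes()].
#' @param recon The [reconstruct_ancestral()] result (supplies the
#'   ancestral residues behind the expectation).
#' @param bins A [magnitude_bins()].
#' @param property Property name.
#' @param properties Property table.
#' @param z_threshold Strict call threshold (default 3.09).
#' @return data.frame, one row per category: observed, expected, z, call.
#'   Rows with p = 0 but observations carry `z = Inf` (flagged).
#' @export
destabilizing_test <- function(changes, recon, bins, property,
                               properties = default_property_table(),
                               z_threshold = 3.09) {
  if (nrow(changes) == 0L) stop("need at least one observed change")
  ncat_tab <- .aa_neighbor_cats(property, bins, properties)
  # expectation pooled over the ancestral residue of every branch-column
  pt <- recon$tree
  parents <- pt$edge[, 1L]
  anc <- recon$states[parents, , drop = FALSE]
  cnt <- table(factor(anc, levels = AA_ALPHABET1))
  w <- as.numeric(cnt)
  denom <- sum(w * rowSums(ncat_tab))
  p <- colSums(ncat_tab * w) / sum(w * rowSums(ncat_tab))
  obs <- tabulate(vapply(seq_len(nrow(changes)), function(i)
    categorize(changes$from_aa[i], changes$to_aa[i], bins, property,
               properties), 1L), 8L)
  n <- nrow(changes)
  expd <- n * p
  z <- ifelse(p > 0 & p < 1,
              (obs - expd) / sqrt(n * p * (1 - p)),
              ifelse(obs > 0 & p == 0, Inf, 0))
  # categories with p = 0 have no defined z-test (they are unreachable by
  # single-nucleotide changes); they are reported with the infinite-z flag
  # but never called
  call <- ifelse(seq_len(8L) >= 6L & is.finite(z) & z > z_threshold,
                 "positive_destabilizing", "none")
  data.frame(property = property, category = 1:8, observed = obs,
             expected = expd, p_neutral = p, z = z, call = call,
             infinite_z = is.infinite(z))
}

#' Pairwise (tree-free) destabilizing test
#'
#' Runs the tree-mode machinery on the two-leaf tree of the pair, so the
#' result reduces exactly to the tree-based test restricted to two
#' sequences. Changes are the differing ungapped columns.
#'
#' @param seq_i,seq_j Aligned amino-acid strings.
#' @param bins A [magnitude_bins()].
#' @param property Property name.
#' @param properties Property table.
#' @return As [destabilizing_test()]; zero differing columns returns an
#'   empty data.frame with a `note` attribute.
#' @export
pairwise_mode <- function(seq_i, seq_j, bins, property,
                          properties = default_property_table()) {
  al <- protein_alignment(c(i = seq_i, j = seq_j))
  tree <- ape::read.tree(text = "(i:1,j:1);")
  recon <- reconstruct_ancestral(tree, al)
  changes <- enumerate_changes(recon)
  if (nrow(changes) == 0L) {
    out <- data.frame()
    attr(out, "note") <- "no differing columns"
    return(out)
  }
  destabilizing_test(changes, recon, bins, property, properties)
}
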