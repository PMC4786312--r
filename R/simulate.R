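# Synthetic gene families with full ground truth: gene birth-death along a
# species tree, codon-sequence evolution under the model family,
# pseudogenization lesions, and embedding into genome scaffolds with
# assembly artifacts. Every downstream stage is scored against the truth
# these generators emit. All randomness comes from R's session RNG
# (Mersenne-Twister) seeded once per operation via `seed`.

#' Species tree specification
#'
#' @param newick Newick string with branch lengths in expected substitutions.
#' @return List with the parsed `tree` (phylo) and `n_species`.
#' @export
species_tree_spec <- function(newick) {
  tree <- ape::read.tree(text = newick)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("species tree needs non-negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate species labels")
  list(tree = tree, n_species = length(tree$tip.label))
}

#' Gene birth-death specification
#'
#' @param duplication_rate,loss_rate,pseudogenization_rate Events per unit
#'   branch length (>= 0).
#' @param root_copies Gene copies at the species-tree root (>= 1).
#' @param seed Integer RNG seed.
#' @return A `birth_death_spec` list.
#' @export
birth_death_spec <- function(duplication_rate = 0, loss_rate = 0,
                             pseudogenization_rate = 0, root_copies = 1L,
                             seed = 1L) {
  stopifnot(duplication_rate >= 0, loss_rate >= 0,
            pseudogenization_rate >= 0, root_copies >= 1L,
            is.finite(duplication_rate + loss_rate + pseudogenization_rate))
  list(duplication_rate = duplication_rate, loss_rate = loss_rate,
       pseudogenization_rate = pseudogenization_rate,
       root_copies = as.integer(root_copies), seed = as.integer(seed))
}

#' Simulate a gene family by birth-death along a species tree
#'
#' Each gene lineage evolves independently along every species-tree branch:
#' duplications split it, losses terminate it, pseudogenization marks it (a
#' pseudogenized lineage keeps evolving but stays a pseudogene). At
#' speciation nodes every surviving lineage enters both descendant
#' branches. Leaves are labelled `<species>_g<k>`.
#'
#' @param species A [species_tree_spec()].
#' @param bd A [birth_death_spec()].
#' @return List: `gene_tree` (phylo, NULL when everything was lost),
#'   `all_lost` flag, `events` data.frame (type, species branch, time),
#'   `leaf_status` (named vector, `"functional"`/`"pseudogene"`).
#' @export
simulate_gene_family <- function(species, bd) {
  set.seed(bd$seed)
  stree <- species$tree
  total_rate <- bd$duplication_rate + bd$loss_rate + bd$pseudogenization_rate
  env <- new.env(parent = emptyenv())
  env$counter <- list()
  env$events <- list()
  env$status <- character(0)

  leaf_name <- function(sp) {
    k <- (env$counter[[sp]] %||% 0L) + 1L
    env$counter[[sp]] <- k
    paste0(sp, "_g", k)
  }
  note <- function(type, branch_to, time) {
    env$events[[length(env$events) + 1L]] <-
      data.frame(type = type, species_branch = branch_to, time = time)
  }

  ntip <- length(stree$tip.label)
  children_of <- split(seq_len(nrow(stree$edge)), stree$edge[, 1L])

  # Simulate one lineage entering the branch that leads to `node`, with
  # `remaining` branch length left; returns a newick fragment or NULL.
  descend <- function(node, remaining, acc, pseudo) {
    repeat {
      w <- if (total_rate > 0) rexp(1L, total_rate) else Inf
      if (w >= remaining) break
      remaining <- remaining - w
      acc <- acc + w
      u <- runif(1L) * total_rate
      if (u < bd$duplication_rate) {
        node_lab <- node_label(node)
        note("duplication", node_lab, remaining)
        a <- descend(node, remaining, 0, pseudo)
        b <- descend(node, remaining, 0, pseudo)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(add_len(b, acc))
        if (is.null(b)) return(add_len(a, acc))
        return(sprintf("(%s,%s):%g", a, b, acc))
      } else if (u < bd$duplication_rate + bd$loss_rate) {
        note("loss", node_label(node), remaining)
        return(NULL)
      } else {
        note("pseudogenization", node_label(node), remaining)
        pseudo <- TRUE
      }
    }
    acc <- acc + remaining
    if (node <= ntip) {
      lab <- leaf_name(stree$tip.label[node])
      env$status[lab] <- if (pseudo) "pseudogene" else "functional"
      return(sprintf("%s:%g", lab, acc))
    }
    kids <- children_of[[as.character(node)]]
    parts <- lapply(kids, function(e)
      descend(stree$edge[e, 2L], stree$edge.length[e], 0, pseudo))
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(add_len(parts[[1L]], acc))
    sprintf("(%s):%g", paste(unlist(parts), collapse = ","), acc)
  }
  node_label <- function(node)
    if (node <= ntip) stree$tip.label[node] else paste0("node", node)
  add_len <- function(frag, extra) {
    # bump the top-level branch length of a newick fragment
    m <- regmatches(frag, regexpr(":[0-9.eE+-]+$", frag))
    len <- as.numeric(substring(m, 2L)) + extra
    paste0(sub(":[0-9.eE+-]+$", "", frag), ":", format(len, digits = 12))
  }

  root <- ntip + 1L
  frags <- lapply(seq_len(bd$root_copies), function(i)
    descend(root, 0, 0, FALSE))
  frags <- frags[!vapply(frags, is.null, TRUE)]
  events <- if (length(env$events)) do.call(rbind, env$events) else
    data.frame(type = character(0), species_branch = character(0),
               time = numeric(0))
  if (length(frags) == 0L)
    return(list(gene_tree = NULL, all_lost = TRUE, events = events,
                leaf_status = env$status))
  newick <- if (length(frags) == 1L)
    paste0(sub(":[0-9.eE+-]+$", ";", frags[[1L]])) else
      paste0("(", paste(unlist(frags), collapse = ","), ");")
  gt <- ape::read.tree(text = newick)
  if (length(gt$tip.label) == 1L || is.null(gt$edge)) {
    # single surviving copy: represent as a one-leaf "tree" list
    return(list(gene_tree = NULL, all_lost = FALSE,
                single_leaf = gt$tip.label %||% gsub(":.*", "", newick),
                events = events, leaf_status = env$status))
  }
  list(gene_tree = gt, all_lost = FALSE, events = events,
       leaf_status = env$status)
}

#' Simulate a gap-free codon alignment on a gene tree
#'
#' Sites are assigned to the model's site classes by their proportions and
#' evolved down the tree under the corresponding Goldman-Yang generators
#' (stop codons are excluded from the state space by construction). The
#' root sequence is drawn from the equilibrium frequencies unless
#' `root_seq` is given.
#'
#' @param gene_tree phylo tree with branch lengths in expected
#'   substitutions per codon.
#' @param model A [codon_model_spec()] (its `foreground` marks apply to
#'   this tree's edges).
#' @param n_codons Number of codon sites (> 0).
#' @param seed Integer RNG seed.
#' @param root_seq Optional in-frame CDS (no stops) used as the root state.
#' @return List: `alignment` ([codon_alignment()]), `site_class` (integer
#'   class id per codon column), `class_omegas` (omega of each class on
#'   background branches), `truth` spec.
#' @export
simulate_codon_alignment <- function(gene_tree, model, n_codons, seed,
                                     root_seq = NULL) {
  if (n_codons <= 0L) stop("n_codons must be positive")
  set.seed(seed)
  pt <- prepare_tree(gene_tree, model$foreground)
  tree <- pt$tree
  gens <- instantiate_model(model, pt$fg)
  nclass <- length(gens$cs$props)
  site_class <- sample.int(nclass, n_codons, replace = TRUE,
                           prob = gens$cs$props)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_codons)
  root <- tree$edge[nrow(tree$edge), 1L]
  if (is.null(root_seq)) {
    states[root, ] <- sample.int(61L, n_codons, replace = TRUE,
                                 prob = model$freqs)
  } else {
    rs <- codon_index(codon_split(root_seq))
    if (anyNA(rs)) stop("root_seq contains a stop codon or ambiguity")
    if (length(rs) != n_codons) stop("root_seq length != n_codons codons")
    states[root, ] <- rs
  }
  # preorder = reverse postorder
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    child_states <- integer(n_codons)
    for (k in seq_len(nclass)) {
      sites_k <- which(site_class == k)
      if (!length(sites_k)) next
      P <- prob_matrix(gens$eds[[gens$cs$map[k, e]]], tree$edge.length[e])
      ps <- states[parent, sites_k]
      for (s in unique(ps)) {
        sel <- sites_k[ps == s]
        child_states[sel] <- sample.int(61L, length(sel), replace = TRUE,
                                        prob = pmax(P[s, ], 0))
      }
    }
    states[child, ] <- child_states
  }
  codons <- sense_codons()
  seqs <- vapply(seq_len(ntip), function(i)
    paste0(codons[states[i, ]], collapse = ""), "")
  names(seqs) <- tree$tip.label
  list(alignment = codon_alignment(seqs), site_class = site_class,
       class_omegas = gens$cs$omegas, model = model)
}

#' Disrupt a coding sequence into a pseudogene
#'
#' @param cds In-frame CDS (length a multiple of 3, no internal stops).
#' @param mode `"premature_stop"` (substitute a stop codon at `position`)
#'   or `"frameshift"` (insert or delete 1-2 nucleotides in that codon).
#' @param position 1-based codon index strictly inside the ORF (not the
#'   terminal stop codon).
#' @param seed Integer RNG seed (chooses the stop codon / indel form).
#' @return List: `sequence`, `defect` record (type, codon, detail).
#' @export
pseudogenize <- function(cds, mode = c("premature_stop", "frameshift"),
                         position, seed = 1L) {
  mode <- match.arg(mode)
  n_codons <- nchar(cds) %/% 3L
  if (position < 1L || position >= n_codons)
    stop("position must lie strictly inside the ORF")
  set.seed(seed)
  nt_at <- (position - 1L) * 3L + 1L
  if (mode == "premature_stop") {
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    seq <- paste0(substr(cds, 1L, nt_at - 1L), stop_codon,
                  substring(cds, nt_at + 3L))
    defect <- list(type = "premature_stop", codon = position,
                   detail = stop_codon)
  } else {
    del <- runif(1L) < 0.5
    k <- sample(1:2, 1L)
    if (del) {
      seq <- paste0(substr(cds, 1L, nt_at - 1L), substring(cds, nt_at + k))
      defect <- list(type = "frameshift", codon = position,
                     detail = sprintf("del%d", k))
    } else {
      ins <- random_nt(k)
      seq <- paste0(substr(cds, 1L, nt_at - 1L), ins, substring(cds, nt_at))
      defect <- list(type = "frameshift", codon = position,
                     detail = sprintf("ins%d", k))
    }
  }
  list(sequence = seq, defect = defect)
}

#' Embed genes in a genome scaffold with truth coordinates
#'
#' Genes are laid down in order separated by spacers drawn from
#' `spacer_law`; minus-orientation genes are reverse complemented. Optional
#' assembly artifacts: an N-run (default 100 nt) dropped inside a gene, or
#' truncation of the scaffold partway through a gene (the locus then abuts
#' the contig end and downstream genes are dropped).
#'
#' @param genes data.frame with columns `id`, `sequence`, `strand`
#'   (`"+"`/`"-"`); optional logical columns `n_run` and `truncate`.
#' @param spacer_law List: either `list(dist = "fixed", length = L)` or
#'   `list(dist = "lognormal", meanlog = log(10000), sdlog = 0.5)`
#'   (default: lognormal with median 10 kb).
#' @param seed Integer RNG seed.
#' @param scaffold_id Name of the scaffold.
#' @param flank Plain-sequence flank placed before the first and after the
#'   last gene (default 500 nt).
#' @param n_run_length Length of inserted ambiguity runs (default 100).
#' @return List: `scaffold` (named character vector of length 1), `truth`
#'   (data.frame: gene id, start, end 0-based half-open, strand, artifact),
#'   and the realized `spacers`.
#' @export
embed_in_genome <- function(genes,
                            spacer_law = list(dist = "lognormal",
                                              meanlog = log(10000),
                                              sdlog = 0.5),
                            seed = 1L, scaffold_id = "scaffold1",
                            flank = 500L, n_run_length = 100L) {
  set.seed(seed)
  if (nrow(genes) == 0L) {
    warning("empty gene list: returning empty scaffold")
    return(list(scaffold = setNames("", scaffold_id),
                truth = data.frame(id = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   artifact = character(0)),
                spacers = integer(0)))
  }
  n <- nrow(genes)
  draw_spacer <- function() {
    if (spacer_law$dist == "fixed") as.integer(spacer_law$length)
    else as.integer(round(rlnorm(1L, spacer_law$meanlog, spacer_law$sdlog)))
  }
  spacers <- if (n > 1L) vapply(seq_len(n - 1L), function(i) draw_spacer(),
                                0L) else integer(0)
  if (any(spacers < 0L)) stop("spacer lengths must be >= 0")
  pieces <- character(0)
  truth <- list()
  pos <- 0L
  add_piece <- function(s) { pieces[[length(pieces) + 1L]] <<- s
                             pos <<- pos + nchar(s) }
  add_piece(random_nt(flank))
  truncated_at <- NA_integer_
  for (i in seq_len(n)) {
    s <- genes$sequence[i]
    if (genes$strand[i] == "-") s <- revcomp(s)
    artifact <- "none"
    if (isTRUE(genes$n_run[i])) {
      # replace an internal stretch by Ns, keeping the locus span
      mid <- nchar(s) %/% 2L
      s <- paste0(substr(s, 1L, mid),
                  strrep("N", n_run_length),
                  substring(s, mid + n_run_length + 1L))
      artifact <- "n_run"
    }
    if (isTRUE(genes$truncate[i])) {
      keep <- nchar(s) %/% 2L
      s <- substr(s, 1L, keep)
      artifact <- "contig_end"
      truth[[length(truth) + 1L]] <-
        data.frame(id = genes$id[i], start = pos, end = pos + nchar(s),
                   strand = genes$strand[i], artifact = artifact)
      add_piece(s)
      truncated_at <- i
      break
    }
    truth[[length(truth) + 1L]] <-
      data.frame(id = genes$id[i], start = pos, end = pos + nchar(s),
                 strand = genes$strand[i], artifact = artifact)
    add_piece(s)
    if (i < n) add_piece(random_nt(spacers[i]))
  }
  if (!is.na(truncated_at)) spacers <- spacers[seq_len(truncated_at - 1L)]
  else add_piece(random_nt(flank))
  scaffold <- setNames(paste0(pieces, collapse = ""), scaffold_id)
  truth <- do.call(rbind, truth)
  truth$scaffold <- scaffold_id
  list(scaffold = scaffold, truth = truth, spacers = spacers)
}

#' Install a signature motif of chosen strength into a protein
#'
#' `strict` rewrites the anchor region to satisfy the strict grammar;
#' `weak` satisfies the requested weak variant while violating the strict
#' grammar; `absent` leaves no grammar match anywhere in the sequence.
#'
#' @param protein Amino-acid string.
#' @param grammars Grammar list as in [scan_signature_motif()]; element 1
#'   must be the strict grammar.
#' @param strength `"strict"`, `"weak"` or `"absent"`.
#' @param anchor 1-based position where the motif is written.
#' @param weak_variant Name or index of the weak grammar used for
#'   `strength = "weak"` (default the first weak variant).
#' @return Edited amino-acid string.
#' @export
decorate_motif <- function(protein, grammars = taar_motif_grammars(),
                           strength = c("strict", "weak", "absent"),
                           anchor, weak_variant = 2L) {
  strength <- match.arg(strength)
  chars <- split1(protein)
  strict <- grammars[[1L]]
  target <- switch(strength, strict = strict,
                   weak = grammars[[weak_variant]], absent = NULL)
  span <- if (is.null(target)) strict$span else target$span
  if (anchor < 1L || anchor + span - 1L > length(chars))
    stop("grammar span exceeds sequence at the requested anchor")
  if (strength == "absent") {
    # scrub any existing matches of every grammar
    repeat {
      hit <- scan_signature_motif(paste0(chars, collapse = ""), grammars)
      if (is.null(hit)) break
      g <- grammars[[hit$grammar]]
      p <- hit$position + 1L
      i <- p
      for (e in g$elements) {
        if (e$type == "any") { i <- i + e$n; next }
        chars[i] <- "A"   # alanine satisfies neither N/S/P/Y-type anchors
        i <- i + 1L
      }
    }
    return(paste0(chars, collapse = ""))
  }
  i <- anchor
  for (e in target$elements) {
    if (e$type == "any") {
      # wildcards keep original residues
      i <- i + e$n
    } else if (e$type == "fixed") {
      chars[i] <- e$aa; i <- i + 1L
    } else {
      pick <- if (strength == "weak") e$aas[length(e$aas)] else e$aas[1L]
      chars[i] <- pick; i <- i + 1L
    }
  }
  if (strength == "weak") {
    # ensure the strict grammar fails everywhere
    out <- paste0(chars, collapse = "")
    hit <- scan_signature_motif(out, grammars[1L])
    if (!is.null(hit)) {
      # break the strict match minimally: flip its first fixed residue that
      # the weak grammar leaves free
      p <- hit$position + 1L
      chars[p] <- if (chars[p] == "A") "G" else "A"
      out <- paste0(chars, collapse = "")
      if (!is.null(scan_signature_motif(out, grammars[1L])))
        stop("could not construct a weak-only motif at this anchor")
    }
    return(paste0(chars, collapse = ""))
  }
  paste0(chars, collapse = "")
}
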