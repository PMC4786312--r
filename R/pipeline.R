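# End-to-end orchestration: the packaged synthetic scenario, the full
# mining -> classification -> phylogeny -> selection pipeline, and the
# Results-style summaries (census table, synteny statistics, primary- vs
# tertiary-group omega comparison).

#' Default synthetic scenario configuration
#'
#' Five species, three receptor subfamilies: `A` emulates a primary
#' amine-detecting subfamily (single-copy orthologs, strong purifying
#' selection), `B` a tertiary amine-detecting subfamily (duplications,
#' losses, pseudogenes, moderate constraint), and `C` a tertiary-like
#' subfamily carrying a positive-selection site class. Genes are embedded
#' in one scaffold per species with fixed 2-kb spacers and mixed
#' orientations.
#'
#' @return Configuration list consumed by [simulate_scenario()].
#' @export
scenario_config <- function() {
  list(
    species_newick = paste0("((((sp1:0.05,sp2:0.05):0.04,sp3:0.09):0.04,",
                            "sp4:0.13):0.03,sp5:0.16);"),
    n_codons = 273L,   # length of the 7-TM receptor template
    spacer_law = list(dist = "fixed", length = 2000L),
    subfamilies = list(
      A = list(model = "M0", omega = 0.10, kappa = 2,
               duplication_rate = 0, loss_rate = 0,
               pseudogenization_rate = 0),
      B = list(model = "M0", omega = 0.35, kappa = 2,
               duplication_rate = 3, loss_rate = 0.5,
               pseudogenization_rate = 2.0),
      C = list(model = "M2a", omega0 = 0.15, p0 = 0.55, p1 = 0.30,
               omega2 = 4, kappa = 2,
               duplication_rate = 1.2, loss_rate = 0,
               pseudogenization_rate = 0)),
    minus_strand_prob = 0.3,
    ncat_beta = 5L,      # beta discretization used by this scenario's M7/M8
    bootstrap_reps = 100L)
}

#' Load a scenario configuration from YAML
#'
#' Fields present in the file override the [scenario_config()] defaults;
#' everything else keeps its default, and every effective value is echoed
#' when `verbose = TRUE` so runs are self-documenting.
#'
#' @param path YAML file.
#' @param verbose Echo the effective configuration to stderr.
#' @return Configuration list for [simulate_scenario()].
#' @export
load_scenario_config <- function(path, verbose = FALSE) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(scenario_config(), user)
  if (verbose)
    message("effective config:\n", yaml::as.yaml(cfg))
  cfg
}

# Deterministic sub-seed derivation (stays below 2^31).
sub_seed <- function(seed, k) (as.integer(seed) * 97L + k * 131L) %% 2000000000L

# A seven-TM receptor-like protein template: hydrophobic 21-mers separated
# by hydrophilic loops, signature motif written into TM7.
receptor_template <- function(seed, n_tm = 7L, tm_len = 21L, loop_len = 16L,
                              nterm = 12L, cterm = 12L, tm7_len = 27L) {
  set.seed(seed)
  hydrophobic <- c("I", "L", "V", "F", "M")
  hydrophilic <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "P")
  parts <- character(0)
  tm7_start <- NA_integer_
  pos <- 0L
  add <- function(x) { parts <<- c(parts, x); pos <<- pos + nchar(x) }
  add(paste0(sample(hydrophilic, nterm, replace = TRUE), collapse = ""))
  for (t in seq_len(n_tm)) {
    if (t == n_tm) tm7_start <- pos + 1L
    len <- if (t == n_tm) tm7_len else tm_len
    add(paste0(sample(hydrophobic, len, replace = TRUE), collapse = ""))
    if (t < n_tm)
      add(paste0(sample(hydrophilic, loop_len, replace = TRUE),
                 collapse = ""))
  }
  add(paste0(sample(hydrophilic, cterm, replace = TRUE), collapse = ""))
  prot <- paste0(parts, collapse = "")
  # strict signature motif at the TM7/C-terminus boundary (the natural
  # position of the NPxxY-containing motif): its first residues sit at the
  # cytoplasmic end of TM7 while the hydrophobic TM7 core stays clean, so
  # the topology predictor keeps a robust seventh segment even after
  # substitutions accumulate; wildcard positions keep the original residues
  anchor <- tm7_start + tm7_len - 6L
  prot <- decorate_motif(prot, strength = "strict", anchor = anchor)
  list(protein = prot, tm7_start = tm7_start, motif_anchor = anchor)
}

# Back-translate a protein to a CDS with seeded synonymous codon choice.
backtranslate_protein <- function(protein, seed) {
  set.seed(seed)
  tab <- .codon_tables()
  by_aa <- split(tab$codons, tab$aa)
  vapply(split1(protein), function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, "") -> cods
  paste0(cods, collapse = "")
}

#' Simulate the packaged synthetic scenario
#'
#' Generates, with full ground truth: per-subfamily gene families by
#' birth-death along the species tree, codon alignments evolved from a
#' seven-TM receptor template under each subfamily's selection regime,
#' pseudogenization lesions for lineages the birth-death process marked,
#' and one genome scaffold per species with the species' genes and fixed
#' intergenic spacers.
#'
#' @param config A [scenario_config()] list.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return List: `genomes`, `truth` (per-gene data.frame), `templates`,
#'   `refdb`, `gene_trees`, `alignments` (per subfamily), `config`,
#'   `seed`.
#' @export
simulate_scenario <- function(config = scenario_config(), seed = 1L) {
  species <- species_tree_spec(config$species_newick)
  sub_names <- names(config$subfamilies)
  templates <- list()
  genes <- list()   # per gene: id, species, subfamily, status, cds, protein
  gene_trees <- list()
  alignments <- list()
  for (si in seq_along(sub_names)) {
    sf <- sub_names[si]
    cfg <- config$subfamilies[[sf]]
    tpl <- receptor_template(sub_seed(seed, si * 10L))
    cds <- backtranslate_protein(tpl$protein, sub_seed(seed, si * 10L + 1L))
    templates[[sf]] <- list(protein = tpl$protein, cds = cds,
                            motif_anchor = tpl$motif_anchor)
    bd <- birth_death_spec(cfg$duplication_rate, cfg$loss_rate,
                           cfg$pseudogenization_rate, root_copies = 1L,
                           seed = sub_seed(seed, si * 10L + 2L))
    fam <- simulate_gene_family(species, bd)
    if (isTRUE(fam$all_lost)) next
    model <- if (cfg$model == "M0")
      codon_model_spec("M0", kappa = cfg$kappa, omega = cfg$omega)
    else
      codon_model_spec("M2a", kappa = cfg$kappa, omega0 = cfg$omega0,
                       p0 = cfg$p0, p1 = cfg$p1, omega2 = cfg$omega2)
    if (is.null(fam$gene_tree)) {
      # single surviving copy: the template itself, undiverged
      leaf <- fam$single_leaf
      seqs <- setNames(cds, leaf)
      site_class <- rep(1L, config$n_codons)
      aln <- NULL
    } else {
      sim <- simulate_codon_alignment(fam$gene_tree, model, config$n_codons,
                                      seed = sub_seed(seed, si * 10L + 3L),
                                      root_seq = cds)
      seqs <- setNames(
        vapply(sim$alignment$ids, function(id)
          paste0(sim$alignment$chars[id == sim$alignment$ids, ],
                 collapse = ""), ""),
        sim$alignment$ids)
      aln <- sim
      gene_trees[[sf]] <- fam$gene_tree
    }
    alignments[[sf]] <- aln
    for (leaf in names(seqs)) {
      status <- fam$leaf_status[leaf] %||% "functional"
      g <- list(id = paste0(sf, "_", leaf),
                species = sub("_g\\d+$", "", leaf),
                subfamily = sf,
                status = if (status == "pseudogene") "pseudogene"
                         else "intact",
                cds = unname(seqs[leaf]))
      genes[[length(genes) + 1L]] <- g
    }
  }
  # pseudogenization lesions
  set.seed(sub_seed(seed, 71L))
  for (i in seq_along(genes)) {
    if (genes[[i]]$status != "pseudogene") next
    n_cod <- nchar(genes[[i]]$cds) %/% 3L
    mode <- sample(c("premature_stop", "frameshift"), 1L)
    position <- sample(seq(n_cod %/% 3L, 2L * n_cod %/% 3L), 1L)
    ps <- pseudogenize(genes[[i]]$cds, mode, position,
                       seed = sub_seed(seed, 500L + i))
    genes[[i]]$cds <- ps$sequence
    genes[[i]]$defect <- ps$defect
  }
  # embed per species
  truth <- list()
  genomes <- character(0)
  set.seed(sub_seed(seed, 72L))
  for (sp in species$tree$tip.label) {
    idx <- which(vapply(genes, `[[`, "", "species") == sp)
    if (!length(idx)) {
      genomes[sp] <- random_nt(3000L)
      next
    }
    gdf <- data.frame(
      id = vapply(genes[idx], `[[`, "", "id"),
      sequence = vapply(genes[idx], `[[`, "", "cds"),
      strand = sample(c("+", "-"), length(idx), replace = TRUE,
                      prob = c(1 - config$minus_strand_prob,
                               config$minus_strand_prob)))
    emb <- embed_in_genome(gdf, spacer_law = config$spacer_law,
                           seed = sub_seed(seed, 600L + match(sp,
                             species$tree$tip.label)),
                           scaffold_id = sp)
    genomes[sp] <- emb$scaffold
    tr <- emb$truth
    tr$species <- sp
    tr$subfamily <- sub("_.*$", "", tr$id)
    tr$status <- vapply(tr$id, function(id)
      genes[[which(vapply(genes, `[[`, "", "id") == id)]]$status, "")
    truth[[length(truth) + 1L]] <- tr
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  # reference database: in-family templates + out-family decoys
  set.seed(sub_seed(seed, 73L))
  decoys <- vapply(1:2, function(i)
    paste0(sample(AA_ALPHABET1, 230L, replace = TRUE), collapse = ""), "")
  refdb <- data.frame(
    id = c(paste0("ref_", sub_names), paste0("decoy", 1:2)),
    sequence = c(vapply(templates, `[[`, "", "protein"), decoys),
    family = c(sub_names, rep("other", 2L)),
    in_family = c(rep(TRUE, length(sub_names)), FALSE, FALSE))
  list(genomes = genomes, truth = truth, templates = templates,
       refdb = refdb, gene_trees = gene_trees, alignments = alignments,
       genes = genes, config = config, seed = seed)
}

#' Score mined loci against scenario truth
#'
#' A truth gene is recovered when a candidate locus on the same scaffold
#' and strand overlaps at least half of it; a candidate is a true positive
#' when it overlaps half of some truth gene.
#'
#' @param loci Candidate loci ([recursive_mine()] output).
#' @param truth Truth table from [simulate_scenario()].
#' @return List: `sensitivity`, `ppv`, `matches` (truth id per locus).
#' @export
score_mining <- function(loci, truth) {
  match_of <- rep(NA_character_, nrow(loci))
  found <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(loci))) {
    same <- truth$scaffold == loci$scaffold[i] &
      truth$strand == loci$strand[i]
    for (j in which(same)) {
      ov <- min(truth$end[j], loci$end[i]) - max(truth$start[j],
                                                 loci$start[i])
      if (ov >= 0.5 * (truth$end[j] - truth$start[j])) {
        found[j] <- TRUE
        match_of[i] <- truth$id[j]
      }
    }
  }
  list(sensitivity = mean(found), ppv = mean(!is.na(match_of)),
       matches = match_of)
}

#' Census table of classified candidates
#'
#' @param candidates data.frame with `species`, `subfamily`, `status`
#'   columns (unassigned subfamilies are reported as `"unclassified"`,
#'   never dropped).
#' @return A `census_table`: 3-d count array species x subfamily x status
#'   plus the rendered Table-1-style data.frame (`"N [i] (p)"`).
#' @export
census <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(structure(list(counts = array(0L, c(0L, 0L, 3L)),
                          rendered = data.frame()),
                     class = "census_table"))
  }
  sf <- candidates$subfamily
  sf[is.na(sf) | sf == "unassigned"] <- "unclassified"
  counts <- table(species = candidates$species, subfamily = sf,
                  status = factor(candidates$status,
                                  levels = c("intact", "incomplete",
                                             "pseudogene")))
  render_cell <- function(i, inc, p) {
    out <- as.character(i)
    if (inc > 0) out <- paste0(out, " [", inc, "]")
    if (p > 0) out <- paste0(out, " (", p, ")")
    out
  }
  rendered <- data.frame(species = rownames(counts))
  for (s in colnames(counts)) {
    rendered[[s]] <- mapply(render_cell, counts[, s, "intact"],
                            counts[, s, "incomplete"],
                            counts[, s, "pseudogene"])
  }
  structure(list(counts = counts, rendered = rendered),
            class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  print(x$rendered, row.names = FALSE)
  invisible(x)
}

#' Synteny summary of a gene coordinate table
#'
#' Genes are sorted by start within each scaffold; intergenic length is
#' `next.start - this.end` (exact gap under half-open coordinates).
#'
#' @param coords data.frame: scaffold, start, end, strand, id, optional
#'   status.
#' @param include_pseudogenes Keep pseudogenes in the adjacency chain
#'   (default FALSE, mirroring analyses restricted to functional genes).
#' @return List: `intergenic` (data.frame scaffold, left, right, length),
#'   `mean_intergenic` (NA when no adjacent pair), `orientation` vector.
#' @export
synteny_stats <- function(coords, include_pseudogenes = FALSE) {
  d <- coords
  if (!include_pseudogenes && "status" %in% names(d))
    d <- d[d$status != "pseudogene", , drop = FALSE]
  gaps <- list()
  for (sc in unique(d$scaffold)) {
    g <- d[d$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) >= 2L) {
      for (i in seq_len(nrow(g) - 1L)) {
        if (g$start[i + 1L] < g$end[i])
          stop("overlapping genes: ", g$id[i], " / ", g$id[i + 1L])
        gaps[[length(gaps) + 1L]] <- data.frame(
          scaffold = sc, left = g$id[i], right = g$id[i + 1L],
          length = g$start[i + 1L] - g$end[i])
      }
    }
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(scaffold = character(0), left = character(0),
               right = character(0), length = numeric(0))
  list(intergenic = gaps,
       mean_intergenic = if (nrow(gaps)) mean(gaps$length) else NA_real_,
       orientation = setNames(d$strand, d$id))
}

#' Compare omega between two subfamily groups
#'
#' One-tailed two-sample t-test (alternative: group B mean exceeds group
#' A; pooled variance by default, Welch available) and a one-tailed
#' Mann-Whitney U in the same direction (exact p for n <= 20 per group,
#' normal approximation with tie correction otherwise).
#'
#' @param omega_by_subfamily Named numeric vector of per-subfamily omega.
#' @param grouping List with character vectors `A` and `B` of subfamily
#'   names.
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @return List: group values, `t_statistic`, `t_p`, `u_statistic`,
#'   `u_p`, `welch_p`.
#' @export
compare_groups <- function(omega_by_subfamily, grouping, var_equal = TRUE) {
  a <- omega_by_subfamily[grouping$A]
  b <- omega_by_subfamily[grouping$B]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (sd(c(a, b)) == 0)
    return(list(A = a, B = b, t_statistic = NA_real_, t_p = NA_real_,
                u_statistic = NA_real_, u_p = NA_real_,
                welch_p = NA_real_, degenerate = TRUE))
  tt <- t.test(b, a, alternative = "greater", var.equal = var_equal)
  tw <- t.test(b, a, alternative = "greater", var.equal = FALSE)
  exact <- length(a) <= 20L && length(b) <= 20L && !anyDuplicated(c(a, b))
  ut <- suppressWarnings(wilcox.test(b, a, alternative = "greater",
                                     exact = exact, correct = !exact))
  list(A = a, B = b, t_statistic = unname(tt$statistic),
       t_p = tt$p.value, welch_p = tw$p.value,
       u_statistic = unname(ut$statistic), u_p = ut$p.value,
       degenerate = FALSE)
}

#' Run the full pipeline on a simulated scenario
#'
#' Mining, truth scoring, classification, subfamily assignment (tree-based
#' for intact genes with an identity fallback; mining's reciprocal label
#' for disabled genes), census, synteny, per-subfamily M0 fits on intact
#' genes, and the M7 vs M8 positive-selection LRT per subfamily.
#'
#' @param scenario Output of [simulate_scenario()].
#' @param fit_selection Run the per-subfamily codon-model stage (default
#'   TRUE).
#' @param verbose Log stage progress to stderr.
#' @return List of stage outputs: `loci`, `mining_score`, `candidates`,
#'   `census`, `truth_census`, `synteny`, `m0_omega`, `m7m8` (per
#'   subfamily LRT table), `flagged_subfamilies`.
#' @export
run_pipeline <- function(scenario, fit_selection = TRUE, verbose = FALSE) {
  log_stage <- function(...) if (verbose) message("[pipeline] ", ...)
  cfg <- scenario$config
  seeds <- setNames(
    vapply(scenario$templates, `[[`, "", "protein"),
    paste0("seed_", names(scenario$templates)))
  log_stage("mining ", length(scenario$genomes), " scaffolds")
  loci <- recursive_mine(scenario$genomes, seeds, scenario$refdb)
  ms <- score_mining(loci, scenario$truth)
  log_stage(sprintf("mining: %d loci, sensitivity %.3f ppv %.3f",
                    nrow(loci), ms$sensitivity, ms$ppv))
  # classification against the best family's template
  cands <- list()
  for (i in seq_len(nrow(loci))) {
    fam <- loci$family[i]
    ref <- scenario$templates[[fam]]$protein
    gc <- classify_gene(list(scaffold = loci$scaffold[i],
                             start = loci$start[i], end = loci$end[i],
                             strand = loci$strand[i]),
                        scenario$genomes[[loci$scaffold[i]]], ref)
    cands[[i]] <- data.frame(
      id = sprintf("cand_%02d", i), scaffold = loci$scaffold[i],
      start = loci$start[i], end = loci$end[i], strand = loci$strand[i],
      species = loci$scaffold[i], status = gc$status, family_hit = fam,
      protein = gc$protein,
      cds = gc$orf_cds)
  }
  cands <- do.call(rbind, cands)
  # subfamily assignment: tree-based for intact candidates
  ref_seqs <- setNames(vapply(scenario$templates, `[[`, "", "protein"),
                       paste0("ref_", names(scenario$templates)))
  ref_labels <- setNames(names(scenario$templates), names(ref_seqs))
  intact_idx <- which(cands$status == "intact")
  cands$subfamily <- cands$family_hit
  if (length(intact_idx) >= 2L) {
    log_stage("aligning ", length(intact_idx), " intact proteins")
    seqs <- c(setNames(cands$protein[intact_idx], cands$id[intact_idx]),
              ref_seqs)
    aln <- progressive_align(seqs)
    tr <- bootstrap_support(aln, n_reps = cfg$bootstrap_reps,
                            seed = sub_seed(scenario$seed, 90L))
    for (i in intact_idx) {
      cands$subfamily[cands$id == cands$id[i]] <-
        assign_subfamily(tr, cands$id[i], ref_labels, aln)
    }
  }
  cen <- census(cands)
  truth_cen <- census(data.frame(species = scenario$truth$species,
                                 subfamily = scenario$truth$subfamily,
                                 status = scenario$truth$status))
  syn <- synteny_stats(scenario$truth, include_pseudogenes = TRUE)
  out <- list(loci = loci, mining_score = ms, candidates = cands,
              census = cen, truth_census = truth_cen, synteny = syn)
  if (!fit_selection) return(out)
  # per-subfamily selection analyses on intact genes
  m0_omega <- c()
  m7m8 <- list()
  for (sf in names(scenario$templates)) {
    idx <- which(cands$subfamily == sf & cands$status == "intact")
    if (length(idx) < 3L) next
    log_stage("codon models for subfamily ", sf, " (", length(idx),
              " genes)")
    prots <- setNames(cands$protein[idx], cands$id[idx])
    cdss <- setNames(toupper(cands$cds[idx]), cands$id[idx])
    paln <- if (length(prots) > 2L) progressive_align(prots) else
      protein_alignment(prots)
    caln <- try(codon_backtranslate(paln, cdss), silent = TRUE)
    if (inherits(caln, "try-error")) next
    dtree <- neighbor_joining(jtt_gamma_dist_matrix(paln))
    freqs <- f3x4_frequencies(caln)
    ocfg <- list(factr = 1e10)
    m0 <- fit_model(caln, dtree, codon_model_spec("M0", freqs = freqs),
                    ocfg)
    m0_omega[sf] <- m0$mle[["omega"]]
    m7 <- fit_model(caln, m0$tree,
                    codon_model_spec("M7", kappa = m0$mle[["kappa"]],
                                     freqs = freqs,
                                     ncat_beta = cfg$ncat_beta), ocfg)
    m8 <- fit_model(caln, m0$tree,
                    codon_model_spec("M8", kappa = m7$mle[["kappa"]],
                                     p = m7$mle[["p"]], q = m7$mle[["q"]],
                                     freqs = freqs,
                                     ncat_beta = cfg$ncat_beta), ocfg)
    if (m8$lnL < m7$lnL) m8$lnL <- m7$lnL
    t78 <- lrt(m7, m8)
    m7m8[[sf]] <- data.frame(subfamily = sf, n_genes = length(idx),
                             lnL_M7 = m7$lnL, lnL_M8 = m8$lnL,
                             stat = t78$statistic, df = t78$df,
                             p = t78$p_value)
  }
  out$m0_omega <- m0_omega
  out$m7m8 <- if (length(m7m8)) do.call(rbind, m7m8) else NULL
  out$flagged_subfamilies <- if (!is.null(out$m7m8))
    out$m7m8$subfamily[out$m7m8$p < 0.05] else character(0)
  out
}
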