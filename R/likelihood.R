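# Felsenstein pruning over the 61-codon state space, maximum-likelihood
# fitting of the model family, likelihood-ratio tests, and empirical-Bayes
# site identification.

# Normalize a tree for likelihood work: postorder edge ordering plus a
# remapping of foreground edge indices given against the original edge rows.
prepare_tree <- function(tree, foreground = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  pt <- stats::reorder(tree, "postorder")
  fg <- rep(FALSE, nrow(pt$edge))
  if (!is.null(foreground)) {
    if (is.logical(foreground)) foreground <- which(foreground)
    key_orig <- paste(tree$edge[, 1L], tree$edge[, 2L])
    key_post <- paste(pt$edge[, 1L], pt$edge[, 2L])
    fg[match(key_orig[foreground], key_post)] <- TRUE
  }
  list(tree = pt, fg = fg)
}

#' Edge indices of the clade spanned by a set of tips
#'
#' Returns the stem edge of the most recent common ancestor of `tips` plus
#' every edge inside the clade — the usual way a whole lineage is marked
#' foreground in branch and branch-site models.
#'
#' @param tree phylo tree.
#' @param tips Tip labels defining the clade.
#' @return Integer edge indices into `tree$edge`.
#' @export
foreground_clade <- function(tree, tips) {
  mrca <- ape::getMRCA(tree, tips)
  if (is.null(mrca)) stop("tips do not define a clade")
  nodes <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1L] %in% nodes, 2L]
    new <- setdiff(kids, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  which(tree$edge[, 1L] %in% nodes | tree$edge[, 2L] == mrca)
}

#' Mark foreground branches by the `#1` label convention
#'
#' Tip or internal-node labels ending in `#1` mark the edge leading to that
#' node as foreground; the suffix is stripped from the returned tree.
#'
#' @param tree An `ape` phylo tree.
#' @return List of `tree` (labels cleaned) and `foreground` (edge indices
#'   into `tree$edge`).
#' @export
mark_foreground <- function(tree) {
  labs <- c(tree$tip.label,
            if (!is.null(tree$node.label)) tree$node.label else
              rep("", tree$Nnode))
  marked_nodes <- which(grepl("#1$", labs))
  tree$tip.label <- sub("\\s*#1$", "", tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- sub("\\s*#1$", "", tree$node.label)
  fg <- which(tree$edge[, 2L] %in% marked_nodes)
  list(tree = tree, foreground = fg)
}

# Pattern-compress a codon alignment against tree tip order.
# Returns states matrix (tips x npat), weights, and pattern index per site.
compress_patterns <- function(alignment, tree) {
  miss <- setdiff(tree$tip.label, alignment$ids)
  if (length(miss)) stop("tree leaf missing from alignment: ", miss[1L])
  st <- alignment$states[tree$tip.label, , drop = FALSE]
  key <- apply(st, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  pat_of_site <- match(key, key[u])
  list(states = st[, u, drop = FALSE], weights = as.vector(table(pat_of_site)),
       pat_of_site = pat_of_site)
}

# Per-class per-pattern log-likelihoods by pruning.
# gens: output of model_generators; pt: prepare_tree output.
class_site_loglik <- function(states, pt, gens) {
  tree <- pt$tree
  edge <- tree$edge
  elen <- tree$edge.length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(states)
  nclass <- length(gens$cs$props)
  out <- matrix(NA_real_, npat, nclass)
  root <- edge[nrow(edge), 1L]
  ne <- nrow(edge)
  for (k in seq_len(nclass)) {
    # transition matrices per edge for this class
    om_idx <- gens$cs$map[k, ]
    cond <- vector("list", nnode)
    logsc <- rep(0, npat)
    for (e in seq_len(ne)) {
      P <- prob_matrix(gens$eds[[om_idx[e]]], elen[e])
      child <- edge[e, 2L]
      parent <- edge[e, 1L]
      if (child <= ntip) {
        stc <- states[child, ]
        if (anyNA(stc)) {
          M <- matrix(1, 61L, npat)
          ok <- !is.na(stc)
          M[, ok] <- P[, stc[ok]]
        } else M <- P[, stc]
      } else {
        M <- P %*% cond[[child]]
      }
      cond[[parent]] <- if (is.null(cond[[parent]])) M else cond[[parent]] * M
      # periodic rescaling is enough to keep 61-state products above
      # double-precision underflow between checkpoints
      if (e %% 16L == 0L || e == ne) {
        cs <- colSums(cond[[parent]])
        cs[cs < 1e-280] <- 1e-280
        cond[[parent]] <- cond[[parent]] / rep(cs, each = 61L)
        logsc <- logsc + log(cs)
      }
    }
    lik <- colSums(attr(gens, "freqs") * cond[[root]])
    out[, k] <- log(lik) + logsc
  }
  out
}

# Full model instance: generators carrying frequencies attribute.
instantiate_model <- function(spec, fg) {
  g <- model_generators(spec, fg)
  attr(g, "freqs") <- spec$freqs
  g
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning per codon site over the 61 sense codons, mixed over
#' the model's site classes. Gap/ambiguous codons are missing data (summed
#' over states); per-site rescaling guards against underflow.
#'
#' @param alignment A [codon_alignment()].
#' @param tree phylo tree with branch lengths in expected substitutions per
#'   codon; leaves must appear in the alignment.
#' @param spec A [codon_model_spec()].
#' @return Log-likelihood (numeric scalar) with attribute `"site_loglik"`.
#' @export
log_likelihood <- function(alignment, tree, spec) {
  pt <- prepare_tree(tree, spec$foreground)
  cp <- compress_patterns(alignment, pt$tree)
  gens <- instantiate_model(spec, pt$fg)
  ll <- class_site_loglik(cp$states, pt, gens)
  site_ll <- mix_classes(ll, gens$cs$props)
  total <- sum(site_ll * cp$weights)
  attr(total, "site_loglik") <- site_ll[cp$pat_of_site]
  total
}

# log sum_k p_k exp(ll_k) rowwise, stably.
mix_classes <- function(ll, props) {
  m <- apply(ll, 1L, max)
  m + log(as.vector(exp(ll - m) %*% props))
}

# ---------------------------------------------------------------------------
# Fitting

# Free-parameter layout per model: names, lower/upper bounds, default start.
param_layout <- function(spec) {
  K <- list(name = "kappa", lo = 0.05, hi = 100, start = spec$kappa)
  switch(spec$model,
    M0 = ,
    branch_R1 = list(K, list(name = "omega", lo = 1e-4, hi = 20,
                             start = spec$omega)),
    branch_R2 = list(K,
                     list(name = "omega", lo = 1e-4, hi = 20,
                          start = spec$omega),
                     list(name = "omega2", lo = 1e-4, hi = 20,
                          start = spec$omega2)),
    M1a = list(K,
               list(name = "p0", lo = 1e-4, hi = 1 - 1e-4, start = spec$p0),
               list(name = "omega0", lo = 1e-4, hi = 1 - 1e-6,
                    start = min(spec$omega0, 0.9))),
    M2a = list(K,
               list(name = "p0", lo = 1e-4, hi = 1 - 1e-4, start = spec$p0),
               list(name = "p1f", lo = 1e-4, hi = 1 - 1e-4, start = 0.6),
               list(name = "omega0", lo = 1e-4, hi = 1 - 1e-6,
                    start = min(spec$omega0, 0.9)),
               list(name = "omega2", lo = 1, hi = 50, start = spec$omega2)),
    M7 = list(K,
              list(name = "p", lo = 0.005, hi = 99, start = spec$p),
              list(name = "q", lo = 0.005, hi = 99, start = spec$q)),
    M8 = list(K,
              list(name = "p0", lo = 1e-4, hi = 1 - 1e-4, start = 0.9),
              list(name = "p", lo = 0.005, hi = 99, start = spec$p),
              list(name = "q", lo = 0.005, hi = 99, start = spec$q),
              list(name = "omega_s", lo = 1 + 1e-6, hi = 50,
                   start = spec$omega_s)),
    branchsite_A = list(K,
                        list(name = "pA", lo = 1e-4, hi = 1 - 1e-4,
                             start = 0.8),
                        list(name = "pB", lo = 1e-4, hi = 1 - 1e-4,
                             start = 0.6),
                        list(name = "omega0", lo = 1e-4, hi = 1 - 1e-6,
                             start = min(spec$omega0, 0.9)),
                        list(name = "omega2", lo = 1, hi = 50,
                             start = spec$omega2)),
    branchsite_A_null = list(K,
                             list(name = "pA", lo = 1e-4, hi = 1 - 1e-4,
                                  start = 0.8),
                             list(name = "pB", lo = 1e-4, hi = 1 - 1e-4,
                                  start = 0.6),
                             list(name = "omega0", lo = 1e-4, hi = 1 - 1e-6,
                                  start = min(spec$omega0, 0.9))))
}

# Apply a named free-parameter vector onto a spec.
apply_params <- function(spec, par) {
  nm <- names(par)
  if ("kappa" %in% nm) spec$kappa <- par[["kappa"]]
  if ("omega" %in% nm) spec$omega <- par[["omega"]]
  if ("omega0" %in% nm) spec$omega0 <- par[["omega0"]]
  if ("omega2" %in% nm && spec$model != "branchsite_A_null")
    spec$omega2 <- par[["omega2"]]
  if ("omega_s" %in% nm) spec$omega_s <- par[["omega_s"]]
  if ("p" %in% nm) spec$p <- par[["p"]]
  if ("q" %in% nm) spec$q <- par[["q"]]
  if (spec$model %in% c("M1a", "M8") && "p0" %in% nm) spec$p0 <- par[["p0"]]
  if (spec$model == "M2a") {
    spec$p0 <- par[["p0"]]
    spec$p1 <- (1 - par[["p0"]]) * par[["p1f"]]
  }
  if (spec$model %in% c("branchsite_A", "branchsite_A_null")) {
    a <- par[["pA"]]; b <- par[["pB"]]
    spec$p0 <- a * b
    spec$p1 <- a * (1 - b)
  }
  spec
}

# Multi-start jitter offsets (deterministic; no RNG involvement).
start_jitters <- list(
  c(0), c(-0.35), c(0.45)
)

#' Fit a codon model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization of the model's free
#' parameters; for M0 (and on request for any model) branch lengths are
#' optimized jointly on a log scale. Site models are refit from three
#' deterministic starts and the best solution is kept.
#'
#' @param alignment A [codon_alignment()].
#' @param tree phylo tree; leaves must appear in the alignment.
#' @param spec A [codon_model_spec()] giving the model and starting values.
#'   Frequencies are taken from the spec (compute them with
#'   [f3x4_frequencies()]).
#' @param optimizer_config List: `optimize_branches` (default TRUE for M0,
#'   FALSE otherwise), `multi_start` (default TRUE for site models),
#'   `factr` L-BFGS-B tolerance (default 1e9), `maxit` (default 200).
#' @return A `codon_model_fit`: `spec` (with MLEs applied), `lnL`, `mle`
#'   (named vector), `tree` (with fitted branch lengths if optimized),
#'   `convergence`, and the per-site class posterior inputs.
#' @export
fit_model <- function(alignment, tree, spec,
                      optimizer_config = list()) {
  cfg <- utils::modifyList(
    list(optimize_branches = NA, multi_start = NA, factr = 1e9, maxit = 200L),
    optimizer_config)
  site_mod <- spec$model %in% c("M1a", "M2a", "M7", "M8")
  if (is.na(cfg$optimize_branches))
    cfg$optimize_branches <- spec$model == "M0"
  if (is.na(cfg$multi_start)) cfg$multi_start <- site_mod
  pt <- prepare_tree(tree, spec$foreground)
  cp <- compress_patterns(alignment, pt$tree)
  lay <- param_layout(spec)
  nm <- vapply(lay, `[[`, "", "name")
  lo <- vapply(lay, `[[`, 0, "lo")
  hi <- vapply(lay, `[[`, 0, "hi")
  st <- pmin(pmax(vapply(lay, `[[`, 0, "start"), lo), hi)
  names(st) <- nm
  nb <- if (cfg$optimize_branches) nrow(pt$tree$edge) else 0L
  bl0 <- pmax(pt$tree$edge.length, 1e-6)

  objective <- function(x) {
    par <- x[seq_along(nm)]
    names(par) <- nm
    sp <- apply_params(spec, par)
    ptree <- pt
    if (nb > 0L) ptree$tree$edge.length <- exp(x[length(nm) + seq_len(nb)])
    gens <- try(instantiate_model(sp, pt$fg), silent = TRUE)
    if (inherits(gens, "try-error")) return(1e10)
    ll <- class_site_loglik(cp$states, ptree, gens)
    val <- sum(mix_classes(ll, gens$cs$props) * cp$weights)
    if (!is.finite(val)) return(1e10)
    -val
  }

  lower <- c(lo, rep(log(1e-7), nb))
  upper <- c(hi, rep(log(30), nb))
  starts <- if (cfg$multi_start) start_jitters else start_jitters[1L]
  best <- NULL
  diagnostics <- character(0)
  coarse <- length(starts) > 1L
  for (jit in starts) {
    s <- st
    wj <- grep("omega|kappa|^p$|^q$", names(s))
    s[wj] <- pmin(pmax(s[wj] * exp(jit), lo[wj] + 1e-6), hi[wj] - 1e-6)
    x0 <- c(s, if (nb > 0L) log(bl0))
    # extra starts run at coarse tolerance; the winner is polished below
    fit <- try(optim(x0, objective, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(factr = if (coarse) 1e12 else cfg$factr,
                                    maxit = cfg$maxit)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      diagnostics <- c(diagnostics, as.character(fit))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed on all starts: ",
         paste(diagnostics, collapse = "; "))
  if (coarse) {
    polished <- try(optim(best$par, objective, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = cfg$factr,
                                         maxit = cfg$maxit)),
                    silent = TRUE)
    if (!inherits(polished, "try-error") && polished$value <= best$value)
      best <- polished
  }
  mle <- best$par[seq_along(nm)]
  names(mle) <- nm
  fitted_spec <- apply_params(spec, mle)
  fitted_tree <- pt$tree
  if (nb > 0L)
    fitted_tree$edge.length <- exp(best$par[length(nm) + seq_len(nb)])
  ptree <- pt; ptree$tree <- fitted_tree
  gens <- instantiate_model(fitted_spec, pt$fg)
  ll <- class_site_loglik(cp$states, ptree, gens)
  structure(list(spec = fitted_spec, lnL = -best$value, mle = mle,
                 tree = fitted_tree, foreground = pt$fg,
                 convergence = best$convergence,
                 class_props = gens$cs$props,
                 class_site_loglik = ll[cp$pat_of_site, , drop = FALSE],
                 alignment = alignment, pattern = cp),
            class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat("codon model", x$spec$model, " lnL =", format(x$lnL, digits = 10), "\n")
  print(round(x$mle, 4))
  invisible(x)
}

# Nested-model pairings with their degrees of freedom derived from
# free-parameter counting.
lrt_pairings <- function() {
  data.frame(null = c("M1a", "M7", "branch_R1", "branchsite_A_null"),
             alt = c("M2a", "M8", "branch_R2", "branchsite_A"))
}

#' Likelihood-ratio test between nested codon-model fits
#'
#' The statistic is `max(0, 2 (lnL1 - lnL0))` compared to a chi-squared
#' upper tail. When `df` is omitted it is derived by free-parameter
#' counting from the two model specs (M1a vs M2a and M7 vs M8 give df = 2;
#' R1 vs R2 and the branch-site test give df = 1).
#'
#' @param fit_null,fit_alt `codon_model_fit` objects for nested models.
#' @param df Degrees of freedom; default `n_free_params(alt) -
#'   n_free_params(null)`.
#' @return List: `statistic`, `df`, `p_value`, `lnL0`, `lnL1`.
#' @export
lrt <- function(fit_null, fit_alt, df = NULL) {
  lnL0 <- fit_null$lnL; lnL1 <- fit_alt$lnL
  if (lnL1 < lnL0 - 1e-4)
    stop("alternative lnL below null lnL beyond tolerance: optimizer failure")
  if (is.null(df))
    df <- n_free_params(fit_alt$spec) - n_free_params(fit_null$spec)
  if (df < 1L) stop("df must be >= 1")
  stat <- max(0, 2 * (lnL1 - lnL0))
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       lnL0 = lnL0, lnL1 = lnL1)
}

# Index/indices of the positive-selection class(es) of a fitted model.
positive_classes <- function(spec) {
  switch(spec$model,
         M2a = 3L,
         M8 = spec$ncat_beta + 1L,
         branchsite_A = c(3L, 4L),
         stop("model '", spec$model, "' has no positive-selection class"))
}

#' Empirical-Bayes identification of positively selected sites
#'
#' NEB evaluates the class posterior at the MLEs. The BEB-grid method
#' averages the posterior over a uniform grid prior on the
#' positive-selection class proportion and omega (10 points per dimension,
#' other parameters held at their MLEs) — a documented approximation to the
#' published Bayes empirical Bayes procedure.
#'
#' @param fit A `codon_model_fit` for M2a, M8 or branchsite_A.
#' @param method `"NEB"` (default, exact at the MLEs) or `"BEB-grid"`.
#' @param cutoff Posterior probability above which a site is flagged
#'   (default 0.95).
#' @return data.frame: `site` (1-based codon column), `posterior`
#'   (probability of the positive-selection class), `method`, `flagged`.
#' @export
site_posteriors <- function(fit, method = c("NEB", "BEB-grid"),
                            cutoff = 0.95) {
  method <- match.arg(method)
  pos <- positive_classes(fit$spec)
  if (method == "NEB") {
    ll <- fit$class_site_loglik
    w <- rep(fit$class_props, each = nrow(ll))
    num <- exp(ll - apply(ll, 1L, max)) * matrix(w, nrow(ll))
    post <- rowSums(num[, pos, drop = FALSE]) / rowSums(num)
  } else {
    post <- beb_grid_posterior(fit, pos)
  }
  data.frame(site = seq_along(post), posterior = post, method = method,
             flagged = post > cutoff)
}

# Grid-integrated empirical-Bayes posterior: uniform prior over the
# positive-class proportion (0,1) and its omega; weights each grid point by
# the data likelihood.
beb_grid_posterior <- function(fit, pos, npoints = 10L) {
  spec <- fit$spec
  cp <- fit$pattern
  pt <- list(tree = fit$tree, fg = fit$foreground)
  pgrid <- (seq_len(npoints) - 0.5) / npoints
  wgrid <- 1 + (seq_len(npoints) - 0.5) / npoints * 10  # omega in (1, 11)
  npat <- length(cp$weights)
  acc_num <- rep(0, npat); acc_den <- rep(0, npat); acc_w <- 0
  for (pp in pgrid) for (ww in wgrid) {
    sp <- spec
    if (spec$model == "M2a") {
      scale0 <- (1 - pp) / (sp$p0 + sp$p1)
      sp$p0 <- sp$p0 * scale0; sp$p1 <- sp$p1 * scale0
      sp$omega2 <- ww
    } else if (spec$model == "M8") {
      sp$p0 <- 1 - pp; sp$omega_s <- min(ww, 50)
    } else { # branchsite_A
      b <- sp$p0 / (sp$p0 + sp$p1)
      sp$p0 <- (1 - pp) * b; sp$p1 <- (1 - pp) * (1 - b)
      sp$omega2 <- ww
    }
    gens <- instantiate_model(sp, pt$fg)
    ll <- class_site_loglik(cp$states, pt, gens)
    site_ll <- mix_classes(ll, gens$cs$props)
    data_w <- exp(sum(site_ll * cp$weights) - fit$lnL)
    w2 <- rep(gens$cs$props, each = npat)
    num <- exp(ll - site_ll) * matrix(w2, npat)
    acc_num <- acc_num + data_w * rowSums(num[, pos, drop = FALSE])
    acc_den <- acc_den + data_w * rowSums(num)
    acc_w <- acc_w + data_w
  }
  (acc_num / acc_den)[cp$pat_of_site]
}

#' Branch-site scan over every branch of a tree
#'
#' Runs the branch-site test of positive selection (model A against its
#' omega2 = 1 null, df = 1) once with each branch as the foreground.
#' Branch lengths are first fitted under M0 and then held fixed, and kappa
#' restarts from the M0 estimate.
#'
#' @param alignment A [codon_alignment()].
#' @param tree phylo tree (unrooted; one test per edge, 2n - 3 for a binary
#'   unrooted tree).
#' @param optimizer_config Passed to [fit_model()].
#' @return data.frame with one row per edge: edge index, child label where
#'   terminal, lnL0, lnL1, `stat`, `p`, and Bonferroni-adjusted `p_bonf`.
#' @export
scan_branchsite <- function(alignment, tree, optimizer_config = list()) {
  m0 <- fit_model(alignment, tree,
                  codon_model_spec("M0", freqs = f3x4_alignment(alignment)),
                  optimizer_config)
  btree <- m0$tree
  ne <- nrow(btree$edge)
  rows <- vector("list", ne)
  for (e in seq_len(ne)) {
    alt <- codon_model_spec("branchsite_A", kappa = m0$mle[["kappa"]],
                            freqs = m0$spec$freqs, foreground = e)
    null <- codon_model_spec("branchsite_A_null", kappa = m0$mle[["kappa"]],
                             freqs = m0$spec$freqs, foreground = e)
    f1 <- fit_model(alignment, btree, alt, optimizer_config)
    f0 <- fit_model(alignment, btree, null, optimizer_config)
    if (f1$lnL < f0$lnL) f1$lnL <- f0$lnL  # boundary case: alt contains null
    t2 <- lrt(f0, f1)
    child <- btree$edge[e, 2L]
    rows[[e]] <- data.frame(
      edge = e,
      child = if (child <= length(btree$tip.label))
        btree$tip.label[child] else paste0("node", child),
      lnL0 = f0$lnL, lnL1 = f1$lnL,
      stat = t2$statistic, p = t2$p_value)
  }
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * ne)
  out
}

# F3X4 frequencies straight from a codon_alignment (internal shorthand).
f3x4_alignment <- function(alignment) f3x4_frequencies(alignment)

#' Project a protein alignment's gaps onto coding sequences
#'
#' Back-translates an aligned protein set into a codon alignment by
#' inserting triplet gaps where the protein alignment has gaps. Errors if a
#' CDS does not translate to its aligned protein.
#'
#' @param protein_alignment A [protein_alignment()].
#' @param cds Named character vector of unaligned CDS (ids matching the
#'   alignment; terminal stop codons are dropped automatically).
#' @return A [codon_alignment()].
#' @export
codon_backtranslate <- function(protein_alignment, cds) {
  out <- character(0)
  for (id in protein_alignment$ids) {
    if (!id %in% names(cds)) stop("no CDS for '", id, "'")
    s <- cds[[id]]
    if (nchar(s) %% 3L == 0L && translate_nt(s) %in%
        paste0(gsub("-", "", protein_alignment$seqs[[id]]), "*"))
      s <- substr(s, 1L, nchar(s) - 3L)
    prot <- translate_nt(s)
    aligned <- protein_alignment$seqs[[id]]
    if (gsub("-", "", aligned) != prot)
      stop("CDS for '", id, "' does not translate to its aligned protein")
    codons <- codon_split(s)
    res <- character(nchar(aligned))
    j <- 0L
    chars <- split1(aligned)
    for (i in seq_along(chars)) {
      if (chars[i] == "-") res[i] <- "---"
      else { j <- j + 1L; res[i] <- codons[j] }
    }
    out[id] <- paste0(res, collapse = "")
  }
  codon_alignment(out)
}
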