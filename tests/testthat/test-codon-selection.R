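test_that("F3X4 frequencies: symmetry, single-codon, and tally oracle", {
  ca <- codon_alignment(random_codon_seqs(4, 200, 1))
  f <- f3x4_frequencies(ca)
  expect_equal(sum(f), 1)
  # independent per-position tally oracle
  chars <- ca$chars
  pf <- sapply(1:3, function(p) {
    nt <- substr(chars, p, p)
    table(factor(nt, levels = c("T", "C", "A", "G"))) / length(nt)
  })
  tab <- do.call(rbind, strsplit(sense_codons(), ""))
  raw <- pf[, 1][tab[, 1]] * pf[, 2][tab[, 2]] * pf[, 3][tab[, 3]]
  raw[raw == 0] <- raw[raw == 0] + 1e-6
  expect_equal(unname(f), unname(raw / sum(raw)), tolerance = 1e-12)
  # single repeated codon dominates after smoothing
  one <- codon_alignment(c(a = strrep("AAA", 20), b = strrep("AAA", 20)))
  f1 <- f3x4_frequencies(one)
  expect_gt(f1[["AAA"]], 0.99)
  # in-frame stop is an error naming the site
  expect_error(codon_alignment(c(a = "ATGTAAGGG")), "stop codon.*codon site 2")
})

test_that("rate matrix structure: omega zero, symmetry, row-stochastic exponential", {
  pi <- rep(1 / 61, 61)
  q0 <- build_rate_matrix(0, 2, pi)
  aa <- codon_aa()
  for (i in c(1, 10, 30)) {
    nonsyn <- which(aa != aa[i])
    expect_true(all(q0[i, nonsyn] == 0))
  }
  q1 <- build_rate_matrix(1, 1, pi, scale = FALSE)
  off <- q1[q1 > 0]
  expect_equal(length(unique(round(off, 12))), 1L)
  # detailed balance under non-uniform frequencies
  set.seed(4)
  pi2 <- runif(61); pi2 <- pi2 / sum(pi2)
  Q <- build_rate_matrix(0.5, 3, pi2)
  A <- pi2 * Q    # A_ij = pi_i q_ij must be symmetric (detailed balance)
  expect_lt(max(abs(A - t(A))), 1e-12)
  ed <- taarevol:::eigen_generator(Q, pi2)
  for (t in c(0.01, 0.1, 1)) {
    P <- taarevol:::prob_matrix(ed, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-9)
    expect_true(all(P >= 0))
  }
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(1)
  codons <- sense_codons()
  # 3-taxon star (one internal node) and 4-taxon tree (two internal nodes)
  for (case in 1:2) {
    if (case == 1) {
      tr <- ape::read.tree(text = "(a:0.1,b:0.25,c:0.3);")
    } else {
      tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.3,d:0.12);")
    }
    n <- length(tr$tip.label)
    seqs <- setNames(vapply(seq_len(n), function(i)
      paste0(sample(codons, 4, replace = TRUE), collapse = ""), ""),
      tr$tip.label)
    ca <- codon_alignment(seqs)
    spec <- codon_model_spec("M0", omega = 0.3, kappa = 2.5)
    ll <- as.numeric(log_likelihood(ca, tr, spec))
    pt <- taarevol:::prepare_tree(tr)
    gens <- taarevol:::instantiate_model(spec, pt$fg)
    tree <- pt$tree
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      taarevol:::prob_matrix(gens$eds[[1]], tree$edge.length[e]))
    st <- ca$states[tree$tip.label, ]
    ntip <- n
    internals <- (ntip + 1):(ntip + tree$Nnode)
    tot <- 0
    for (site in 1:4) {
      s <- st[, site]
      lik <- 0
      grid <- do.call(expand.grid,
                      rep(list(1:61), length(internals)))
      for (g in seq_len(nrow(grid))) {
        assign_states <- c(s, as.integer(grid[g, ]))
        p <- spec$freqs[assign_states[internals[1]]]
        for (e in seq_len(nrow(tree$edge))) {
          p <- p * Ps[[e]][assign_states[tree$edge[e, 1]],
                           assign_states[tree$edge[e, 2]]]
        }
        lik <- lik + p
      }
      tot <- tot + log(lik)
    }
    expect_equal(ll, tot, tolerance = 1e-10)
  }
})

test_that("degenerate likelihoods have closed forms", {
  seqs <- c(a = strrep("ATGCTG", 4), b = strrep("ATGCTG", 4),
            c = strrep("ATGCTG", 4))
  ca <- codon_alignment(seqs)
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  spec <- codon_model_spec("M0", omega = 0.4, kappa = 2)
  ll <- as.numeric(log_likelihood(ca, tr, spec))
  expect_equal(ll, 4 * log(1 / 61) + 4 * log(1 / 61))
  # duplicating every column doubles lnL
  seqs2 <- vapply(seqs, function(s) paste0(s, s), "")
  tr2 <- ape::read.tree(text = "(a:0.1,b:0.2,c:0.15);")
  ca1 <- codon_alignment(seqs)
  ca2 <- codon_alignment(seqs2)
  expect_equal(2 * as.numeric(log_likelihood(ca1, tr2, spec)),
               as.numeric(log_likelihood(ca2, tr2, spec)),
               tolerance = 1e-10)
  expect_error(log_likelihood(ca1, ape::read.tree(text = "(a:1,b:1,z:1);"),
                              spec), "missing")
})

test_that("LRT statistic, p-value, and auto-df by free-parameter counting", {
  f0 <- structure(list(lnL = -1003, spec = codon_model_spec("M1a")),
                  class = "codon_model_fit")
  f1 <- structure(list(lnL = -1000, spec = codon_model_spec("M2a")),
                  class = "codon_model_fit")
  r <- lrt(f0, f1)
  expect_equal(r$statistic, 6)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, exp(-3), tolerance = 1e-12)
  same <- lrt(f0, structure(list(lnL = -1003,
                                 spec = codon_model_spec("M2a")),
                            class = "codon_model_fit"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt(f1, f0), "below null")
})

test_that("nesting: M2a fit never falls below M1a on M1a data", {
  tr <- balanced8_tree(0.2)
  sim <- simulate_codon_alignment(
    tr, codon_model_spec("M1a", p0 = 0.6, omega0 = 0.2, kappa = 2),
    150, seed = 77)
  freqs <- f3x4_frequencies(sim$alignment)
  cfg <- list(factr = 1e10)
  m0 <- fit_model(sim$alignment, tr, codon_model_spec("M0", freqs = freqs),
                  cfg)
  m1a <- fit_model(sim$alignment, m0$tree,
                   codon_model_spec("M1a", freqs = freqs), cfg)
  m2a <- fit_model(sim$alignment, m0$tree,
                   codon_model_spec("M2a", freqs = freqs), cfg)
  expect_gte(m2a$lnL, m1a$lnL - 1e-4)
  expect_lt(lrt(m1a, m2a)$statistic, 10)
})

test_that("branch model R2 with a null foreground matches the background", {
  tr <- balanced8_tree(0.25)
  sim <- simulate_codon_alignment(tr, codon_model_spec("M0", omega = 0.3,
                                                       kappa = 2),
                                  300, seed = 13)
  freqs <- f3x4_frequencies(sim$alignment)
  m0 <- fit_model(sim$alignment, tr, codon_model_spec("M0", freqs = freqs),
                  list(factr = 1e10))
  fg <- 3L
  r2 <- fit_model(sim$alignment, m0$tree,
                  codon_model_spec("branch_R2", freqs = freqs,
                                   foreground = fg),
                  list(factr = 1e10))
  expect_lt(abs(r2$mle[["omega"]] - r2$mle[["omega2"]]), 0.25)
  r1 <- fit_model(sim$alignment, m0$tree,
                  codon_model_spec("branch_R1", freqs = freqs),
                  list(factr = 1e10))
  t12 <- lrt(r1, r2)
  expect_equal(t12$df, 1)
})

test_that("site posteriors normalize and NEB flags simulated positive sites", {
  tr <- balanced8_tree(0.3)
  spec <- codon_model_spec("M2a", p0 = 0.45, p1 = 0.35, omega0 = 0.1,
                           omega2 = 5, kappa = 2)
  sim <- simulate_codon_alignment(tr, spec, 400, seed = 21)
  freqs <- f3x4_frequencies(sim$alignment)
  m0 <- fit_model(sim$alignment, tr, codon_model_spec("M0", freqs = freqs),
                  list(factr = 1e10))
  fit <- fit_model(sim$alignment, m0$tree,
                   codon_model_spec("M2a", freqs = freqs),
                   list(factr = 1e10))
  post <- site_posteriors(fit, "NEB")
  expect_equal(nrow(post), 400L)
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
  sel <- sim$site_class == 3
  expect_gt(mean(post$posterior[sel]), mean(post$posterior[!sel]))
  # class posteriors sum to 1 at every site
  ll <- fit$class_site_loglik
  w <- matrix(rep(fit$class_props, each = nrow(ll)), nrow(ll))
  num <- exp(ll - apply(ll, 1, max)) * w
  expect_equal(rowSums(num / rowSums(num)), rep(1, nrow(ll)))
  # BEB-grid stays in [0,1] and correlates with NEB
  beb <- site_posteriors(fit, "BEB-grid")
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
  expect_gt(cor(beb$posterior, post$posterior), 0.8)
  expect_error(site_posteriors(m0), "positive-selection class")
})

test_that("NG86 counting: identical, synonymous-only, and path-averaging oracle", {
  a <- "ATGCTGAAA"
  expect_equal(ng86_dnds(a, a)$dN, 0)
  expect_equal(ng86_dnds(a, a)$dS, 0)
  # fourfold-degenerate third-position changes are purely synonymous
  b1 <- paste0(strrep("ATGAAA", 10), strrep("CTGGGA", 3), strrep("ATGAAA", 10))
  b2 <- paste0(strrep("ATGAAA", 10), strrep("CTAGGG", 3), strrep("ATGAAA", 10))
  r <- ng86_dnds(b1, b2)
  expect_equal(r$Nd, 0)
  expect_gt(r$dS, 0)
  expect_equal(r$dN, 0)
  # two-difference codon: explicit enumeration of both substitution orders
  r2 <- taarevol:::ng86_diff_counts(codon_index("TTT"), codon_index("GTA"))
  # TTT(F)->GTT(V)->GTA(V): N then S ; TTT->TTA(L)->GTA(V): N then N
  expect_equal(unname(r2["Sd"]), 0.5)
  expect_equal(unname(r2["Nd"]), 1.5)
  expect_error(ng86_dnds("ATG", "ATGATG"), "length")
})

test_that("M0 MLE and NG86 agree at moderate divergence", {
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  sim <- simulate_codon_alignment(tr, codon_model_spec("M0", omega = 0.3,
                                                       kappa = 2),
                                  500, seed = 3)
  seqs <- apply(sim$alignment$chars, 1, paste0, collapse = "")
  ng <- ng86_dnds(seqs[[1]], seqs[[2]])
  freqs <- f3x4_frequencies(sim$alignment)
  fit <- fit_model(sim$alignment, tr, codon_model_spec("M0", freqs = freqs),
                   list(factr = 1e10))
  expect_false(ng$undefined)
  expect_lt(abs(ng$omega - fit$mle[["omega"]]) / fit$mle[["omega"]], 0.3)
})

test_that("increasing true omega increases the M0 estimate monotonically", {
  tr <- balanced8_tree(0.2)
  med <- vapply(c(0.1, 0.5, 1.5), function(w) {
    fits <- vapply(1:3, function(s)
      sim_and_fit_m0(tr, w, 2, 200, seed = 7000 + s * 13 +
                       round(w * 100))$mle[["omega"]], 0)
    median(fits)
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("branch-site scan covers every branch of an unrooted tree", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.2):0.15,(c:0.2,d:0.2):0.15,e:0.3);")
  sim <- simulate_codon_alignment(tr, codon_model_spec("M0", omega = 0.2,
                                                       kappa = 2),
                                  120, seed = 15)
  tab <- scan_branchsite(sim$alignment, tr,
                         optimizer_config = list(factr = 1e11,
                                                 multi_start = FALSE))
  expect_equal(nrow(tab), 2 * 5 - 3)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$p_bonf >= tab$p))
})

test_that("codon backtranslation projects gaps and validates translations", {
  cds <- c(x = "ATGAAACTG", y = "ATGCTG")
  paln <- protein_alignment(c(x = "MKL", y = "M-L"))
  ca <- codon_backtranslate(paln, cds)
  expect_equal(unname(ca$chars[2, 2]), "---")
  expect_equal(unname(ca$chars[1, ]), c("ATG", "AAA", "CTG"))
  bad <- c(x = "ATGAAACTG", y = "ATGATT")
  expect_error(codon_backtranslate(paln, bad), "does not translate")
})
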