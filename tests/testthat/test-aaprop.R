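props <- default_property_table()
bins <- magnitude_bins(props)

test_that("magnitude bins span all 190 pairs with an 8-bin histogram oracle", {
  for (pr in names(props)) {
    v <- setNames(props[[pr]], rownames(props))
    pairs <- combn(rownames(props), 2)
    deltas <- abs(v[pairs[1, ]] - v[pairs[2, ]])
    cats <- vapply(seq_len(ncol(pairs)), function(k)
      categorize(pairs[1, k], pairs[2, k], bins, pr, props), 1L)
    # independent re-binning: equal-width bins, boundary to the lower bin
    width <- max(deltas) / 8
    oracle <- pmin(pmax(ceiling(deltas / width - 1e-12), 1L), 8L)
    expect_equal(cats, unname(oracle))
    expect_true(any(cats == 8L))   # the max pair lands in bin 8
  }
  expect_equal(categorize("A", "A", bins, "hydropathy", props), 1L)
  expect_error(categorize("A", "Z", bins, "hydropathy", props), "unknown")
})

test_that("Fitch reconstruction: constant columns, hand-worked sets, oracle counts", {
  al <- protein_alignment(c(a = "A", b = "A", c = "A", d = "A"))
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rec <- reconstruct_ancestral(tr, al)
  expect_true(all(rec$states[, 1] == "A"))
  expect_equal(rec$score, 0L)
  # ((A,A),(W,W)): root ambiguous {A,W}, resolved lexicographically to A;
  # child nodes unambiguous
  al2 <- protein_alignment(c(a = "A", b = "A", c = "W", d = "W"))
  rec2 <- reconstruct_ancestral(tr, al2)
  expect_equal(rec2$score, 1L)
  ntip <- 4
  root <- rec2$rooted_at
  expect_equal(rec2$states[root, 1], "A")
  expect_equal(sort(rec2$states[setdiff(5:7, root), 1]), c("A", "W"))
})

test_that("Fitch score equals brute-force minimum over labelings (<= 6 leaves)", {
  set.seed(8)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    obs <- sample(c("A", "C", "D", "W"), n, replace = TRUE)
    al <- protein_alignment(setNames(as.list(obs), tr$tip.label))
    rec <- reconstruct_ancestral(tr, al)
    # brute force over internal labelings restricted to observed states
    states <- unique(obs)
    pt <- rec$tree
    nint <- pt$Nnode
    grid <- do.call(expand.grid, rep(list(states), nint))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      lab <- c(obs[match(pt$tip.label, tr$tip.label)],
               as.character(unlist(grid[g, ])))
      changes <- sum(lab[pt$edge[, 1]] != lab[pt$edge[, 2]])
      best <- min(best, changes)
    }
    expect_equal(rec$score, best)
    # enumerated changes per column equal the parsimony score
    expect_equal(nrow(enumerate_changes(rec)), best)
  }
})

test_that("observed counts are conserved and neutral probabilities sum to 1", {
  set.seed(9)
  seqs <- setNames(vapply(1:5, function(i) random_protein(60, 400 + i), ""),
                   paste0("s", 1:5))
  tr <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1,s5:2);")
  al <- protein_alignment(seqs)
  rec <- reconstruct_ancestral(tr, al)
  ch <- enumerate_changes(rec)
  expect_equal(nrow(ch), sum(rec$score))
  res <- destabilizing_test(ch, rec, bins, "hydropathy", props)
  expect_equal(sum(res$observed), nrow(ch))
  expect_equal(sum(res$p_neutral), 1, tolerance = 1e-12)
})

test_that("threshold semantics are strict: z = 3.09 uncalled, z = 3.10 called", {
  res <- data.frame(category = 1:8)
  # construct counts giving exact z values in category 7
  n <- 400
  # use the machinery directly: fabricate p and observed
  p <- rep(1 / 8, 8)
  z_exact <- function(o) (o - n * p[7]) / sqrt(n * p[7] * (1 - p[7]))
  o309 <- n * p[7] + 3.09 * sqrt(n * p[7] * (1 - p[7]))
  # inline the call rule used by destabilizing_test
  call_rule <- function(z, cat) cat >= 6 & z > 3.09
  expect_false(call_rule(3.09, 7))
  expect_true(call_rule(3.10, 7))
  # and through the exported function with an engineered expectation:
  # two-residue alphabet trick is impractical here, so verify on real data
  # that no call has z <= 3.09 and every category-6:8 row with z > 3.09
  # is called
  set.seed(10)
  seqs <- setNames(vapply(1:4, function(i) random_protein(80, 500 + i), ""),
                   paste0("s", 1:4))
  tr <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1);")
  al <- protein_alignment(seqs)
  rec <- reconstruct_ancestral(tr, al)
  ch <- enumerate_changes(rec)
  for (pr in names(props)) {
    r <- destabilizing_test(ch, rec, bins, pr, props)
    called <- r$call == "positive_destabilizing"
    expect_true(all(r$z[called] > 3.09))
    expect_true(all(r$category[called] >= 6))
    uncalled_radical <- !called & r$category >= 6 & is.finite(r$z)
    expect_true(all(r$z[uncalled_radical] <= 3.09))
    # unreachable categories (p = 0) are flagged, never called
    expect_true(all(r$call[r$infinite_z] == "none"))
  }
})

test_that("radically biased changes are called; unbiased properties are not", {
  # enrich radical hydropathy changes 5x over neutral expectation
  set.seed(11)
  tab <- taarevol:::.codon_tables()
  aa <- taarevol:::AA_ALPHABET1
  ncat_tab <- taarevol:::.aa_neighbor_cats("hydropathy", bins, props)
  calls <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    from <- sample(aa, 200, replace = TRUE)
    to <- character(200)
    for (i in 1:200) {
      # draw a single-nucleotide-reachable target, radical ones upweighted
      cods <- which(tab$aa == from[i])
      nbrs <- unique(unlist(lapply(cods, function(ci) {
        nb <- tab$neighbors[[ci]]
        nb$to[!nb$synonymous]
      })))
      targets <- unique(tab$aa[nbrs])
      wts <- vapply(targets, function(t2)
        if (categorize(from[i], t2, bins, "hydropathy", props) >= 6) 5
        else 1, 0)
      to[i] <- sample(targets, 1, prob = wts)
    }
    ch <- data.frame(edge = 1L, child = 2L, column = seq_len(200),
                     from_aa = from, to_aa = to)
    # recon stand-in: expectation pool = the 'from' residues themselves
    rec <- list(states = matrix(from, nrow = 2, ncol = 200, byrow = TRUE),
                tree = list(edge = matrix(c(1L, 2L), 1)))
    r <- destabilizing_test(ch, rec, bins, "hydropathy", props)
    if (any(r$call == "positive_destabilizing")) calls <- calls + 1L
    r_vol <- destabilizing_test(ch, rec, bins, "isoelectric_point", props)
  }
  expect_gte(calls, 9L)
})

test_that("pairwise mode reduces exactly to the two-leaf tree analysis", {
  a <- "ACDEFGHIKL"
  b <- "ACDEFGHIKW"   # one difference, L->W
  r <- pairwise_mode(a, b, bins, "hydropathy", props)
  expect_equal(sum(r$observed), 1)
  cat_lw <- categorize("L", "W", bins, "hydropathy", props)
  expect_equal(r$observed[r$category == cat_lw], 1)
  # identical pair -> empty with note
  r0 <- pairwise_mode(a, a, bins, "hydropathy", props)
  expect_equal(nrow(r0), 0L)
  expect_match(attr(r0, "note"), "no differing")
  # reduction identity against the tree machinery
  al <- protein_alignment(c(i = a, j = b))
  tr <- ape::read.tree(text = "(i:1,j:1);")
  rec <- reconstruct_ancestral(tr, al)
  ch <- enumerate_changes(rec)
  tree_r <- destabilizing_test(ch, rec, bins, "hydropathy", props)
  expect_equal(r$observed, tree_r$observed)
  expect_equal(r$z, tree_r$z)
})

test_that("calls are invariant to affine transforms of the property", {
  set.seed(12)
  seqs <- setNames(vapply(1:4, function(i) random_protein(100, 600 + i), ""),
                   paste0("s", 1:4))
  tr <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1);")
  al <- protein_alignment(seqs)
  rec <- reconstruct_ancestral(tr, al)
  ch <- enumerate_changes(rec)
  p2 <- props
  p2$hydropathy <- 3 * p2$hydropathy + 7
  b2 <- magnitude_bins(p2)
  r1 <- destabilizing_test(ch, rec, bins, "hydropathy", props)
  r2 <- destabilizing_test(ch, rec, b2, "hydropathy", p2)
  expect_equal(r1$observed, r2$observed)
  expect_equal(r1$z, r2$z)
})
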