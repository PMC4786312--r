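make_planted_genome <- function(seed = 5, identity_mut = 0L) {
  tpl <- taarevol:::receptor_template(seed)
  cds <- taarevol:::backtranslate_protein(tpl$protein, seed + 1L)
  mutate <- function(cds, n, s) {
    set.seed(s)
    cod <- taarevol:::codon_split(cds)
    idx <- sample(length(cod), n)
    cod[idx] <- sample(sense_codons(), n, replace = TRUE)
    paste0(cod, collapse = "")
  }
  paralogs <- c(cds, mutate(cds, identity_mut, 91), mutate(cds, identity_mut, 92))
  genes <- data.frame(id = paste0("g", 1:3), sequence = paralogs,
                      strand = c("+", "-", "+"))
  emb <- embed_in_genome(genes, spacer_law = list(dist = "fixed",
                                                  length = 3000), seed = 6)
  list(template = tpl$protein, emb = emb)
}

test_that("an exact planted copy is recovered with identity 1", {
  pg <- make_planted_genome()
  hits <- translated_search(pg$emb$scaffold, pg$template)
  top <- hits[1, ]
  expect_equal(top$start, pg$emb$truth$start[1])
  expect_equal(top$end, pg$emb$truth$end[1])
  expect_equal(top$identity_fraction, 1.0)
  expect_lt(top$evalue, 1e-100)
})

test_that("E-value formula is linear in database length and decreasing in score", {
  p1 <- search_params(effective_db_length = 1.1e10)
  p2 <- search_params(effective_db_length = 2.2e10)
  e1 <- karlin_evalue(500, 300, p1)
  expect_equal(karlin_evalue(500, 300, p2), 2 * e1)
  expect_lt(karlin_evalue(501, 300, p1), e1)
})

test_that("random scaffolds produce no hits at the 1e-30 threshold", {
  q <- random_protein(300, 31)
  for (s in 1:20) {
    set.seed(s)
    scaf <- setNames(taarevol:::random_nt(20000), "r")
    hits <- translated_search(scaf, q)
    expect_true(nrow(hits[hits$evalue <= 1e-30, ]) == 0L)
  }
})

test_that("strand symmetry: reverse-complementing the genome mirrors hits", {
  pg <- make_planted_genome()
  scaf <- pg$emb$scaffold
  L <- nchar(scaf[[1]])
  h1 <- translated_search(scaf, pg$template)
  h2 <- translated_search(setNames(revcomp(scaf[[1]]), names(scaf)),
                          pg$template)
  h1 <- h1[order(h1$start), ]
  h2 <- h2[order(-h2$end), ]
  expect_equal(h1$raw_score, h2$raw_score)
  expect_equal(h1$start, L - h2$end)
  expect_equal(h1$end, L - h2$start)
  expect_true(all(h1$strand != h2$strand))
})

test_that("local alignment kernel agrees with the quadratic reference DP", {
  set.seed(77)
  for (i in 1:15) {
    a <- random_protein(sample(10:30, 1), 200 + i)
    b <- random_protein(sample(10:30, 1), 300 + i)
    r <- taarevol:::local_align(a, b)
    expect_equal(r$score, ref_local_score(a, b))
  }
})

test_that("recursive mining recovers planted paralogs and converges", {
  pg <- make_planted_genome(identity_mut = 80)  # ~70% aa identity paralogs
  refdb <- data.frame(
    id = c("fam", "decoy"),
    sequence = c(pg$template, random_protein(276, 13)),
    family = c("A", "other"), in_family = c(TRUE, FALSE))
  loci <- recursive_mine(pg$emb$scaffold, c(seed1 = pg$template), refdb)
  expect_equal(nrow(loci), 3L)
  sc <- score_mining(loci, pg$emb$truth)
  expect_equal(sc$sensitivity, 1.0)
  expect_equal(sc$ppv, 1.0)
  # fixed point: re-running from the recovered proteins adds nothing
  qs <- setNames(gsub("[*]", "X", loci$protein), paste0("q", 1:3))
  loci2 <- recursive_mine(pg$emb$scaffold, qs, refdb)
  expect_equal(nrow(loci2), 3L)
})

test_that("out-family decoys are excluded by reciprocal verification", {
  # plant a decoy gene whose best reciprocal hit is out-family
  decoy_prot <- random_protein(276, 55)
  decoy_cds <- taarevol:::backtranslate_protein(decoy_prot, 56)
  tpl <- taarevol:::receptor_template(5)
  cds <- taarevol:::backtranslate_protein(tpl$protein, 6)
  emb <- embed_in_genome(
    data.frame(id = c("true", "decoy"), sequence = c(cds, decoy_cds),
               strand = "+"),
    spacer_law = list(dist = "fixed", length = 3000), seed = 7)
  refdb <- data.frame(
    id = c("fam", "out"),
    sequence = c(tpl$protein, decoy_prot),
    family = c("A", "other"), in_family = c(TRUE, FALSE))
  loci <- recursive_mine(emb$scaffold,
                         c(s1 = tpl$protein, s2 = decoy_prot), refdb)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start[1], emb$truth$start[1])
})

test_that("reciprocal ties break deterministically by lexicographic id", {
  cand <- random_protein(100, 3)
  refdb <- data.frame(id = c("zeta", "alpha"),
                      sequence = c(cand, cand),
                      family = c("A", "B"), in_family = c(TRUE, FALSE))
  rv <- reciprocal_verify(cand, refdb)
  expect_equal(rv$best_hit, "alpha")
  expect_false(rv$verified)
  expect_error(reciprocal_verify(cand, refdb[0, ]), "empty reference")
})

test_that("profile search ranks training sequences above shuffles", {
  set.seed(9)
  base <- random_protein(60, 21)
  vars <- vapply(1:4, function(i) {
    ch <- taarevol:::split1(base)
    idx <- sample(60, 6)
    ch[idx] <- sample(taarevol:::AA_ALPHABET1, 6, replace = TRUE)
    paste0(ch, collapse = "")
  }, "")
  aln <- protein_alignment(setNames(vars, paste0("s", 1:4)))
  prof <- sequence_profile(aln)
  intact_score <- profile_search(prof, c(x = vars[1]), threshold = -Inf)
  expect_equal(intact_score$id, "x")
  for (i in 1:20) {
    set.seed(1000 + i)
    shuf <- paste0(sample(taarevol:::split1(vars[1])), collapse = "")
    ss <- profile_search(prof, c(sh = shuf), threshold = -Inf)
    expect_lt(ss$bits_per_column[1], intact_score$bits_per_column[1])
  }
  expect_equal(nrow(profile_search(prof, character(0))), 0L)
})
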