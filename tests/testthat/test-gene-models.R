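fixture_gene <- function(seed = 11) {
  tpl <- taarevol:::receptor_template(seed)
  cds <- taarevol:::backtranslate_protein(tpl$protein, seed + 1L)
  list(tpl = tpl, cds = cds)
}

embed1 <- function(sequences, strands = "+", n_run = FALSE,
                   truncate = FALSE, seed = 3) {
  n <- length(sequences)
  embed_in_genome(data.frame(id = paste0("g", seq_len(n)),
                             sequence = sequences,
                             strand = rep_len(strands, n),
                             n_run = rep_len(n_run, n),
                             truncate = rep_len(truncate, n)),
                  spacer_law = list(dist = "fixed", length = 2000),
                  seed = seed)
}

locus_of <- function(emb, i) {
  list(scaffold = emb$truth$scaffold[i], start = emb$truth$start[i],
       end = emb$truth$end[i], strand = emb$truth$strand[i])
}

test_that("clean simulated genes classify intact with no defects", {
  fx <- fixture_gene()
  emb <- embed1(fx$cds)
  gc <- classify_gene(locus_of(emb, 1), emb$scaffold[[1]], fx$tpl$protein)
  expect_equal(gc$status, "intact")
  expect_length(gc$defects, 0)
  expect_equal(translate_nt(gc$orf_cds), gc$protein)
})

test_that("planted lesions give pseudogene with the right defect", {
  fx <- fixture_gene()
  ps <- pseudogenize(fx$cds, "premature_stop", 100, seed = 2)
  fs <- pseudogenize(fx$cds, "frameshift", 120, seed = 3)
  emb <- embed1(c(ps$sequence, fs$sequence), strands = c("-", "+"))
  g1 <- classify_gene(locus_of(emb, 1), emb$scaffold[[1]], fx$tpl$protein)
  expect_equal(g1$status, "pseudogene")
  types1 <- vapply(g1$defects, `[[`, "", "type")
  expect_true("premature_stop" %in% types1)
  stop_codon <- g1$defects[[which(types1 == "premature_stop")[1]]]$codon
  expect_lt(abs(stop_codon - 100), 4)
  g2 <- classify_gene(locus_of(emb, 2), emb$scaffold[[1]], fx$tpl$protein)
  expect_equal(g2$status, "pseudogene")
  expect_true("frameshift" %in% vapply(g2$defects, `[[`, "", "type"))
})

test_that("ambiguity outranks completeness but not unambiguous lesions", {
  fx <- fixture_gene()
  emb <- embed1(fx$cds, n_run = TRUE)
  g <- classify_gene(locus_of(emb, 1), emb$scaffold[[1]], fx$tpl$protein)
  expect_equal(g$status, "incomplete")
  expect_true("n_run" %in% vapply(g$defects, `[[`, "", "type"))
  # N-run plus a clean premature stop upstream of it -> pseudogene
  ps <- pseudogenize(fx$cds, "premature_stop", 40, seed = 5)
  emb2 <- embed1(ps$sequence, n_run = TRUE)
  g2 <- classify_gene(locus_of(emb2, 1), emb2$scaffold[[1]],
                      fx$tpl$protein)
  expect_equal(g2$status, "pseudogene")
})

test_that("contig truncation classifies incomplete with contig_end", {
  fx <- fixture_gene()
  emb <- embed1(c(fx$cds, fx$cds), truncate = c(FALSE, TRUE))
  expect_equal(nrow(emb$truth), 2L)
  g <- classify_gene(locus_of(emb, 2), emb$scaffold[[1]], fx$tpl$protein)
  expect_equal(g$status, "incomplete")
  expect_true("contig_end" %in% vapply(g$defects, `[[`, "", "type"))
})

test_that("classification is strand-invariant", {
  fx <- fixture_gene()
  ps <- pseudogenize(fx$cds, "premature_stop", 90, seed = 8)
  emb <- embed1(ps$sequence, strands = "+")
  scaf <- emb$scaffold[[1]]
  L <- nchar(scaf)
  loc <- locus_of(emb, 1)
  g1 <- classify_gene(loc, scaf, fx$tpl$protein)
  flipped <- list(scaffold = loc$scaffold, start = L - loc$end,
                  end = L - loc$start,
                  strand = if (loc$strand == "+") "-" else "+")
  g2 <- classify_gene(flipped, revcomp(scaf), fx$tpl$protein)
  expect_equal(g1$status, g2$status)
  expect_equal(vapply(g1$defects, `[[`, "", "type"),
               vapply(g2$defects, `[[`, "", "type"))
})

test_that("two-exon references yield exon2-only incomplete calls", {
  fx <- fixture_gene()
  emb <- embed1(fx$cds)
  g <- classify_gene(locus_of(emb, 1), emb$scaffold[[1]], fx$tpl$protein,
                     reference_two_exon = TRUE)
  expect_equal(g$status, "incomplete")
  expect_true("exon2_only" %in% vapply(g$defects, `[[`, "", "type"))
})

test_that("frameshift detector localizes 1-nt deletions, ignores in-frame indels", {
  fx <- fixture_gene()
  # 1-nt deletion at codon 50
  nt <- (50 - 1) * 3 + 1
  del1 <- paste0(substr(fx$cds, 1, nt - 1), substring(fx$cds, nt + 1))
  fs <- detect_frameshift(del1, fx$tpl$protein)
  expect_equal(nrow(fs), 1L)
  expect_lt(abs(fs$ref_codon[1] - 50), 3)
  # 3-nt (in-frame) deletion
  del3 <- paste0(substr(fx$cds, 1, nt - 1), substring(fx$cds, nt + 3))
  expect_equal(nrow(detect_frameshift(del3, fx$tpl$protein)), 0L)
  expect_equal(nrow(detect_frameshift(fx$cds, fx$tpl$protein)), 0L)
  # unalignable input flagged low-confidence
  junk <- strrep("GCGC", 200)
  res <- detect_frameshift(junk, fx$tpl$protein)
  expect_equal(nrow(res), 0L)
  expect_true(attr(res, "low_confidence"))
})

test_that("classifier confusion matrix is diagonal on simulator output", {
  # >= 200 genes across independent simulations with planted truth
  set.seed(123)
  n_ok <- 0; total <- 0
  confm <- matrix(0L, 3, 3,
                  dimnames = list(truth = c("intact", "pseudogene",
                                            "incomplete"),
                                  called = c("intact", "pseudogene",
                                             "incomplete")))
  for (rep in 1:9) {
    fx <- fixture_gene(rep + 40)
    truth <- sample(c("intact", "pseudogene", "incomplete"), 24,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
    seqs <- character(24); nrun <- logical(24)
    for (i in 1:24) {
      s <- fx$cds
      if (truth[i] == "pseudogene") {
        mode <- sample(c("premature_stop", "frameshift"), 1)
        s <- pseudogenize(s, mode, sample(80:180, 1),
                          seed = rep * 100 + i)$sequence
      }
      nrun[i] <- truth[i] == "incomplete"
      seqs[i] <- s
    }
    emb <- embed1(seqs, strands = sample(c("+", "-"), 24, replace = TRUE),
                  n_run = nrun, seed = rep)
    for (i in 1:24) {
      g <- classify_gene(locus_of(emb, i), emb$scaffold[[1]],
                         fx$tpl$protein)
      confm[truth[i], g$status] <- confm[truth[i], g$status] + 1L
      total <- total + 1
    }
  }
  expect_gte(total, 200)
  expect_equal(sum(confm) - sum(diag(confm)), 0)
})
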