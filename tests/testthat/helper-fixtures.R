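# Shared fixtures, all generated in code under fixed seeds.

balanced8_tree <- function(len = 0.25) {
  nwk <- paste0("(((t1:L,t2:L):L,(t3:L,t4:L):L):L,",
                "((t5:L,t6:L):L,(t7:L,t8:L):L):L);")
  ape::read.tree(text = gsub("L", format(len), nwk))
}

random_codon_seqs <- function(n_taxa, n_codons, seed) {
  set.seed(seed)
  codons <- sense_codons()
  setNames(vapply(seq_len(n_taxa), function(i)
    paste0(sample(codons, n_codons, replace = TRUE), collapse = ""), ""),
    paste0("t", seq_len(n_taxa)))
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste0(sample(taarevol:::AA_ALPHABET1, n, replace = TRUE), collapse = "")
}

# Reference affine-gap local alignment score by an independent quadratic DP
# (scores only; O(n*m) with explicit 3-state recursion).
ref_local_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  m <- taarevol:::blosum62_encoded()
  ai <- taarevol:::encode_aa(a) + 1L
  bi <- taarevol:::encode_aa(b) + 1L
  n1 <- length(ai); n2 <- length(bi)
  H <- matrix(0, n1 + 1, n2 + 1)
  E <- matrix(-Inf, n1 + 1, n2 + 1)
  F <- matrix(-Inf, n1 + 1, n2 + 1)
  best <- 0
  for (i in 2:(n1 + 1)) for (j in 2:(n2 + 1)) {
    E[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                   E[i - 1, j] - gap_extend)
    F[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                   F[i, j - 1] - gap_extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + m[ai[i - 1], bi[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Simulate + fit wrapper used in several recovery tests.
sim_and_fit_m0 <- function(tree, omega, kappa, n_codons, seed) {
  sim <- simulate_codon_alignment(
    tree, codon_model_spec("M0", omega = omega, kappa = kappa), n_codons,
    seed = seed)
  freqs <- f3x4_frequencies(sim$alignment)
  fit_model(sim$alignment, tree,
            codon_model_spec("M0", omega = 0.5, kappa = 2, freqs = freqs))
}
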