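# Goldman-Yang codon substitution models over the 61 sense codons: model
# specifications (site models M0/M1a/M2a/M7/M8, branch models R1/R2, and the
# branch-site model A with its omega2 = 1 null), F3X4 equilibrium
# frequencies, reversible rate matrices, and their eigendecompositions.

#' Codon alignment container
#'
#' @param seqs Named character vector of equal-length, in-frame, gap-aligned
#'   coding sequences (alignment length a multiple of 3). Codons containing
#'   `-`, `N` or other ambiguity characters are treated as missing data.
#' @param allow_stops If FALSE (default), an in-frame stop codon raises an
#'   error naming the sequence and codon site; if TRUE, stops become missing.
#' @return A `codon_alignment`: ids, integer state matrix (ntaxa x nsites,
#'   values 1..61 or NA) and the codon character matrix.
#' @export
codon_alignment <- function(seqs, allow_stops = FALSE) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences differ in length")
  if (L %% 3L != 0L) stop("alignment length is not a multiple of 3")
  tab <- .codon_tables()
  chars <- t(vapply(seqs, codon_split, character(L / 3L)))
  states <- matrix(tab$index[chars], nrow = length(seqs))
  is_stop <- matrix(chars %in% tab$stops, nrow = length(seqs))
  if (any(is_stop)) {
    if (!allow_stops) {
      w <- which(is_stop, arr.ind = TRUE)[1L, ]
      stop("in-frame stop codon in sequence '", names(seqs)[w[1L]],
           "' at codon site ", w[2L])
    }
    states[is_stop] <- NA_integer_
  }
  rownames(states) <- names(seqs)
  structure(list(ids = names(seqs), states = states, chars = chars,
                 n_sites = ncol(states)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$ids), "sequences x", x$n_sites, "codons\n")
  invisible(x)
}

#' F3X4 codon equilibrium frequencies
#'
#' Nucleotide frequencies are tallied separately at the three codon
#' positions; each sense codon's frequency is the product over its
#' positions, stops are removed and the vector renormalized. Frequencies of
#' exactly zero are smoothed by adding 1e-6 before renormalization.
#'
#' @param alignment A [codon_alignment()] (or named character vector of
#'   in-frame CDS, which will be converted).
#' @return Numeric 61-vector over [sense_codons()], summing to 1.
#' @export
f3x4_frequencies <- function(alignment) {
  if (!inherits(alignment, "codon_alignment"))
    alignment <- codon_alignment(alignment)
  tab <- .codon_tables()
  chars <- alignment$chars
  pos_freq <- matrix(0, nrow = 3L, ncol = 4L, dimnames = list(NULL, NUCS))
  for (p in 1L:3L) {
    nt <- substr(chars, p, p)
    nt <- nt[nt %in% NUCS]
    if (!length(nt)) stop("no unambiguous nucleotides at codon position ", p)
    cnt <- table(factor(nt, levels = NUCS))
    pos_freq[p, ] <- as.numeric(cnt) / sum(cnt)
  }
  pi61 <- pos_freq[1L, tab$split[, 1L]] *
    pos_freq[2L, tab$split[, 2L]] *
    pos_freq[3L, tab$split[, 3L]]
  pi61[pi61 == 0] <- pi61[pi61 == 0] + 1e-6
  pi61 <- pi61 / sum(pi61)
  names(pi61) <- tab$codons
  pi61
}

#' Codon model specification
#'
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`,
#'   `"branch_R1"`, `"branch_R2"`, `"branchsite_A"`, `"branchsite_A_null"`.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param freqs Codon equilibrium 61-vector (default uniform 1/61).
#' @param omega,omega0,omega2 dN/dS parameters as used by the model; the
#'   neutral class omega1 = 1 is fixed where applicable, and the
#'   branch-site null fixes omega2 = 1.
#' @param p0,p1 Site-class proportions (model-dependent meaning; for the
#'   branch-site models these are the purifying and neutral proportions and
#'   class 2 is split in the ratio p0:p1, the codeml convention).
#' @param p,q Beta-distribution parameters for M7/M8.
#' @param omega_s Positive-selection omega of M8 (constrained to (1, 50]).
#' @param ncat_beta Number of equal-probability beta discretization
#'   categories, placed at category medians (default 10).
#' @param foreground Integer or logical index of foreground edges (rows of
#'   `tree$edge`) for branch and branch-site models; see
#'   [mark_foreground()].
#' @return A `codon_model_spec`.
#' @export
codon_model_spec <- function(model, kappa = 2, freqs = NULL,
                             omega = NULL, omega0 = NULL, omega2 = NULL,
                             p0 = NULL, p1 = NULL, p = NULL, q = NULL,
                             omega_s = NULL, ncat_beta = 10L,
                             foreground = NULL) {
  model <- match.arg(model, c("M0", "M1a", "M2a", "M7", "M8", "branch_R1",
                              "branch_R2", "branchsite_A",
                              "branchsite_A_null"))
  if (is.null(freqs)) freqs <- rep(1 / 61, 61)
  if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
  if (kappa <= 0) stop("kappa must be > 0")
  defaults <- list(omega = 0.5, omega0 = 0.2, omega2 = 2, p0 = 0.5, p1 = 0.3,
                   p = 1, q = 2, omega_s = 2)
  sp <- list(model = model, kappa = kappa, freqs = freqs,
             omega = omega %||% defaults$omega,
             omega0 = omega0 %||% defaults$omega0,
             omega2 = if (model == "branchsite_A_null") 1
                      else omega2 %||% defaults$omega2,
             p0 = p0 %||% defaults$p0, p1 = p1 %||% defaults$p1,
             p = p %||% defaults$p, q = q %||% defaults$q,
             omega_s = omega_s %||% defaults$omega_s,
             ncat_beta = as.integer(ncat_beta), foreground = foreground)
  if (model == "M1a" && !(sp$omega0 > 0 && sp$omega0 < 1))
    stop("M1a requires 0 < omega0 < 1")
  if (model == "M2a" && sp$omega2 < 1) stop("M2a requires omega2 >= 1")
  if (model == "M8" && !(sp$omega_s > 1 && sp$omega_s <= 50))
    stop("M8 requires omega_s in (1, 50]")
  structure(sp, class = "codon_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of free parameters of a codon model
#'
#' Counts the free model parameters (kappa plus omega/proportion/beta
#' parameters; branch lengths and frequencies excluded). Used to derive LRT
#' degrees of freedom by free-parameter counting.
#'
#' @param spec A [codon_model_spec()] or model id string.
#' @return Integer count.
#' @export
n_free_params <- function(spec) {
  model <- if (inherits(spec, "codon_model_spec")) spec$model else spec
  switch(model,
         M0 = 2L,                 # kappa, omega
         M1a = 3L,                # kappa, p0, omega0
         M2a = 5L,                # kappa, p0, p1, omega0, omega2
         M7 = 3L,                 # kappa, p, q
         M8 = 5L,                 # kappa, p0, p, q, omega_s
         branch_R1 = 2L,          # kappa, omega
         branch_R2 = 3L,          # kappa, omega_back, omega_fore
         branchsite_A = 5L,       # kappa, p0, p1, omega0, omega2
         branchsite_A_null = 4L,  # as above with omega2 fixed at 1
         stop("unknown model: ", model))
}

# Median-of-category discretization of a Beta(p, q) into K equal-probability
# classes (the M7/M8 convention).
beta_category_omegas <- function(p, q, K) {
  # extreme shapes explored by the optimizer make qbeta complain about
  # attainable accuracy; quantile error there does not affect the optimum
  suppressWarnings(qbeta((2 * seq_len(K) - 1) / (2 * K), p, q))
}

# Class structure of a model instance: omega values, class proportions, and
# a nclass x nedge map from class/edge to omega index. `fg` is a logical
# vector over tree edges (all FALSE for site models).
class_structure <- function(spec, fg) {
  ne <- length(fg)
  one_row <- function(i) matrix(i, nrow = 1L, ncol = ne)
  with(spec, switch(spec$model,
    M0 = list(omegas = omega, props = 1, map = one_row(1L)),
    branch_R1 = list(omegas = omega, props = 1, map = one_row(1L)),
    branch_R2 = list(omegas = c(omega, omega2),
                     props = 1,
                     map = matrix(ifelse(fg, 2L, 1L), nrow = 1L)),
    M1a = list(omegas = c(omega0, 1), props = c(p0, 1 - p0),
               map = rbind(one_row(1L), one_row(2L))),
    M2a = list(omegas = c(omega0, 1, omega2),
               props = c(p0, p1, 1 - p0 - p1),
               map = rbind(one_row(1L), one_row(2L), one_row(3L))),
    M7 = {
      w <- beta_category_omegas(p, q, ncat_beta)
      list(omegas = w, props = rep(1 / ncat_beta, ncat_beta),
           map = matrix(seq_len(ncat_beta), ncol = ne,
                        nrow = ncat_beta))
    },
    M8 = {
      w <- c(beta_category_omegas(p, q, ncat_beta), omega_s)
      list(omegas = w,
           props = c(rep(p0 / ncat_beta, ncat_beta), 1 - p0),
           map = matrix(seq_len(ncat_beta + 1L), ncol = ne,
                        nrow = ncat_beta + 1L))
    },
    branchsite_A = ,
    branchsite_A_null = {
      # classes 0, 1, 2a, 2b; omega indices: 1 = omega0, 2 = 1, 3 = omega2
      p2 <- 1 - p0 - p1
      b <- p0 / (p0 + p1)
      map <- rbind(one_row(1L), one_row(2L),
                   matrix(ifelse(fg, 3L, 1L), nrow = 1L),
                   matrix(ifelse(fg, 3L, 2L), nrow = 1L))
      list(omegas = c(omega0, 1, omega2),
           props = c(p0, p1, p2 * b, p2 * (1 - b)),
           map = map)
    }))
}

#' Goldman-Yang instantaneous rate matrix
#'
#' Single-nucleotide codon changes get rate pi_j, multiplied by kappa for
#' transitions and by omega for nonsynonymous changes; multi-nucleotide
#' changes are 0; the diagonal makes rows sum to 0. Unless `scale = FALSE`
#' the generator is divided by its expected rate so branch lengths are in
#' expected substitutions per codon.
#'
#' @param omega dN/dS for this site class.
#' @param kappa Transition/transversion rate ratio.
#' @param freqs Equilibrium 61-vector.
#' @param scale Scale to one expected substitution per unit time.
#' @return 61 x 61 generator matrix (detailed balance holds exactly).
#' @export
build_rate_matrix <- function(omega, kappa, freqs, scale = TRUE) {
  tab <- .codon_tables()
  Q <- matrix(0, 61L, 61L, dimnames = list(tab$codons, tab$codons))
  r <- freqs[tab$edge_j]
  r[tab$edge_ts] <- r[tab$edge_ts] * kappa
  r[!tab$edge_syn] <- r[!tab$edge_syn] * omega
  Q[cbind(tab$edge_i, tab$edge_j)] <- r
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rho <- -sum(freqs * diag(Q))
    Q <- Q / rho
  }
  Q
}

# Expected rate (substitutions per codon per unit time) of an unscaled GY
# generator under freqs.
rate_of <- function(omega, kappa, freqs) {
  Q <- build_rate_matrix(omega, kappa, freqs, scale = FALSE)
  -sum(freqs * diag(Q))
}

# Eigendecomposition of a reversible generator for fast P(t).
# Returns U2, lambda, U1 with P(t) = U2 %*% (exp(lambda t) * U1).
eigen_generator <- function(Q, freqs) {
  s <- sqrt(freqs)
  S <- Q * (s %o% (1 / s))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U2m = e$vectors * (1 / s),  # D^-1/2 U (column recycling over rows)
       lambda = e$values,
       U1 = t(e$vectors) * rep(s, each = 61L))
}

prob_matrix <- function(ed, t) {
  P <- ed$U2m %*% (exp(ed$lambda * t) * ed$U1)
  P[P < 0] <- 0
  P
}

# All distinct scaled generators + eigendecompositions for a model instance.
# Scaling uses the mixture-average rate over classes (background omegas for
# branch-site models), the codeml convention, so branch lengths are expected
# substitutions per codon.
model_generators <- function(spec, fg) {
  cs <- class_structure(spec, fg)
  Qs <- lapply(cs$omegas, build_rate_matrix, kappa = spec$kappa,
               freqs = spec$freqs, scale = FALSE)
  rates <- vapply(Qs, function(Q) -sum(spec$freqs * diag(Q)), 0)
  # average rate over classes on background branches
  bg_idx <- cs$map[, if (any(!fg)) which(!fg)[1L] else 1L]
  rho <- sum(cs$props * rates[bg_idx])
  eds <- lapply(Qs, function(Q) eigen_generator(Q / rho, spec$freqs))
  list(cs = cs, eds = eds, rho = rho)
}
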