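---
title: "Models and methods behind taarevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind taarevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`taarevol` reconstructs, as one tested pipeline, the comparative-genomics
workflow used to study chemosensory receptor gene families such as the
trace amine-associated receptors (TAARs): mining receptor loci out of
genome scaffolds by translated homology search, classifying each locus as
an intact gene, an incomplete model or a pseudogene, building protein
phylogenies, fitting Goldman–Yang codon models to test for selection, and
testing amino-acid physicochemical properties for destabilizing selection.
Because the real inputs of such studies are whole-genome assemblies, the
package carries its own simulator: every stage can be exercised against
synthetic gene families with known truth, and the test suite does exactly
that.

# The simulator

**Gene birth–death.** Gene lineages evolve along a fixed species tree.
On each branch a lineage draws exponential waiting times with rates for
duplication (the lineage splits), loss (it ends) and pseudogenization (it
is marked disabled but keeps evolving). At speciation every surviving
lineage enters both daughter branches. With all rates zero the gene tree
is exactly the species tree; with duplication rate $\lambda$ and no loss
the expected copy number per species is $e^{\lambda T}$ for root-to-tip
length $T$, which the test suite checks against 2000 replicates.

**Codon evolution.** Sequences evolve over the 61 sense codons of the
standard nuclear code (stop codons excluded from the state space, the
GY94/PAML convention). Site classes are drawn from the model's class
proportions and evolved under the corresponding generators; branch-site
classes switch generators between foreground and background branches. The
root sequence is drawn from the equilibrium frequencies or supplied (the
packaged scenario supplies a receptor-like template, see below). There is
no indel evolution: simulated alignments are gap-free by design, so
alignment uncertainty is out of scope for what the recovery tests show.

**Pseudogenes and assembly artifacts.** Disabled genes receive either a
premature stop codon or a 1–2 nt frameshift at a chosen codon. Assembly
artifacts are modelled at embedding time: an N-run (default 100 nt,
comfortably above the classifier's 10-nt ambiguity threshold) replacing
part of a gene, or truncation of the scaffold inside a gene so the locus
abuts the contig end. Genes are laid down with spacers drawn from a
configurable law (default lognormal with median 10 kb, the scale of
intergenic spacing seen in real receptor clusters; the packaged scenario
uses fixed 2-kb spacers so that the synteny stage has an exact target)
and mixed orientations via reverse complementation. Truth coordinates are
kept 0-based half-open internally and converted to 1-based inclusive on
GFF3 export, so round trips are exact.

**The receptor template.** Classification requires that intact genes look
like seven-transmembrane receptors to the hydropathy predictor, so the
scenario's root sequences are built as alternating hydrophobic 21-mers
(I/L/V/F/M) and hydrophilic loops (16 residues), with the strict signature
motif written at the TM7/C-terminus boundary — the natural position of an
NPxxY-like motif. The motif's fixed residues (N, S, P, ...) are
hydrophilic; anchoring it mid-helix carves a dip into TM7's hydropathy
profile that substitutions can deepen until the helix splits or drops
below the calling threshold, so TM7 keeps a clean 21-residue core and
carries the motif in a 6-residue boundary extension. Templates are 273
residues; subfamily templates are drawn
independently, giving within-subfamily identities near 1 and
between-subfamily identities far below, the regime in which reference-based
subfamily assignment is expected to be exact.

# Mining

Scaffolds are translated in all six frames (ambiguous codons become `X`,
translation runs to the frame boundary) and aligned to protein queries
with an affine-gap Smith–Waterman kernel under BLOSUM62 (gap open 11,
extend 1). Within a frame, hits are peeled off iteratively: best hit
first, matched region masked, repeat until the attainable E-value exceeds
the threshold. E-values follow the Karlin–Altschul form
$E = K\,m\,n_\mathrm{eff}\,e^{-\lambda S}$ with the published ungapped
BLOSUM62 constants ($\lambda = 0.3176$, $K = 0.134$) and a fixed effective
database length (default $1.1 \times 10^{10}$), which makes E-values
comparable across genomes of different sizes. The default reporting
threshold is $10^{-30}$.

Hits become candidate loci by two rules: same-strand hits overlapping at
least 50% of the shorter hit merge (union of spans), and same-strand hits
separated by at most 1 kb chain into one locus. The chaining rule is this
package's convention: a premature stop or frameshift splits a pseudogene
into two local alignments in different frames, and without chaining each
fragment would be counted as a separate locus, inflating the census. A
locus whose chained hits span multiple frames is annotated as frameshift
evidence. Mining is recursive: translations of newly accepted loci are
used as fresh queries until no new locus appears (the candidate set is
monotone, and a 20-round cap guards the loop). Every candidate must pass
reciprocal verification — its best-scoring reference must be in-family,
with ties broken by identity then lexicographic id. A log-odds profile
scanner (gap-majority columns removed, uniform background, bits-per-column
scores) covers the divergent-subfamily search that profile HMMs perform in
larger toolchains.

# Gene models

Classification follows a fixed decision order. (1) *Ambiguity*: an N-run
of ≥ 10 nt inside the locus, or a locus within 50 nt of a contig end,
makes the model incomplete — unless (2) an *unambiguous lesion* is found:
a premature stop in the best reading frame's alignment to the reference,
or a frameshift, detected by chaining the three frame translations along
the reference and flagging junction offsets that are not multiples of 3;
either lesion makes the locus a pseudogene. (3) Otherwise the model is
intact iff the alignment covers at least 90% of the reference and the
hydropathy predictor reports exactly 7 TM segments; shortfalls are
incomplete with TM-deficit evidence. The ambiguity-before-lesion order
exists because lesion calls adjacent to long N-runs are unreliable; a
clean lesion far from the ambiguity still wins. Candidates matching a
reference flagged as a two-exon gene are classified incomplete with an
exon2-only note rather than spliced-modelled.

The TM predictor is a sliding-window hydropathy caller: Kyte–Doolittle
scale, window 19, threshold 1.6, minimum inter-segment gap 5, maximal
above-threshold runs as segments. Loops alternate sides from an
extracellular N-terminus, and Ballesteros–Weinstein numbers are assigned
from a reference annotation: a residue aligned into reference TM $t$ whose
index-50 residue is $r_{50}$ gets $t.(50 + \mathrm{pos} - r_{50})$.

The signature-motif grammar language covers fixed residues, alternative
sets and fixed-length wildcards; the strict tetrapod motif
`NSX2NPX2[YH]X3YXWF` and the two weakened variants are packaged. The
scanner is tested for exact equivalence against a regular expression
derived mechanically from each grammar.

# Phylogenetics

Protein distances are maximum-likelihood under the JTT matrix (published
exchangeabilities embedded in the package) with discrete-Gamma rate
variation: shape $\alpha = 1.3004$ by default, 4 equal-probability
categories at category means. The 1-D likelihood is maximized to
tolerance $10^{-8}$, capped at 10 substitutions/site with a saturation
flag; pairs with no shared ungapped column are flagged undefined rather
than silently 0. Trees are built by neighbor joining with the standard
Q criterion, smallest-index tie-breaking, and negative branch lengths
clamped to zero with the deficit moved to the sister branch.
Nonparametric bootstrap supports resample columns; replicate distances
are maximized over a dense log-spaced grid (240 points), which agrees
with the exact optimizer to well below resampling noise and makes
1000-replicate runs practical. Subfamily assignment takes the smallest
clade containing the candidate whose references are label-unanimous with
support ≥ 70% (the support level commonly used as a reporting cutoff for
tree figures, reused here as an assignment threshold), falling back to
best-hit identity, and returning "unclassified" below 40% identity.
In-package tree inference is deliberately NJ-only; ML or Bayesian trees
can be imported as Newick.

# Codon models

The engine implements GY94-family models over the 61 sense codons:
off-diagonal rates are $\pi_j$ times $\kappa$ for transitions and
$\omega$ for nonsynonymous changes, zero for multi-nucleotide changes;
generators satisfy detailed balance exactly and are scaled so branch
lengths are expected substitutions per codon under the class-mixture
average (background omegas for branch-site models). Equilibrium
frequencies use F3X4 — per-position nucleotide frequencies multiplied,
stops removed, renormalized, zeros smoothed by $10^{-6}$.

Implemented models: M0; M1a ($0<\omega_0<1$, $\omega_1=1$); M2a (adds
$\omega_2 \ge 1$); M7 (beta, 10 equal-probability categories at medians by
default); M8 (beta plus $\omega_s \in (1, 50]$); branch models R1/R2;
branch-site model A with its $\omega_2 = 1$ null (class proportions
parameterized as in codeml, class 2 split in the ratio $p_0 : p_1$).
Likelihoods use Felsenstein pruning over pattern-compressed sites with
periodic rescaling; gaps and ambiguous codons are missing data. Likewise
per the package's oracle tests, the pruning likelihood matches exhaustive
enumeration over internal-node states on small trees to $10^{-10}$.

Fitting is bounded L-BFGS-B on the natural scale ($\kappa$ free in every
model, start 2). Branch lengths are optimized jointly (log scale) under
M0 and then held fixed for the other models — a deliberate stabilization
of the many branch-site fits, switchable via `optimize_branches`. Site
models refit from three deterministic starts; the extra starts run at
coarse tolerance and the winner is polished. LRTs use
$2\Delta\ell$ against $\chi^2$ with degrees of freedom derived by
free-parameter counting (M1a/M2a and M7/M8: 2; R1/R2 and branch-site
test 2: 1); an alternative falling below its null by more than $10^{-4}$
raises an optimizer-failure error rather than reporting a negative
statistic. Site identification: NEB evaluates class posteriors at the
MLEs exactly; the BEB-grid method averages posteriors over a uniform
10-point-per-dimension grid on the positive-class proportion and omega —
a documented approximation to published Bayes empirical Bayes, and the
calibration experiments use NEB. A Nei–Gojobori (1986) counting
estimator with pathway averaging and Jukes–Cantor correction serves as a
likelihood-free cross-check of M0.

**Power-study design.** The branch-site detection-power experiment uses
an 8-taxon balanced tree with all branches at 0.3 substitutions/codon and
the whole left 4-taxon clade (7 edges) as the foreground lineage, with
$\omega_2 = 4$ on 20% of sites and alignments of 1000 codons; posteriors
are taken from the fit on the generating tree, which isolates the
site-detection step from branch-length estimation error (M0-estimated
branch lengths shrink foreground branches and mask the signal — a known
cost of the fixed-branch-length design that users can avoid with
`optimize_branches = TRUE`). A single short foreground edge gives PP>0.95
power near zero; detecting sites at that stringency requires the
positive-selection class to accumulate several substitutions, which is
why the foreground is a lineage rather than one branch.

# Amino-acid property selection

Ancestral residues are reconstructed by Fitch parsimony on a rooted
binary tree (unrooted input is rooted on the edge to its first tip;
multifurcations are resolved deterministically with zero-length edges —
both necessary for the realized change count to equal the parsimony
score). Ties resolve to the parent's state, then to the alphabetically
first member of the node's set. Each inferred replacement is binned by
$|\Delta\text{property}|$ into 8 equal-width categories spanning the full
range over all 190 unordered residue pairs — left-closed, right-open,
bin 8 right-closed, boundaries to the lower bin. The neutral expectation
pools, over every branch-column, the parent residue's single-nucleotide
nonsynonymous codon neighbours (uniform over changes); the z statistic is
$(o_c - np_c)/\sqrt{np_c(1-p_c)}$ and only categories 6–8 with $z$
strictly greater than 3.09 ($P < 0.001$) are called
positive-destabilizing. Four properties are packaged (hydropathy,
side-chain volume, polarity, isoelectric point); any TSV with 20 values
per property plugs in. The pairwise mode runs the identical machinery on
the two-leaf tree, so it reduces exactly to tree mode.

# The packaged scenario and experiment sizes

The default scenario has 5 species (tree depth 0.21 substitutions/codon),
three subfamilies: A — single-copy, M0 with $\omega = 0.10$ (a
primary-amine-receptor-like regime of strong constraint); B — duplication
rate 3, loss 0.5, pseudogenization 2 per unit branch length, M0 with
$\omega = 0.35$; C — duplication 1.2, M2a with 15% of sites at
$\omega_2 = 4$ (the tertiary-amine-receptor-like regime). Spacers are
fixed at 2000 nt, orientations minus with probability 0.3, and the
scenario's M7/M8 fits use 5 beta categories (the package default is 10) to
keep the multi-seed recovery experiments fast. Experiment sizes used by
the validation suite — chosen once as a balance between statistical
resolution and runtime, and stated here so they are reproducible: M0
recovery 8 taxa × 500 codons × 20 seeds; branch-site power 10 seeds of
1000 codons; M1a/M2a calibration 100 nulls of 5 taxa × 120 codons fit on
the generating tree; property-test calibration 50 neutral replicates of
6 taxa × 200 codons; end-to-end recovery 10 scenario seeds.

# Determinism and numerics

All randomness flows through R's session RNG (Mersenne-Twister), seeded
once per operation; identical seeds give byte-identical outputs, and the
scenario derives per-stage seeds from one master seed. Reversible
generators are exponentiated via symmetric eigendecomposition; negative
round-off entries are clamped at zero. Optimizer defaults: L-BFGS-B
`factr` $10^9$ (heavy multi-fit experiments use $10^{10}$), bounds
$\kappa \in [0.05, 100]$, $\omega \in [10^{-4}, 20]$, beta shapes
$[0.005, 99]$, branch lengths $[10^{-7}, 30]$ on the log scale.

# Limitations

The destabilizing-selection z-test is anticonservative under neutrality:
codons struck twice on one branch yield replacements (D→K, E→R and
kin) that the single-nucleotide-step neutral expectation assigns
(near-)zero probability, and at short branch lengths the expected radical
counts are of order one, where the normal approximation overstates the
0.001 tail several-fold. Structurally unreachable categories are flagged
(infinite z) rather than called, but the reachable-category excess
remains: in the package's neutral calibration experiments the family-wise
false-call rate stays near 8% rather than the nominal ≤5% across every
regime tried. Calls from this stage should be read as screening evidence,
strongest for properties whose radical categories are reachable by single
substitutions (hydropathy, volume).

Simulated alignments are gap-free and real alignments are not; the
recovery rates reported by the tests say nothing about alignment error.
The hydropathy TM caller stands in for dedicated topology predictors and
is tuned to the synthetic templates, not benchmarked on real receptors.
BEB-grid is an approximation; NEB is exact only at the MLEs. Two-exon
genes are recognized but never spliced-modelled. The birth–death
parameterization is a scenario device, not an inference target.
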