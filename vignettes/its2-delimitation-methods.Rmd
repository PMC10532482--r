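---
title: "Integrated ITS2 species delimitation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated ITS2 species delimitation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2delimit)
```

## The problem

Closely related fungal species — the orchid-mycorrhizal genus *Tulasnella*
is a canonical example — are often impossible to separate by morphology,
and their ribosomal ITS2 region is so variable that multiple sequence
alignments become unreliable exactly where the phylogenetic signal lives.
`its2delimit` implements an integrated delimitation strategy that combines
three sources of evidence:

1. an **alignment-based (AB)** distance matrix from a trusted multiple
   sequence alignment under a nucleotide substitution model;
2. an **alignment-free (AF)** distance matrix computed directly between
   predicted ITS2 secondary structures, without positional homology;
3. a **compensatory base change (CBC)** analysis of the sequence–structure
   alignment, used as an independent corroborating marker, together with
   consensus secondary-structure typing of the delimited groups.

The AB and AF tables are fused into a single *compromise* matrix by
DISTATIS; a single-linkage tree built from the compromise is made
ultrametric and submitted to single- or multiple-threshold GMYC
(generalized mixed Yule-coalescent) delimitation.

## Module by module

### Folding model

`fold_mfe()` predicts one nested, pseudoknot-free structure per sequence by
dynamic programming over the simplified nearest-neighbour objective: pair
rewards GC = 3, AU = 2, GU = 1, a bonus of +1 for every stacked pair, a
minimum hairpin loop of `min_loop = 3` unpaired bases, canonical pairs
only, and IUPAC ambiguity codes treated as unpairable. There are no Turner
tables, dangles, or temperature settings: the model is deliberately
self-contained and reproducible, and `brute_force_fold()` provides an
exact, exhaustive oracle for sequences up to 18 nt (the test suite checks
the two agree on hundreds of random sequences). Ties in the traceback are
broken deterministically (pairing preferred over leaving a base unpaired,
smallest pairing partner first, stacked continuations preferred), so
output is bit-stable across platforms. Users who want thermodynamically
realistic structures can supply any external folder's output in Vienna
dot-bracket format via `read_vienna()` or the pipeline's `structures`
input; the downstream machinery is agnostic to where structures come from.

### Distances

The AF table uses, by default, the unit-cost global edit distance between
dot-bracket strings (match 0, substitution 1, indel 1), which handles
length-variable ITS2; the base-pair set difference is available for
equal-length structures. The AB table offers JC69, K80 and F84; the
default is F84 with empirical base frequencies, mirroring the default of
the classic PHYLIP distance tool. Sites carrying a gap or an ambiguity
code in either sequence of a pair are excluded pairwise rather than
column-wide, preserving signal in length-variable regions. Saturated pairs
(logarithm arguments at or below zero) are reported as errors naming the
pair; an optional cap can truncate them instead. The `tstv` setting is
accepted for configuration compatibility but the moment estimators derive
the transition/transversion ratio from the observed proportions, so it
does not enter the computation.

### DISTATIS

Each distance table is transformed to a cross-product matrix
(`double_center()`), normalized so its first eigenvalue is 1
(`mfa_normalize()`), and compared through RV coefficients. The table
weights `alpha` are the positive first eigenvector of the RV matrix,
rescaled to sum to one, and the compromise is the `alpha`-weighted sum of
the normalized tables. Compromise distances are recovered by
`d_ij = s_ii + s_jj - 2 s_ij`, which is non-negative for any centered
input by the centering identity, even when non-Euclidean tables make the
compromise indefinite (a warning, not an error).

Whether distances should be squared before centering is a genuine
convention choice. `double_center()` and `distatis()` default to the
classical Torgerson convention (`square_first = TRUE`), under which
centering exactly inverts squared Euclidean distances. The *pipeline*
defaults to `square_first = FALSE`, which reproduces the behaviour of the
DistatisR call the original workflow uses (`Distance = TRUE` centers the
supplied table as given). The unsquared convention also behaves better
downstream: squaring stretches large distances, and the row-profile
(Minkowski) step of tree building then amplifies within-species noise
relative to between-species signal.

### Trees

`neighbor_joining()` is standard Saitou–Nei agglomeration (negative branch
lengths clamped to zero with a warning). The compromise tree follows the
original workflow's clustering tool semantics: each taxon's row of the
compromise-derived distance matrix is treated as its feature vector,
pairwise Minkowski distances (`p = 2` by default; the exponent is not
stated in the original workflow) are clustered by single linkage, and
merge heights become node heights. `bootstrap_support()` resamples feature
columns with replacement and reports plain bootstrap proportions per
clade; multiscale/AU p-values are deliberately not implemented.
`make_ultrametric()` rescales an ultrametric dendrogram linearly so the
root sits at the top of the requested interval (default `c(0, 10)`); a
non-ultrametric tree is first rooted on the declared outgroup and given
node heights from mean half-patristic distances between its child
subtrees, monotonized root-wards. The original analysis printed a
branching-time assignment call whose exact semantics are not recoverable;
the linear rescaling rule here is this package's declared stand-in, and
GMYC results are invariant to the overall time scale in any case.

### GMYC

The generalized mixed Yule-coalescent model classifies every branching
event of an ultrametric tree as either *diversification* (older than a
threshold) or *within-cluster coalescence* (younger). Between successive
events the two processes compete: the diversification hazard is
`lambda_div * N^p_div` with `N` the number of species lineages crossing
the interval (a species lineage runs from its parent divergence node down
to the MRCA of its cluster), and the coalescent hazard is
`lambda_coal * sum_j (n_j (n_j - 1))^p_coal` over the clusters' current
lineage counts. Each interval that ends in an event contributes
`ln(total rate) - (total rate) * x` to the log-likelihood; the final
tip-ward interval contributes only its survival term, and the root event
is conditioned upon. Writing the event term with the *total* rate lets
the first coalescence of each cluster draw its hazard from the processes
active just above it, which is what makes the threshold identifiable; the
per-process attribution alternative has zero hazard at entity roots under
any side convention and, in our experiments, loses all power against the
exponent-flexible null.

The null model is a single coalescent-type process over the whole tree
(`lambda * (n (n - 1))^p`), which coincides with the all-coalescent
candidate, so the best model's likelihood can never fall below the null's.
Rates and exponents are optimized jointly by bounded quasi-Newton search
(with a clamped Nelder–Mead fallback for cliff-shaped surfaces), rates on
a log scale from moment-based starting values. The exponents are bounded
to `[0.1, 2]` by default: wider bounds let the diversification term with
`n^5` scaling absorb the bursts of tied merge heights that single-linkage
dendrograms produce by construction (many one-substitution pairs merge at
exactly the same height), which manifests as spurious oversplitting.

The likelihood-ratio test against the null uses a chi-square with 3
degrees of freedom by default (threshold, extra rate, extra exponent),
with an equal-weights chi-square mixture available. Candidate-model
Akaike weights give per-node support: the summed weight of candidate
delimitations in which the node lies inside one delimited entity. Model
size for AIC is `2 x (processes with data) + t`, where `t` is the minimal
number of distinct threshold times that can generate the delimitation
(an interval-piercing computation over the entity boundary edges); a
single-threshold model has 5 parameters against the null's 2, consistent
with the LRT default.

Two practical behaviours are worth knowing. First, branchings at exactly
zero height (identical sequences) carry no waiting-time information and
would otherwise look like an instantaneous-coalescence regime; by default
`gmyc()` collapses such clades to one representative tip and re-expands
the clusters afterwards, the standard practice for this model. Second,
`mode = "multiple"` hill-climbs over per-lineage threshold assignments
starting from the single-threshold optimum, scoring neighbour moves at
the incumbent's parameter values (a cheap profile) and re-optimizing
fully only for accepted moves; the visited candidate set feeds the
Akaike-weight supports.

### CBC analysis

Per-sequence structures are projected through each row's gap pattern onto
alignment columns (`project_structures()`), replacing simultaneous
folding-and-alignment, which is out of scope. For every sequence pair the
homologous paired columns in scope — the intersection of the two rows'
projected pair sets by default, or the consensus structure's pairs — are
classified: a CBC when both sides differ and both pairs are canonical, a
hemi-CBC when exactly one side differs, not comparable when a gap,
ambiguity or non-canonical pair intervenes (such columns never contribute
counts). The CBC-zero partition is the set of connected components of the
graph joining sequences with zero CBCs. The classical probabilities
attached to CBC presence/absence (~0.93 that a CBC separates species,
~0.76 that its absence indicates conspecificity) are reported as fixed
literature annotations and never used in computation.
`consensus_structure()` ranks candidate column pairs by the fraction of
rows supporting them and accepts them greedily (support at least the
threshold, default 0.5; no crossings or shared endpoints; ties broken by
support, span, position), and `count_domains()` types the result by the
number of helices on the exterior loop ("4-domain", "5-domain", ...),
with helices branching off internal multiloops counted as subdomains.

## The synthetic family generator

`generate_family()` builds ITS2-like families with fully known truth so
every stage is testable offline: a multi-helix scaffold (leading linker,
stems, hairpin loops, spacers) shared within clades, with the smaller
clade's extra regions unpaired where the larger clade has helices, so the
leading helices are positionally homologous across clades; species
ancestors drifting at unpaired sites; species-diagnostic planted CBCs
(full canonical pair swaps such as G-C to A-U) at dedicated stem positions
of the conserved helices, disjoint across species and kept away from all
other variation; and within-species variation along a coalescent genealogy
(`rcoal`), with at most one single-side canonical-preserving stem change
per pair per species. The single-side rule is what guarantees
within-species CBC counts of exactly zero: a mirrored double substitution
would itself be a CBC, so compensatory double changes only ever separate
species. Generation is bit-identical per seed.

`default_tulasnella_like()` is the preset study family: 142 ingroup
sequences in 7 species over 2 clades (three species with a 4-helix
scaffold, four with 6 helices; cluster sizes 24/22/18 and 22/20/20/16),
plus one divergent outgroup. The scaffold is 400 nt — this genus'
ribosomal region is long and highly divergent — and the rates are
`between_div = 0.10` per branch (about 10–20 % interspecific divergence,
realistic for the group) with `within_div = 0.007`, chosen so the largest
intraspecific divergence stays roughly twenty-fold below the smallest
interspecific divergence. That twenty-fold deep/shallow separation is the
same study condition used in the delimitation simulations
(`simulate_delimitation_tree()` with `species_depth = 10`,
`coal_depth = 0.5`), and is what makes the threshold model identifiable;
at much higher intraspecific variation the model increasingly reports
deep intraspecific substructure as additional clusters — a documented
behaviour of threshold-based delimitation, not an artifact of this
implementation.

What the generator does *not* emulate: indel evolution (the true
alignment is gap-free), realistic thermodynamic landscapes (the true
structures are the scaffold itself), intragenomic ribotype variation, and
alignment error. Passing the end-to-end tests therefore demonstrates the
correctness and integration of the machinery under clean, delimitable
conditions; it does not certify performance on real data whose alignments
and structures are themselves uncertain.

## Numerical choices and degenerate inputs

* Distance matrices are symmetrized by averaging when asymmetry is at
  most `1e-8` and rejected otherwise; negative entries are errors.
* `mfa_normalize()` rejects tables whose first eigenvalue is not
  positive (degenerate all-zero tables).
* Compromise distances in `(-1e-8, 0)` are clamped to zero; anything
  lower is an error.
* Tied branching times are staggered upward in postorder by
  `1e-6 x root age` so waiting intervals stay positive; the perturbation
  is orders of magnitude below any biological signal.
* The bootstrap, the generator and the simulators restore the caller's
  RNG state; all randomness is seed-driven.
* Coordinates in reports are 1-based inclusive.

## Problem sizes

The test-suite and acceptance computations use the preset 143-sequence
family (two full pipeline runs with 200–1000 bootstrap replicates), 200
random sequences of 8–18 nt for the folding oracle, 100 random additive
matrices (up to 12 taxa) for neighbor joining, and 150 simulated trees
(50 planted-structure, 100 single-population) for the delimitation model —
sizes at which every check completes in a few minutes on one CPU while
still exercising the full 142-taxon geometry of the motivating dataset.

## Known limitations

* The folding objective is intentionally simple; its predictions on real
  ITS2 are not thermodynamically accurate, and the AF table of a real
  study should come from a dedicated folder via the `structures` input.
* Plain bootstrap proportions are reported for the compromise tree, not
  multiscale/AU p-values.
* The multiple-threshold search is a deterministic hill climb; it
  inherits the usual local-optimum caveats, mitigated by starting from
  the single-threshold optimum.
* GMYC cluster counts on distance-derived dendrograms are sensitive to
  within-species substructure; the CBC partition provides an independent
  check, and disagreement between the two is itself informative.
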