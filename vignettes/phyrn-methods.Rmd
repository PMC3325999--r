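---
title: "Profile-distance phylogenetics for highly divergent proteins: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-distance phylogenetics for highly divergent proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Below roughly 25% pairwise amino-acid identity (the "twilight zone", and the
"midnight zone" near 10%), multiple sequence alignment degrades, and with it
every tree built on top of an alignment. `phyrn` implements an
alignment-free alternative: every query sequence is described not by its
letters but by how well it aligns to a library of position-specific scoring
matrices (PSSMs), one per query. The vector of those per-profile scores is a
coordinate system in which Euclidean distance still orders sequences by
relatedness after pairwise identity has saturated, because each profile
pools the signal of a whole gathered neighborhood rather than a single
sequence.

This vignette records the models, parameter choices and known limits of the
implementation; the README shows the worked end-to-end example.

# The product score

For the best local alignment of query against profile the package records
`ids` (query letters equal to the profile's seed letter at the aligned
position), `alen` (alignment columns), `aqlen` (columns holding a query
residue) and `plen` (profile length). The per-(query, profile) statistic is

\[
s \;=\; \%i \times \%c \;=\; \frac{ids}{alen} \times \frac{aqlen}{plen},
\]

which factors exactly as \((1 - p_{ARP})(1 - w_g)\) with the
alignment-restricted p-distance \(p_{ARP} = (plen - ids)/plen\) and the gap
weight \(w_g = (alen - aqlen)/alen\). The test suite checks this identity to
1e-12 on randomized inputs; it holds whenever gap characters are counted on
the query side (`gap_chars = alen - aqlen`), which is the convention the
aligner uses. Coverage is clamped at 1 in the rare case that query
insertions push `aqlen` past `plen`, keeping every score in \([0,1]\). A
query-profile pair with no positive-scoring local alignment contributes 0 —
the "no alignment" encoding; no significance filter is applied at scoring
time (the nominal threshold of \(10^{10}\) means "keep everything
positive").

Scores are stored as fractions rather than percent-times-percent; neighbor
joining is invariant to a uniform rescaling of Euclidean distances, so this
is a cosmetic choice recorded in the matrix metadata.

# Profile construction

Each query seeds its own profile. Gathering mimics iterative PSI-BLAST: the
single-sequence profile searches the database (by default the query set
itself — simulated families have no outside homologs, which is exactly why
the original procedure embedded its synthetic queries in a larger database);
members at e-value \(\le 10^{-6}\) are realigned to seed coordinates and the
profile rebuilt, for up to 6 iterations. Members accumulate across
iterations, so the gathered set is monotone by construction. Significance
uses a Gumbel law fitted once per library to scores of profiles against
residue-shuffled database sequences (moment fit:
\(\lambda = \pi/(\sigma\sqrt6)\), \(\mu = \bar S - \gamma/\lambda\); e-value
\(= n_{db} e^{-\lambda(S-\mu)}\)). The shuffles are drawn under a fixed
internal stream so that library construction is a pure function of
(queries, database, parameters).

Frequencies use Henikoff position-based sequence weighting and a single
pseudocount mass per column. Two pseudocount priors are available:

* **substitution** (default): the pseudocount distribution is the Dayhoff
  conditional distribution of the observed residues,
  \(g(a) = \sum_b \hat f(b)\, P_{250}[b, a]\). A sparsely populated column
  then scores chemically similar residues positively — a single-sequence
  profile behaves like a classical PAM substitution matrix. This is what
  makes profile search sensitive in the twilight zone and keeps distant
  local alignments long enough for the product score to carry signal. With
  plain background pseudocounts the same pipeline loses to a pairwise
  p-distance baseline at high divergence; with the substitution prior it
  clearly beats it (see the benchmark below). The default mass of 10 per
  column is the conventional PSI-BLAST magnitude.
* **background**: background-proportional pseudocounts, kept as an option
  and used by some unit tests because its blending arithmetic is easy to
  verify by hand.

Scores are half-bit log-odds, \(2\log_2(f/b)\) — the scale on which the
BLAST affine gap convention (open 11, extend 1) sits. Both penalties are
exposed.

# The sequence-evolution simulator

The benchmark needs families whose true history is known. The simulator
puts an i.i.d. Dayhoff-equilibrium sequence (default 450 residues) at the
root of an ultrametric tree and evolves it down every branch:

* **Substitutions.** A branch of length \(d\) PAM substitutes each site by
  a draw from the corresponding row of the Dayhoff transition matrix at
  distance `round(d)` (the PAM-1 matrix raised to that power; powers come
  from a cached eigendecomposition of the rate matrix). 1 PAM = 0.01
  expected accepted substitutions per site; the classical anchor — about
  20% expected identity at 250 PAM — falls out of the matrix and is
  asserted in the tests.
* **Indels.** After substitution, indel events arrive as a Poisson count
  with mean `ISR × (d/100) × L` (ISR = indel-to-substitution ratio, default
  0.03, matching the regime the benchmark targets), each an insertion or a
  deletion with probability 1/2, with truncated-Zipf lengths (exponent 1.7,
  cap 40 — the conventional indel length law family; both exposed).
  Inserted residues are background draws. Every surviving site carries a
  persistent coordinate key, so the emitted alignment of the leaves is the
  true alignment: un-gapping any row reproduces the leaf sequence exactly,
  an invariant the tests enforce on every replicate.

Divergence statistics mirror the usual reporting conventions: pairwise
identity counts only columns where both rows carry residues (so that heavy
gap loads do not masquerade as substitutions); both the event rate and the
gap-character rate per residue are reported, because "gaps per position" is
ambiguous between the two; the average gap length is the mean logged event
length; the realized ISR is events over realized substitutions.

## Tree shapes and the clock convention

Three ultrametric topology modes exist: `yule` (random coalescent-order
joins), `balanced` (near-perfect binary) and `pectinate` (caterpillar).
All are strict-clock trees rescaled so that the mean over all unordered
leaf pairs of patristic distance equals the requested PAM level — the
"divergence dial".

The join *times* of the `yule` mode are a genuine modeling choice: the
random-joins topology process does not fix them. Kingman-coalescent times
disperse pairwise distances so strongly that the mean identity of a
100-taxon family at mean-pairwise 650 PAM would sit near 19%; pure-birth
times give about 10%; evenly spaced join heights give 8.8%, which is the
value that matches both the classical identity-versus-PAM curve at the
dial setting and the behavior this family of simulators is known for
(identities near 9.0% and 8.6% at 650 and 700 PAM). The package therefore
spaces join heights evenly. This was decided by comparing the three
conventions against those calibration statistics once, up front; it is the
simulator's definition, not a tunable.

Interpreting the dial as *mean pairwise* (rather than mean root-to-leaf)
distance is the other half of the same calibration: at 650 PAM the
root-to-leaf reading would push pairwise identities to ~6.5%, well below
the expected ~9%.

# Distances, trees, support

Distances are plain Euclidean distances between matrix rows (`stats::dist`
with symmetry enforced), which guarantees the metric axioms. Neighbor
joining is the canonical Q-criterion algorithm as implemented in `ape`
(`ape::nj`), with negative branch-length estimates clamped to zero;
NJ's exact consistency on additive matrices is part of the test suite.
Alternative distance-tree backends can be slotted in at the same
distance-matrix interface; the original study found the choice immaterial.

Branch support resamples **profile columns** of the N×M matrix — the only
exchangeable unit in a profile-distance method (there is no site matrix to
bootstrap). `bootstrap` draws M columns with replacement; `jackknife80`
draws 80% without replacement; each replicate is carried through distances
and NJ, and support is the percentage of replicate trees containing the
branch's bipartition.

# Scoring inferred trees

Robinson–Foulds distance is the size of the symmetric difference of the
two trees' nontrivial bipartition sets (maximum \(2(n-3)\) for resolved
trees); the implementation is cross-checked against `phangorn::RF.dist`,
against a brute-force bipartition extractor, and exhaustively over all 105
six-leaf topologies. Two-tree consensus marks annotate each true branch
100 (present in the estimate) or 50 (absent), so the number of 50-marks is
RF/2 for resolved trees. Deep-node recovery operationalizes "ancestors of
the last two tiers of leaves" as internal nodes whose minimum edge-distance
to a descendant leaf is at least 2 (the cutoff is exposed, since "tier"
admits neighboring readings); a deep node is recovered when its bipartition
occurs in the estimated tree.

# The benchmark harness

`benchmark_run()` simulates families across divergence levels and scores
each method's tree against the truth. Built-in baselines deliberately stay
inside the package: p-distance on the simulator's true alignment (the
"perfect alignment" reference) and p-distance on all-against-all global
pairwise alignments (`Biostrings::pairwiseAlignment`, BLOSUM62, 11/1 — the
classical guide-tree distance). External aligners and likelihood or
Bayesian tree programs are out of scope.

The shipped acceptance checks run 5 replicates of 50 taxa × ~450 aa at PAM
100/400/700 on **balanced** trees. The tree shape matters and is worth
being explicit about: on balanced clock trees every internode is far above
the statistical resolution floor at 450 residues, and the benchmark
reproduces the expected pattern — every method exact at PAM 100, profile
distances degrading far more slowly than pairwise p-distance at PAM 700
(mean RF ≈ 27 versus ≈ 42 of a possible 94, with the true-alignment
reference near 0). On 50-taxon `yule` trees with evenly spaced join
heights the internodes are ~1 PAM, i.e. ~5 expected substitutions over the
whole sequence; there no distance method — not even p-distance on the true
alignment — recovers the topology, which says something about those trees,
not about the methods. Problem sizes throughout (10 calibration replicates
at 100 taxa; 5 benchmark replicates per level at 50 taxa) were chosen as
the smallest at which the compared quantities stabilize.

# Numerical choices and degenerate inputs

* PAM matrix powers: eigendecomposition of the reversible rate matrix via
  symmetrization; tiny negative entries from round-off are clipped and rows
  renormalized. Powers are cached per integer distance.
* The profile aligner breaks ties deterministically (match > query-gap >
  profile-gap; first maximal cell in row-major order), so every
  downstream artifact is reproducible byte-for-byte from the seed.
* All randomness flows from one user seed through fixed derivation
  offsets; `withr::with_seed` keeps the global RNG state untouched.
* PSSM libraries, score matrices and distance matrices are written with
  `%.17g`, making write→read→write byte-identical.
* Degenerate cases signal errors rather than guessing: trees with all-zero
  branch lengths cannot be rescaled; empty alignments have no statistics;
  distance matrices below 3 taxa have no NJ tree; star-like trees have no
  deep nodes at the default cutoff.

# Known limitations

* No site-rate heterogeneity, domain shuffling or recombination in the
  simulator; all sites evolve at one rate. Real protein families have
  conserved cores that profile methods exploit further, so passing
  benchmarks here likely *understates* the profile advantage on biological
  data — but none of these tests speak to model misspecification on real
  alignments.
* The e-value stand-in is a moment-fit Gumbel without length or composition
  corrections; it ranks hits well at these scales but is not comparable to
  NCBI e-values.
* Profile gathering against the query set alone cannot reach beyond the
  statistical detection limit (~30% identity for single profiles); at
  extreme divergence the deep structure signal comes from the scoring
  step's smooth product scores, not from gathering whole families into
  each profile.
* Strict clock only; rate-heterogeneous branches are a non-goal.
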