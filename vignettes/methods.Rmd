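---
title: "Methods: in-silico resurrection of gas-cavity evolution in selenoprotein hydrogenases"
author: "hyscav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico resurrection of gas-cavity evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

[NiFeSe] hydrogenases are H2-cycling enzymes whose Ni–Fe active site is
coordinated in part by a selenocysteine (Sec). Because Sec is encoded by an
in-frame opal codon (UGA), these genes look prematurely truncated in
standard annotation; reading the opal codon through as Sec recovers the
full protein, and a SECIS stem-loop downstream of the opal codon licenses
that readthrough. Over evolutionary time the enzyme's gas cavities — the
dents, cracks, crevices and insulated internal voids that carry H2 and
admit or exclude O2 — have been reshaped, and one can ask how cavity
morphology evolved along the phylogeny: which cavities appeared first,
how they widened, and whether the residues that form them were under
positive selection or are in fact highly conserved.

`hyscav` implements the computational core of that study as a reusable,
fully testable pipeline:

1. **Phylogenetic machinery** — GTR+Γ(+I) pruning likelihood on a fixed
   rooted tree, marginal (maximum a posteriori) ancestral sequence
   reconstruction, model fitting, NJ tree building from model-based ML
   distances, and column-resampling bootstrap support.
2. **Codon selection profiling** — Nei–Gojobori (NG86) counting of
   synonymous/nonsynonymous sites and pathway-averaged differences,
   per-column δN and δS aggregated over ancestor→descendant branches, and
   a codon-based Z-test.
3. **Selenoprotein readthrough** — opal-codon detection, extended
   translation with U, and a minimal SECIS-like hairpin scanner.
4. **Cavity geometry** — alpha-complex detection of pockets and insulated
   voids from atomic coordinates, Monte-Carlo volume/area measurement,
   lining-residue extraction, and the dent/crack/crevice/internal
   classification.
5. **Cavity evolution** — cavity identity across structures by
   lining-residue overlap, lineage numbering by order of appearance, the
   per-column cavity score, and the overlay of cavity formation with the
   selection profile.
6. **Synthetic data** — seeded generators for trees, codon alignments
   with planted selection regimes (with true ancestral sequences and the
   full event log retained), and atom-cloud structures with voids of
   known geometry, so every stage is verifiable end to end without any
   external data.

Real structural inputs (homology models, MD refinement) are outside the
package's scope; the geometry stage consumes any PDB-format atom cloud.

# Evolutionary model and reconstruction

## Substitution model

The nucleotide model is the general time-reversible (GTR) rate matrix
with stationary frequencies π (A, C, G, T order everywhere) and six
exchangeabilities (AC, AG, AT, CG, CT, GT order), scaled so the expected
substitution rate is 1 — branch lengths are expected substitutions per
site. Rate heterogeneity uses the discrete gamma with equal-probability
bins and conditional category means (the common "mean" method; category
rates therefore average to exactly 1 for any shape), default 4
categories. An invariant-site class of weight `p_invariant` has rate 0
and the gamma rates are rescaled by 1/(1 − p_invariant), keeping the
overall expected rate at 1; this matches the convention of mainstream
likelihood packages, and the package's pruning log-likelihood agrees with
`phangorn::pml` to ~1e-6 on shared inputs (asserted in the test suite).

## Likelihood and marginal ASR

`log_likelihood()` is Felsenstein pruning with per-site pattern
compression and per-category root-scaling; a category may legitimately
contribute zero at a site (the invariant class at a variable column), and
the mixture absorbs it. `marginal_asr()` adds the standard up-down pass:
the posterior of state x at node v is proportional to the mixture over
rate categories of (partial likelihood of the subtree below v) × (partial
likelihood of the rest of the tree), normalised per node and column. The
MAP base is the argmax with ties broken in fixed A < C < G < T order.
Branch lengths are taken as given and not re-optimised during
reconstruction, mirroring the reconstruct-on-a-given-tree workflow.

MAP bases are assembled into codons per internal node; an assembled stop
codon is replaced by the sense codon with the highest posterior product
(candidates ranked by probability, ties by alphabetical codon order), and
the repair count is reported. A nucleotide model with codon assembly was
chosen over a 61-state codon model deliberately: it matches the standard
GTR-based workflow the analysis emulates and keeps the state space small;
the stop-repair rule makes the assembled ancestors usable by the
codon-level profiling stage.

Internal nodes receive stable labels `N1..Nk` in postorder completion
order (the root always has the highest index). Any numbering is
inherently arbitrary; this one is deterministic and documented.

## Trees, distances, support

`build_nj_tree()` estimates each pairwise distance by one-dimensional ML
optimisation under the full model, applies neighbor joining, clamps
negative NJ branches to zero and midpoint-roots the result (the true
rooting being unknowable from the distance matrix alone).
`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate and reports the percentage of
replicates containing each internal bipartition of the point-estimate
tree. `fit_model()` maximises the pruning likelihood over the five free
exchangeabilities (GT fixed at 1), the gamma shape and the invariant
proportion by L-BFGS-B on log/logit-transformed parameters, with
empirical base frequencies; non-convergence is flagged, not hidden.

# Selection profiling (NG86)

Per codon, synonymous site fractions count, at each position, the
single-nucleotide changes preserving the amino acid among those not
creating a stop (mutations to stops are excluded and the position
renormalised, so S + N = 3 exactly for every sense codon). Differences
between two codons are averaged with equal weight over all orderings of
the differing positions, discarding orderings that pass through a stop;
if every ordering is stop-interrupted the pair is flagged inadmissible
and skipped rather than imputed. Both computations are verified exactly
against literal brute-force enumerators over all 61×61 sense-codon pairs.

`site_profile()` aggregates per column over all branches of the rooted
tree (tips from the alignment, internal nodes from the reconstruction):
δS = ΣSd/ΣS̄ and δN = ΣNd/ΣN̄, with site counts averaged between the two
branch endpoints. δN − δS > 0 marks positions under apparent positive
selection. The per-column Z statistic uses bootstrap-over-branches
variances (seeded, configurable replicate count) rather than the analytic
NG86 variance — simpler, and consistent with codon-based Z-test behaviour
within sampling error. Columns informative on no branch are reported as
NA, never zero-filled. A `root_to_tips` mode comparing the root ancestor
directly with each extant sequence is exposed as an alternative; the
default aggregates all branches.

One property deserves emphasis because it bounds what "specificity"
can mean here: for the two-block codon families (Arg CGN/AGR, Leu
CTN/TTR, Ser UCN/AGY), a purely synonymous substitution history can
produce codon pairs whose mutational pathways all pass through a
different amino acid. Pathway averaging then assigns a fractional
nonsynonymous difference, so a strictly conserved column can show a small
positive δN. In the package's own simulations (ω = 0 columns, tree
length 1.5, 8 taxa) this affects well under 1% of column-replicates,
and the affected columns still have δN − δS < 0; it is a property of the
NG86 estimator, not noise one should tune away.

# Selenoprotein readthrough

`find_opal_readthrough()` reports the first in-frame TGA that is followed
in frame by a second stop; the standard protein ends before it, the
extended protein decodes it as U and continues to the second stop. A
TAA/TAG terminating the frame before any TGA means there is no
readthrough candidate. `scan_secis()` is deliberately a minimal hairpin
maximiser, not a thermodynamic folder: it enumerates all perfect-stem
hairpins (Watson–Crick plus GU wobble, no bulges) with loop length in a
given range and returns the highest-scoring one (score = stem length;
ties by smaller start, then longer stem). The default scan window is the
60 nt immediately 3' of the opal codon — bacterial SECIS elements are
proximal, but the window is a parameter, not an inference. The scanner is
verified exactly against a literal geometry enumerator on random windows.

# Cavity geometry

## Alpha complex

Atom centers are tetrahedralised by an incremental Bowyer–Watson 3D
Delaunay implementation (vectorised circumsphere tests; degenerate inputs
raise an error recommending an opt-in seeded jitter). A tetrahedron is in
the alpha complex iff its circumradius ≤ mean of its four atom radii +
probe radius (default probe 1.4 Å, water); the complement ("empty")
tetrahedra host potential cavities. This unweighted, probe-augmented
alpha test is a deliberate simplification of the weighted alpha-shape
machinery used by pocket-detection servers: with near-uniform radii (the
synthetic regime, or a united-atom radius table) it approximates the same
pockets at a fraction of the complexity.

Three facet/tetrahedron roles are distinguished:

* **exterior** — an empty tetrahedron whose convex-hull facet is wide
  enough to admit the probe (facet circumradius > mean facet-atom radius
  + probe). These are the probe-accessible outside.
* **connectivity** — two empty tetrahedra belong to the same void iff
  sphere-free space actually crosses their shared facet, decided by a
  fixed barycentric grid (8 subdivisions, 45 points) with an exact
  point-vs-inflated-sphere test. The grid is deterministic, so the
  decision is exactly isometry-invariant. Using the probe-disc
  (circumradius) rule for connectivity instead would fragment a
  contiguous void into dozens of pieces whenever atoms lie near a common
  sphere, because for cospherical points every Delaunay tetrahedron
  shares the global circumsphere.
* **mouths** — facets between a cavity and exterior tetrahedra that pass
  the probe-disc rule, grouped into edge-connected patches; the patch
  count is the mouth count. A cavity with no such facet is an insulated
  internal void.

Cavities smaller than the probe sphere (4/3·π·r³ ≈ 11.5 ų at the default
probe) are discarded: a void that cannot host the probe is not a
solvent-accessible cavity, and sub-probe interstitial slivers between
atoms would otherwise dominate the census.

## Measurement and classification

Volumes are probe-excluded: stratified Monte-Carlo over the member
tetrahedra (samples proportional to tetrahedron volume, minimum 10 per
tetrahedron) counting the fraction clear of all probe-inflated atom
spheres, with a binomial standard error. The area reported is the
sphere-free area of the cavity's boundary facets estimated by the same
sampler — effectively the open (probe-accessible) boundary, which is 0
for insulated voids; it supports relative statements (e.g. a wider
aperture has a larger mouth area), not absolute molecular-surface areas.
Lining residues are the residues owning a vertex of any member
tetrahedron, augmented by atoms whose inflated sphere comes within 0.5 Å
of a sampled void point — the latter recovers boundary atoms whose only
tetrahedra are outside the void component.

Classification follows the published scheme: mouthless → internal (i);
otherwise dent (d) below 500 ų, crack (k) from 500 ų inclusive to
1000 ų exclusive, crevice (v) at 1000 ų and above. The boundaries are
exact in the code and asserted exactly in the tests. Absolute volumes of
real structures depend on the upstream structural models and the probe
convention; the package claims threshold and relative behaviour, which is
what the detector-vs-oracle agreement tests cover (within 5% on cage
fixtures).

Per-element van der Waals radii (C 1.7, N 1.55, O 1.52, S 1.8, Se 1.9 Å)
apply when a PDB provides element symbols; a uniform united-atom 1.8 Å
is the fallback and the synthetic default.

# Cavity evolution

Cavity identity across structures is defined by lining-column overlap:
greedy maximum-Jaccard matching on the sets of alignment columns lined by
each cavity, accepting pairs at Jaccard ≥ 0.3 (configurable), ties broken
by lower cavity id. Residue overlap is the testable reading of identity
based on "location and residues involved"; spatial-proximity matching
would be a reasonable alternative but requires superposed coordinate
frames, which ancestral models do not share by construction.

`number_by_appearance()` walks the tree in pre-order (root first,
natural child order); each structure-bearing node is matched against its
*nearest structure-bearing ancestor* (structures typically exist only at
selected nodes), unmatched cavities found a new lineage with the next
integer id, and per-node class labels accumulate into the lineage's class
history — yielding composite designations like `5d + 5i` per node.

The cavity score of an alignment column is the number of structures in
which the residue at that column lines any cavity (the
count-of-structures reading; a sum-of-lining-atoms alternative would
weight large cavities more but no longer be bounded by the structure
count). `overlay_report()` joins the score with the selection profile and
summarises: columns with δN − δS > 0, cavity-lining columns, their
intersection, and the cavity-forming-but-conserved count (lining columns
with δN − δS < 0) — the signature that most cavity-forming residues are
in fact highly conserved.

# Synthetic data: what it emulates, and what it does not

`simulation_spec()`/`generate_tree()`/`evolve_codon_alignment()` produce
a rooted binary tree (Yule or balanced; branch lengths rescaled so their
sum equals `total_tree_length`) and codon sequences evolved site by site:
single-nucleotide changes are proposed under the GTR mutation process,
synonymous changes proceed at the full mutation rate, nonsynonymous
changes at ω times it, and changes creating stops are rejected (rate
zero). This exact-rate Gillespie formulation reduces to
stop-rejection/acceptance thinning for ω ≤ 1 and remains well defined
for ω > 1 (an acceptance "probability" of ω = 5 is not). True internal
sequences and the full accepted-event log are retained as ground truth,
which is what the event-counting oracles and recovery tests consume.

Default study conditions, chosen once: 8 taxa, total tree length 1.5
substitutions/site (within the 1–2 range a moderately diverged bacterial
enzyme family suggests; the real divergence depth is unknown), ω = 5 for
hotspots, 0.2 background, 0 conserved, uniform base frequencies and equal
exchangeabilities unless a scenario says otherwise.

`structure_spec()`/`generate_structure()` produce atom clouds with known
void topology: a Fibonacci-lattice shell (deterministic coverage, hence
reproducible mouth topology) for sealed cages, the same shell minus a
polar cone (default solid angle 0.8 sr) for aperture cages, and
cubic-lattice balls (spacing 2 Å) for dense blobs and surface dents. A
small seeded jitter (1e-3 Å) keeps lattice points in general position for
the triangulation. The reference void volume comes from an independent
flood-fill Monte-Carlo oracle living in the synthetic module, not the
detector: atom spheres inflated by the probe, a 0.4 Å voxel grid
flood-filled from the bounding box to find probe-insulated space, and
exact sphere tests on ≥1e5 uniform samples within the insulated void
dilated one voxel into the blocking shell (the dilation samples the
sphere-bounded rim without touching the shell's outer skin, which would
otherwise bias the reference upward).

What the generators do **not** emulate: indels and alignment error
(alignments are generated gap-free; real-data mode accepts gaps by
skipping affected codons), among-site rate correlation, MD-quality
structural detail, solvation, or any force-field energetics — structures
are geometric stand-ins. Passing tests therefore demonstrate the
correctness of the algorithms under their stated models, not the fidelity
of any particular biological reconstruction.

`wired_scenario()` ties the two generators together: cage structures at
selected tree nodes whose shell residues map onto the planted hotspot
columns, the planted conserved columns and background columns, so the
selection-vs-cavity overlay has a full ground truth.

# Numerical choices

* Pruning uses per-category root scaling; underflow to exact zero in a
  category is kept (the mixture absorbs it).
* The Bowyer–Watson insphere test uses a 1e-12 relative tolerance;
  circumspheres of numerically flat tetrahedra are treated as infinite.
* MAP ties break A < C < G < T; stop-repair candidates rank by posterior
  product, then alphabetically.
* NG86 inadmissible pairs (all pathways stop-interrupted) are flagged and
  skipped, never imputed; Jukes–Cantor correction saturates at p ≥ 3/4
  and returns the uncorrected proportion with a flag.
* Negative NJ branch lengths are clamped to 0 before midpoint rooting.
* All stochastic steps (simulation, bootstraps, Monte-Carlo measurement)
  take explicit integer seeds and restore the caller's RNG state.

# Problem sizes

The shipped verification suite uses sizes chosen to make each property
measurable with comfortable margins: 61×61 codon pairs exhaustively;
200 random ≤5-leaf instances against the brute-force likelihood
enumerator; 8-taxon, 300-column reconstructions for ASR recovery; 100
replicates of the 240-column selection scenario; sealed cages at radii
6, 8 and 12 Å (shell size ≈ πR² atoms) against the volume oracle; and 20
seeds of the wired overlay scenario. The acceptance script recomputes the
same quantities at moderately reduced replicate counts.

# Known limitations

* The exterior rule (hull facet wide enough for the probe) is a
  simplification of discrete-flow pocket analysis; very convoluted
  surface pockets may be split differently than a discrete-flow
  implementation would split them.
* Reported cavity areas are open-boundary areas, not molecular-surface
  areas; insulated voids report area 0.
* The SECIS scanner is a geometry heuristic; it finds the best perfect
  hairpin, not a thermodynamically validated SECIS element.
* ASR uses MAP sequences for the selection profile; posterior-weighted
  profiling is a natural extension and is not implemented.
* The NG86 profile shows the two-block codon-family effect described
  above; interpret small positive δN at otherwise conserved positions
  accordingly.
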