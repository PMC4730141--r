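# hyscav

In-silico resurrection toolkit for studying how gas cavities evolve in
selenocysteine-containing [NiFeSe] hydrogenases — and, more generally,
for any analysis that combines ancestral sequence reconstruction,
per-codon selection profiling, and geometric cavity detection on a
phylogeny.

[NiFeSe] hydrogenases carry a selenocysteine (Sec) at the Ni–Fe active
site, encoded by an in-frame opal codon (UGA) that is read through when a
SECIS stem-loop follows it. Along their phylogeny, the enzyme's gas
cavities — surface dents, cracks, crevices, and insulated internal voids —
have been progressively remodelled. `hyscav` provides the machinery to
reconstruct that history and ask whether cavity-forming positions were
driven by positive selection or are, in fact, highly conserved.

## What it computes

* **GTR+Γ(+I) likelihood and marginal ASR** on a fixed rooted tree:
  Felsenstein pruning, per-node posterior base distributions, MAP
  ancestral sequences assembled into sense codons; NJ trees from
  model-based ML distances; column-resampling bootstrap support;
  model fitting by bounded quasi-Newton.
* **NG86 selection profile**: synonymous/nonsynonymous site counts with
  stop-exclusion renormalisation (S + N = 3), pathway-averaged difference
  counts, and the per-column profile over all ancestor→descendant
  branches,

  δN = ΣNd / ΣN̄,  δS = ΣSd / ΣS̄,

  with a codon-based Z-test, Z = (dN − dS)/√(var N + var S), from
  bootstrap variances. δN − δS > 0 flags positions under positive
  selection pressure.
* **Opal readthrough and SECIS scan**: extended translation with U at the
  opal codon to the second stop, plus a hairpin maximiser (WC + GU stems)
  over the downstream window.
* **Cavity geometry**: Bowyer–Watson 3D Delaunay, probe-augmented alpha
  complex, void components with mouth counting, stratified Monte-Carlo
  probe-excluded volumes with standard errors, lining residues, and the
  volume classification dent (< 500 Å³) / crack (500–1000 Å³) /
  crevice (≥ 1000 Å³) / internal (no mouth).
* **Cavity lineages and overlay**: cavity identity across structures by
  lining-column Jaccard overlap, lineage numbering by order of appearance
  on the tree (designations like `5d + 5i`), the per-column cavity score,
  and its overlay with the selection profile.
* **Synthetic data**: seeded generators for trees, codon alignments with
  planted ω regimes (true ancestors and event logs retained), and
  atom-cloud structures with voids of known geometry, including an
  independent flood-fill Monte-Carlo volume oracle.

## Worked example

```r
library(hyscav)

# a synthetic study: 8 taxa, 120 codon columns, 12 hotspot (omega = 5)
# and 12 conserved (omega = 0) columns, tree length 1.5 subs/site
spec <- simulation_spec(n_leaves = 8, total_tree_length = 1.5,
                        n_columns = 120, hotspot_columns = 1:12,
                        conserved_columns = 13:24, seed = 1)
tree <- generate_tree(spec)
sim  <- evolve_codon_alignment(tree, spec)
sim$alignment
#> Codon alignment: 8 sequences x 120 codon columns

# reconstruct ancestors and profile selection per column
asr  <- marginal_asr(tree, sim$alignment, subst_model(gamma_shape = 1))
asr
#> Ancestral states: 7 internal nodes x 360 sites; logL = -1604.6678
#>   stop codons repaired in assembled ancestors: 1
prof <- site_profile(sim$alignment, tree, asr, n_boot = 100, seed = 1)
prof
#> Site selection profile: 120 codon columns over 14 branch pairs (all)
#>   columns with deltaN - deltaS > 0: 31
summarize_positive_sites(prof)$fraction
#> [1] 0.2583333

# detect the cavity in a sealed-cage structure and check it against the
# independent Monte-Carlo oracle
gs <- generate_structure(structure_spec("sealed_cage", cage_radius = 8,
                                        n_shell_atoms = 200, seed = 1))
cs <- detect_cavities(gs$structure,
                      geometry_params(volume_mc_samples = 5e4, seed = 1))
cs
#> Cavity set: 1 cavities in 200-atom structure
#>  id    class  volume volume_se area mouth_count n_lining_residues
#>   1 internal 486.884  2.829509    0           0               200
gs$ground_truth$reference_void_volume
#> [1] 482.4  (independent oracle, A^3)

# opal readthrough
find_opal_readthrough("ATGTGATTTTAA")[c("standard_protein",
                                        "extended_protein")]
#> $standard_protein  "M"
#> $extended_protein  "MUF"
```

The detected internal cavity (mouth count 0, all 200 shell residues
lining) measures 486.9 ± 2.8 Å³ against the oracle's 482.4 Å³ — the two
independent Monte-Carlo routes agree within 1%. The selection profile
recovers the planted hotspots among the 31 positively scored columns,
and the opal codon of the toy CDS is decoded as Sec (`U`) up to the
second stop.

The full pipeline (ASR → selection → cavities → lineages → overlay) runs
from files via `run_pipeline(pipeline_config(...))` or the thin CLI
wrapper in `inst/scripts/hyscav`; `write_fixture_bundle()` produces a
complete on-disk study (FASTA/Newick/PDB/TSV plus a checksum manifest).

## Layout

```
R/                  implementation (one file per stage)
tests/testthat/     unit, property and end-to-end verification suites
scripts/acceptance.R   headline-quantity reproduction script
vignettes/methods.Rmd  the full methods description
inst/scripts/hyscav    command-line wrapper
```
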