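---
title: "Detecting and grafting heparan sulfate binding sites"
author: "hsgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and grafting heparan sulfate binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsgraft)
```

## The problem

Heparan sulfate (HS) is a long, negatively charged glycosaminoglycan
carried on cell-surface proteoglycans. Proteins bind it electrostatically
through groups of basic residues — arginine, lysine and (weakly, at
physiological pH) histidine. Two geometries recur in characterized
HS-binding proteins:

* **Linear motifs**: contiguous sequence patterns of basic (B) and
  non-basic (X) residues such as `XBBXBX`, `BBBXXBB` or `BBXXXBB`, and the
  short spaced pairs `BB-X-B` and `BB-XX-B`.
* **Spatial clusters**: basic residues far apart in sequence that the fold
  brings together, with charged groups spaced roughly 5–10 Å (a secondary
  ~20 Å spacing is also described for extended sites).

Protein engineers exploit this: a *single point mutation* next to an
existing pair of surface basics can complete a new HS-binding cluster
(neutral→Lys), and mutating the basics of an existing site to a
polar-neutral residue (basic→Gln) removes it. Both directions matter — HS
binding influences cell-surface retention, tissue distribution and renal
handling of small protein drugs such as single-chain antibody fragments,
and engineered variants with added or deleted sites are the standard way
to probe those effects.

`hsgraft` operationalizes this design loop on a user-supplied structure
(typically a homology model): detect sites, screen candidate mutations
against surface and stability constraints, rank them, and verify the
mutant by re-scanning.

## The pipeline and its assumptions

1. **Structure input** (`read_structure()`): PDB or mmCIF; first model
   only; heteroatoms excluded; alternate locations resolved by occupancy.
   All reporting is in *author residue numbering*. Residues missing from
   the coordinates (e.g. a disordered C-terminal tail a modelling server
   declined to build) can be restored from the full-length sequence with
   `reconcile_sequence()`. Such residues are assumed disordered and
   surface-exposed: they participate in sequence-level scanning and are
   eligible for mutation, but never enter distance computations.
2. **Surface gate** (`surface_profile()`): a residue is eligible for
   structure-based detection and design only if it is *on the surface
   with its side chain facing outward*.
3. **Detection** (`scan_model_motifs()`, `find_spatial_clusters()`).
4. **Design** (`propose_introductions()`, `propose_removals()`) and
   **verification** (`verify_design()`), with net-charge bookkeeping
   (`net_charge()`, `mutation_charge_delta()`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (rel. SASA) | 0.20 | exposure gate; common surface-residue convention |
| `probe_radius` | 1.4 Å | water-sized probe |
| `n_points` | 960 | sphere-sampling density per atom |
| short band | 5–10 Å | charged-group spacing of compact sites |
| long band | 18–22 Å | operationalizes the ~20 Å literature spacing |
| `min_anchors` | 2 | anchors an introduction must gain |
| `min_cluster_size` | 3 | members for a "complete" cluster |
| hydrophobic set | I, V, L, F, M, W | never mutated into charged residues |
| `introduce_to_aa` | K | grafted residue (Arg available) |
| `removal_to_aa` | Q | replacement on removal (Asn available) |
| pKa table | Lehninger values | Henderson–Hasselbalch charges |

Design choices behind the less obvious defaults:

* **Exposure is SASA × orientation.** Relative SASA alone admits residues
  whose backbone is exposed but whose side chain points into the core.
  The orientation test asks whether the Cα→side-chain-tip vector makes an
  angle below 90° with the centroid→Cα direction. A centroid test was
  chosen over surface normals because it is robust on small and on
  synthetic models; any angular cutoff here is a convention — the
  published precedents judged "facing outward" by eye in a molecular
  viewer, so no threshold can be reconstructed, only a reasonable one
  chosen.
* **Distances are tip-to-tip**, between charged-group centroids (Lys NZ;
  Arg mean of NH1/NH2/NE; His mean of ND1/NE2), not Cα–Cα: HS contacts
  the charged groups themselves. Missing side-chain atoms fall back to
  Cβ, then Cα, with a flag.
* **The long band is detection-only by default.** Documented single-
  mutation designs use the compact 5–10 Å range; the ~20 Å spacing is
  kept for survey reports but does not drive design unless enabled.
* **Pattern `X` matches any non-basic residue** by default. The
  literature says linker positions *often* consist of neutral residues —
  "often" argues for the permissive reading; a strict mode
  (`x_semantics = "neutral"`) additionally excludes Asp/Glu, and its hits
  are provably a subset of the default's. A fully permissive
  `x_semantics = "any"` (X matches anything, including basics) is also
  available for maximum-sensitivity surveys.
* **Histidine counts as basic by default** (it appears in the classical
  motif definitions) but His anchors are down-weighted to 0.5 in ranking,
  since His is mostly uncharged at pH 7.4; `use_histidine = FALSE` drops
  it entirely.
* **Proline sites are allowed** as introduction positions (exemplar
  designs include a Pro→Lys) but flagged, because the substitution also
  changes backbone flexibility.
* **Introduction tips are projected**, not repacked: a pseudo-tip is
  placed 5.5 Å from Cα along the Cα→Cβ direction (the span of an
  extended lysine). This is a deliberate approximation — no rotamer
  search is attempted — and is the same geometry the fixture generator
  and the verifier use, so the design loop is self-consistent.

## Removal semantics

`propose_removals()` has two modes. `per_site` proposes mutating every
basic member of every targeted site (outside masks and explicit
exclusions). `minimal_set` searches for the smallest mutation set that
*neutralises* every targeted site, where a site counts as neutralised
when **at most one** of its basic members remains basic. The rationale:
every HS-binding element — linear or spatial — requires at least two
cooperating basics, so one surviving basic residue cannot reconstitute
the site; conversely, demanding only that the literal pattern string no
longer matches would under-delete (removing the middle basic of a
B-XXX-B-B motif breaks the string match yet leaves an in-range basic
pair). The exact search enumerates subsets for up to 20 candidate
residues; beyond that a greedy cover is used and flagged. Excluded
residues (e.g. a basic that also anchors a cluster being kept) still
count as "remaining", which is what forces both downstream basics of a
B-XXX-B-B motif into the removal set when its first basic is excluded.

## The synthetic fixture generator

`generate_fixture()` builds minimal structures — backbone N/Cα/C/O, Cβ,
and correctly named charged-group pseudo-atoms — on a line, an ideal
helix, or a sphere shell, and plants (i) a basic pair at a requested
tip–tip distance and (ii) a candidate residue whose *projected* mutant
tip sits at requested distances from both anchors, realised within
0.1 Å and verified by recomputation. Filler positions are leucine, so
the planted candidate is the only introduction-eligible residue; variants
bury the candidate under an occluding atom shell, cover it with a mask,
or make it hydrophobic. `fixture_cluster_motif_removal()` builds a
hairpin-sheet benchmark with a three-membered cluster (an adjacent basic
pair at 42/43 plus a distal anchor at 239, edges 8.0 and 8.9 Å) and a
B-XXX-B-B motif at 239/243/244 whose last residue lies on an unmodeled
tail; a ballast chain of core pseudo-atoms below the sheet gives the
centroid-orientation test an interior to point away from.

What the fixtures emulate: controlled charged-group geometry, burial,
masking, hydrophobicity constraints, disordered tails, author-numbering
bookkeeping. What they do **not** emulate: real side-chain rotamers and
packing, backbone irregularity, solvent structure, or electrostatics
beyond counting charges. Passing the planted-recovery tests therefore
demonstrates that the *decision logic* is correct under its stated
geometric assumptions, not that those assumptions capture every real
surface; on a real homology model the dominant uncertainty is the model
itself (side-chain orientations in homology models are routinely wrong
at the 1–2 Å scale that separates "in band" from "out of band" — a
caveat inherited by every tool of this kind).

## Numerical choices

* SASA uses a deterministic golden-spiral point set, so results are
  exactly reproducible and rotation-invariance holds to sampling
  tolerance. At the 960-point default the per-residue quantisation is
  roughly 2% worst-case (total area agrees to ~0.01%); the invariance
  tests sample at 2000 points, where per-residue agreement is within 1%.
  Boundary ties (a sample point exactly on a neighbour's sphere, as with
  duplicated atoms) are awarded to the earlier atom so a coincident
  sphere counts exactly once.
* Relative SASA divides by the Tien et al. (2013) theoretical maxima.
  A table computed by the package's own engine on idealised tripeptides
  was considered and rejected: with minimal side-chain representations it
  would be representation-dependent, while the published theoretical
  table is convention-stable. `relative_sasa()` accepts any reference
  table for users who prefer a different convention. Values above 1
  (distorted geometries) are clamped at 1.2.
* Ranking is deterministic: score = anchor count (His = 0.5) +
  0.1 × relative SASA + 0.05 × in-band pairs created; ties break by
  ascending author number. The score is a constructed heuristic — no
  published screen exists to calibrate it against — so it is kept simple
  and monotone in the quantity that matters most (anchors gained).
* Degenerate inputs: Gly orientation defaults to outward; a residue
  without Cα is "orientation undetermined", reported unexposed with a
  flag; Cα=Cβ coincidence is a hard error for tip projection; empty
  structures, empty pattern lists and pH outside [0, 14] are errors;
  a structure with no basic residues yields empty (not failing) reports.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: 1000 random sequences
(length ≤ 200) against an independent regex oracle for the scanner; 200
random site clouds (≤ 50 sites) against a brute-force union-find oracle
for the cluster finder; 100 seeded planted fixtures (~24 residues) for
design recovery, plus buried/masked/hydrophobic spoiler variants; and the
246-residue hairpin benchmark for removal design. These sizes give full
coverage of the combinatorics while keeping a complete run in the
low minutes on one CPU.

## Known limitations

* No ΔΔG / stability prediction: the hydrophobicity rule is a guard, not
  an energy model.
* No rotamer search: projected tips assume an extended side chain.
* No structure-aware pKa shifts (His protonation is environment-sensitive
  in real proteins).
* Masks and exclusions are the only functional-site awareness; the tool
  does not know where a receptor epitope is unless told.
* Insertion codes and multi-model ensembles are rejected rather than
  interpreted.
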