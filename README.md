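# hsgraft

Detection and grafting of heparan sulfate (HS) binding sites on protein
structures.

HS chains are negatively charged glycosaminoglycans on cell surfaces;
proteins bind them through groups of basic residues (B = Arg/Lys/His),
either as **linear motifs** — sequence patterns such as `XBBXBX`,
`BBBXXBB`, `BBXXXBB`, `BB-X-B`, `BB-XX-B` — or as **spatial clusters**:
surface-exposed basics whose charged groups the fold brings within
~5–10 Å (or ~20 Å for extended sites). Engineering these sites in or out
with single point mutations is the standard way to probe and tune
HS-dependent behaviour (cell-surface retention, renal handling) of small
protein drugs such as single-chain antibody fragments.

`hsgraft` is a design tool for that loop, aimed at protein engineers
working from a (homology-)modelled structure:

* **Detect**: linear motif scan on the sequence
  (`scan_model_motifs()`) and spatial cluster search over exposed basic
  residues with tip-to-tip distances in configurable bands
  (`find_spatial_clusters()`), gated by a deterministic Shrake–Rupley
  SASA engine plus a side-chain orientation test (`surface_profile()`).
* **Design**: `propose_introductions()` finds exposed, unmasked,
  non-hydrophobic positions where a projected lysine tip completes a
  cluster (neutral→K); `propose_removals()` proposes basic→Gln sets, per
  site or as a provably minimal set. Masked regions (e.g. antibody
  variable domains) and charged↔hydrophobic swaps are never touched.
* **Verify and account**: `verify_design()` re-scans the mutant;
  `net_charge()` / `mutation_charge_delta()` do Henderson–Hasselbalch
  charge bookkeeping.
* **Test without downloads**: `generate_fixture()` builds synthetic
  structures with planted binding-site geometry (realised within 0.1 Å)
  and known ground truth.

## Worked example

Plant a Lys–Lys pair 6 Å apart next to a serine whose projected mutant
tip would sit 6.5 and 7 Å from the two anchors, then ask the package to
find the design:

```r
library(hsgraft)
fx   <- generate_fixture(seed = 3)        # 24-residue sphere-shell fixture
surf <- surface_profile(fx$model)         # SASA + orientation gate
find_spatial_clusters(fx$model, surf, use_long = FALSE)
#> hs_clusters: 1 cluster(s) over 2 exposed basic site(s)
#>   C1 [incomplete, 2 members]: K5 K8

pr <- propose_introductions(fx$model, surf)
pr[, c("mutation", "kind", "n_anchors", "anchor_detail", "score")]
#>   mutation      kind n_anchors   anchor_detail   score
#> 1     S13K introduce         2 K5:6.50;K8:7.00 2.19014

verify_design(fx$model, pr)
#> hs_verification: all proposals verified (net charge delta +1.00)
#>   mutation      kind verified              note
#> 1     S13K introduce     TRUE in C1 (3 members)
```

Reading the output: the two planted lysines form an *incomplete* cluster
(a pair is one mutation short of the 3-member default). The only
eligible surface position is the serine; mutating it to lysine (`S13K`)
gains 2 anchors at 6.50 and 7.00 Å — inside the 5–10 Å band — and the
verifier confirms the mutant now carries a complete 3-member cluster,
raising the net charge by +1.

Removal works the same way in reverse: on the shipped hairpin benchmark
(`fixture_cluster_motif_removal()`), per-site removal of the detected
cluster proposes `K42Q, K43Q`, and minimal-set removal of the
B-XXX-B-B motif at 239/243/244 — with K239 excluded because it anchors
the cluster being kept — returns exactly `K243Q, R244Q`.

A thin command-line wrapper is installed as `exec/hsgraft` with
subcommands `scan`, `design-add`, `design-remove`, `charge` and
`fixture` (exit codes: 0 ok, 2 bad input, 3 no proposal, 4 verification
failure).

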