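---
title: "Detecting alpha-strand backbone conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpha-strand backbone conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(alphastrand)
library(dplyr)
```

## The alpha-strand motif

The alpha-strand is an atypical backbone conformation implicated in the
early, toxic stages of amyloid aggregation -- notably of the
amyloid-beta 1-42 peptide of Alzheimer's disease, where the central
region V24-G25-S26 adopts it transiently before oligomers pair strands
into alpha-sheets. Unlike a helix or a beta-strand it does not occupy
one Ramachandran basin: successive residues alternate between the
right-handed (alpha_R) and left-handed (alpha_L) helical quadrants, so
main-chain carbonyls line up along one edge of the strand and amide NH
groups along the other, producing two oppositely polarised interfaces.

The operational definition is deliberately coarse and sign-based. A
residue is

* **alpha_R** ("R") when -180 < phi < 0 and -180 < psi < 0,
* **alpha_L** ("L") when 0 < phi < 180 and 0 < psi < 180,
* **other** ("O") for every remaining defined pair, and
* **undefined** ("U") when either dihedral does not exist (chain
  termini, chain breaks, degenerate geometry).

An alpha-strand is then a run of at least three successive residues
whose states strictly alternate R/L (either phase). The inequalities
are strict: a dihedral exactly on 0 or +/-180 is a measure-zero boundary
and maps to "O", never to an alpha state, so a strand can never hinge on
a boundary value. We do not define a beta region -- transitions are
reported as state changes into R or L from "O" -- because the sign rule
is the only numerically specified boundary and inventing beta bounds
would add a free parameter the detection does not need.

## From coordinates to states

Torsions are computed with the two-plane-normal atan2 formula under the
IUPAC convention (cis = 0, trans = 180), reported in (-180, 180]. phi(i)
uses C(i-1)-N(i)-CA(i)-C(i), psi(i) uses N(i)-CA(i)-C(i)-N(i+1). Two
numerical conventions matter:

* **Degeneracy.** If either atom triple of a torsion is collinear
  (cross-product norm below 1e-9) the torsion is undefined rather than
  numerically arbitrary.
* **Chain breaks.** A consecutive residue pair whose C-N distance
  exceeds 2.5 Angstrom (about twice a peptide bond) is a break; the
  dihedrals across it are undefined. A pure numbering gap with intact
  geometry does not sever the chain, but is still reported by
  `chain_breaks()`. Author residue numbering is authoritative
  throughout, so "region 24-26" always means author numbers 24-26.

Note that the torsion is *invariant* under reading the four atoms in
reverse order -- chi(ABCD) = chi(DCBA) -- while a mirror reflection of
the coordinates flips its sign; the test suite pins down both
identities against an independently coded projection oracle.

```{r states}
bb <- ideal_alpha_strand("VGSNK", start_res = 24)
residue_states(bb) |> select(res_seq, aa, phi, psi, state)
```

## Scanning structures

`find_alternating_runs()` reports every *maximal* alternating run of a
minimum length (default 3); `match_anchored()` asks whether an exact
residue window spells an exact pattern, the formulation in which
per-region strand counts are defined; `scan_structure()` enumerates
every model and chain, optionally restricted to a one-letter sequence
motif such as `"VGS"`. Generic runs accept either start state, but
region-24-26 analyses conventionally require the first residue to be
alpha_R, matching the alpha_R-alpha_L-alpha_R notation of the motif.
Maximal runs cannot overlap; motif-restricted windows are reported
individually, overlaps included, because an occurrence census counts
windows, not runs.

```{r scan}
scan_structure(bb, motif = "VGS", required_start = "R")
```

## Trajectories: counts, appearance times, flips

`state_matrix()` turns per-frame dihedral tables (the whitespace
`phi psi label` dialect of trajectory dihedral extractors, read by
`read_dihedral_table()`) into a frames x residues state grid.
`window_summary()` then computes, for an anchored window and pattern:

* `frame_count` -- the number of recorded frames in which the window
  matches. This is the meaning of "number of alpha-strands" for a
  region over a trajectory: totals of order 10^3 against 25,000
  recorded frames (50 ns at 2 ps) are per-frame tallies, not distinct
  events;
* `event_count` -- maximal runs of consecutive matching frames, i.e.
  distinct formation events, so both readings of a per-region count are
  available;
* `first_appearance_ps`/`_ns` -- the earliest matching frame time
  (reported in ns as well, the natural axis for 50-ns runs), with an
  explicit `NA` when the window never matches;
* `occupancy_fraction` -- `frame_count / n_frames`.

Because the windows nest (24-26 is a prefix of 24-27 of 24-28), the
counts are monotone non-increasing and the first-appearance time
monotone non-decreasing as the pattern lengthens -- the structural
analogue of the printed per-region orderings in the reference
simulations.

A peptide-plane flip is the concerted rotation of a rigid CO-NH unit:
psi(i) and phi(i+1) change together while phi(i) and psi(i+1) stay
put. No published numeric rule exists for it, so `detect_flips()`
adopts a thresholded concerted-change criterion: circular
|delta psi(i)| and |delta phi(i+1)| at least `theta_deg` (default 90
degrees -- the scale of a quadrant crossing) with both neighbour deltas
below `neighbor_theta_deg` (default 90). Differences are circular
through +/-180, so -45 to 150 is a 165-degree rotation. The default
comparison is frame-to-frame; `compare = "vs_initial"` reproduces the
initial-vs-first-strand superposition view.

## Mining structure collections

`mine_collection()` batch-scans a directory: entries without amino-acid
residues (nucleic-acid-only files) are excluded from the census,
unreadable entries are logged as skipped without aborting the batch,
and every model and chain is scanned independently. One *occurrence* is
one matching window in one (model, chain); one *structure-with-hits* is
an entry with at least one occurrence -- a multi-model NMR entry can
therefore contribute many occurrences, which is why occurrence totals
exceed structure totals in method-stratified censuses. Reports are
deterministic, merge additively over disjoint directories
(`combine_reports()`), and carry an auditable skip log. Archive-scale
censuses are supported but inherently snapshot-dependent; their totals
drift with database version.

## Synthetic data: what it emulates, and what it does not

All tests run on synthetic inputs built by the package itself.

**Backbones.** `build_backbone()` places N, CA, C, O sequentially by
internal coordinates (NeRF) with standard peptide geometry (N-CA 1.458,
CA-C 1.525, C-N 1.329 Angstrom; angles 111.2/116.2/121.7 degrees; O in
the carbonyl plane trans to the next N). Only dihedral signs matter
downstream, so these constants affect realism, not classification.
Requested phi/psi are reproduced on re-measurement to well below the
0.5-degree documented tolerance; atom pairs closer than 0.5 Angstrom
(impossible geometry) are rejected. The canonical quadrant-interior
dihedrals are (-60, -45) for alpha_R and (60, 45) for alpha_L -- any
interior values are equivalent under the sign rule; these sit away from
boundaries for numerical robustness. `ideal_alpha_strand()` adds one
glycine cap per end continuing the alternation, because a bare terminus
has an undefined dihedral and would otherwise hide the first and last
named residues from the scanner; the caps themselves are the undefined
termini, so the single maximal run spans exactly the named residues.

**Trajectories.** `simulate_states()` is a statistical stand-in for an
MD trajectory, not a physical model: each flip-able residue carries an
independent two-state Markov chain between its baseline quadrant and
the flipped one, with per-frame transition probabilities. Defaults
emulate the high-temperature reference condition: 25,000 frames at 2 ps
(a 50-ns run) over V24-K28 with baseline RLRLR and rates
(on 0.012, off 0.008 per frame) giving 40% per-residue baseline
occupancy and hence roughly 6-7% RLR-window occupancy, the order
observed in the reference high-temperature simulations; chains start
flipped so the strand is absent initially and first appears
stochastically. What the simulator does *not* reproduce: inter-residue
coupling, temperature or pH dependence, sequence effects, or any real
free-energy surface -- so passing tests demonstrate correct counting,
kinetics bookkeeping and recovery on known ground truth, not fidelity
to real ensembles. Planted windows override sampled states in listed
frames, and the manifest records the resulting per-frame matches by
direct comparison inside the generator, independent of the analysis
path being tested.

**Collections.** `plant_collection()` writes mini PDB collections with
exact ground truth: hit entries embed an alternating motif window in
beta-like (-120, 130) context (one occurrence per model), decoys carry
the same sequence uniformly beta-like, and X-ray/NMR records alternate
so stratification is exercised. Files are bit-reproducible per seed.

```{r sim, fig.alt = "state matrix heatmap"}
sim <- simulate_states(n_frames = 5000, seed = 7)
ws <- window_summary(sim$states, 24:26, "RLR")
glance(ws)
autoplot(sim$states)
```

## The simulation-campaign manifest

The package ships a transcription of the 39-system MD campaign the
method was developed on (three NMR starting structures of amyloid-beta
1-42; wild type and six point mutants; 310 and 498 K; neutral and low
pH; 50 ns each) plus the wild-type 42-residue sequence.
`load_manifest()` validates every row (temperatures in {310, 498} K,
low-pH rows with anionic counter ions, known variant labels) and
`aggregate_run_time()` reproduces the campaign's 1950 ns total. The
shipped sequence must pass the V24-G25-S26-N27-K28 checkpoint at load
time; `apply_variant()` applies single point mutations (e.g. `"G25P"`,
which destroys the VGS motif) and errors on re-application.

```{r manifest}
m <- load_manifest()
aggregate_run_time(m)
count(m, temperature_K, ph_class)
```

## Problem sizes and design choices

The test suite and the reproduction script run entirely on synthetic
data at desk scale, chosen to exercise every guarantee without waste:
1,000 random quadruples for the torsion oracle, 200 random backbone
specs for the build-measure round trip, 10,000 random state strings for
the scanner-vs-brute-force equivalence, one 25,000-frame trajectory at
the default condition plus 2,000-frame planted trajectories, and ten
8-entry planted collections. The headline numbers of the reference
study itself (per-region strand counts from 50-ns MD runs; a
207-structure, 464-occurrence archive census from a 2019 snapshot) are
not recomputable from a desk-scale package -- they require the original
trajectories and archive state -- which is exactly why the validation
strategy is property-based recovery on planted ground truth plus the
in-manifest worked example.

Known limitations: no alpha-sheet *pairing* detection (the
hydrogen-bonded association of strands is out of scope; only strands
are detected), no hydrogen-bond-based secondary-structure assignment,
no binary trajectory formats (multi-model coordinate files and dihedral
tables only), and no structure-level mutagenesis (variants act on
sequences and fixture generation).
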