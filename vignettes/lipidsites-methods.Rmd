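---
title: "Methods: protein-lipid contacts, helix tilt and lipid site-transition networks"
author: "lipidsites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-lipid contacts, helix tilt and lipid site-transition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsites)
```

## What the package computes

`lipidsites` analyses coarse-grained (CG) molecular dynamics
trajectories of a transmembrane helix bundle — prototypically a GPCR
such as the mu opioid receptor — embedded in a phospholipid bilayer.
In the MARTINI-style CG description each lipid is 12-13 beads (a
choline/ethanolamine head, one phosphate, two glycerol beads and two
acyl chains; the `D3B` bead marks a chain-B unsaturation) and the
protein is reduced to roughly one backbone bead per residue. The
package quantifies four things:

1. **Contacts.** A contact is a (protein bead, lipid bead) pair at
   minimum-image distance strictly below a cutoff, 0.5 nm by default.
   Counts are accumulated per frame and keyed by (residue, lipid
   species, lipid bead name), so one residue-lipid pair can contribute
   several bead contacts in a frame. Per-residue totals normalised to
   the most-contacted residue give the 0-100% contact-frequency map.
2. **Geometry.** Frames are superposed on the reference structure by
   least-squares (Kabsch) rotation over all protein beads; per-helix
   RMSD is then measured without refitting. Helix tilt uses a
   four-residue sliding window yielding local axes whose maximal angle
   to the membrane normal is the helix's tilt; kinked helices are
   additionally split into pre- and post-torsion-zone segments.
3. **Membrane descriptors.** Area per lipid (lateral box area over the
   larger leaflet's lipid count) and bilayer thickness (distance
   between mean phosphate planes).
4. **Site-transition networks.** For every lipid in contact with the
   protein at least 20% of the time, each frame is labelled with the
   set of helices the lipid touches (e.g. `"167"` = H1+H6+H7); runs of
   identical labels are collapsed so the sequence records movements
   between sites. Pooled per leaflet, the collapsed paths define a
   weighted graph — nodes are sites weighted by visits, edges are
   transitions — clustered with the Louvain method.

## Model assumptions and parameter choices

* **Cutoff (0.5 nm, strict `<`).** The conventional CG bead-contact
  criterion. The package also evaluates 0.6 and 0.7 nm and reports the
  Spearman rank agreement of the resulting frequency maps; relative
  contact profiles are expected to be stable across this range, and
  the boundary convention is immaterial because equality has measure
  zero in floating-point trajectories.
* **Occupancy threshold (0.20, inclusive).** A lipid enters the
  network analysis when it contacts the protein in at least 20% of
  frames. The boundary is inclusive: exactly 20% is retained.
* **Leaflet assignment** uses the phosphate bead as the per-lipid
  anchor (the one unambiguous reference bead in the head group) and is
  computed once per trajectory from a reference frame (frame 1 by
  default), because the network analysis treats each lipid as
  belonging to one leaflet throughout. Lipids whose frame-by-frame
  side of the per-frame midplane disagrees with that assignment in
  more than 10% of frames are reported as possible flip-flops.
* **Tilt reference axis** is the box z axis (the membrane normal for
  bilayers built in the xy plane). Reported values are the mean over
  frames of the per-frame maximum window tilt, folded into [0, 90]
  degrees since tilt carries no sign.
* **Louvain resolution (0.8).** The clustering runs
  `igraph::cluster_louvain` on the transition-count-weighted graph at
  resolution 0.8. We read the conventional "modularity coefficient
  0.8" phrasing of network workflows as this resolution parameter —
  it is the only free coefficient of the method — and expose it as a
  plain argument; node order is fixed by canonical label sort and the
  RNG is seeded, so assignments are reproducible.
* **Edges are undirected by default** (transition counts symmetrised),
  since a lipid transfer frequency between two sites is naturally
  symmetric; `directed = TRUE` preserves the direction of travel.
* **Units.** Coordinates are nm internally (cutoffs are quoted in nm);
  RMSD, area per lipid and thickness are reported in angstrom-scale
  units as is conventional for structural tables. PDB and DCD files
  are angstrom-native and converted on read; GRO is nm-native.

## The local-axis construction

For a window of four consecutive backbone beads
\(P_1 \dots P_4\), the two interior bisectors
\(v_i = (P_{i-1}-P_i) + (P_{i+1}-P_i)\) point from the helix surface
towards its axis and are perpendicular to it on an ideal helix, so
\(v_2 \times v_3\) is parallel to the local axis. This construction is
exact for an ideal helical spiral of any radius, pitch and phase. A
principal-component direction was rejected: with a CG backbone spiral
of radius ~0.23 nm and rise 0.15 nm, a four-bead window has in-plane
variance comparable to its axial variance, so the leading PC can point
tens of degrees away from the true axis. For (near-)collinear windows
the bisectors vanish and the window chord is used instead, which is
exact for straight segments; axes are sign-aligned along increasing
residue order. Smoothing splines, used by visualisation tools built on
the same sliding window, change only the rendering, not which window
attains the maximal tilt, and are not applied.

Sub-segment tilts of a kinked helix are evaluated on the residues up
to `kink_begin` and from `kink_end` onwards; residues strictly between
the two bounds (the torsion zone, e.g. 241-243 for the default H5
240/244 bounds) belong to neither segment.

## The synthetic-data generator

No reference trajectories are distributable with the package, so every
stage is validated on generated fixtures with planted ground truth.
The generator emulates the geometry of the study system, not its
physics:

* A static ring of 8 ideal helices (ring radius 1.5 nm, spiral radius
  0.23 nm, rise 0.15 nm/residue, twist 100°/residue) spanning the
  bilayer, one backbone bead per residue over the standard mu-opioid
  helix ranges (H1 65-95 ... H8 341-352); short helices such as H8 are
  centred at the internal leaflet, as an intracellular helix.
  Per-helix tilts and post-kink bends are applied as configured.
* Two leaflets of rigid 12/13-bead lipids: 300 per leaflet by default
  (a 600-lipid membrane), phosphate planes at ±21 Å (the 42 Å
  thickness of a POPC bilayer; 38 Å would be typical for DPPC), and a
  lateral box fixed by the planted area per lipid of 65 Å² — a
  realistic bilayer density, which is what the recovery tests must
  reproduce. Bead z-offsets stack head-phosphate-glycerol-tails
  towards the midplane; each lipid carries a fixed random azimuth and
  a small fixed vertical jitter (sd 0.5 Å).
* Lipid centres perform lateral 2D Gaussian random walks
  (sd 0.06 nm/frame) with periodic wrapping, excluded from a 0.45 nm
  disk around each helix axis and from the bundle core. Leaflets never
  exchange and lipids are kinematic — there are no forces, no
  thermostat and no tail flexibility; the generator's purpose is
  exercising analysis code against known truth, not physical realism.
* **Planted residence sites.** A site such as `"67"` has an anchor on
  the corresponding helix face; within a 0.8 nm shell of the anchor
  the step sd is divided by the *square root* of the configured
  affinity multiplier. The stationary density of a kinematic walk with
  space-dependent step scales as the inverse square of the step, so
  this makes time-averaged residence in the shell scale approximately
  linearly with the multiplier — dividing by the multiplier itself
  would plant a quadratic enrichment. Collapsed visit weights at the
  biased face are enriched as well, but their face-to-face statistics
  are heavy-tailed at desk scale (visits are bursty), so quantitative
  recovery tests use shell residence, and the qualitative test asserts
  that the planted face is the top-weight network node.

What passing these tests does *not* show: the generator has rigid
lipids, a rigid protein, instantaneous uncorrelated steps and
perfectly flat leaflets, so agreement on fixtures cannot certify
behaviour on real trajectories with undulations, protein flexibility,
tail entanglement or lipid flip-flop. The file readers and the
contact/geometry kernels are exercised on the real formats, which is
what transfers.

## Numerical choices and degenerate inputs

* Contact search uses a cell grid, contractually identical to the
  all-pairs scan (asserted by test against an independent brute-force
  oracle); cutoffs above half the smallest box length are rejected
  (minimum-image violation), as are triclinic boxes.
* Superposition requires at least 3 non-collinear beads; the rotation
  is forced proper (determinant +1) via the SVD sign correction.
* An all-zero contact table maps to an all-zero frequency map with a
  warning; an empty path list yields an empty network; a single-node
  network gets one cluster and modularity 0; a zero-frame trajectory
  flows through every stage as an empty result.
* Frames where a retained lipid touches no helix are gaps: they
  neither emit a site nor break a run of identical labels. Breaking
  runs on every brief detachment would inflate self-transitions.
* Loop and terminal residues never enter site labels (nodes are helix
  combinations), but their contacts are fully counted in the contact
  tables and frequency maps.
* Replicate runs are pooled (counts summed, paths concatenated) before
  normalisation and network construction; per-run tables are also
  written for error bars.

## Problem sizes used in the validation suite

The test suite and the acceptance script regenerate all inputs at run
time. Module tests use 60-lipid bilayers of tens of frames; the
statistical recovery checks use the full 600-lipid membrane at 300-5000
frames, with the planted-site recovery repeated over 40 seeds and the
face-symmetry check over 20 seeds. These sizes were chosen so the
statistical assertions have adequate power while a complete validation
run stays in the minutes range on one CPU.

## Known limitations

* XTC trajectories are not read; use DCD or multi-frame GRO. PDB
  structures must be single-frame and orthorhombic.
* Per-helix RMSD is evaluated after one global fit (no per-helix
  refit), so it includes rigid-body displacement of the helix within
  the aligned receptor frame; the global value therefore bounds the
  helix-local fit from above.
* Area per lipid does not subtract the protein cross-section; in
  protein-containing systems the value is biased upward relative to a
  protein-free membrane at equal lateral density.
* CG beads are treated equally (no mass weighting) throughout.

## A compact worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_frames = 300,
                        site_affinity = c("67" = 5))
fx <- generate_cg_trajectory(cfg, seed = 1)
lf <- assign_leaflets(fx$system, fx$trajectory)

summary(membrane_summary(fx$trajectory, fx$system, lf))
frequency_map(accumulate_contacts(fx$trajectory, fx$system))
nets <- site_transition_network(fx$trajectory, fx$system, leaflets = lf)
nets$external
```
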