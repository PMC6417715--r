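# lipidsites

Analysis of protein–lipid interactions in coarse-grained (CG) membrane
simulations: contact counting and frequency mapping, helix-tilt
measurement by sliding-window local axes, bilayer descriptors, and
lipid **site-transition networks** — a graph view of how annular lipids
move between binding sites on a transmembrane helix bundle.

## Who it is for

Computational structural biologists analysing MARTINI-style CG
trajectories of membrane proteins (prototypically GPCRs such as the μ
opioid receptor) in phospholipid bilayers (POPC, DPPC, POPE), who want
reproducible, tested implementations of the standard per-residue
contact analyses plus the network description of lipid site exchange.

## The methods at the core

* **Contacts.** A contact is a protein-bead/lipid-bead pair with
  minimum-image distance d < c on the orthorhombic box, c = 0.5 nm by
  default (0.6 and 0.7 nm evaluated for rank stability). Counts are
  keyed by (residue, lipid species, lipid bead name); the per-residue
  contact-frequency map is 100 × nᵢ / maxⱼ nⱼ.
* **Superposition & RMSD.** Least-squares (Kabsch) rotation of every
  frame onto the reference over all protein beads; per-helix RMSD is
  then measured without refitting.
* **Helix tilt.** A 4-residue sliding window yields local helix axes
  (exact bisector-cross construction for ideal helices); the reported
  tilt is the per-frame maximum angle to the membrane normal, folded
  into [0°, 90°]. Kinked helices (H5, torsion zone 240–244) are also
  split into pre-/post-kink segments.
* **Site networks.** Each lipid in contact ≥ 20% of the time gets a
  per-frame label: the set of helices within the cutoff, written as
  ascending digits ("167" = H1+H6+H7). Runs of identical labels are
  collapsed; the collapsed paths, pooled per leaflet, define a
  weighted graph (nodes = sites by visit weight, edges = transitions)
  clustered with Louvain at resolution 0.8.
* **Membrane descriptors.** Area per lipid = LxLy / (larger leaflet
  count); thickness = distance between mean phosphate planes.

A seeded synthetic-bilayer generator (600 rigid 13-bead lipids around
a static 8-helix ring, lateral random walks with planted residence
sites) provides ground truth for every stage; see the methods
vignette (`vignettes/lipidsites-methods.Rmd`).

## Worked example

```r
library(lipidsites)

cfg <- generator_config(n_frames = 2000, site_affinity = c("67" = 5))
fx  <- generate_cg_trajectory(cfg, seed = 1)
lf  <- assign_leaflets(fx$system, fx$trajectory)

fx$system
#> Coarse-grained system: 8021 beads
#>   lipid      7800 beads
#>   protein     221 beads
#>   lipids: POPC x 600
#>   box: 13.964 x 13.964 x 9.000 nm

summary(membrane_summary(fx$trajectory, fx$system, lf))
#>            quantity     mean sd
#> 1 area_per_lipid_A2 65.00000  0
#> 2       thickness_A 41.96833  0

fm <- frequency_map(accumulate_contacts(fx$trajectory, fx$system))
head(fm[order(-fm$frequency_pct), ], 3)
#>     residue_id residue_name helix count frequency_pct
#> 153        277           BB     6  9357     100.00000
#> 157        281           BB     6  8715      93.13883
#> 145        254           BB     5  7942      84.87763

site_transition_network(fx$trajectory, fx$system, leaflets = lf)$internal
#> Site-transition network (internal leaflet): 16 sites, 24 undirected transitions
#>   top sites: 7 (103), 67 (97), 6 (84), 5 (59), 4 (57)
#>   3 communities, modularity 0.502
```

The planted values are recovered: the bilayer was built at 65 Å² per
lipid and a 42 Å phosphate separation, and the membrane summary
returns exactly those numbers (thickness within the per-lipid jitter).
The frequency map peaks on H6/H5/H7 residues and the "67" site carries
a large visit weight in both leaflets — the residence affinity of 5
planted on the H6/H7 face. Pooled over both leaflets, "67" is the
top-weight node; at the full validation scale (5000 frames) this
recovery holds in ≥ 95% of seeded runs.

Structures and trajectories can also be read from disk
(`read_system()` for PDB/GRO, `read_trajectory()` for DCD/multi-frame
GRO), and `run_pipeline(run_config(...))` executes all six stages and
writes TSV/CSV/GEXF outputs plus a JSON manifest. A thin CLI wrapper
lives at `inst/cli/lipidsites.R`.

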