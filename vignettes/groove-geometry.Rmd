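---
title: "Minor groove geometry: models, measurements and assumptions"
author: "grooveDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minor groove geometry: models, measurements and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grooveDNA)
```

## The problem

The width of the DNA minor groove varies with sequence, and proteins that
read DNA shape — prominently the bacterial nucleoid-associated protein Fis,
whose dimer places two helix-turn-helix recognition helices into adjacent
major grooves only ~20 A apart — require a strongly compressed central
minor groove to bind. A/T-rich centers compress readily; G/C centers
resist. The structural determinant is the exocyclic purine 2-amino (N2)
group on the floor of the minor groove: guanine carries it, adenine does
not, and the base analogs inosine (guanine minus N2) and 2-aminopurine
(adenine with an amino group moved to the guanine N2 position) let the
group be added or removed without changing anything else about a sequence.
This package implements the complete analysis chain for studying that
mechanism: helical-parameter analysis of structures, rebuilding of
coordinates from parameters, groove-width measurement, steric-clash
analysis of N2 groups in compressed models, and distribution statistics
over trajectory-derived groove widths.

## The rigid-body model of DNA

Each base is described by the standard reference frame: idealized base
geometries (embedded constants; planar rings, x pointing from the minor-
toward the major-groove edge, y toward the backbone) are superposed onto
the observed base atoms by least-squares rigid fitting (`fitBaseFrame()`;
rotation + translation, never scaling or reflection; the fit RMSD is
always reported). The inosine template is the guanine template with N2
deleted; the 2-aminopurine template is the adenine template with N6
deleted and an N2 added at the guanine N2 position — the analogs are
*defined* by presence or absence of the exocyclic groups.

Two paired bases (the strand-2 frame has its y and z axes reversed to
account for the antiparallel strand) combine into a base-pair frame, and
the six intra-base-pair parameters (shear, stretch, stagger / buckle,
propeller, opening) are the rigid-body parameters between the two base
frames, decomposed through their mid-frame: the bend angle is split
symmetrically by half-rotation interpolation, the twist-like component is
measured about the shared z axis, and translations are expressed in the
mid-frame. The same decomposition applied to consecutive pair frames
yields the six base-pair-step parameters (shift, slide, rise / tilt,
roll, twist). This mid-frame construction is chosen because its build
direction is an exact closed-form inverse: `buildDuplex()` followed by
`parameterTable()` returns the input parameters to 1e-6 or better, a
property the test suite asserts on a thousand random parameter sets.

Sign conventions are anchored twice: twist is positive for right-handed
B-DNA (~36 deg), and propeller is negative for A-tract-like pairs
(rotating the strand-2 base by -15 deg about the pair long axis yields
propeller = -15).

## Rebuilding coordinates, and what the models contain

`buildDuplex()` chains pair frames from an identity start (global
placement is arbitrary; every quantity the package measures is invariant
under rigid motion, which the tests assert), splits each pair by its
intra-pair parameters, and places base atoms from the templates.
`buildMeanDuplex()` takes per-step parameters from the embedded mean
dinucleotide table — the crystallographic survey averages of the ten
unique dinucleotide steps, with complementary steps obtained by negating
tilt and shift — and zero intra-pair deformation. Analog bases use the
step means of the canonical purine they derive from (I as G, 2AP as A),
since the survey table is defined for canonical steps only and the
analogs differ from their parents exactly and only by the exocyclic
groups.

Rebuilt nucleotides carry a rigid phosphate group (P, OP1, OP2) placed in
the base frame; sugars are not modelled. This is a deliberate
approximation: every quantity measured downstream — groove widths,
N2-centered clash scans, Watson-Crick hydrogen-bond lengths — depends
only on base atoms and phosphorus, and no reliable idealized B-form sugar
geometry would add information. The phosphorus sits at the fiber-model
helix radius (8.91 A); its azimuth and axial offset in the base frame
were calibrated once, jointly against canonical B-DNA groove widths
(minor ~5.8 A, major ~11.6 A under the convention below) and the
published 7.1 A center width of a mean-parameter model of the
G/C-centered binding site. The calibrated values (azimuth 80.609 deg,
axial offset -2.647 A) are frozen constants; they were not revisited
afterwards.

## Groove widths

`grooveProfile()` implements the phosphate-distance convention: the width
at a position is the smallest cross-strand P-P distance, minus 5.8 A
(2.9 A per phosphate group, the standard phosphate-group van der Waals
radius), among phosphate pairs whose index offset falls in a window
(defaults: offsets 2..5 for the minor groove, -7..-2 for the major
groove, with the offset counted as strand-1 index minus strand-2 index
and the pair assigned to the midpoint of the two indices). The default
windows coincide with the geometric minima of ideal B-DNA: on a 36 deg /
3.38 A helix the closest minor-groove pair sits at offset 4 and the
closest major-groove pair at offset -2. Positions where a 5'-terminal
residue lacks its phosphate are reported `NA`, never extrapolated.
Profiles equal an exhaustive all-pairs scan (asserted in the tests), are
invariant under rigid motion and under strand relabelling, and on
mean-parameter B-DNA the minor groove is narrower than the major groove
at every interior position.

One convention serves crystal structures, rebuilt models and trajectory
frames alike. No curvilinear-helical-axis (spline) width is computed;
where published values were derived with a different convention,
comparisons should allow a few tenths of an Angstrom.

## Compressed models and 2-amino clashes

`makeCompressedDuplex()` produces duplexes with a centrally compressed
minor groove by a deterministic amplitude search over a smooth central
perturbation of exactly the parameters that carry compression:
overtwisting, negative roll and negative slide (a Gaussian envelope of
sd 2 steps around the center; per unit amplitude +4 deg twist, -5 deg
roll, -0.6 A slide at the center; bisection until the center width is
within 0.1 A of target). `reconstructPartial()` demonstrates the
sufficiency of those three parameters directly: rebuilding a duplex that
keeps only twist, roll and slide of a compressed reference — all other
step parameters refilled from the mean table, intra-pair set to zero —
reproduces the central compression almost quantitatively.

`compressedClashModel()` builds a named sequence variant at the geometry
of the high-affinity bound site (center width 3.9 A, central propeller
-15 deg — the published central means of that complex). `findClashes()`
then reports atom pairs closer than the sum of their van der Waals radii
(C 1.70, N 1.55, O 1.52, P 1.80 A) minus a tolerance, excluding
same-residue pairs and the Watson-Crick donor/acceptor pairs of each
base-pair type, over base atoms plus phosphorus.

Tolerance deserves a word. The default 0.4 A follows standard heavy-atom
clash practice, where it absorbs contacts mediated by apolar hydrogens.
Amino-group contacts are the opposite case: an N-H...X overlap occurs at
heavy-atom separations around 2.9-3.2 A — *below* the radii sum but
*above* the radii sum minus 0.4 — so subtracting the allowance masks
precisely the contacts the 2-amino analysis looks for. N2-focused scans
should therefore run at `tolerance = 0`. At that setting the compressed
G/C-centered model shows all three central N2 groups in steric clashes
with exocyclic groups of paired or diagonally apposed bases, the
2-aminopurine variant behaves identically, and the inosine variant — no
N2 anywhere in the center — shows none. Uncompressed mean-parameter
B-DNA shows no N2 clashes at any tolerance and is entirely clash-free at
the 0.4 A default.

## Trajectory statistics

`grooveSeries()` applies the groove measurement per frame after
discarding a burn-in fraction (default 0.2, matching the common practice
of analysing the last 40 of 50 ns). Groove-width distributions over
trajectories can be skewed or multimodal, in which case the most probable
value describes the system better than the mean; `summarizeSeries()`
therefore reports both: the mode is the maximum of a Gaussian-kernel
density (Silverman's rule bandwidth, evaluated on a grid of 0.01 A; the
bandwidth is always reported next to the mode), the Gaussian fit is
moment-matched, and normality is tested with the Anderson-Darling
omnibus test at alpha = 0.01 (chosen because it remains defined for the
long series MD produces; the test name, p-value and verdict are all
reported, and series shorter than 30 or constant are flagged
`"undefined"` rather than judged). `pearsonProfiles()` compares
per-position width profiles; `hbondSeries()` and `rmsdSeries()` provide
the standard equilibration diagnostics (Watson-Crick donor-acceptor
distances — three per G:C, two per A:T, I:C and 2AP:T — and
least-squares-superposed RMSD).

The package never drives an MD engine; trajectories arrive as multi-model
PDB. `mdRunDescription()` emits an engine-agnostic plain-text description
of the reference simulation protocol for reproducibility records.

## The synthetic generator, and what passing tests do not show

`synthTrajectory()` rebuilds every frame from base step parameters plus
either independent Gaussian jitter per parameter or per-frame draws from
a k-state mixture of parameter sets, with the drawn parameters returned
so any frame can be recomputed exactly. Frames are independent: the
estimators under test are order-agnostic, and independence keeps the
ground truth exact. That choice also bounds what the tests demonstrate:
synthetic trajectories have no autocorrelation, no solvent, no
force-field physics and no backbone relaxation, so passing the recovery
suite shows the *estimators* are correct, not that real MD would produce
any particular width distribution. Likewise the mean-parameter models
capture sequence-averaged geometry only; real A-tract narrowing is
largely a dynamic property that mean tables underrepresent.

The 15-mer fixture sequences deserve a caveat: the central 5-mers
(AATTT, AACTT, AGCGT, AICIT, A-2AP-T-2AP-T, GGCGC, IICIC) are the
authoritative variant definitions; the flanking 5-mers are a synthetic
G/C-edged, A/T-rich context shared by all variants so that variants
differ only at the center. In the analog variants the substituted pair
keeps its orientation: whichever strand carried the purine carries the
analog, which is why the dI and 2AP fixtures specify an explicit partner
strand (C:I and T:2AP pairs) rather than the canonical complement.

Numerical choices collected in one place: KDE grid 0.01 A; bandwidth
Silverman (`bw.nrd0`); normality alpha 0.01; compression search
tolerance 0.1 A with amplitude bound 3; clash tolerance 0.4 A default, 0
for N2 scans; groove vdW subtraction 5.8 A; pairing criteria C1'-C1'
9.5-11.5 A, base-plane inclination <= 65 deg, donor-acceptor < 3.5 A;
altloc policy highest occupancy, ties to the first encountered;
hydrogens ignored throughout (the structures this package targets are
2.7-2.9 A X-ray models without them). Problem sizes used by the test
suite — duplexes of 8-15 bp, trajectories of up to a few hundred frames,
series of 4 x 10^4 draws, 100-seed calibration loops — were chosen so
statistical tolerances are meaningful at desk scale.

## Known limitations

- Backbone atoms beyond the phosphate group are not modelled; quantities
  that depend on sugars or backbone torsions (puckers, BI/BII, bend-angle
  estimation) are out of scope.
- Groove widths use the direct P-P convention only.
- Mean-parameter models are static; they reproduce printed
  mean-parameter results, not ensemble behaviour.
- The clash analysis is qualitative (directional presence/absence), not
  an energy model.
- Reading mmCIF, binary trajectory formats (DCD/XTC) and symmetry
  expansion are not supported; multi-model PDB is the trajectory format.

## Worked example

```{r example}
fx <- fixtureSequences()
f28 <- buildMeanDuplex(fx$full15[fx$name == "F28"])
grooveWidthAt(grooveProfile(f28), 0)

cz <- makeCompressedDuplex(fx$full15[fx$name == "F28"], 4.4)
cz$achieved

m <- compressedClashModel("F28")
rep <- findClashes(m, tolerance = 0)
sum(rep$involvesN2)
```
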