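---
title: "Comparing Eph/ephrin binding modes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing Eph/ephrin binding modes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephcompare)
```

Eph receptor tyrosine kinases bind their ephrin ligands through an
N-terminal ligand-binding domain (LBD) that docks the ephrin GH loop into a
hydrophobic pocket. Crystal structures show that the *same* ephrin can sit
on different receptors at visibly different orientations, and that a more
tilted ligand can recruit extra contact surface outside the pocket. This
package implements the quantitative toolkit needed to compare such binding
modes across structures — orientation, buried surface, contact inventory,
local backbone deformation — together with one-site isothermal titration
calorimetry (ITC) analysis for the solution-side picture. This vignette
records the models, the parameters that matter, and the design decisions
taken where conventions genuinely diverge.

## The three-atom tilt metric

The orientation of an ephrin on its receptor is reduced to one number: the
angle between a ligand marker atom, a receptor vertex atom and a distal
receptor atom (defaults: ephrin-A5 L112, EphA3 F152 and Y180, CA atoms),
minus the same angle measured in a reference complex that defines 0°.
`measure_tilt()` follows the comparative protocol in order: both complexes
are trimmed to the residues they share (global sequence alignment of
receptors and of ligands; match +1, mismatch 0, gap open −1, extend −0.5),
the query receptor is superposed onto the reference receptor by a CA-only
Kabsch fit, the marker residues are mapped through the alignments onto the
query's *own* residues, and the raw angle is measured there.

Three choices were open and are fixed as follows:

* **Atom choice — CA.** The protocol names residues, not atoms; CA is the
  conventional marker and makes the measure independent of side-chain
  conformation and rotamer differences between homologs.
* **Sign — signed difference, magnitude reported alongside.** The
  comparison tables in the literature print magnitudes rounded to whole
  degrees; `tilt_result` carries the signed value (`raw − reference`) plus
  `tilt_abs_rounded` for table-style output, and stamps the convention into
  the result so numbers are never mixed silently.
* **Correspondence — sequence alignment.** Eph LBDs are highly conserved,
  so a global alignment of one-letter sequences is unambiguous on real
  homologs. On deliberately degenerate sequences (e.g. poly-alanine
  scaffolds of *different* lengths) gap placement is arbitrary; the
  synthetic fixtures therefore use identical residue ranges, for which the
  alignment is the identity.

A three-atom angle is invariant under rigid motion of the complex, so the
superposition step cannot change it; it is retained because the protocol
reports the receptor-fit RMSD and pair count as quality metadata, and
because the transformed coordinates are what one inspects visually.

## Superposition

`kabsch()` is the closed-form SVD solution with the reflection corrected by
flipping the smallest singular vector, so the rotation is always proper
(determinant +1 to 1e−6). Collinear or <3-point inputs raise a
degenerate-input error rather than returning an ill-conditioned fit. The
test suite checks the result against an independent quaternion
eigen-decomposition oracle and against 10,000 random rotations per instance
(Monte-Carlo minimality); RMSD symmetry between the two point sets holds to
1e−6 Å.

## Accessible surface and buried interface area

`shrake_rupley_sasa()` places a deterministic golden-angle spiral lattice
(default 960 points) on each probe-expanded atom sphere (probe 1.4 Å) and
counts points outside every neighbour's expanded sphere. A deterministic
lattice rather than random sampling makes results bit-reproducible without
seeds. Quadrature error at 960 points is below 1% against the analytic
single-sphere and two-sphere (spherical-cap) closed forms, and doubling the
density moves totals by <1% on random clusters.

Radii follow a NACCESS-style per-element table (carbonyl/aromatic C 1.70,
aliphatic C 1.87, N 1.65, O 1.40, S 1.85), chosen so buried-area magnitudes
are comparable to PISA-derived published values. Hydrogens are ignored
throughout — the structures this toolkit targets are ~2.3 Å resolution and
carry none — and waters/heteroatoms are excluded from interface work.

`buried_interface_area()` reports each chain's SASA loss on complexation
and the **interface area as half the sum of the two buried areas**. This
half-sum is the PISA convention used by published interface-area tables;
the full buried area is also returned, so either convention can be quoted.
A residue is listed as interfacial when it loses more than 0.1 Å².
Published areas for these complexes were computed with unknown PISA
versions and settings, so agreement should be judged at the ±10% level, not
digit-for-digit.

## Contact classification

`enumerate_contacts()` applies field-standard, hydrogen-free geometric
criteria: van der Waals contact for any inter-chain heavy-atom pair ≤4.0 Å;
hydrogen bond for donor/acceptor heavy atoms ≤3.5 Å with an
antecedent–donor–acceptor angle ≥90° (the antecedent standing in for the
missing hydrogen); salt bridge for Asp/Glu side-chain oxygens against Lys
NZ, Arg NE/NH1/NH2 or His ND1/NE2 at ≤4.0 Å. Each pair is reported once
under its most specific class (salt > hbond > vdw). The cutoffs are
arguments, not constants, because published tables rarely state theirs;
defaults are the values most contact-map software uses.
`residue_contact_summary()` reproduces the published table layout: grouped
by ligand residue, GH-loop rows (ephrin-A5 121–129) first,
backbone/side-chain tags and class markers on each partner.

## Shape complementarity

`sc_statistic()` implements the Lawrence–Colman statistic: for each buried
dot on one surface, S = (n·−n′)·exp(−w·d²) against the nearest partner dot,
the directional score is the median of S, and Sc is the mean of the two
directional medians. Defaults are the original method's w = 0.5 Å⁻² and
1.5 Å interface band; peripheral-band trimming is implemented and on by
default but toggleable, since published invocations rarely say whether it
was applied. The dot substrate (`dot_surface()`) is an accessible-surface
lattice repositioned onto the van der Waals sphere with radial outward
normals — a deliberate approximation to the solvent-excluded surface that
avoids re-entrant surface construction; its convergence is checked by the
dot-count-vs-area and plane-fixture tests rather than assumed. On parallel
planar grids the statistic has the closed form exp(−w·d²), which the
engine reproduces to <1e−3; note that testing separations beyond the
default band requires widening `band`, which the plane tests do explicitly
(band = 4 Å).

## Strand twist

No community convention exists for "cumulative twist" of a β-strand, so
`strand_twist()` defines one and stamps it into every report: carbonyl
vectors C(i)→O(i) are compared two residues apart (i against i+2, stepping
by two), each pair projected onto the plane perpendicular to the local
CA(i)→CA(i+2) axis, and the cumulative twist is the sum of absolute signed
step angles. Comparing i to i+2 cancels the alternating carbonyl pleat of a
β-strand, which the pleated synthetic fixture verifies explicitly. Reported
values — e.g. the large twist of the EphA3 C strand (S49–V58) versus the
100–150° of other receptors — are comparable only within this convention;
the published 198° figure was produced by an unstated convention and is
treated as qualitative, not as a reproduction target.

## ITC: one set of sites

`simulate_titration()` evaluates the single-class independent-sites
(Wiseman) isotherm for cumulative heat, with the standard perfusion-cell
dilution model: after cumulative injected volume v, cell species
concentration M₀(1−v/2V₀)/(1+v/2V₀) and injectant X₀(v/V₀)/(1+v/2V₀).
Per-injection heats are differences of cumulative heat plus the
displacement correction (dVᵢ/V₀)(Qᵢ+Qᵢ₋₁)/2 for liquid expelled from the
overfilled cell — without it, the heats fail the stoichiometric-limit check
(pre-saturation normalized heat = ΔH) and late injections change sign as
bound complex is diluted out; with it both behaviours are correct, which is
why the correction defaults to on while the uncorrected increments remain
available (`displacement_correction = FALSE`) because they telescope
exactly to the cumulative heat. The closed form is verified against an
independent per-injection equilibrium solver (bisection on free injectant)
to 0.1%.

`fit_one_set_of_sites()` is Levenberg–Marquardt least squares over (n,
log K_a, ΔH) on the normalized heats, first injection excluded by default
(the conventional discard of the small pre-injection), K_a parameterised in
log space for positivity, with bounded restarts over K_a starting values.
R = 1.9872 cal mol⁻¹ K⁻¹ and T = 298.15 K throughout, matching the
calorie-based units of published tables; `thermodynamic_linkage()` closes
the cycle ΔG = −RT ln K_a, TΔS = ΔH − ΔG, K_d = 1/K_a. Fit standard errors
are asymptotic (from the Jacobian); run-to-run spread over repeated noisy
titrations is a different quantity and should be computed by repeated
simulation, as the calibration test does.

The reference protocol reproduced in `epha3_schedule()` is the VP-ITC
experiment: 2 mL of 10 µM cell species titrated with 5 µL + 19 × 15 µL of
100 µM injectant at 25 °C (the iTC200 variant is also provided). At the
published affinity (K_d ≈ 9 nM) this sits at c ≈ 1,100 — a nearly
rectangular isotherm in which ΔH and n are sharply determined but K_a is
constrained by only a couple of transition injections. The calibration
study (20 simulated titrations with 1% of |ΔH| Gaussian noise on normalized
heats) accordingly recovers ΔH within 5% and n within 2% per run, while
K_d scatters within about a factor of 3 — a property of the experimental
design, not of the optimizer.

## Synthetic fixtures: what they do and do not show

The generator module produces inputs whose correct answers are known by
construction: a two-chain complex whose ligand is rotated by θ about the
axis through the vertex CA perpendicular to the marker plane (measured tilt
= θ exactly); sphere clusters with closed-form accessible areas; ideal and
uniformly twisted strands; planar dot grids with closed-form Sc; and
titration curves from stated parameters. All randomness is local to the
call and seed-controlled; the same seed reproduces files byte for byte.

These fixtures validate the *numerics* — quadrature, superposition,
alignment plumbing, isotherm inversion — under exactly known conditions.
They are deliberately not protein-like: poly-alanine scaffolds have
degenerate sequences, no side chains, no packing, and ideal geometry. Tests
passing on them demonstrate that the measurement machinery is correct, not
that any particular published number for a real crystal structure will be
reproduced; real-structure comparisons additionally inherit coordinate
error, alternate conformations, and the unknown settings of the original
analysis software.

## Problem sizes and numerical choices

The shipped tests run on clusters of ≤40 spheres at 960–10,000 lattice
points, 400-dot planar grids, 50-residue scaffolds and 20-injection
titrations — sizes at which every closed form is exact and the whole suite
completes in well under a minute. Degenerate inputs fail loudly and early:
zero-length angle arms, collinear Kabsch input, chains without radii,
surfaces with no buried dots, strand ranges under 4 residues, and
non-converging fits all raise typed errors naming the offending entity.
Altloc resolution keeps the highest occupancy (ties → 'A'); only the first
model of a file is read; author residue numbering is authoritative
throughout, since that is how residues are cited in the literature.
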