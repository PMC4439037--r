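# ephcompare

Comparative interface geometry and binding thermodynamics of Eph
receptor/ephrin complexes.

Eph receptor tyrosine kinases recognise their membrane-anchored ephrin
ligands through a ligand-binding domain (LBD) that docks the ephrin GH loop
into a hydrophobic pocket. Across crystal structures the same ephrin can sit
on different receptors at markedly different orientations ("tilt"), and a
more tilted ligand buries extra surface outside the pocket. `ephcompare` is
an R toolkit for quantifying such binding-mode differences, for structural
biologists comparing Eph/ephrin (or other two-chain) complexes:

* **Three-atom tilt metric** — after trimming two complexes to their shared
  residues and superposing the receptors (CA-only Kabsch fit), the ligand
  orientation is summarised as the angle ligand-marker → receptor-vertex →
  receptor-distal (defaults: ephrin-A5 L112, EphA3 F152, Y180, CA atoms),
  minus the same angle in a reference complex that defines 0°.
* **Buried interface area** — Shrake–Rupley solvent-accessible surface area
  on a deterministic spiral lattice (probe 1.4 Å, NACCESS-style radii);
  interface area reported as half the sum of the two chains' buried areas
  (the PISA convention of published interface tables).
* **Contact table** — inter-chain heavy-atom contacts classified as van der
  Waals (≤4.0 Å), hydrogen bond (≤3.5 Å, antecedent–donor–acceptor ≥90°,
  hydrogen-free criterion) or salt bridge (acidic O vs basic N, ≤4.0 Å),
  with backbone/side-chain tags and GH-loop grouping.
* **Shape complementarity** — the Lawrence–Colman Sc statistic,
  Sc = mean of the two directional medians of (n·−n′)·exp(−w·d²) over
  buried surface dots (w = 0.5 Å⁻², band 1.5 Å).
* **β-strand twist** — cumulative carbonyl rotation about the local chain
  axis, measured i vs i+2 so the β-pleat alternation cancels.
* **ITC one-set-of-sites** — simulation of the Wiseman isotherm with
  perfusion-cell dilution corrections, Levenberg–Marquardt fitting of
  (n, K_a, ΔH), and the linkage relations ΔG = −RT ln K_a, TΔS = ΔH − ΔG
  (R = 1.9872 cal mol⁻¹ K⁻¹).
* **Synthetic fixtures** — rotated two-chain complexes, sphere clusters
  with closed-form areas, twisted strands, planar dot grids and noisy
  titration curves, so the whole pipeline is testable without downloading
  structures.

Structure I/O (PDB and mmCIF) is handled through `bio3d`; sequence
correspondence through `Biostrings`; fitting through `minpack.lm`.

## Worked example

Measure the tilt of a synthetic complex whose ligand was rotated by 9°
(the construction guarantees the answer), then fit a simulated titration
of the published VP-ITC protocol (2 mL of 10 µM cell species, 5 µL + 19 ×
15 µL of 100 µM injectant, 25 °C):

```r
library(ephcompare)

cs  <- complex_spec("A", "B")
ref <- extract_complex(make_tilted_complex(0), cs)
q   <- extract_complex(make_tilted_complex(9), cs)
measure_tilt(q, ref)
#> tilt 9.00 deg (raw 49.00, reference 40.00; |tilt| ~ 9 deg)
#> receptor fit: 50 CA pairs, rmsd 0.000 A; atom CA; sign: query - reference

sch   <- epha3_schedule()
truth <- thermo_params(n = 1, K_d = 9e-9, dH = -2145)
sim   <- simulate_titration(truth, sch, noise_sd = 21.45, seed = 7)
fit_one_set_of_sites(sim, sch)
#> one-set-of-sites fit on 19 injections (rss 1.01e+04)
#>   n   = 0.9974 +/- 0.0017
#>   K_d = 1.02e-08 +/- 1e-09 M
#>   dH  = -2144 +/- 8 cal/mol
#>   dG  = -10900, TdS = 8756 cal/mol at 298.15 K

thermodynamic_linkage(dH = -2145, TdS = 8855)
#> n = 1.000, K_d = 8.65e-09 M (K_a = 1.16e+08 M^-1), T = 298.15 K
#> dH = -2145, dG = -11000, TdS = 8855 cal/mol
```

The tilt read-out is exactly the constructed 9° because the fixture rotates
the ligand in the plane of the three marker atoms. The fit recovers the
simulated thermodynamics; at this protocol's c ≈ 1,100 the isotherm is
nearly rectangular, so ΔH and n are sharp while K_d carries most of the
uncertainty. The linkage call shows that ΔH = −2,145 and TΔS = 8,855
cal/mol imply ΔG = −11,000 cal/mol and K_d ≈ 8.6 nM at 298.15 K.

A thin command-line front end over the same functions ships at
`inst/scripts/ephcompare.R` (`info`, `tilt`, `interface`, `sc`, `twist`,
`itc-sim`, `itc-fit`, `make-fixture`).

## Scope

The package analyses given coordinates; it does not fetch structures from
the PDB, build crystallographic assemblies, place hydrogens, or integrate
raw calorimeter power traces. The β-strand twist number is
convention-dependent (the convention is stamped into every report) and
published twist figures from unstated conventions should be treated as
qualitative.
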