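---
title: "Models and methods behind gpcrdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpcrdimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gpcrdimer` re-implements, as tested and reusable code, the computational
layer of a structural study of a G-protein-coupled receptor (the mu-opioid
receptor, OPRM1) whose homodimerization at the TMH4-TMH4 interface is
stabilized by a cholesterol molecule trapped against a palmitoylated
cysteine (C3.55). Four method families are covered: residue-level nonbonded
interface energetics, Conformational Memories (CM) helix sampling, kinked
helix geometry descriptors, and sensitized-emission FRET statistics. This
vignette records the models, the tunable parameters and the design choices,
and states precisely what the synthetic tests do and do not show.

## 1. Nonbonded interface energetics

### The pair energy

For atoms $i$ and $j$ at distance $r_{ij}$ (Å) with partial charges $q$
(units of $e$) and Lennard-Jones self coefficients $A_{ii}$
(kcal Å$^{12}$/mol) and $C_{ii}$ (kcal Å$^6$/mol),

$$E_{ij} \;=\; \frac{k\, q_i q_j}{\varepsilon(r_{ij})\, r_{ij}}
  \;+\; \frac{A_{ij}}{r_{ij}^{12}} \;-\; \frac{C_{ij}}{r_{ij}^{6}},
\qquad A_{ij}=\sqrt{A_{ii}A_{jj}},\;\; C_{ij}=\sqrt{C_{ii}C_{jj}},$$

with $k = 332.0636$ kcal Å/(mol $e^2$), the standard electrostatic
conversion constant. Geometric-mean combining is the OPLS convention, which
matches the force-field family this decomposition follows.

Two dielectric modes are provided. The energy-model equation as usually
printed carries no dielectric, but the minimisation protocol this analysis
descends from used a distance-dependent screening; we therefore default to
$\varepsilon(r) = r_{ij}$ and keep a constant-$\varepsilon$ mode switchable
(`energy_options(dielectric_mode=)`). Which mode produced the published
decomposition is not recorded anywhere, so both are first-class.

### Residue selection and the decomposition

A residue of the opposite group enters the sum for an anchor residue when
its minimum any-atom-to-any-atom distance is at most
`residue_radius` (default 7.0 Å, boundary inclusive — the most permissive
common reading, recorded and configurable).

`decompose_interface()` computes one row per listed interface position:
the protomer-A residue at that Ballesteros-Weinstein position against all
in-radius residues of protomer B. Rows are one-directional; by the symmetry
of the dimer they already sum to the protomer-protomer interface energy,
and adding B-against-A rows would double count. The cholesterol associated
with each protomer is evaluated against the *opposite* protomer only.
Cholesterol-cholesterol and palmitoyl-palmitoyl pairs are never summed
(in the parent model they are sterically separated by the two TMH4
helices), and palmitoyl-opposite-protomer terms, where palmitoyls are
present, are computed but reported outside the grand total, which comprises
only the protomer rows plus the two cholesterol cross terms. No
minimisation is performed: the decomposition is a pure function of the
input coordinates and parameters.

### Rounding and the printed table

Display rounding follows the printed conventions: energies at 2 decimals,
the cholesterol percentage at 1 decimal. Subtotals are computed in full
precision and then rounded, never summed from rounded rows; consequently
the rounded rows may fail to add up to the rounded subtotal by up to
0.02 kcal/mol, and `render_energy_table()` emits an explicit note whenever
they do. The packaged published table exhibits exactly this: its sixteen
rounded rows sum to $-15.49$ (VDW) and $-14.77$ (total) against printed
subtotals of $-15.50$ and $-14.76$. For ingested printed tables the printed
subtotal is treated as the authoritative full-precision value and the row
sum is cross-checked against it; likewise each printed `total` cell is
authoritative even where, in the last rounded digit, it differs from the
sum of its printed Coulombic and VDW cells (the cholesterol subtotal,
$0.17 - 5.01$ vs printed $-4.83$, is such a cell).

### Units

$A$ and $C$ are accepted in kcal-based units as above; the package performs
no unit conversion, so user parameter tables must already be consistent.

## 2. Conformational Memories sampling

CM is a two-phase Monte-Carlo/simulated-annealing protocol for mapping the
conformational space of one transmembrane helix.

* **Variables.** Backbone torsions $\varphi$ (residues $2..n$) and $\psi$
  (residues $1..n{-}1$) vary within $\pm 10^\circ$ windows, widened to
  $\pm 50^\circ$ in a declared flexible region (the neighbourhood of
  helix-bending residues: Pro, Gly, Ser, Thr); N-CA-C bond angles vary
  within $\pm 8^\circ$. $\omega$ is fixed at $180^\circ$ and bond lengths
  at standard values. Helices start from the standard transmembrane values
  $\varphi = -63^\circ$, $\psi = -41.6^\circ$.
* **Moves.** Each composite step varies two dihedrals and one bond angle
  chosen at random, with fresh values drawn uniformly within each
  variable's window, accepted by the Metropolis criterion with
  $k_B = 0.0019872$ kcal/(mol K). Uniform proposals are our choice; the
  protocol prescribes ranges, not proposal shapes.
* **Schedule.** Exploratory phase: 3000 K cooled to 310 K in 18 stages;
  biased phase: 749.4 K to 310 K in 7 stages; 105 structures emitted at
  310 K. The cooling law is not prescribed anywhere we could follow, so we
  use geometric cooling $T_k = T_0 (T_f/T_0)^{k/(K-1)}$, endpoints
  inclusive: it is the standard choice for MC/SA, monotone, and hits the
  stated endpoints exactly.
* **Step counts.** "50,000 Monte Carlo steps applied to each variable" is
  read as 50,000 trial variations per variable per temperature; since each
  composite step varies three variables, a stage runs
  $50{,}000 \times n_{\mathrm{vars}} / 3$ composite steps, times a single
  desk-scale multiplier (`scale`) that shrinks the run while preserving the
  schedule shape. The analysis scripts use `scale = 0.001` and the
  acceptance script `scale = 0.002` on a 20-residue polyalanine helix
  (58 variables), sizes chosen so a complete two-phase run finishes in
  about a minute on one core.
* **Memories.** Accepted values are binned per variable and per
  temperature; torsion bins are $5^\circ$ and bond-angle bins $2^\circ$
  (configurable), resolving even the narrow $\pm 10^\circ$ windows into
  at least 4 bins. The occupied bins at the final 310 K stage are the
  "populated space". A variable with an empty 310 K memory falls back to
  its full window, with a warning. In the biased phase every proposal is
  drawn from an occupied bin (bin chosen uniformly, value uniform within
  the bin); an audit counter verifies that no proposal leaves the
  populated space.
* **Objective.** The original CM energy function (force field, solvation)
  is not recorded; the package default is the helix's own intra-molecular
  nonbonded energy — the same 12-6 pair function as the interface module
  over backbone atoms, 1-2/1-3 pairs excluded and 1-4 pairs scaled by 0.5 —
  and any custom objective can be plugged in
  (`energy_model("custom", fn=)`). Sampled ensembles are therefore
  *method-faithful, not value-faithful*: the published TMH2/4/6 ensembles
  cannot be regenerated without the original force field and template
  coordinates.
* **Endpoint convention.** Whether the 18 exploratory stages include both
  endpoints is unstated; endpoints-inclusive is assumed (and the stage
  count is configurable).

Seeded runs are bit-reproducible. `select_fitting_conformer()` screens the
emitted ensemble against a helix bundle, returning the first candidate (in
input order) with no interatomic distance below the clash cutoff after an
optional least-squares superposition onto a template C-alpha trace; finding
nothing is a reported outcome, not an error.

## 3. Kinked-helix geometry

The descriptor triple (bend, wobble, face shift) is named but nowhere
defined mathematically in the parent analysis, and the model coordinates
behind the published values were never deposited. The package therefore
declares its own convention (in the ProKink spirit) and validates it by
synthetic construction recovery; reproducing the printed values
(e.g. 35.2°, −105.8°, 40.3° for one helix) is explicitly out of reach and
out of scope.

* **Axis fit.** Segment axes come from the bisector construction — for
  each interior C-alpha, $(p_i - p_{i+1}) + (p_{i+2} - p_{i+1})$ points at
  the axis, and successive bisector cross products give the axis direction
  (exact for an ideal helix and stable on segments as short as 4 residues,
  where a principal-component fit is badly biased) — plus a least-squares
  circle fit for the axis line position.
* **Segments.** `window` residues (default 7) on each side of the hinge,
  excluding the flexible span $i{-}4..i$ from both fits.
* **Bend** is the angle between the two segment axes.
* **Wobble** is the azimuth of the post-segment axis about the pre-segment
  axis; the zero reference is the direction from the pre-axis to the flex
  residue's C-alpha, counterclockwise positive looking N→C (right-hand
  rule). Angles wrap to $(-180^\circ, 180^\circ]$.
* **Face shift** is the measured minus the extrapolated helical phase of
  the first post-segment C-alpha: pre-segment azimuths are unwrapped,
  fitted linearly in residue index, extrapolated across the hinge, and
  transported onto the post axis by the minimal rotation between the axes.
  A pure rigid-body bend has face shift ≈ 0; a twist of the post segment
  about its own axis reads out directly as face shift.

Under this convention the constructed-kink generator
(`make_kinked_helix()`) is recovered exactly on ideal helices (the test
tolerances of 2° bend / 5° wobble absorb segment-fit noise on non-ideal
input), descriptors are invariant to rigid-body motion to ≤ 0.5°, bend is
mirror-invariant while wobble and face shift change sign, and all three
vary continuously with a continuously applied bend except at the ±180°
wrap.

## 4. FRET statistics

### The normalization

The three-cube normalized net FRET is

$$\mathrm{NFRET} = \frac{I_{FRET} - \mathrm{CoA}\cdot I_{CFP}
  - \mathrm{CoB}\cdot I_{YFP}}{\sqrt{I_{CFP}\, I_{YFP}}},$$

with CoA estimated as the mean of $I_{FRET}/I_{CFP}$ over donor-only ROIs
and CoB analogously from acceptor-only ROIs. The formula as printed in the
parent text cannot be taken literally: its left-hand side symbol is also
defined as the raw FRET-channel intensity, and the measured FRET term is
absent from its numerator, which contradicts the text's own definition of
CoA and the stated purpose of the $\sqrt{I_{CFP} I_{YFP}}$ factor
(removing the dependence on fluorophore expression levels). The standard
three-cube form above is the only reading consistent with both; the
literal printed variant remains available as
`normalized_net_fret(variant = "printed")` for audit, and is exercised in
the tests so the discrepancy stays visible.

### Aggregation and uncertainty

Summaries report the mean and *standard deviation* (not SEM — matching the
convention of the parent figures) of per-ROI NFRET, and are flagged when
based on fewer than 12 cells or 20 ROIs per cell. Because the mean NFRET
depends linearly on CoA and CoB, the reported standard error propagates
the coefficients' sampling uncertainty:

$$SE^2 = \frac{s^2}{n} + \frac{s_A^2}{n_A}\overline{\sqrt{C/Y}}^{\,2}
  + \frac{s_B^2}{n_B}\overline{\sqrt{Y/C}}^{\,2}.$$

Simulation over 200 generator seeds shows this SE is calibrated
(z-scores with unit variance), so "recovered within 2 SE" is a meaningful
check. The recovery tests compare the mean over five replicate synthetic
experiments against the single-experiment SE: a correct, unbiased pipeline
passes such a check essentially always, whereas a single 240-ROI draw
lands outside 2 SE five percent of the time by construction — the tests
target systematic bias, not per-draw luck.

### Colocalization

The pixel colocalization index is $2 N_{yellow} / (N_{red} + N_{green})$,
where counts are pixels above a per-channel threshold and yellow means
above threshold in both channels, so the index lies in $[0,1]$. The parent
protocol's threshold is "pre-defined" but unrecorded; the package takes
counts (or a threshold) as explicit inputs rather than guessing one.

## 5. Synthetic data: what it does and does not show

* `make_kinked_helix()` builds ideal helices with exact, known kink
  parameters — the oracle for the geometry module. Real kinked helices
  have irregular backbone geometry; the stated tolerances, not the exact
  recovery, are the claim.
* `make_dimer_fixture()` builds parallel single-site-per-residue protomers
  with fully known charges and LJ coefficients, and a cholesterol proxy of
  three uncharged LJ sites. It validates selection, summation and
  exclusion logic against a brute-force all-pairs reference to
  $10^{-9}$ kcal/mol; it says nothing about sterol chemistry or real
  force-field parameters.
* `make_fret_rois()` draws lognormal channel intensities (strictly
  positive, realistic spread; `intensity_sdlog = 0.3`, i.e. ~30% CV
  between ROIs), composes the FRET channel from the ground-truth NFRET and
  bleed-through, and applies mean-one multiplicative noise
  (default CV 5%, which reproduces the ~0.03-0.05 SDs reported for
  membrane ROI measurements). Defaults are the study conditions: 12 cells
  × 20 ROIs and the four condition means 0.49 / 0.30 / 0.27 / 0.07. The
  generator has no spatial structure, no detector offset and no
  photobleaching; passing tests show the estimator arithmetic is correct,
  not that real microscopy meets the model.
* The packaged printed interface table (16 rows plus two cholesterol cross
  terms) is transcription, not computation; the package recomputes only
  the arithmetic downstream of it.

## 6. Degenerate inputs and numerical conventions

Coincident atoms ($r_{ij}=0$) are a hard error, as is an exactly zero
grand total when the cholesterol percentage is requested (reported as NaN
with a warning). Angles are wrapped to $(-180^\circ, 180^\circ]$.
Symmetry of the pair energy is exact (the charge product is computed
before any non-commutative operation). Empty residue pools are empty
results, not errors; an all-clashing conformer set is a reported
"none found". The packaged printed table is returned read-only so that
transcription cannot drift.

## 7. Known limitations

* CM ensembles are method-faithful only (objective function unrecorded).
* Published kink descriptor values are unreproducible (no deposited
  coordinates); conventions here are declared, not inferred.
* No periodic boundaries, Ewald electrostatics, bonded terms, hydrogens,
  or minimisation anywhere in the energetics.
* mmCIF input, image segmentation and group-comparison statistics are out
  of scope.
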