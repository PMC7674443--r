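---
title: "Methods: ensemble geometry, disulfide inference, exchange dynamics"
author: "ensdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble geometry, disulfide inference, exchange dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdyn)
```

# Scope

`ensdyn` analyzes solution-NMR structure ensembles of small disulfide-rich
proteins — the motivating system is the 168-residue, ten-cysteine
*Gaussia princeps* luciferase (GLuc) — and the orthogonal experiments that
accompany such a structure determination: disulfide connectivity from
ensemble geometry and from mass spectrometry of linked proteolytic
fragments, backbone flexibility from heteronuclear NOE and H/D exchange,
microsecond–millisecond exchange from CPMG relaxation dispersion, interior
cavity geometry, and oligomeric state from sedimentation equilibrium. Every
stage can be driven from synthetic inputs with planted ground truth, so the
whole chain is testable without any external data.

# Ensemble geometry

An *ensemble* is an ordered set of models sharing one residue sequence;
the sequence identity is validated when the ensemble is built, never
assumed. Superposition uses the standard least-squares (Kabsch) solution
via the singular value decomposition, with the reflection branch excluded
so the rotation is always proper (`det R = +1`). Collinear point sets, for
which the optimal rotation is not unique, are rejected rather than
silently resolved.

The *representative* model is the one minimizing the mean pairwise RMSD to
all others, computed on a caller-chosen atom set and residue selection
(for a GLuc-like protein, backbone C-alpha of the well-defined ranges
10–18, 36–81, 96–145). Ties are broken toward the lowest model index, and
the selection used is recorded on the RMSD matrix object. Whether the
pairwise matrix for representative selection is computed on the restricted
ranges or on all residues is a genuine free choice; both are supported and
the choice is an explicit argument, with the restricted ranges used in the
pipeline defaults because disordered segments would otherwise dominate the
metric.

Per-residue displacement profiles superpose each model onto the
representative **on an explicitly supplied rigid-core selection** — there
is no hidden default, because the profile is only interpretable relative
to a stated frame — then measure each residue's atom displacement, and
report mean and standard deviation over the non-representative models.

For heavy-atom RMSDs, atoms not present in every model are dropped
pairwise with a warning rather than failing, since NMR ensembles
occasionally differ in modeled side-chain atoms.

# Disulfide connectivity from ensemble geometry

For every unordered cysteine pair the gamma-sulfur (Sγ–Sγ) distance is
recorded in every model, and the pair's *frequency* is the fraction of
models with distance strictly below a threshold (default 3.0 Å — a bonded
disulfide sits near 2.05 Å, and 3 Å comfortably separates bonded from
merely adjacent sulfurs). Frequencies are counted **independently per
pair**: one Sγ may be sub-threshold to two partners in the same model.
Disjointness is imposed only afterwards, by selecting the perfect matching
of cysteines that maximizes the summed frequency. This two-step design
reproduces the kind of per-pair percentage statistics an ensemble analysis
reports, while still returning a chemically consistent pairing.

The matching is solved exactly by recursive search; at the ten cysteines
of a five-disulfide protein there are 945 perfect matchings, and the
implementation stays exact through twelve cysteines (10,395 matchings).
Bonds that are unambiguous in every model can be fixed a priori and are
honored verbatim. An odd number of free cysteines is an error: the
intended use case is a fully oxidized protein (as established by a thiol
assay such as Ellman's), in which every cysteine is bonded. A model is
*consistent* with a pairing when every pair of the pairing is
sub-threshold in that model simultaneously; the same 3.0 Å default is used
because no separate criterion is warranted, and it is configurable.

# Disulfide mapping by limited proteolysis and LC–MS

With disulfides intact, proteolytic fragments that are covalently linked
through one or more bonds co-elute as a single species whose mass is the
sum of the member peptide masses minus two hydrogens per disulfide. The
module digests a sequence in silico (trypsin rule: cleave after K or R
except before P, with configurable missed cleavages), enumerates linked
species of up to `max_peptides` non-overlapping fragments in which every
member carries at least one cysteine, computes masses, and matches
observed masses within a tolerance (default 0.5 Da).

Average masses are the default scale because intact multi-kilodalton
species are typically reported as average masses (monoisotopic differs by
about 2.7 Da at 4.3 kDa); both scales are supported. The default oxidation
model pairs all cysteines (`n_disulfides = floor(n_cys / 2)`), again
reflecting the fully oxidized use case; a free-thiol mode enumerates every
feasible bond count instead. Uniform ^15^N labeling is supported as a
+0.99703 Da shift per nitrogen (backbone plus side chain); the unlabeled
scale is the default since linked-fragment masses from a proteolysis
experiment on unlabeled material only reconstruct correctly unlabeled.

The worked example shipped with the package: digesting the mature GLuc
sequence (UniProtKB Q9BLZ2 minus its 17-residue secretion tag, with the
expression substitutions E100A and G103R; `gluc_sequence()`,
`inst/extdata/gluc_mature.fasta`) yields fragments 50–54, 55–64 and
106–129, whose three-bond linked species computes to 4259.00 Da (average).
Matching an observed 4259.01 Da identifies that species within 0.1 Da, and
`connectivity_implications()` enumerates which cysteine pairings could
realize the linkage, reporting pairs present in *some* valid pairing
(compatible) and in *every* valid pairing (implied), optionally restricted
to a candidate set from the ensemble analysis.

# Flexibility classification

Heteronuclear NOE values below 0.5 (strict `<`) label a residue flexible;
0.5 is the conventional boundary between sub-nanosecond disorder and
restricted backbone motion, and the strictness at the boundary is
documented and tested rather than left to floating-point accident.
Missing interior values are interpolated as the mean of the nearest
measured flanking values (a run of consecutive gaps receives the same
mean), with provenance recorded per residue; leading and trailing gaps are
left missing because one-sided extrapolation would fabricate data at
exactly the termini where flexibility matters most.

H/D exchange is classified three ways from signal retention at 20 min and
18 h: `fast`, `protected_20min`, `protected_18h`. Retention at 18 h
without retention at 20 min violates exchange monotonicity and is an
error, not a fourth class.

# CPMG relaxation dispersion

Effective relaxation rates follow the constant-time relation
`R2eff(ν) = −ln(I(ν)/I0) / T_relax`, with `T_relax` defaulting to 40 ms
(two 20 ms CPMG blocks). The screening statistic
`ΔR2 = R2eff(50 Hz) − R2eff(1 kHz)` flags residues strictly above 2 1/s;
it is computed from the two single points, not from fitted curves, which
is the simpler and assumption-free reading of a two-point difference.

The default fit is the fast-exchange (Luz–Meiboom) closed form

$$R_2^{eff}(\nu) = R_2^0 + \frac{\Phi_{ex}}{k_{ex}}
  \left[1 - \frac{4\nu}{k_{ex}} \tanh\!\frac{k_{ex}}{4\nu}\right]$$

with a single exchange rate `kex` shared across residues and per-residue
`R2⁰` and `Φex ≥ 0`. Fast exchange is the right default regime when the
fitted rate (here ~2500 1/s) far exceeds typical ^15^N shift differences
and residue-specific single-rate fits are too ill-conditioned to trust; a
global rate mirrors that situation. The general equal-`R2` two-state
(Carver–Richards) expression is available per residue behind
`model = "general"` for cases outside the fast regime.

Numerically, the model is linear in `(R2⁰, Φex)` at fixed `kex`, so those
are profiled out exactly by per-residue linear least squares (with the
`Φex ≥ 0` constraint applied by clamping) and `kex` is found by
one-dimensional minimization on a log scale over 10–10⁶ 1/s. A dataset
with no measurable dispersion leaves the objective flat in `kex`; this is
detected on a coarse grid and the fit is returned flagged unidentifiable
instead of reporting an arbitrary rate. The `kex` uncertainty is a
bootstrap over residues (default 200 resamples), which treats residues —
not time points — as the exchangeable unit, appropriate when the dominant
uncertainty is which residues sense the exchange process; the nominal
scale of such an interval is validated in the tests by coverage of the
planted rate.

# Cavity detection

Cavity analysis substitutes a reproducible grid algorithm for what is
usually a visualization-level operation, with every parameter exposed. A
regular grid (default 0.6 Å) covers the model plus margin; cells within
`vdW + probe` (Bondi radii, 1.4 Å water probe) of any heavy atom are
occupied; flood-fill with 6-connectivity from the box boundary marks the
exterior; remaining empty components of at least 30 Å³ are interior
cavities. Occupied, exterior and interior cells partition the grid
exactly, and the discretization converges: halving the spacing moves a
test-shell volume by under 10%.

Open-mouthed pockets — like a substrate-binding site with an entrance —
are invisible to the closed-cavity definition, so a pocket mode first
seals the surface by repeating the exterior fill with an enlarged probe
(default 3.0 Å, a heuristic sized so a coelenterazine-scale mouth is
bridged) and reports empty cells inside that envelope. Lining residues
are those with any heavy atom within 4.5 Å of a cavity voxel, and
composition is reported in the conventional surface-coloring classes:
positive {R, K, H}, negative {E, D}, hydrophobic
{A, V, L, I, M, F, W, Y, P}, polar the remainder. Because the grid
parameters are heuristic, lining lists on real structures are soft
targets: the expectation is substantial overlap with a reference list,
not identity.

# Sedimentation equilibrium

A single ideal species at equilibrium follows
`c(r) = c_ref · exp[M(1−v̄ρ)ω²(r²−r_ref²)/(2RT)] + baseline` in cgs units
(`R = 8.314×10⁷ erg mol⁻¹ K⁻¹`). The global fit shares one molar mass
across all scans with per-scan reference concentration and baseline. As
in the dispersion fit, the per-scan parameters are linear at fixed `M`
and are profiled out exactly; `M` is minimized on a log scale and then
polished by a few Newton steps, which brings the noiseless-data residual
to machine precision rather than the ~10⁻⁸ floor of golden-section search
alone. Scans with no radial gradient (zero field, or neutral buoyancy
`v̄ρ = 1`) leave `M` undetermined and are flagged, not fitted. The partial
specific volume is a required input (default 0.73 mL/g, the usual protein
value) because it cannot be inferred from the scans themselves; meniscus
depletion, bottom artifacts and mass-conservation constraints are not
modeled — the analysis is the ideal single-exponential approximation to a
full equilibrium package.

# Synthetic data: what it emulates, and what it does not

The generators produce exactly the statistics the analyses consume and
deliberately nothing more; they are pure functions of a spec and a seed.

The ensemble generator builds a compact C-alpha trace by relaxing a
correlated random walk under three constraint sets (3.8 Å chain spacing,
planted-bond C-alpha pairs at 5.5 Å, bond midpoints at least 8 Å apart,
weak spherical confinement), adds N and C backbone atoms by local
geometry, and places Sγ atoms on the designated cysteines. Per model,
rigid-range atoms receive isotropic per-axis Gaussian noise `σ_core` and
all other residues `σ_flex`. The default `σ_core = 0.57 Å` is chosen so
the model-to-representative C-alpha RMSD lands near 1.4 Å (two
isotropically perturbed copies differ by ≈ σ√6); `σ_flex = 5 Å` makes
termini and linkers behave as disordered segments. For each planted bond
the Sγ pair is placed at a uniform 1.9–2.3 Å distance in an exactly
counted fraction of models and ≥ 5 Å apart otherwise, so pair frequencies
are exact by construction. The defaults (19 models, 168 residues, rigid
core 10–18/36–81/96–145, five bonds at fractions 0.924/0.561/1/1/1) are
the study conditions of the motivating system. What the generator does
*not* emulate: Ramachandran statistics, side chains, packing, or any
energetics — so passing tests demonstrate the correctness of the
analysis chain under its stated statistical assumptions, not robustness
to the full pathology of real structures.

Dispersion datasets are the forward Luz–Meiboom model converted to
intensities with multiplicative Gaussian noise; hetNOE tables draw rigid
residues from 0.7–0.9 and flexible from −0.3–0.4 (protection assigned
only within rigid ranges); sedimentation scans are the forward exponential
over the 3-speed × 3-concentration design with additive absorbance noise
(0.005 AU default); observed-mass tables are computed linked-group masses
with optional Gaussian mass error.

# Numerical choices and problem sizes

Thresholds are strict inequalities at their printed values (Sγ `< 3.0` Å,
hetNOE `< 0.5`, ΔR2 `> 2` 1/s) and asserted exactly at the boundary in
the tests. Residue numbering is taken verbatim from coordinate files —
no renumbering — and model indices are 1-based. Alternate locations keep
`'A'`/blank and drop the rest with a warning; insertion codes are
rejected (multi-model NMR depositions do not use them, and rejecting
keeps the residue-identity contract simple); hydrogens are parsed but
excluded from geometry selections.

The validation suite runs at deliberately modest sizes chosen to exercise
every claim in minutes on one core: 100 seeded ensemble replicates for
pairing recovery, 50 replicates each for the noisy dispersion and
sedimentation recoveries, a 10⁶-rotation grid for the superposition
oracle, and exhaustive enumeration for the matching and
representative-selection oracles.

# Known limitations

Single-chain models only (no chain-aware logic, no mmCIF); no structure
calculation or restraint handling; no MS/MS fragment-ion analysis or
charge-state deconvolution; no offset-effect correction for dual-center
CPMG acquisitions (the caller supplies the per-peak series chosen for
smaller offset error); cavity detection is parameter-sensitive by nature;
the sedimentation model omits non-ideality and association equilibria.
Ensembles deposited by an actual structure determination are user-supplied
input — the package bundles only the sequence-level fixture and its
synthetic generators.
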