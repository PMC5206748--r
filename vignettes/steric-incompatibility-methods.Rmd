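---
title: "Scoring steric incompatibility of antibody-bound cadherin dimers"
author: "xdclash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring steric incompatibility of antibody-bound cadherin dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdclash)
```

## The problem

Classical cadherins mediate cell-cell adhesion by trans-dimerizing their
N-terminal extracellular domains (EC1-EC2). Two dimeric states matter: the
final, thermodynamically stable **strand-swap dimer**, and the **X-dimer**,
a kinetic intermediate stabilized at the EC1-EC2 hinge through which
strand-swap dimerization proceeds. An antibody fragment (scFv) bound to EC1
can abolish adhesion *without touching any dimer interface*: if the
geometry of a dimeric state places the two bound antibody molecules on top
of each other, that state cannot form while antibody is bound. Whether this
happens is a purely steric question, and it is quantitative: one needs a
score that distinguishes "the two antibody copies interpenetrate by
thousands of cubic Angstrom" (state blocked) from "they clear each other"
(state unaffected), and that responds to single-residue design changes
intended to *create* hindrance where none exists.

`xdclash` implements that analysis end to end:

1. **Assembly** — superpose the antigen domain of an antibody-antigen
   complex onto each protomer of a dimer template, producing a hypothetical
   "dimer + two antibodies" model (`buildAssembly()`).
2. **Sterics** — score the two placed antibody bodies by grid-based van der
   Waals overlap volume and a signed clearance margin (`overlapVolume()`,
   `signedClearance()`), with SASA/BSA support (`sasa()`,
   `buriedSurfaceArea()`).
3. **Design** — model point mutations with deterministic idealized rotamers
   and rank them by the change in signed clearance (`mutateResidue()`,
   `runDesignScreen()`).
4. **Solution-state corroboration** — fit one-site ITC isotherms (the
   stoichiometry discriminator: n per antibody cell content doubles when one
   antibody binds per dimer) and global 1:1 SPR kinetics (`fitItc()`,
   `fitSprGlobal()`).
5. **Epitope calling** — classify mutant-panel binding levels against a
   below-20%-of-wild-type rule (`callEpitopes()`).

## Rigid superposition and RMSD conventions

`kabschSuperpose()` is the standard SVD solution with reflection
correction; the fitted transform is a proper rotation by construction.
Atoms are paired by **author residue numbering** plus atom name, never by
sequence alignment: every comparison this package is designed for involves
the same construct crystallized in different states, so numbering is the
correct correspondence and alignment would only add failure modes. Missing
residues are dropped pairwise and reported.

RMSD over a residue window is reported two ways. The scalar RMSD is the
usual root-mean-square over all fitted main-chain atoms. In addition,
`deviationSummary()` reports the mean and SD of *per-residue* mean
deviations, which is what an "RMSD = x ± y Å over residues i-j" statement
denotes: a single scalar RMSD cannot carry a spread, so the ± must be read
as dispersion across residues (or, for two-copy comparisons, across
copies; both are available from `perResidueDeviation()`).

Relative domain rotation is frame-based (`domainRotation()`): superpose
both structures on a reference domain (e.g. chain A's EC1), fit each
structure's moving domain (chain B's EC1), and report the angle of the
residual rotation, θ = arccos((tr R − 1)/2). This measures the same
quantity as hinge-detection tools for the rigid two-domain case but does
not attempt dynamic-domain decomposition.

## The overlap score

Overlap is defined on **van der Waals envelopes** (union of atom spheres),
not on solvent-excluded molecular surfaces. The motivation is
reproducibility from first principles: a surface-based volume depends on
the surfacing algorithm's triangulation and probe handling, whereas the
union-of-spheres intersection is fully determined by coordinates and a
radii table. The shipped radii (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å)
are explicit and swappable (`vdwRadiiTable()`) because every reported
volume depends on them. Hydrogens are ignored by default, as crystal
structures lack them.

The volume is measured by counting grid cells whose centres lie inside
both envelopes, over the intersection of the two padded bounding boxes,
with the grid anchored at the box corner — no randomness, so a report is
bit-reproducible at a given spacing. The default spacing is 0.5 Å
(reported alongside every volume); on analytic two-sphere fixtures a 0.3 Å
grid is within 2% of the closed-form lens volume
`pi (4r + d)(2r - d)^2 / 12`. A consequence of grid quantization worth
knowing: an overlap sliver thinner than the spacing can be missed, so
sub-cell interpenetrations may report zero volume even when two atom pairs
technically touch.

The **signed clearance** (`signedClearance()`) compresses "how badly do
they clash / how close is the miss" into one number: positive scores equal
the raw overlap volume; when the raw envelopes are disjoint the score is
minus the overlap of **probe-inflated** envelopes (every radius +1.4 Å, a
water radius), i.e. a negative near-miss margin; if even inflated
envelopes are disjoint the score is zero with a far-apart flag. This
convention is this package's own, chosen because surface-based tools print
small negative "overlap volumes" for near misses without documenting
their meaning; reports flag the negative branch as method-divergent. Note
the score is monotone *within* each branch (deeper interpenetration gives
a larger positive score; a closer miss gives a more negative margin) and
jumps from negative to positive at raw contact — by design, since the sign
is the verdict.

## Assembly construction and the mutation model

`buildAssembly()` superposes on **main-chain atoms of the antigen domain**
(default residue window 10-99 in the pipeline wrappers, matching the usual
EC1 comparison window; always configurable) and never moves the template.
Placed copies are rigid transforms of the input complex — internal
geometry is preserved exactly, which the tests assert to 1e-6 Å. Which
template chain is protomer A is explicit input: with two copies in an
asymmetric unit and no annotation of which is which, guessing would be
silent wrong-answer territory.

`mutateResidue()` replaces a side chain with an idealized geometry of the
target residue in its most common rotamer (shipped table, one rotamer per
type), built atom by atom from internal coordinates (NERF placement). An
existing CB is kept, so the new side chain inherits the parent's local
frame; main-chain atoms are bit-identical. There is no clash relief or
repacking: the design screen estimates a *change* in a steric score, and a
deterministic, reproducible estimate is worth more there than a relaxed
but solver-dependent one. Supported targets are the 18 standard residues
with acyclic or planar-ring side chains; proline (backbone ring closure)
is rejected.

## SASA and buried surface area

`sasa()` is Shrake-Rupley with a deterministic Fibonacci-spiral point set
(default 960 points/atom, probe 1.4 Å) — again no RNG, so totals are
bit-reproducible. One isolated atom reproduces 4π(r+p)² to well under 1%;
clusters agree with an independent random-point Monte-Carlo estimate
within 2%. `buriedSurfaceArea()` is the standard
SASA(A) + SASA(B) − SASA(AB); it is symmetric by construction and
non-negative up to point-sampling noise.

## Binding models

**ITC.** The one-site cumulative heat is the closed form

Q = n·Mt·ΔH·V0/2 · [1 + Xt/(n·Mt) + 1/(n·K·Mt) − √((1 + Xt/(n·Mt) + 1/(n·K·Mt))² − 4·Xt/(n·Mt))]

with per-injection dilution bookkeeping (factor 1 − dV/V0 applied to the
cell species and to previously injected titrant) and a trapezoidal
displaced-volume heat correction. The fitter (`fitItc()`) runs
Levenberg-Marquardt least squares on the same model with a constant
baseline-offset nuisance parameter (raw dilution heats are not modelled
explicitly, so the offset absorbs them), excludes the first injection by
default (its effective volume is corrupted by syringe diffusion during
equilibration), and restarts from a deterministic stoichiometry grid
n ∈ {0.5, 1, 1.5, 2} because one-site fits are multimodal at low c-value;
ties break by residual norm, then lowest n. Standard errors come from the
Jacobian at the optimum. With the default layout (20 µM cell, 200 µM
syringe, 25 × 1.5 µL injections — concentrations in the range typical of
scFv-cadherin titrations) and 1% noise, the planted n = 1.5 versus
n = 0.75 cases separate by an order of magnitude more than the fit error,
which is exactly the stoichiometry argument the score supports: n ≈ 0.7-0.8
per antibody means one cadherin per antibody, n ≈ 1.5 means a dimer bound
to a single antibody.

**SPR.** Association follows R(t) = C·kon·Rmax/(C·kon+koff)·(1−e^−(C·kon+koff)t),
dissociation decays exponentially from the association end point. The
global fit shares (kon, koff, Rmax) across the concentration series,
initializes koff from the pooled log-linear dissociation tail, and reports
KD = koff/kon by identity. No mass-transport term is included: the model
is a plain 1:1 interaction, which is also what the fits it emulates used.
At 1 RU noise on 100 RU signals the median KD error over 50 seeds is well
under 10%, and a planted two-fold KD difference for a dimer analyte (with
an unchanged monomer KD) is recovered — the discrimination needed to
verify a designed affinity change.

## Epitope calling

A mutant set whose binding level falls **strictly below 20% of the
wild-type signal** for an antibody assigns its mutated positions to that
antibody's epitope; a level of exactly 0.20 is not called, because the
rule is "below 20%". Mutants that lose binding to more than one antibody
are flagged as possible fold disruptions but still counted. The rule is
monotone by construction: lowering the threshold can only shrink an
epitope, and calls are independent of panel row order. Positions use the
same author numbering as the structures, so calls can be painted onto EC1
(`paintEpitope()`).

## What the synthetic data emulates — and what it does not

The generators (`makeToyComplexAndTemplate()`, `perturbStructure()`,
`makeItcFixture()`, `makeSprFixture()`, `makeEpitopePanel()`) exist so the
full pipeline runs with *known* ground truth: a helix "antigen" with a
rigidly attached "antibody" body (a single large sphere when an analytic
overlap is wanted, a seeded atom cluster otherwise), dimer templates whose
protomer separation and arrangement (translated or C2-rotated) control the
placed antibody-antibody distance, isotherms and sensorgrams from the same
closed forms the fitters use plus seeded Gaussian noise, and panels with
disjoint planted epitopes (own-mutant levels 5 ± 3% of WT, others
95 ± 5%). Every generator takes an explicit seed, surfaces it in the
ground-truth record, and leaves the caller's RNG untouched; toy structures
are written as legal PDB so the reader is exercised rather than bypassed.

What passing on this data shows: the geometry, grid, fitters and
classification are correct against closed forms and planted truth. What it
does not show: behaviour on real crystal structures — conformational
strain, alternate conformations, disordered loops, radii-set sensitivity,
and the gap between vdW-envelope and molecular-surface overlap volumes are
all absent from the toys. Checks against deposited entries retrieve them
at run time; absolute overlap volumes on real structures should be read
with method-dependent tolerance (tens of percent), while verdicts
(clash / no-clash) and RMSD-level comparisons are robust.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear paired atoms; degeneracy is
  detected from the singular-value spectrum and raised as an error.
* Altloc resolution keeps the highest-occupancy conformer, ties broken
  alphabetically — a deterministic single-conformer geometry for volumes
  and RMSD.
* The rotation-angle arccos is clamped to [−1, 1]; angles near zero are
  accurate only to about √ε degrees (~1e-6), which the tests respect.
* Overlap grid spacing is restricted to (0.1, 1] Å; fits refuse fewer than
  8 injections (ITC) or fewer than 2 concentrations (SPR); empty bodies,
  empty selections, absent chains, unknown mutation targets and missing
  WT panel rows are all immediate errors rather than NA propagation.
* Simulation sizes in the tests (30-90-point clouds, 25-injection
  isotherms, 5-concentration sensorgram series, 50-seed recovery studies)
  were chosen as the smallest sizes at which the recovery statistics are
  stable; they complete in seconds.

## Known limitations

* Overlap is vdW-envelope, not solvent-excluded-surface, volume; absolute
  numbers differ from surface-based tools by a method-dependent factor,
  which matters when comparing against volumes computed elsewhere.
* The mutation model is single-rotamer and rigid; it will overestimate
  clashes that a real side chain would avoid by repacking, and it reports
  estimates, not energies.
* The frame-based rotation angle assumes the moving domain is internally
  rigid between the two structures.
* The ITC model is strictly one-site; competitive or two-site regimes are
  out of scope, as are bivalent-analyte and mass-transport SPR models.
* No crystallographic symmetry expansion: templates must contain both
  protomers explicitly.

## A worked toy run

```{r demo}
demo <- runDemo(seed = 1)
reportResults(demo$compatibility)
demo$itcFit
demo$sprFit
all(demo$checks)
```

The close template forces the two placed antibody bodies to interpenetrate
(clash verdict, volume matching the analytic sphere-lens ground truth);
the wide template clears them; the ITC fit recovers the planted
one-antibody-per-dimer stoichiometry n = 1.5; the SPR fit recovers
KD = 1 nM; the planted epitopes are called exactly.
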