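---
title: "Models and methods behind npmhub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npmhub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(npmhub)
```

`npmhub` analyses how the pentameric N-terminal domain of nucleophosmin
(Nter-NPM1) recognises nucleolar localization signals (NoLS). This
vignette records the models the package implements, the assumptions and
tunable parameters behind them, what the synthetic-data generators do and
do not emulate, and the design decisions taken where the problem left a
genuine choice.

## 1. NoLS scanning

A NoLS is a short disordered stretch dense in K/R residues. The scanner
slides a 13-residue window (slippage 1) along the sequence and scores each
window

    score(w) = min(1, n_basic(w) / s_max),    s_max = 6,

calling a window when `score > 0.8` and merging overlapping called windows
into candidate segments. The saturating linear score is a deliberate,
fully transparent surrogate for neural-network NoLS predictors, whose
weights are not reproducible; `s_max = 6` is the basic-residue count of
the experimentally confirmed Fbw7γ NoLS epitope, so that epitope saturates
the score. Consequences to keep in mind:

- the surrogate has no notion of residue context or secondary structure;
  it reproduces *charge-density* calls only;
- the 0.8 threshold is applied per window, not to a smoothed profile
  (the simplest reading, and segment merging makes the two nearly
  equivalent at slippage 1);
- histidine is not counted as basic at physiological pH; `basic_set`
  makes this configurable;
- peptides shorter than the window are scored as a single truncated
  window and flagged, rather than silently skipped — useful for the short
  control peptides in the titration panel.

Coordinates are 1-based inclusive throughout; the BED-like segment export
converts to 0-based half-open.

## 2. Equilibrium binding model and fitting

Titrations hold the dansylated peptide fixed (n = 5 µM) and vary the
protein concentration A₀. The observed fluorescence is modelled by the
exact bimolecular equilibrium ("quadratic") form

    F(A₀) = C + k·A₀ + (B/n)·[PA],
    [PA]  = ((n + A₀ + K_D) − sqrt((n + A₀ + K_D)² − 4·n·A₀)) / 2,

where B is the total fluorescence change, C the zero-protein fluorescence
and k a linear drift at high protein concentration. Under pseudo
first-order conditions (n ≪ K_D) this collapses to the hyperbolic form
F = C + k·A₀ + B·A₀/(K_D + A₀); the package asserts the sup-norm
difference is below 10⁻³·B at n/K_D = 10⁻³.

**Fitting.** Parameters are estimated by Levenberg–Marquardt least squares
on (log K_D, B, C, k), the log keeping K_D positive. A hand-rolled LM is
used because the recovery contract — noise-free synthetic curves must
return K_D to 10⁻⁶ relative — needs robust behaviour on zero-residual
problems, where `nls()`'s relative-offset convergence test is unreliable.
Choices, in order of appearance:

- *Initialisation*: K_D₀ at the concentration reaching half the observed
  range, B₀ the observed span, C₀ = F(0), k₀ the terminal slope; if the
  first fit fails to converge or explains the data no better than a
  straight line, a multistart over five log-spaced K_D₀ follows.
- *Weighting*: by default a second, reweighted pass uses weights
  1/(µ̂ − Ĉ)² (floored at 5% of the signal span) — the likelihood weighting
  for multiplicative (constant-CV) fluorescence noise, written in terms of
  the fitted *signal* rather than total fluorescence so that the estimate
  is exactly invariant under affine rescaling F → αF + β. This matters for
  the weakly identified high-K_D mutants (K_D ≈ 650 µM probed only to
  400 µM), where unweighted fitting is visibly biased.
- *Replicates* are fitted independently and K_D reported as mean ± s.d.
  across replicates, matching how triplicate experiments are summarised
  (rather than a pooled fit, whose standard error answers a different
  question).
- *No interaction*: a curve whose signal is indistinguishable from a
  straight line in A₀ is flagged instead of producing an arbitrary K_D,
  mirroring the "no interaction" outcome for control peptides.
- *Stoichiometry*: an optional multiplier m rescales the protein
  concentration entering the binding term (A_eff = m·A₀). On data
  generated with 1:1 peptide/monomer stoichiometry the fit recovers
  m = 1.00 ± 0.01; the x-axis is interpreted as *monomer* concentration,
  which is what makes 1:1 the expected answer for a pentameric receptor
  binding one peptide per subunit.
- Trial LM steps clamp log-scale parameters to ±30 to avoid overflow;
  ionic-strength variants are represented as separate datasets, with no
  explicit salt term (they are fitted identically).

The preset table stores each measured complex's K_D (and reported s.d.)
with documented optical defaults B = 1, C = 0, k = 0.001 µM⁻¹: the raw
fluorescence scales were never published, so these are declared, not
inferred — chosen so the linear drift is visible but small.

## 3. Coarse-grained structural models

Each residue becomes two beads: a backbone bead on the Cα and a sidechain
bead at the sidechain heavy-atom centroid (glycine's rides on the Cα).
Sidechain beads carry the formal charge (K/R +1, D/E −1); bead radii
(1.5–2.0 Å) are deliberately compact so that an ion pair, under the energy
model below, equilibrates near 3.5 Å — inside the conventional 4 Å
salt-bridge cutoff. Peptides are flexible chains with fixed 3.8 Å virtual
Cα–Cα bonds, a 120° virtual bond angle, and free virtual torsions about
consecutive Cα–Cα axes (n − 3 of them); a torsion rotates everything
beyond its bond, including the sidechain of the bond's distal residue.

**Energy model.** The score is deliberately minimal, because the
conclusions it must support are electrostatics-driven:

    E = Σ_pairs 332·q_i·q_j / (4·r²)  (ε(r) = 4r, cutoff 40 Å)
      + Σ_pairs ε_rep·(σ_ij / r)⁸     (σ_ij = radius_i + radius_j, ε_rep = 2)
      [+ bias_k · Σ_mapped |x − x_template|²  during template-biased search]

in kcal/mol with charges in e and distances in Å. The distance-dependent
dielectric ε(r) = 4r mirrors the screening used in the minimisation
protocols this replaces; the r⁻⁸ soft sphere keeps the landscape smooth
for annealing and gradient descent. Near-coincident beads are evaluated at
a capped distance (0.5 Å) and flagged. The same screened Coulomb term,
evaluated per unit probe charge, provides the surface-potential maps; this
is a *qualitative* patch locator, not a Poisson–Boltzmann solver, and no
absolute potential should be read off it.

**Accessibility and burial.** Probe points closer than bead radius plus a
1.4 Å solvent probe to any bead are excluded from potential maps and
cavity grids. Cavity detection marks an accessible grid point (1 Å
spacing) as buried when rays in at least 9 of 14 scan directions (6 axes,
8 cube diagonals) pass within blocking radius (bead + probe) of a bead;
buried points are 6-connectivity labelled and the largest component is
reported with volume = point count × spacing³. The 9-of-14 criterion and
probe radius are declared constants; the cavity volume of the proprietary
detector the protocol originally used is *not* a target of this
implementation. On a fixed axis-aligned grid, rigid-motion invariance
holds only up to grid re-sampling; the tests allow for that.

The acidic patch is found by taking the lowest-potential 5% of probes
(negative only), single-linkage clustering at 3 Å, keeping the largest
cluster and reporting residues with a charged bead within 6 Å.

## 4. The synthetic crown receptor

`make_toy_receptor()` builds the world the docking tests live in: five
monomers with exact 5-fold symmetry about z, each contributing three
acidic beads and eight neutral wall beads (bead count = n_fold × (3 + 8),
total charge −15 e). The acidic beads form three stacked rings — a tight
equatorial ring (radius 3.6 Å) flanked at z = ±6 Å by rings flared 2 Å
outward, staggered 36° per level — inside a neutral wall at 9 Å. The
geometry was *co-designed once* with the energy model so that, by
construction:

- the solvent-accessible electrostatic minimum sits on the pore axis (the
  narrow equator keeps every accessible lumen point within ~1.5 Å of the
  axis), and the pore centre is recorded as the planted optimum;
- a bead at the focus is within 4 Å of the whole equatorial ring, so a
  buried basic sidechain forms several salt bridges at once;
- the flared rims catch a *second* basic sidechain of a chain exiting the
  pore, making the global optimum of a basic tripeptide a genuinely
  multivalent pose rather than a single buried charge.

This receptor emulates the topology that matters — a crown-shaped
pentamer whose negative surface funnels into a central cavity — and
nothing else: no realistic monomer fold, no neutral-polar surface
chemistry, no receptor flexibility. A green docking test therefore
establishes that the *protocol* finds and ranks planted electrostatic
optima reproducibly; it says nothing about all-atom pose accuracy.

## 5. The hierarchical docking protocol

Stage 1 enumerates all L − 2 tripeptides and docks each with 10
independent simulated-annealing runs in a 20 Å sphere centred on the
detected cavity; per-run best poses are clustered at 1.2 Å RMSD (greedy,
energy-ordered, receptor-frame RMSD without re-superposition, ties broken
by provenance) and cluster representatives retained. Stage 2 docks every
contiguous hexamer window under a harmonic template bias toward the
representative poses of its two constituent tripeptides (positions 1–3
and 4–6), pooling up to 25 template combinations per window, best
combinations first. Stage 3 docks the whole peptide, each of the 100
top-scoring hexamer poses anchoring its own sequence window. Stage 4
minimises the top pose: steepest descent to RMS gradient ≤ 0.005, then
Polak–Ribière conjugate gradients to max |gradient| ≤ 4×10⁻⁴, central
finite differences over the pose degrees of freedom (rigid body +
torsions), with a backtracking line search guaranteeing a non-increasing
energy trace. Salt bridges are reported as acidic(receptor)–basic(peptide)
sidechain-bead pairs within 4 Å, sorted by distance, peptide residues in
parent numbering (the docked 13-mer PFCRRRMKRKLDH maps to residues 44–56
of Fbw7γ).

Decisions where the protocol description left room:

- *Search engine*: simulated annealing (geometric schedule, default
  T 5 → 0.05 over 3000 steps plus 300 downhill-only quench steps, move
  mix 40% translation / 30% rigid rotation / 30% torsion, proposal scales
  shrinking with √T) replaces the original evolutionary search; 10 runs
  per fragment are retained. The annealing kernel is compiled (Rcpp) and
  draws from R's RNG, so every stage is bit-reproducible from
  (config, seed); per-run seeds are derived from the base seed, a
  fragment/window offset and the run index.
- *Gradient thresholds* are taken at their stated numeric values in the
  score's native units (kcal/mol per Å or per rad); the "0.005 Å" unit
  attached to the steepest-descent threshold in the source protocol is
  read as a units typo for a gradient.
- *Clustering input*: all per-run best poses (not every visited pose)
  enter clustering.
- *Hexamer assembly*: contiguous windows guided by their two constituent
  tripeptides; the combination count is capped (25) to bound runtime.
- *Template anchoring*: each hexamer template anchors its own sequence
  window in the full peptide; the bias steers the search only and is
  excluded from reported energies. With `bias_k = 0` template docking
  degenerates exactly (same seeds, same poses) to free docking.
- *Conformer generation*: torsions are sampled inside the search instead
  of pre-generating minimised rotamer libraries.
- The mean pairwise RMSD of the top-ten poses is reported but has no
  reference value: it is a property of the scoring function, and this
  package's score is declaredly not the original one.

## 6. Trajectory generation and analytics

The generator applies an Ornstein–Uhlenbeck process per bead coordinate
about the start position: x_{t+1} = x₀ + (1 − λ)(x_t − x₀) + η, with the
innovation scaled so the *stationary* per-coordinate s.d. equals
σ_anchor (default 0.5 Å) for anchored residues (default 1–6, the
N-terminal half of the docked NoLS peptide) and σ_free (default 3 Å)
otherwise; λ = 0.1 per frame, 500 frames at a nominal 5 ps/frame. Frame 0
is exactly the start coordinates. This emulates one phenomenon only — a
bound peptide whose anchored residues hold their docked position while
the rest explores conformations — with no force field, no receptor
dynamics and purely nominal time units; a green test establishes the
analytics, not any molecular mechanics.

Analytics: Kabsch superposition (SVD with a proper-rotation determinant
correction; collinear point sets are rejected as degenerate), RMSD time
series (each frame superposed on a reference frame via a fit selection,
default the receptor Cα beads, measured over a second selection), and
per-residue profiles sqrt(mean_t |x_i(t) − x_i(ref)|²). All averaging is
quadratic, so the residue-wise quadratic mean of the profile equals the
quadratic time-average of the selection RMSD exactly. Profiles average
the full trajectory by default, with an optional burn-in.

## 7. Pipeline and reproducibility

`run_config()` / `validate_config()` / `run_all()` orchestrate
scan → fit → dock → trajectory from one configuration object: validation
(schema and cross-field checks, e.g. the dock stage requires a receptor)
runs before any stage; each stage derives its seed from the global seed by
stage-name hashing so stages can be re-run in isolation; outputs are plain
CSVs plus a JSON manifest (package version, seed, per-stage seeds, config
hash). A stage failure is logged and the remaining stages still run. This
function surface *is* the package's command-line story: the analysis is
meant to be driven from R or Rscript, and `scripts/acceptance.R` shows the
pattern.

## 8. Known limitations

- The scanner reproduces charge-density NoLS calls, not trained-predictor
  scores.
- All structural energetics are coarse-grained and screened-Coulomb; pose
  geometries are meaningful at bead resolution (a few Å), not at contact
  chemistry resolution.
- The binding fitter assumes independent multiplicative noise; correlated
  instrument drift beyond the linear term is not modelled.
- High-K_D presets (≥ 500 µM) probed to 400 µM sit on a shallow
  K_D–B ridge; even with likelihood weighting their estimates are skewed
  at realistic noise, which is faithfully reflected in wide
  across-replicate s.d. values.
- Grid-based cavity results depend on grid alignment at the ±1 grid-cell
  level; only statements robust to that should be drawn from them.
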