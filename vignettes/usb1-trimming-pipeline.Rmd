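---
title: "Models and methods: free-energy, kinetic and structural analysis of RNA 3'-end trimming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: free-energy, kinetic and structural analysis of RNA 3'-end trimming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotrim)
```

## The scientific problem

Usb1 is a 3'→5' exoribonuclease of the 2H phosphodiesterase superfamily that
trims the oligo-uridine tail of U6 snRNA, leaving a 2',3'-cyclic phosphate.
Catalysis is intramolecular transphosphorylation: the 2'-oxygen of the
penultimate (n−1) nucleotide, deprotonated by a histidine general base,
attacks the adjacent scissile phosphate while a second histidine protonates
the 5'-oxygen leaving group of the terminal (n) nucleotide. Three coupled
questions define the system:

1. **Mechanism** — in what order do nucleophile deprotonation, phosphoryl
   transfer and leaving-group protonation occur, and is the transition state
   tight (associative) or loose (dissociative)?
2. **Substrate preference** — why does the enzyme remove 3'-terminal
   adenosines ~20-fold more efficiently than uridines (the origin of
   adenylated U6 species when Usb1 is lost)?
3. **Extent of processing** — what stops trimming at the mature 107-nt form
   of U6 when the enzyme could in principle keep cutting?

This package re-implements, at desk scale, the computational chain used to
answer them: biased sampling on reaction surfaces, free-energy-surface (FES)
reconstruction and minimum-free-energy-path analysis, transition-state-theory
(TST) rates and isotope-effect predictions, solvation and contact-geometry
analysis, single-cleavage Michaelis–Menten kinetics, and a
secondary-structure-gated model of distributive 3' trimming.

## Model surfaces instead of an electronic-structure engine

In QM/MM studies of this enzyme the free-energy landscapes come from
molecular dynamics on an electronic-structure energy function. That
energy function is not the object of interest here — the downstream
*algorithms* are — so the package replaces it with analytic model surfaces
whose stationary points are known exactly (`make_double_well()`,
`make_mechanism_surface()`, `make_harmonic_well()`). Every listed feature has
an analytically vanishing gradient, which turns each pipeline stage into a
test against oracle-grade ground truth.

The three-coordinate mechanism surface is built from C¹ pieces of quintic
smoothersteps in the collective variables (CVs)
*nucleophile deprotonation* (x₁), *phosphoryl transfer* (x₂) and
*leaving-group protonation* (x₃), each running from −0.8 Å (reactant) to
+0.8 Å (product):

* a monotone ramp `P(x₁)` of height `deprotonation_cost` — the proton moves
  to the base first, ending in a *shoulder* with zero gradient but no
  reverse barrier (the deprotonated state is not a genuine intermediate);
* a ridge `Q(u)` along the mean of x₂ and x₃ peaking at `main_barrier`
  (default 21.6 kcal/mol) — the single rate-limiting saddle;
* a coupling `K·h(x₁)·(u+a)²` that forbids phosphoryl motion before
  deprotonation completes (K = 2·main_barrier/a², large enough that corner
  cutting always costs more than the staged route);
* a synchrony term `M·(v − α·φ(u))²` in the difference coordinate
  v = (x₂−x₃)/2; the `asynchronicity` parameter α displaces the saddle so
  one of the two late coordinates leads without changing the barrier.

`deprotonation_cost` defaults to 6 kcal/mol. Simulations of this reaction
characterise the step only as modestly uphill, without a number, so the
default is a package choice: far enough below the 21.6 kcal/mol main barrier that the
shoulder is a distinct feature of the landscape, high enough to be visible
on 2D slices. The product basin is placed at min(2, main_barrier/4) kcal/mol
so that the reactant is always the global minimum (verified by exhaustive
grid scan in the tests).

## Collective variables

All three CV kinds carry length units (Å):

* `antisym_stretch(A, H, B)` = d(A,H) − d(H,B), the coordinate of an atom in
  flight from donor A to acceptor B;
* `relay_zeta` — the average of the two antisymmetric stretches of a
  donor–H1–shuttle–H2–acceptor relay. This is a deliberate topological
  simplification of the centre-of-excess-charge coordinate used for
  triester-like mechanisms: it is monotone in overall relay progress but is
  **not** the literal Fermi-weighted coordinate, and the package makes no
  claim beyond topology for it;
* `distance_cv` for contact monitoring.

Sign convention (the package's own): every CV
increases as the reaction proceeds, so reactants sit at negative values. For
the phosphoryl-transfer coordinate this means the atom order is
(O5', P, O2') — nucleophilic attack shortens d(P,O2') and lengthens
d(O5',P), moving the CV upward. Analytic gradients are supplied for every
CV and are validated against central finite differences at 10⁻⁶ tolerance;
rigid-motion invariance is property-tested to 10⁻⁹ Å.

## The sampler: metadynamics in CV space

`run_multiwalker()` integrates Langevin dynamics (BAOAB splitting) *directly
in CV space* with effective masses, rather than atomistic MD with a biased
CV. This surrogate preserves the bias/FES mathematics exactly — the quantity
the estimator sees is identical — while removing the MD engine. Defaults
follow the standard protocol for this class of reaction coordinate: hills of
height 0.1 kcal/mol and width σ = 0.1 Å deposited every 200 steps of 0.5 fs
(one hill per 100 fs per walker), T = 298.15 K, friction 10 ps⁻¹, effective
mass 0.0239 kcal mol⁻¹ ps² Å⁻² (≈10 u). Reflecting walls at the domain box
stand in for the chemical boundedness of the real coordinates.

Multi-walker sampling is synchronous at deposition granularity: all walkers
advance `pace` steps, then each deposits one hill into the shared log, and
from the next step every walker feels all hills deposited so far. With one
walker this reduces bit-for-bit to the single-walker sampler. Runs are
reproducible under a fixed seed (R's RNG drives the noise). Standard
fixed-height metadynamics is the default, matching the fixed-height
protocol these landscapes are sampled with in practice; a well-tempered `bias_factor` is available but off by default.
Gaussian contributions below e⁻³⁰ are truncated — a deterministic cutoff far
below any quantity of interest.

## FES estimators and why there are two

`reconstruct_fes()` defaults to the textbook estimator F(s) = −V_bias(s)
from the final accumulated bias. In fixed-height metadynamics this estimator
does not converge pointwise: once the wells are full the bias *oscillates*
around the true (inverted) surface with an amplitude of several hill
heights, which at h = 0.1 kcal/mol produces barrier errors up to
±0.7 kcal/mol at the default budget. The `average_from` argument therefore
enables the equally standard variance-reduction estimator: the average of
the running −V_bias over the later fraction of the deposition history
(implemented exactly, as per-hill weights). Averaging over the last half
reduces the double-well barrier error to about ±0.2 kcal/mol at the same
budget. Use the default for diagnostics (e.g. `convergence_check()`, which
compares first- and second-half reconstructions) and `average_from = 0.5`
for quantitative recovery.

Default grid: the hills' bounding box padded by 3σ, at 0.02 Å resolution.

### Problem sizes

The package's standard double-well recovery experiment is 8 walkers ×
60 000 steps (2 400 hills). The hill count needed to fill two 5 kcal/mol
wells spanning ~3 Å is roughly 5 × 3 / (0.1 × σ√(2π)) ≈ 600, so the default
budget is ~4× fill — enough for all walkers to diffuse across the whole
domain repeatedly. Full 3D reconstruction of the 21.6 kcal/mol mechanism
surface by sampling is *not* a desk-scale computation (converged 3D landscapes of this kind take
~10⁶ hills over hundreds of walkers); 3D mechanism analysis here runs on the
exact surface grid (`surface_fes_grid()`), which is the appropriate oracle
for path and ordering algorithms.

## Path extraction and mechanism ordering

`minimax_path()` finds, among all grid-adjacent paths (king moves: all
3^d − 1 unit offsets; bottleneck-optimal paths are insensitive to the
adjacency choice, diagonal moves just smooth them), a path minimising the maximum free
energy en route — Dijkstra on the bottleneck metric, ties broken by hop
count, then predecessor order. The barrier is measured from the reactant
basin minimum (steepest descent from the reactant node), and non-finite
grid values act as masked, impassable regions. The implementation is tested
for exact agreement with two independent oracles: exhaustive path
enumeration on small grids and threshold-connectivity search on 100 random
grids.

`mechanism_order()` reports, per CV, the fraction of reactant→product
displacement completed at the path's transition state. The tightness call
uses the phosphoryl-transfer taxonomy: TS progress of that CV within the
central 25% of its range ⇒ *tight* (associative, SN2-like — nucleophile
bound before the leaving group departs); beyond the central 60% ⇒ *loose*;
otherwise *indeterminate*. Zero-displacement CVs report "not applicable"
rather than failing.

## Rates and isotope observables

`eyring_rate()` is plain TST, k = κ·(k_BT/h)·exp(−ΔG‡/RT), with CODATA
constants and κ = 1. The temperature is always echoed because the
barrier→rate conversion is meaningless without it; 298.15 K is the default.
Evaluating the 21.6 kcal/mol barrier gives 9.1×10⁻⁴ s⁻¹ at 298.15 K and
3.8×10⁻³ s⁻¹ at 310 K — the same order as the measured kcat values
(0.5–12 ×10⁻³ s⁻¹), and agreement with measured turnover is claimed only at
that order-of-magnitude level, since a barrier-to-rate comparison depends
on the (often unreported) conversion temperature.

`gross_butler()` builds the proton-inventory curve
k_n = k₀·∏(1 − n + n·φᵢ). With exactly one fractionation factor the curve
is a straight line (zero chord deviation, to machine precision) and
k_H/k_D = 1/φ — the diagnostic that the rate-limiting TS moves a single
proton; two or more sites bow the curve below its chord.

`semiclassical_kie()` is a harmonic zero-point-energy surrogate for the
H/D effect on the in-flight proton: deuterium frequencies idealised as
ν_H/√2 (real X–H/X–D ratios are 1.35–1.41; the idealisation is documented,
not hidden), giving KIE = exp[(ν_GS − ν_TS)(1 − 1/√2)·hc/2k_BT]. A fully
lost 3000 cm⁻¹ stretch gives ≈8.3; a TS stretch of ≈2524 cm⁻¹ reproduces
the predicted 1.4. Path-integral methods are out of scope; inverse effects
(ν_TS > ν_GS) are computed but flagged.

## Hydration and contact geometry

`rdf()` normalises per frame by shell volume 4πr²dr and a bulk number
density — supplied, or estimated from the outer 20% of the histogram range.
`first_shell_count()` finds the first minimum of the lightly smoothed g(r)
after its first peak (threshold 1.3) and reads the integrated RDF there;
featureless curves return an explicit "no shell" outcome. The generator
`sample_hydration_shell()` plants a known first-shell occupancy over an
ideal-gas background, which the tests recover exactly for backgrounds up to
0.02 Å⁻³.

`detect_hbonds()` uses heavy-atom N/O distance ≤ 3.5 Å, flagging
3.3–3.5 Å as weak; the bracket follows the observed contact geometry (a
2.7 Å serine–phosphate bond is unambiguous, 3.3 Å is "long", 3.7 Å cannot
hydrogen bond). Donor–H–acceptor angles (≥120°) are tested only when
explicit hydrogens exist. `glycosidic_chi()` classifies syn as
χ ∈ (−30°, 90°] — the standard nucleic-acid window. Altloc policy: highest occupancy wins,
ties go to altloc A. `kabsch_rmsd()` is the usual SVD superposition with the
determinant correction, cross-checked in tests against direct minimisation
over rotations.

The deposited co-crystal structures (wild type with AMP; the inactive
H208Q mutant with UU- and UA-RNAs) are inputs to this module when
available locally; they are not shipped with the package. All geometry
tests run on synthetic structures built in code and labelled synthetic.

## Kinetics

`generate_mm_kinetics()` simulates initial rates
v = kcat·E₀·S/(Km+S) + N(0, σ) truncated at zero, over the two-fold
dilution series 0.85–55 µM by default. The error model is a package choice
(none is stated for the source data); truncation matters only at noise
levels far above the 5% used in the studies here.
`fit_michaelis_menten()` initialises from a Hanes–Woolf linearisation
(S/v vs S) and refines by Levenberg–Marquardt least squares; standard
errors come from the asymptotic covariance, kcat = Vmax/E₀ assumes fully
active enzyme, and a Km outside [min(S)/50, 50·max(S)] is flagged
ill-determined rather than silently reported. Noiseless data round-trips
the generating parameters to 10⁻⁶ relative; at 5% noise with duplicates the
median Km error is ~8% over 100 seeds.

`efficiency_table()` computes kcat/Km on the 10³ M⁻¹ s⁻¹ scale (numerically
kcat[10⁻³ s⁻¹]/Km[µM]) and relatives from *unrounded* quotients, with
display rounding of 2 decimals / 2 significant figures. Display-rounded values can differ in the last digit from tabulations
rounded along other paths; the unrounded columns are authoritative.

## Secondary-structure-gated trimming

The active site holds exactly two single-stranded nucleotides, and cleavage
consumes the 2'-OH of n−1. `trimming_extent()` therefore removes the
3'-terminal residue while (i) the RNA is above the length floor, (ii)
positions n and n−1 are both unpaired, and (iii) n−1 carries a 2'-OH. On a
111-nt U6-like input paired through position 106 this stalls at 107
nucleotides — the mature form — because positions 107/108 are the last
unpaired pair that fits the site. A 2'-deoxy at n−1 blocks processing
entirely; at n−2 it permits exactly one cut (the single-cleavage substrate
design). Pairing is an *input* (dot-bracket or mask), never predicted; the
default length floor is 1, consistent with complete degradation of an
unstructured oligo.

`simulate_distributive_trimming()` treats each length as a kinetic species
of a first-order chain (the enzyme is distributive — it releases substrate
after every cut) with step rates looked up from the terminal dinucleotide.
The default rate map uses the four measured relative efficiencies
(UA 22, AA 7.2, AU 0.63, UU 1.0), extends them to unmeasured A/U-terminal
dinucleotides via the observed insensitivity to the n−1 identity, and
carries order-of-preference placeholders for G- (0.5) and C-terminal (0.1)
steps, which are flagged qualitative in the object itself. Deterministic
solutions use the matrix exponential of the bidiagonal generator;
stochastic ensembles use exponential waiting-time (Gillespie) sampling.
The two agree to total-variation distance < 0.01 at 10⁴ replicates in the
package's tests.

## What the synthetic generators do and do not show

The generators emulate: landscapes with known basins/saddles and their
hill-by-hill sampling; solvation shells with known occupancy over an ideal
gas; Michaelis–Menten data with Gaussian noise; pairing-gated sequential
cleavage. They do not emulate: real electronic structure or charge
transfer, explicit water structure (hydrogen-bond networks, orientational
correlations), enzyme conformational dynamics, or correlated/heteroscedastic
assay error. Passing tests therefore demonstrate that the *algorithms*
recover known truth under realistic noise — not that the model surfaces are
accurate chemistry. The one place real data would enter — contact geometry
on the deposited crystal structures — requires those coordinate files,
which must be supplied locally.

## Numerical choices and degenerate inputs

* Stationary points of the mechanism surface are flat to second order along
  some axes (smootherstep endpoints); grid analyses are unaffected because
  values change strictly away from features, and gradient checks use the
  stated 10⁻⁶ magnitude threshold.
* `minimax_path()` tie-breaks: bottleneck value, then path length, then
  predecessor index — deterministic on every platform.
* `find_basins()` merges connected equal-valued plateau minima and reports
  flat surfaces as "no basins" with a message, not an error.
* Empty hills logs reconstruct to a flat zero surface; axes excluding >1%
  of hill centres warn.
* Zero-displacement CVs in `mechanism_order()` report NA progress.
* `first_shell_count()` never throws on featureless input; it returns an
  explicit no-shell outcome.
* Coincident atoms in CVs, non-rectangular FES files, malformed hills rows
  (with line numbers) and truncated XYZ frames all fail loudly and early.

## Known limitations

* CV-space Langevin dynamics has no atomistic detail: transmission
  coefficients, friction and effective masses are phenomenological.
* The ζ relay coordinate is a topological stand-in, not the literal
  centre-of-excess-charge coordinate.
* The semiclassical KIE ignores tunnelling and anharmonicity.
* The trimming rate map's G/C entries are qualitative placeholders.
* The final-bias FES estimator should not be used for quantitative barriers
  at fixed hill height; use `average_from`.
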