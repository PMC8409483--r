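---
title: "Computing and learning tautomer free energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and learning tautomer free energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tautofe)
```

## The problem

A tautomer pair is two structural isomers that interconvert by moving a
single proton together with a rearrangement of double bonds (keto/enol,
lactam/lactim, amine/imine, ...).  The tautomeric free energy difference
$\Delta_t G$ decides which form dominates in a given environment, and a
1–2 kcal/mol error in it translates directly into an error of the same
size in any downstream binding or solubility prediction.  `tautofe`
implements two complementary routes to $\Delta_t G$ over a differentiable,
parameterized potential energy function, and a training loop that adjusts
the potential's parameters so that computed free energies match a set of
reference (experimental) values.

The two routes are:

1. **Relative alchemical free energy calculation.**  A single-topology
   hybrid system is built whose atom list is the superset of the two
   tautomers — the atoms of tautomer 1 plus one extra hydrogen bonded to
   the acceptor atom.  Each physical endstate ignores exactly one
   hydrogen (the dummy), and the two endstate energies are mixed linearly,
   $E(\lambda) = (1-\lambda)E_1 + \lambda E_2$.  Sampling all
   $\lambda$-states with Langevin dynamics and estimating the endpoint
   difference with MBAR gives $\Delta_t G$ with full classical
   configurational entropy — no harmonic approximation.
2. **(Quasi-)RRHO thermochemistry.**  Conformers are generated, minimized
   and pruned; each minimum contributes an ideal-gas
   rigid-rotor/harmonic-oscillator free energy (with a free-rotor
   replacement for low modes); conformer free energies are combined by
   Boltzmann weighting, $G = -RT\,\ln\sum_k e^{-G_k/RT}$; and
   $\Delta_t G$ is the difference between the two tautomers' weighted
   values.  A thermodynamic-cycle helper adds externally supplied
   transfer free energies to move from gas phase to solution.

The package's own account of why both routes exist: the RRHO picture
fails precisely for tautomers, whose proton migration creates shallow,
multi-minimum landscapes; the alchemical route is the reference the RRHO
route is compared against (`cmd_compare()` produces that table).

## Input handling and filtering

Pairs arrive as SMILES in a simple TSV (`name`, `smiles1`, `smiles2`,
`logK`) or a DataWarrior-style export in which the two SMILES columns,
the log *K* column and an optional solvent column are auto-detected and
rows are named `tp_<row>`.  Deposited log *K* values are base-10
(`logk_to_free_energy()` has a `base` argument should a source use
natural logs) and convert as $\Delta G = -RT\ln 10\cdot\log K$ at
298.15 K by default.

`parse_and_filter_pairs()` applies, in order: an aqueous-solvent rule, a
$|\log K|\le 10$ rule (missing values fail here), a no-formal-charge
rule, a no-iodine rule, and the structural rule that the two molecules
must be related by exactly one hydrogen moving between two heavy atoms
with a bond-order rearrangement.  An element whitelist (for potentials
trained only on C/H/N/O), a stereo-bond-change exclusion and a named
blocklist for known-bad database rows are available but off by default.
Every row is attributed to the first rule it fails, so the per-rule
counts always sum to the input row count.

The proton shift itself is found by enumerating all element-matched
heavy-atom graph isomorphisms (igraph's VF2) and keeping those under
which exactly one heavy atom loses a hydrogen and exactly one gains it.
Candidates that differ only by a molecular symmetry are collapsed to a
canonical representative; genuinely ambiguous cases are rejected — the
method is only defined for a unique single shift.  When a cis/trans
stereo bond exists in only one tautomer, the pair is stored with that
tautomer first (its geometry defines the stereochemistry that the
hybrid simulation preserves) and the sign of log *K* flips;
`direction_flipped` records this.

A note on indices: everything in this package is 1-based, following R
convention (atom 1 is the first atom of tautomer 1; the dummy hydrogen
is the last atom of the superset).

## The potential and the alchemical Hamiltonian

The bundled potential family (`toy_model()`) is a small bonded force
field: harmonic bonds $\tfrac12 k (r-r_0)^2 - D$ typed by element pair
and bond order, harmonic angles typed by the outer elements and the
central atom's hybridization, and a soft exponential repulsion
$A e^{-r/\rho}$ between non-bonded (1-4 and beyond) atoms.  The
well-depth offsets $D$ act like per-bond formation energies — they are
the lever through which a parameter change shifts one tautomer relative
to the other, playing the role that the final-layer weights of a
machine-learned potential play at full scale.  Parameters live in named
groups ("weight-like" force constants, "bias-like" equilibrium values
and offsets), serialize to JSON, and every model exposes analytic
energies, coordinate gradients and parameter gradients (all verified
against central finite differences in the test suite).  An external
machine-learned potential can be adapted by implementing the same four
generics (`pot_energy()`, `pot_grad()`, `pot_energy_many()`,
`pot_pgrad_many()`); nothing else in the pipeline changes.

Because strongly perturbed intermediate states can let nuclei wander,
every covalent bond of the superset topology (both tautomeric hydrogen
bonds included) carries a flat-bottom restraint
$H(|\Delta|-r_{fb})\,\tfrac12 k(|\Delta|-r_{fb})^2$,
$\Delta = r_{ij}-r^0_{ij}$: zero within the well, harmonic beyond it,
$C^1$-continuous at the boundary (Heaviside convention $H(0)=0$).
Heavy-heavy pairs use $r^0 = 1.3$ Å, $r_{fb} = 0.3$ Å,
$k = k_BT/0.1\,\text{Å}^2$; X–H pairs use $r^0 = 1.02$ Å (the average
C–H/N–H/O–H equilibrium length), $r_{fb} = 0.4$ Å,
$k = k_BT/0.2\,\text{Å}^2$.  Two deliberate choices here: first, the
force constants are read as $k_BT$ divided by a squared length so that
the term carries energy units; second, the restraints are applied
identically at every $\lambda$ and included in the reduced potential, so
they are part of the sampled Hamiltonian and MBAR remains
self-consistent (their direct contribution cancels from the endpoint
difference).  Restraining *all* covalent bonds (not only those of the
migrating hydrogen) is the default; the restraint builder is a separate
function for users who want a narrower set.

The dummy hydrogen is placed by sampling 100 points uniformly on a
1.02 Å sphere around the acceptor and keeping the point of lowest
energy under the endstate potential in which that hydrogen interacts
plus the restraints; ties break to the first sampled index so placement
is deterministic given its seed.

## Sampling

Each $\lambda$-state is prepared by (re)placing the dummy, minimizing
under that state's Hamiltonian (L-BFGS-B to a gradient max-norm of
10⁻³ kcal/mol/Å by default) and running BAOAB Langevin dynamics —
half-kick, half-drift, Ornstein–Uhlenbeck velocity refresh, half-drift,
half-kick — with Maxwell–Boltzmann initial velocities.  Production
defaults follow the reference protocol: 11 equidistant $\lambda$-states
including both endpoints, 300 K, collision rate 10 ps⁻¹, 0.5 fs step,
200 ps per state, 5 replicates with independent seeds, 300 decorrelated
snapshots per state.  The statistical inefficiency
$g = 1 + 2\sum_t (1-t/T)\rho_t$ (autocorrelation sum truncated at its
first non-positive term) sets the thinning stride; frames are then
evenly subsampled to the target count.  Because $g$ is itself a noisy
estimate, a window that comes up short is deterministically re-run at
double length (up to twice) rather than aborting a whole campaign.  The
first 10% of stored frames are discarded as equilibration.  All child
seeds derive from one master seed through a dedicated counter-based
stream, so a full campaign is bitwise reproducible, and no constraint
algorithms are used (masses are standard atomic masses in amu).

Desk-scale work uses deliberately smaller protocols.  The sizes used by
the test suite and the acceptance script — chosen once as what a
practitioner would call a minimal but honest scaled-down experiment —
are: the analytic harmonic benchmark at 11 $\lambda$ × 30 000 steps of
1 fs (unit-mass particles, reduced units $\beta = 1$); toy molecular
pairs at 11 $\lambda$ × 8 000 steps of 0.5 fs with a 15 ps⁻¹ collision
rate, 40 snapshots per state, one replicate; the
thermochemistry-comparison diatomic at 11 $\lambda$ × 10 000 steps, two
replicates.  The toy-pair friction deserves a note: high friction
(100 ps⁻¹) decorrelates the *energy* series fastest, but the dummy
hydrogen's orientation is a diffusive mode whose exploration time scales
with $\gamma$, and at high friction it stays frozen within a window —
campaign-to-campaign scatter then exceeds the MBAR uncertainty while the
energy-based inefficiency estimate sees nothing wrong.  At 15 ps⁻¹ the
measured inter-campaign scatter matches the reported $\sigma$, which is
the property that makes an uncertainty honest.

## MBAR, uncertainties and reweighting

The reduced potential is $u(x,\lambda;\theta) =
\beta[E_\lambda(x;\theta) + E_{\text{restraint}}(x)]$ with no
pressure-volume term (gas-phase NVT).  The $N\times M$ matrix over all
snapshots and states feeds a self-consistent MBAR solver with Newton
acceleration, anchored at $\hat f_1 = 0$ and iterated to a gradient
norm below 10⁻¹⁰·N; the asymptotic covariance of the $\hat f$ vector
comes from the SVD identity on the weight matrix, and the endpoint
uncertainty is $\sigma^2 = \Theta_{11} + \Theta_{MM} - 2\Theta_{1M}$.
A complete loss of overlap between adjacent states is flagged and the
reported uncertainty inflated rather than silently trusted.  Replicates
are aggregated as mean ± sample standard deviation, and a pair passes
the convergence filter only if that standard deviation is strictly
below 0.3 kcal/mol; the reported $\Delta G$ is the replicate mean.

Reweighting appends two zero-sample virtual states — the physical
endstates evaluated with perturbed parameters $\theta^*$ — to the
converged mixture: $\hat f_a = -\log\sum_n e^{-u_a(x_n)}/
\sum_k N_k e^{\hat f_k - u_k(x_n)}$.  The perturbed
$\Delta G(\theta^*)$ is differentiable in $\theta^*$ (its gradient is
the importance-weighted average of $\partial E/\partial\theta^*$ at the
two endstates, checked against finite differences), which is what makes
gradient-based training possible without resimulating.  Three
diagnostics guard the approximation: the Kish effective sample size
$1/\sum_n w_n^2$ per virtual state (below 2 is a hard error); a 1 kT
ceiling on the perturbed estimate's uncertainty; and an ESS degradation
check that fires when a virtual state retains less than half of the
effective samples its unperturbed endpoint had.  The last exists
because asymptotic covariances go quietly wrong at low ESS — a
perturbation can cost 97% of the effective samples while the reported
uncertainty barely moves — and the degradation ratio catches exactly
that.  Either of the last two raises the resample flag.

## Thermochemistry

Frequencies come from a central-difference Hessian of the analytic
gradient (step 5·10⁻³ Å), mass-weighted, with the 6 (5 if linear, 3 for
an atom) rigid-body directions projected out; imaginary modes are
reported as negative wavenumbers and any mode below −10 cm⁻¹ means the
geometry is not a minimum (such conformers are excluded from the
ensemble and logged).  The ideal-gas free energy assembles translation
(Sackur–Tetrode), rigid-rotor rotation divided by a user-supplied
external symmetry number (default 1 — point-group detection is out of
scope), and harmonic vibrations.  Modes strictly below 15 cm⁻¹ are
treated as free rotors: their entropy is replaced by the free-rotor
entropy with moment $\mu = h/(8\pi^2 c\tilde\nu)$ and they contribute
neither zero-point energy nor harmonic thermal energy (no interpolating
damping function — the plain substitution).  Thermal corrections default
to 300 K and 1 atm; 298.15 K is a one-argument change.

Two deliberate conventions: the multi-minimum combination uses the
Boltzmann sum $G = -RT\ln\sum_k e^{-G_k/RT}$ (log-sum-exp, always at or
below the lowest conformer); and the graph-automorphism degeneracy $D$
(nodes matched on element + hybridization, edges on bond order, with
aromatic bonds sharing one color so kekulization does not break ring
symmetry) enters as $-RT\ln D$ only when explicitly enabled — by
default it is reported but not added.  Internal symmetry numbers are not
implemented.

A `vibration_model = "classical"` switch replaces every harmonic mode's
quantum partition function by its classical counterpart (no ZPE).  This
exists because the alchemical route samples *classical* configurational
ensembles: when validating thermochemistry against alchemical results on
a harmonic system, the classical oscillator is the matching reference,
and the two routes then agree to within the MBAR uncertainty (this is
one of the package's acceptance checks, on a diatomic whose endstates
share the equilibrium length so rotation and translation cancel
exactly).

## Conformers

OpenBabel's stochastic 3D builder cannot be seeded through its R
bindings, so embedding is made reproducible differently: the
deterministic 2D layout is lifted to 3D by seeded out-of-plane jitter
and relaxed under the generic bonded force field (which restores sp³
geometry and resolves clashes), and conformational variety comes from
seeded random torsions about acyclic single bonds.  20 conformations
are generated; the set is reduced to 10 if the mean pairwise RMSD is
below 0.5 Å and to 5 if below 0.2 Å.  RMSD uses Kabsch superposition
(bio3d) — the measure must be invariant to rigid motion — over the heavy
atoms plus the hydrogens of the moieties whose proton placement defines
a conformer (primary alcohols, imines, primary/secondary amines,
cyanamides, thiols; implemented as graph patterns).  Near-duplicates are
removed by a greedy pass in frame order (a seed option randomizes the
starting order) with a 0.1 Å cutoff, read as Å; the pass is idempotent
and always keeps at least one frame.  Limitations to keep in mind:
tetrahedral chirality is only preserved as far as the relaxation keeps
the initial layout's handedness, and the generic force field has no
torsional terms, so conformer energies rank by sterics and angle strain
only.

## Training

`split_dataset()` shuffles with a seed and takes 20% test, 20%
validation, the rest training (354 pairs split 71/71/212).  The per-pair
loss is

$$ l(m;\theta^*) = g(\text{epoch})\,[\Delta G(\theta^*)_m -
\Delta G^{\text{exp}}_m]^2 + f(\text{epoch})\,
\frac{1}{2N n_{\text{atoms}}}\sum_{x}\bigl(|E_1(x;\theta^*)-E_1(x;\theta)| +
|E_2(x;\theta^*)-E_2(x;\theta)|\bigr), $$

with $\Delta G(\theta^*)$ from reweighting and the regularization taken
over *all* cached snapshots evaluated with both endstate potentials,
normalized by the atom count (an `endstates_only` switch restricts it to
the endpoint snapshots).  $g$ ramps 0→1 over the first 50 epochs and
$f$ stays at 0.1 by default; both are piecewise-linear schedules the
configuration can replace.  Minibatches of 10 pairs are drawn from a
seeded per-epoch shuffle; weight-like groups update with AdamW
(decoupled weight decay), bias-like groups with plain SGD, mirroring the
optimizer split used when fine-tuning the final layer of a pretrained
machine-learned potential, and the `trainable` setting plays the role of
"final layer only" by naming which groups may move.  Validation RMSE is
computed every epoch by reweighting; the best model is the one with the
lowest validation RMSE.  When any pair's reweighting uncertainty
crosses 1 kT (or its ESS collapses), a resample event fires and — with
`auto_resample` — that pair's states are regenerated at the current
parameters, after which training continues against the fresh mixture.

Two properties are worth stating because the tests rely on them: with
$g = 0$ the loss is pure regularization and the parameters converge back
to the sampling reference; and the total loss is exactly the sum of its
per-pair terms.

## Synthetic data: what it emulates and what it does not

`make_toy_pair()` builds 3–6 atom chain systems whose two endstates
differ in the position of one hydrogen *and* of one elevated bond order
— the structural signature of tautomerism — without any real chemistry.
`make_synthetic_dataset()` draws 30 such pairs (cycling chain lengths
and C/N/O compositions), computes each pair's alchemical
$\Delta G$ under ground-truth parameters, and adds Gaussian noise of
0.5 kcal/mol as synthetic "experimental" error.  The recovery experiment
perturbs the starting parameters — well-depth offsets of the hydrogen
bond types shifted by a sign-alternating, geometrically decaying pattern
(leading shift 2 kcal/mol, so every donor/acceptor element combination
is misfit), force constants scaled by 1.1 — and trains for 100 epochs
with exactly the perturbed degrees of freedom trainable: the three
hydrogen-bond well depths (named individually) plus the stiffness group.
Equilibrium lengths are held fixed as structural constants, and the
heavy-bond well depths stay frozen deliberately — left free, they act as
per-composition offsets that fit single training instances' noise
exactly and generalize badly to held-out instances of the same
composition.  This is the toy-scale face of a general lesson: the
trainable set should match what the data can identify.  One further
detail of the synthetic setup: the training reference is sampled with
each pair's *generation* seed, so the synthetic "experimental" value
differs from the reference mixture only by the parameter change and the
observational noise.  With independent seeds the generation campaign's
own estimator noise would enter every experimental value — an extra,
irreducible error term that real measurements do not carry.  Passing this experiment demonstrates
that the gradient/reweighting/optimizer loop can move parameters toward
values that explain held-out free energies.  It does *not* demonstrate
transferability to real molecules: the toy landscape is nearly harmonic,
its parameter-to-free-energy map is far smoother than a neural
potential's, and the "experimental" noise is exactly Gaussian.

## Numerical choices and degenerate inputs

Angle terms clamp $\cos\theta$ to $\pm(1-10^{-12})$ before `acos`;
torsion-free internal rotations can surface as numerically-zero Hessian
modes and are dropped (below 0.5 cm⁻¹) rather than fed to the
oscillator; the MBAR solver falls back from Newton to self-consistent
steps whenever the Newton step does not reduce the residual; constant
energy series make the statistical inefficiency undefined and raise an
error; minimization never returns a geometry above its starting energy.
The harmonic benchmark uses unit-mass particles because they decorrelate
fastest at the soft stiffnesses involved, and its temperature is chosen
so $k_BT = 1$ kcal/mol (reduced units).

## Known limitations

No solvation model is computed here — transfer free energies enter the
cycle as external numbers.  The bundled potential is a teaching-scale
stand-in for a quantum machine-learned potential: adapters for real QML
backends must supply their own parameter gradients.  Tautomer
*enumeration*, pKa/protomer handling and three-way equilibria are out of
scope; pairs are given, not generated.  Uncertainties are asymptotic
MBAR estimates, not bootstrapped.
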