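---
title: "Models and methods behind matekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind matekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matekit)
```

matekit packages the computational chain used to characterise the conserved
Na+-binding site in the N-lobe of prokaryotic MATE (multidrug and
toxic-compound extrusion) transporters: scoring the ionic identity of a
crystallographic coordination site, resolving the protonation states that
coexist with the bound ion, quantifying Na+/K+ selectivity by alchemical
free-energy perturbation, and reading conformational consequences out of
DEER spectroscopy and trajectory statistics. This vignette explains each
model, its assumptions and tunable parameters, the synthetic-data
generators that stand in for cluster-scale simulation and spectrometer
output, and the numerical choices made where the design was open.

## Bond-valence scoring of coordination sites

A putative ion site is summarised by its ligand contacts: the non-hydrogen
O and N polymer atoms within a cutoff (3 Å by default) of the modelled
central density, which in the deposited MATE structures is a water/ion
`HETATM` the user names explicitly (`extract_site(structure, center =
serial)`). The bond-valence metric

$$v = \sum_i (R_i / R_o)^{-N}$$

sums over the contact distances $R_i$ (Å) with empirical parameters per
candidate ion — Na+ ($R_o = 1.6$, $N = 4.29$), K+ ($2.276$, $9.1$), Ca2+
($1.909$, $5.4$) — and approximates the formal charge of the ion that best
fits the site; `rank_ions()` reports the ion whose charge is closest to
its computed valence, breaking ties by smaller deviation and then
alphabetically. Valences are reported at full precision with a 1-decimal
rounded column for comparison against published values. The metric is
additive over contacts and strictly increasing as any contact shortens,
and both properties are tested against a term-by-term oracle.

The default ligand filter takes "polar contacts" to mean O and N; that
reading, the 3 Å cutoff, and the keep-altloc-A rule are all adjustable
arguments.

## Monte Carlo titration of coupled protonation states

Ionizable sites (Asp, Glu, His; Lys and Arg are treated as fixed
protonated and never sampled) form a coupled two-state system. A
microstate assigns protonated/deprotonated to every site, with energy

$$E(x) = \sum_i x_i\,[\ln(10)\,RT\,(\mathrm{pH} - \mathrm{p}K_{a,i}) + s_i]
 + \sum_{i<j} q_i(x_i)\,q_j(x_j)\,W_{ij} + \sum_i q_i(x_i)\,\iota_i,$$

where $x_i \in \{0, 1\}$, $s_i$ is an intrinsic shift (kcal/mol),
$q_i$ is the site's current charge (acid $0/-1$, base $+1/0$), $W_{ij}$ is
the *unit-charge* coupling between sites, and $\iota_i$ the analogous
factor to a bound +1e cation, included only in the ion-bound condition.
With the signs written this way an isolated site follows the
Henderson–Hasselbalch curve exactly at every pH — the package's most basic
correctness anchor — and a bound cation stabilises the deprotonated form
of a nearby acid, as elementary electrostatics requires. In a strongly
coupled acid pair the same energy produces the carboxyl-carboxylate
signature: with the cation next to one acid, that acid stays deprotonated
(>99%) while its partner takes up the single shared proton, the
configuration inferred for the Asp35/Asp178 pair of the N-lobe site. We
deliberately reproduce this on a synthetic pair system with couplings in
the strong regime, not on the real structure: the published per-residue
percentages depend on Poisson–Boltzmann energies that are outside this
package's scope.

Energies come from one of two sources. `build_screened_coulomb_system()`
derives $W_{ij}$ and $\iota_i$ from charged-group centroids with a
screened Coulomb factor $332.06\,e^{-r/\lambda_D}/(\varepsilon r)$
kcal/mol — a deliberately simple model whose dielectric constant
(default 10) and Debye length are exposed arguments — and
`read_energy_matrix()` imports externally computed shift/coupling sets in
a documented delimited format, which is the intended route when a grid
Poisson solver is available. Temperature enters as $RT$ with
$R = 1.9872 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 298$ K by
default; the preset pH scan list (5.0–7.5) covers the physiological range
of the periplasm and cytoplasm.

`mc_titrate()` is a Metropolis sampler over microstates: one sweep
attempts a flip of every site and then a joint flip of every strongly
coupled pair ($|W_{ij}| > 2$ kcal/mol), because carboxyl-carboxylate
pairs trap single-flip chains in a double-well. Protonation probabilities
are occupancy frequencies after a burn-in of 10% of sweeps (default
10,000 sweeps). Convergence is reported as a split-half discrepancy per
site, plus the acceptance rate; a chain that accepts nothing raises an
error rather than returning frozen occupancies. `enumerate_exact()`
Boltzmann-weights all $2^n$ states (refusing $n > 20$) and is both the
user-facing exact option for small systems and the oracle that the
sampler is tested against: across random 8-site systems the sampler's
occupancies fall within three binomial standard errors of enumeration for
at least 95% of sites. The sampler's move set, chain length and
convergence diagnostic are this package's own choices; they are
replacements for unpublished details, not reconstructions of them.

## Alchemical Na+/K+ selectivity on a toy binding cage

Relative ion-binding free energies are estimated with the standard double
transformation: mutate Na+ into K+ bound in the site while mutating K+
into Na+ in a bulk reference, so that
$\Delta\Delta G = \Delta G_{\mathrm{site}} - \Delta G_{\mathrm{bulk}}$,
positive when the site prefers the smaller ion. Protein-scale FEP is out
of scope; the machinery is exercised on a `toy_site()`: five
Lennard-Jones/Coulomb ligand centres in trigonal-bipyramidal geometry
(partial charge −0.34, contact radius 1.7 Å, well depth 0.12 kcal/mol per
ligand — carbonyl-oxygen-like values softened for a minimal cage), a
harmonic cage confining the ion, and ligands that are either rigid or
mobile on harmonic tethers. The alchemical parameter λ interpolates the
ion's van der Waals radius and well depth linearly between species
(CHARMM-like Na+ 1.36 Å/0.047 kcal/mol, K+ 1.76 Å/0.087 kcal/mol); no
soft-core is needed because the ion never vanishes, and the +1 charge is
common to both species so electrostatic terms cancel along the path.

Sampling is Metropolis Monte Carlo rather than molecular dynamics — the
free-energy estimator is identical, and a desk-scale sampler keeps every
check reproducible in seconds. The default schedule maps a 50-window
protocol with the first third of each window discarded as equilibration
onto 50 × 30,000 MC steps. Each window records
$\Delta U$ to the next window's parameters, combined by the Zwanzig
estimator $\Delta G = -RT \ln \langle e^{-\Delta U / RT} \rangle$
(max-shifted against overflow). Every transformation is run forward and
backward; we report per-leg $\Delta G_{\mathrm{fwd}}$,
$\Delta G_{\mathrm{bwd}}$ (on the reverse path), their mean
$(\Delta G_{\mathrm{fwd}} - \Delta G_{\mathrm{bwd}})/2$ and the
hysteresis $\Delta G_{\mathrm{fwd}} + \Delta G_{\mathrm{bwd}}$, which
shrinks toward zero as chains lengthen and triggers a non-fatal warning
above 1 kcal/mol. On rigid-ligand sites the estimate is validated against
direct 3-D quadrature of the configuration integral (`quadrature_dg()`),
which agrees to within hundredths of a kcal/mol at the default protocol.
The bulk leg is an isotropic cage with no specific ligands; since only
ion–ligand terms depend on λ, its energy differences vanish identically
and it serves as an exact null reference that still exercises the
machinery.

Binding-site deformation is quantified from the mean tracked distances in
the pure-Na+ and pure-K+ ensembles:
$\Delta d_i = \langle d_i(\mathrm{Na^+})\rangle - \langle
d_i(\mathrm{K^+})\rangle$,
$\Delta D = \tfrac{1}{N}\sum |\Delta d_i|$ and
$\Delta\Delta D = [\tfrac{1}{N(N-1)}\sum(|\Delta d_i| -
\Delta D)^2]^{1/2}$, by default over the four geometry-defining distances
of the five-ligand site (the axial pair and the three equatorial pairs).
Distance restraints are flat-harmonic: zero within ±0.5 Å of the
reference distance and harmonic ($k$ up to 120 kcal mol$^{-1}$ Å$^{-2}$)
beyond; the flat width is our choice, as is the Å$^{-2}$ unit for a
harmonic distance constant. On a site whose reference geometry is tuned
to Na+, stiffening the restraints from 0 to 120 raises
$\Delta\Delta G$ and shrinks $\Delta D$ — the selectivity-vs-flexibility
ordering the restrained/unrestrained comparison is designed to expose.
Finally `fold_preference()` converts a penalty into an occupancy ratio,
$e^{\Delta\Delta G / RT}$: 2.32–2.73 kcal/mol at 298 K corresponds to a
50–100-fold preference, with 2.5 kcal/mol giving ~68-fold.

## DEER distance distributions as Gaussian mixtures

A four-pulse DEER trace is modelled as
$V(t) = B(t)\,[1 - \Delta + \Delta \int K(t, r) P(r)\, dr]$ with
modulation depth $\Delta$, stretched-exponential background
$B(t) = e^{-k t^{d/3}}$ (dimension fixed at 3 by default, for a
homogeneous three-dimensional spin bath; the data do not constrain $d$
well and it is user-overridable), and the powder-averaged dipolar kernel

$$K(t, r) = \int_0^1 \cos[(1 - 3x^2)\,\omega_{dd}\,t]\, dx, \qquad
\omega_{dd} = 2\pi \cdot 52.04 / r^3$$

(MHz with $r$ in nm). The kernel is evaluated by Gauss–Legendre
quadrature whose order scales with the largest accumulated phase
($\approx 0.7 \cdot 3\omega t_{max} + 40$ nodes, bucketed and cached), so
columns are accurate to better than $10^{-6}$ even at 1 nm on multi-µs
grids, and $K(0, r) = 1$ holds exactly.

$P(r)$ is a sum of Gaussians on a 1–8 nm grid (0.02 nm spacing),
trapezoid-normalized. `fit_mixture()` fits one or several conditions
globally by Levenberg–Marquardt least squares: component means and widths
are shared across conditions while weights, depth and background are
condition-specific, so an ion-induced change appears as a reweighting of
short- and long-distance components — the signature reported for Na+
addition. (A flag frees the widths per condition; whether the original
analysis shared them is not stated, and sharing is the more parsimonious
default.) Weights are parameterised by softmax logits, widths and
background rates by logs, depth by a logit, with box bounds on the means;
each component count from 1 to `max_components` is fitted from several
deterministic-plus-jittered starts and from warm starts that extend the
best $(k-1)$-component solution by one inserted component, which in
practice removes the local optima that plain multistart occasionally
falls into. The component count is selected by the Bayesian information
criterion, $n \ln(\mathrm{RSS}/n) + p \ln n$. The in-house Bayesian
selection used with the original spectrometer data is not specified in
detail anywhere we can reproduce; BIC is our replacement, chosen because
it is deterministic, desk-scale and shows the same qualitative behaviour
(it refuses to split single-component data and finds genuine second
components), and it is guarded by a parametric-bootstrap comparison in
the test suite.

Uncertainty is propagated to first order: the parameter covariance
$\hat\sigma^2 (J^\top J)^{-1}$ from the residual Jacobian is pushed
through $P(r)$ by the delta method, and bands are reported at 2σ (95%),
truncated below at zero because densities cannot be negative. On
single-component synthetics the delta-method band agrees with a 200-draw
parametric bootstrap to ~25% (median over the region where $P$ exceeds
10% of its maximum), which is the accuracy regime a first-order band can
honestly claim near a peaked optimum.

## Trajectory observables

`coord_series()` tables (frame, selection, x, y, z) stand in for MD
trajectories; adapters from binary trajectory formats are intentionally
out of scope so the module is testable without a simulation engine.
`distance_series()` and `nearest_distance_series()` give per-frame
(centroid) distances and nearest-member distances — the water-escape
diagnostic; `prob_distribution()` produces density-normalized histograms
(0.1 Å bins by default) whose mass sums to one to $10^{-9}$;
`density_map()` bins a selection on a cubic grid (0.5 Å voxels) after
Kabsch least-squares superposition of each frame onto a reference frame
using a named alignment selection — the original maps' alignment choice
is unstated, so a rigid-body fit on a user-named selection is our
replacement. Maps are normalized by frame count and voxel volume, so
they integrate to the mean number of selected atoms, and alignment is
verified to cancel a deliberately injected global rotation.

## Synthetic data: what it emulates, and what it does not

Every generator returns a machine-readable truth record (and
`write_truth()` drops it as a deterministic JSON side-file), so recovery
is always scored against known ground truth:

* `gen_coordination_site()` — ideal trigonal-bipyramidal (or octahedral /
  random) oxygen cages with Gaussian positional noise around a 2.4 Å
  contact distance, written as PDB text with the central ion as a
  `HETATM`.
* `gen_titration_system()` — random coupled acid/base systems (pKa
  uniform in 3–8, couplings Normal(0, 1 kcal/mol) by default) with exact
  enumeration attached as truth.
* `gen_trajectory()` — Gaussian fluctuation (σ = 0.1 Å) about the bound
  geometry, or a ligand-escape event at a known frame.
* `gen_deer_pair()` — two-condition traces from shared components
  (3.0/4.5 nm, widths 0.3 nm, weights 0.7/0.3, depth 0.3, noise 0.005)
  where the second condition moves 0.3 of the mass to the long component,
  mirroring an 80 mM Na+ addition experiment.

These defaults mirror the study conditions where printed (five ligands,
298 K, two-condition DEER pairs, 50-window transformations) and are
otherwise fixed, realistic choices. What passing recovery tests shows is
that the estimators are correct on data matching their generative
assumptions; it does not show robustness to what real data add —
orientation selection and label-rotamer structure in DEER, anharmonic and
correlated protein fluctuations in trajectories, conformational
relaxation coupled to titration, or protein-scale alchemical work. In
particular the published protein-scale selectivity value (~2–3 kcal/mol)
and the Poisson–Boltzmann per-residue probabilities are not
desk-reproducible targets; the package reproduces the estimator
machinery, the restrained/unrestrained ordering, and the qualitative
directions instead.

## Numerical choices and problem sizes

Defaults were chosen so the full test suite and the acceptance script run
in minutes on one core: titration checks use 8-site systems with 10,000
sweeps over 20 seeds; the rigid-site FEP oracle comparison uses 50
windows of 20,000 steps against a 161³ quadrature grid; the
restrained/unrestrained comparison uses the default 50 × 30,000 protocol;
DEER recovery uses 20 seeded two-condition pairs on 0–2.5 µs grids.
Random streams all flow from a single user seed through R's RNG
(including inside the compiled samplers), so every result in the package
is bit-reproducible; generator seeds are recorded in truth records and
run manifests. Degenerate inputs fail loudly: empty sites warn and score
zero valence, zero-acceptance chains error, restraints on ligand-free
cages error, singular fit covariances are ridge-repaired with a warning,
and the exact enumerator refuses systems beyond 2²⁰ states.

## Known limitations

The screened-Coulomb titration energies are a first-order stand-in for
continuum electrostatics; quantitative per-residue probabilities require
imported solver output. The toy FEP cage has no explicit solvent, so its
absolute ΔΔG values are cage properties, not predictions for any real
transporter. The DEER model excludes orientation selection, excited-state
artifacts and model-free (Tikhonov) inversion by design — mixtures of
Gaussians are the assumed representation throughout. Confidence bands are
first-order and will under-cover for strongly nonlinear parameter
combinations (e.g. nearly degenerate components).
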