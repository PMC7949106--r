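# matekit

Ion-binding-site analysis for MATE-family transporters.

MATE (multidrug and toxic-compound extrusion) transporters are
secondary-active antiporters that expel cytotoxic compounds — including
clinically important antibiotics — powered by the downhill uptake of Na+
or H+. Whether a given prokaryotic MATE is sodium- or proton-coupled has
been contested, and the answer hinges on the identity of a small,
conserved coordination site in the transporter's N-lobe: a spherical
density surrounded by five polar contacts in trigonal-bipyramidal
geometry. matekit implements, as a tested R package, the computational
chain used to interrogate that site:

* **Bond-valence ion scoring** (`read_pdb()`, `extract_site()`,
  `rank_ions()`): the valence of a coordination site is
  `v = sum_i (R_i / R_o)^(-N)` over its ligand contact distances `R_i`,
  with empirical `(R_o, N)` per candidate ion — Na+ (1.6 Å, 4.29), K+
  (2.276, 9.1), Ca2+ (1.909, 5.4). The ion whose formal charge best
  matches the computed valence is the statistically most probable
  occupant.
* **Monte Carlo titration** (`mc_titrate()`, `enumerate_exact()`,
  `build_screened_coulomb_system()`): Metropolis sampling of coupled
  protonation microstates of Asp/Glu/His sites at given pH, with or
  without a bound cation, with exact 2^n enumeration as the built-in
  oracle. Reproduces the carboxyl-carboxylate signature in which one
  acid of a coupled pair holds the single shared proton.
* **Alchemical Na+/K+ selectivity** (`run_ddg()`, `zwanzig()`,
  `geometry_change()`, `fold_preference()`): a 50-window
  free-energy-perturbation protocol (forward and backward, with
  hysteresis reporting) on a toy five-ligand binding cage, with
  flat-harmonic geometry restraints and the ΔD/ΔΔD binding-site
  deformation statistics, and the Boltzmann conversion of a free-energy
  penalty into a fold preference (`exp(ΔΔG/RT)`).
* **DEER mixture fitting** (`fit_mixture()`, `confidence_band()`):
  four-pulse DEER time traces fitted globally across conditions as
  background-corrected sums of Gaussian distance components, with
  BIC-selected component count and 2σ confidence bands by covariance
  propagation.
* **Trajectory statistics** (`distance_series()`, `prob_distribution()`,
  `nearest_distance_series()`, `density_map()`): distance probability
  distributions, nearest-molecule (water-escape) series, and
  Kabsch-aligned 3-D occupancy maps from tidy coordinate tables.
* **Synthetic data with ground truth** (`gen_coordination_site()`,
  `gen_titration_system()`, `gen_trajectory()`, `gen_deer_pair()`):
  every input the pipeline needs, generated with known truth records so
  recovery can be scored exactly.

All user-facing functions take data frames (or tidy S3 containers built
from them) and return tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`. A thin command-line wrapper (`exec/matekit`)
exposes `simulate`, `valence`, `titrate`, `fep`, `deer-fit` and
`trajstats` subcommands with JSON configs and sha-256 manifests.

## Worked example

Score a synthetic five-ligand trigonal-bipyramidal site (oxygens at
2.4 Å), then titrate the coupled acid pair next to a bound cation:

```r
library(matekit)

g <- gen_coordination_site(n_ligands = 5, distance = 2.4, seed = 1)
s <- read_pdb(g$pdb_text, id = "toy-site")
site <- extract_site(s, center = g$truth$center_serial, cutoff = 3)
rank_ions(site)
#> <valence_report> 5 contact(s); best match: Na+
#> # A tibble: 3 × 6
#>   ion   charge valence valence_rounded deviation best_match
#>   <chr>  <dbl>   <dbl>           <dbl>     <dbl> <lgl>
#> 1 Na+        1   0.878             0.9     0.122 TRUE
#> 2 K+         1   3.09              3.1     2.09  FALSE
#> 3 Ca2+       2   1.45              1.5     0.547 FALSE
```

Five 2.4 Å oxygen contacts carry a bond valence of 0.88 under the Na+
parameters — essentially the +1 formal charge of sodium — while the K+
and Ca2+ parameters give 3.1 and 1.5, far from their charges: the site is
sodium-like. (On the deposited VcmN/ClbM structures, fetched with
`fetch_pdb("6IDR")`, the same chain reports the published 1.0 / 3.7 / 1.6
rounding.)

```r
pair <- titration_system(
  data.frame(label = c("ASP35", "ASP178"), kind = "acid", pka = 4),
  interaction = matrix(c(0, 11, 11, 0), 2),  # strong carboxyl coupling
  ion_term = c(10, 0)                        # cation beside ASP35
)
tidy(mc_titrate(pair, pH = 7, sweeps = 20000, seed = 1, ion_bound = TRUE))
#> # A tibble: 2 × 4  (columns shown: site, pH, p, se)
#> 1 ASP35      7 0     0.00000000745
#> 2 ASP178     7 1.000 0.0000556
```

With the cation bound, the acid next to it stays deprotonated while its
partner takes up the single shared proton (p > 0.999) — the
carboxyl-carboxylate configuration proposed for the N-lobe site.

```r
res <- run_ddg(toy_site(mobile_ligands = FALSE),
               schedule = fep_schedule(50, 20000), seed = 1)
glance(res)[, c("ddg", "hysteresis_site", "fold_preference")]
#> # A tibble: 1 × 3
#>     ddg hysteresis_site fold_preference
#> 1  50.9          0.0132         1.97e37
fold_preference(2.5)   # the published-scale penalty
#> [1] 68.14579
```

On the rigid toy cage the Na+→K+ transformation costs 50.9 kcal/mol
(hysteresis 0.013; the independent configuration-integral quadrature
gives 50.85). A protein-scale penalty of 2.5 kcal/mol corresponds to a
~68-fold preference for Na+ at 298 K.

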