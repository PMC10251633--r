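---
title: "Cooperative multivalent RNA-protein binding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative multivalent RNA-protein binding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopbind)
```

## The problem

Most RNA-binding domains (RBDs) recognise short, degenerate motifs with
dissociation constants in the micromolar to hundreds-of-micromolar range,
yet RNA-binding proteins (RBPs) in the cell bind their targets with
nanomolar effective affinity and high specificity. The resolution of this
apparent paradox is multivalency: roughly 80% of eukaryotic RBPs carry two
or more RBDs (or assemble into oligomers that do), and once one domain is
bound, its neighbours are tethered next to their own binding sites at
local concentrations that can reach the millimolar range -- far above
their Kd. `coopbind` implements an equilibrium thermodynamic model that
turns this picture into numbers: it predicts the *avidity* (effective
association constant) of an idealized n-domain protein for an n-site RNA
from the affinities of the isolated domains and the geometry of both
binding partners, with no free parameters.

## Model and assumptions

The model makes three idealizations:

1. **Strictly matched binding.** Domain *i* binds only its cognate site
   *i*. (The same-specificity case for two sites, where either domain can
   occupy either site, is available separately as
   `avidity_fuzzy_two_site()`.)
2. **One protein per RNA.** Once one domain of a protein is bound, its
   remaining domains outcompete all other protein molecules at the
   neighbouring sites, because their local concentration far exceeds the
   bulk concentration. The state space is therefore the set of $2^n$
   binding configurations of a single protein, written as bitstrings
   (`"101"` = sites 1 and 3 bound).
3. **Inert linkers.** RNA linkers between motifs and peptide linkers
   between domains behave as ideal worm-like chains that interact with
   nothing.

A non-empty configuration with bound sites $i_1 < i_2 < \dots < i_m$ has
the statistical weight (relative to the free state, per molar of free
protein)

$$ w(S) \;=\; K_{a,i_1} \prod_{k=2}^{m} c_{i_{k-1} i_k}\, K_{a,i_k}, $$

where $K_{a,i}$ is the association constant of domain $i$ and
$c_{ij}$ is the effective local concentration of domain $j$ at site $j$
while domain $i$ is bound: the first domain binds bimolecularly, every
further domain binds intramolecularly against the local concentration set
by the tether to its nearest bound neighbour. Thermodynamic consistency
makes $w$ independent of the order in which the sites are filled
(`configuration_weight()` and the path-independence tests).

The avidity is the summed concentration of all bound states over the
product of free concentrations,

$$ K_\mathrm{av} \;=\; \frac{[\text{all bound states}]}{[A][B]}
   \;=\; \sum_{S \neq \emptyset} w(S), $$

computed by `avidity_exact()` over all $2^n - 1$ non-empty configurations
(capped at $n \le 16$). For two sites this reduces to the familiar
$K_{a,1} + K_{a,2} + K_{a,1} c_{12} K_{a,2}$. When every step factor
$K_{a,i}\, c_{i-1,i} \gg 1$ the fully bound configuration dominates and

$$ K_\mathrm{av} \approx K_{a,1}\, c_{12} K_{a,2}\, c_{23} \cdots
   c_{n-1,n} K_{a,n}, $$

the dominant-path approximation of `avidity_approx()`, which warns when
any step factor falls below 10.

## Effective concentrations from chain statistics

Two models of the local concentration are provided.

**Particle in a sphere** (`c_sphere()`): one molecule uniformly
distributed in a sphere of radius equal to the chain length $l$,
$c = (N_A \tfrac{4}{3}\pi l^3)^{-1}$. This is the classical estimate; it
ignores chain entropy and decays as $l^{-3}$.

**Worm-like chain** (`c_eff_rigid()`, `c_eff_flexible()`): the linker is
a semi-flexible polymer with contour length $l$ and persistence length
$l_p$. In the long-chain limit its end-to-end vector is an isotropic
Gaussian with per-axis variance $\sigma^2 = \langle r^2 \rangle / 3$,
$\langle r^2 \rangle = 2 l_p l$. The local concentration is the Gaussian
number density evaluated at the 3D distance $d$ between the domain
attachment points,

$$ c_{ij} = (2\pi\sigma^2)^{-3/2}
   \exp\!\left(-\frac{d_{ij}^2}{2\sigma^2}\right) \times 1.66054\
   \mathrm{M\,nm^3}. $$

At $d = 0$ this decays only as $l^{-3/2}$, which is why cooperativity
survives surprisingly long linkers. When protein domains are joined by
flexible peptide linkers, the RNA and peptide chains fluctuate
independently and their per-axis variances add (a convolution of
Gaussians); `mixed_geometry()` combines rigid offsets (added collinearly)
and flexible gaps for proteins such as a four-KH-domain protein whose
middle two domains form a rigid unit.

Configurations that skip sites use a tether equal to the sum of the
intervening linkers plus the footprints of the skipped motifs
(`motif_footprint_nt`, default 0), against the direct $d_{ij}$ entry of a
rigid geometry or the concatenated peptide linkers of a flexible one.
This summation is the only choice consistent with treating the combined
tether as one worm-like chain.

### Parameters and defaults

| parameter | default | unit | meaning |
|---|---|---|---|
| `nm_per_nt` | 0.55 | nm | contour length per RNA nucleotide |
| `nm_per_aa` | 0.38 | nm | contour length per amino acid |
| `lp_rna_nm` | 2.7 | nm | persistence length of ssRNA |
| `lp_peptide_nm` | 0.304 | nm | persistence length of disordered peptide |

All four live in one `chain_constants()` table that every operation
accepts, so sequence-specific overrides flow through a whole computation
and are echoed in every CLI output header.

### Numerical and validity choices

* **Variance law.** The default is the pure long-chain Gaussian
  $\langle r^2\rangle = 2 l_p l$. The finite-chain Kratky-Porod form
  $2 l_p l - 2 l_p^2 (1 - e^{-l/l_p})$ is available behind
  `exact_variance = TRUE`; it shrinks the variance for short chains, but
  for chains that short the isotropic-Gaussian *shape* is itself wrong,
  so the correction buys no real accuracy and is off by default. (It also
  moves the four-domain density-response Hill coefficient further from
  the reference behaviour, supporting the plain Gaussian as the intended
  regime.)
* **Short-chain warning.** The radial end-to-end density has a single
  maximum near the origin only for $l / (2 l_p) > 5.6$; below that the
  Gaussian treatment is an extrapolation. Chain-level functions warn once
  (suppressible with `warn = FALSE`) and still compute -- many realistic
  RNA linkers are in this regime, and the model is explicitly an
  order-of-magnitude tool there.
* **Units.** nm and molar internally; the single conversion constant
  $1\ \mathrm{nm^{-3}} = 10^{24}/N_A\ \mathrm{M} = 1.66054\ \mathrm{M}$
  is derived from Avogadro's number at double precision
  (`nm3_to_molar()`/`molar_to_nm3()` round-trip to machine precision).
* **Degenerate tethers.** A zero-length tether with no flexible variance
  (adjacent sites with a 0-nt linker and a rigid geometry) has no
  Gaussian density and is rejected with an explicit error rather than
  returning infinity.

## Binding-site density and cooperativity

For a long RNA of length $L$ nt carrying $N \ge n$ equally spaced
identical sites, the fully bound protein can sit in $N - n + 1$ registers,
so

$$ K_\mathrm{av}(N, n) \approx K_\mathrm{av} \cdot (N - n + 1), $$

implemented by `avidity_at_density()` on top of the exact $n$-site
avidity at the implied linker spacing. `density_scan()` sweeps $N$,
reports $K_\mathrm{av}$ and the occupancy
$[\mathrm{RNA}]/(K_\mathrm{av}^{-1} + [\mathrm{RNA}])$, and `fit_hill()`
quantifies the steepness of the resulting density response with the
two-parameter Hill function $1/(1 + (D_0/D)^h)$.

Design choices here (all exposed as arguments, all logged by the CLI):

* **Spacing convention.** $N$ sites on $L$ nt are separated by linkers of
  $L/N$ nt, making density and linker length exactly reciprocal;
  `spacing = "L/(N-1)"` is available as the alternative edge convention.
* **Scan geometry.** Rigidly linked domains placed collinearly,
  $d_{ij} = |i - j|\, d$, with $d = 2$ nm by default.
* **Density grid.** 200 points log-spaced from one site per RNA ($1/L$)
  up to 0.2 sites/nt. Binding motifs are several nucleotides long, so
  densities much above 0.2/nt are not physically realisable; the
  log-spacing weights the transition region rather than the saturated
  plateau. The fitted Hill coefficient depends mildly (order 10%) on
  these conventions -- which is why they are explicit arguments rather
  than constants.
* **Fit protocol.** Levenberg-Marquardt (`minpack.lm::nlsLM`) on linear
  occupancy, starting from $h_0 = n$ and $D_0$ at the scanned density
  nearest half-occupancy, with $h$ bounded in $(0, 5n]$. A noiseless
  Hill curve is recovered to $10^{-6}$ (tested); non-convergence is an
  error carrying the start values and data range.

Under the reference conditions (per-domain Kd 50 uM, 200-nt RNA,
0.1 uM RNA, $d = 2$ nm) the fitted Hill coefficients for one to four
domains are:

```{r hill}
vapply(1:4, function(n)
  hill_cooperativity(n, kd = 50e-6, rna_length_nt = 200,
                     rna_conc = 1e-7, d_nm = 2)$h, numeric(1))
```

The coefficient grows faster than the domain count: four domains turn a
two-fold density difference into more than an order of magnitude of
avidity (`density_scan(4, ..., site_counts = c(8, 16))`), the quantitative
basis for reading clusters of weak motifs as the physiological targets of
multi-domain RBPs.

## Stochastic cross-check

`build_network()` turns the model into a continuous-time Markov jump
process over all $2^n$ configurations (capped at $n \le 10$): transitions
flip one site, and the equilibrium constant of the step $S \to S+\{i\}$ is
the weight ratio $w(S+i)/w(S)$ -- the local concentration times $K_{a,i}$
for a chain extension, and the conditional concentration
$c_{\ell i} c_{i r}/c_{\ell r}$ times $K_{a,i}$ for an insertion between
two bound neighbours $\ell, r$. Because every step constant derives from
one potential, detailed balance holds on every cycle by construction
(tested edge-by-edge, and the stationary distribution solved by linear
algebra reproduces the analytic avidity).

Only rate *ratios* are fixed by thermodynamics; the split into forward
and backward rates is a simulation choice:

* `rate_split = "uniform"` (default): one shared on-rate scale
  `kon_scale` for every binding step, off-rates `kon_scale / Ka_i`. This
  is the simplest physical picture but becomes numerically stiff for
  high-avidity models, where rebinding is orders of magnitude faster than
  unbinding.
* `rate_split = "balanced"`: $k_f = k_0\sqrt{K}$, $k_b = k_0/\sqrt{K}$.
  Identical stationary law, vastly better mixing; this is the
  recommended setting for cross-checking high-avidity parameter draws.

`run_and_estimate()` runs seeded Gillespie trajectories (an Rcpp kernel
driven by R's RNG, so `set.seed()` makes trajectories bit-reproducible),
discards a burn-in (default 10% of `t_end`), and estimates
$\hat K_\mathrm{av} = f_b / ((1-f_b)\, c)$ from the time-averaged bound
fraction $f_b$, with a standard error from the replicate spread. If every
replicate is stuck at 0 or 1 the estimator is degenerate and the function
errors with advice to move `protein_conc` toward $1/K_\mathrm{av}$. The
shipped property test draws 20 random models with $n \le 3$ and requires
agreement with `avidity_exact()` within three standard errors in at least
90% of them; trajectory lengths are set to about 4000 time units of the
slowest transition (a few seconds total on one core).

## Validation pipeline and the synthetic fixture panel

`predict_full_length()` predicts a full-length dissociation constant
($1/K_\mathrm{av}$) from individual-domain affinities and geometry --
deliberately with no tunable parameter anywhere in the path -- and
reports the independent-binding limit $1/\sum_i K_{a,i}$ (the
infinite-linker value) and the symmetric fold error against a measured
value. `run_validation()` does this for a panel of fixtures and
summarises the maximum and median fold error.

The shipped panel (`inst/extdata/rbp_fixtures_synthetic.json`) is a
**synthetic stand-in**: its seven entries reproduce the *topologies* that
make this validation structurally interesting -- rigid didomains, a
flexibly linked didomain pair, a protein measured against three RNA
linker-length variants, and a four-domain protein whose middle two
domains form a rigid unit -- with affinities and geometries chosen at
literature-typical scales and "measured" values constructed at realistic
(up to ~3-fold) deviations from the model. It pins the entire pipeline,
including the mixed-geometry code paths and the fold-error bookkeeping,
but it is not experimental data: to validate the model against real
measurements, supply your own fixture file via
`builtin_fixtures(path = ...)`. Every fixture must carry a non-empty
`source_note`; the loader refuses tables with unstated provenance.
Domains can be marked `disabled` (binding-dead mutants); their
configurations are removed from the avidity sum exactly.

## What the synthetic generator does and does not emulate

`generate_synthetic_model()` draws per-domain Kds log-uniformly from 1 uM
to 1 mM (the affinity regime of typical RBDs), RNA linkers uniformly from
5 to 40 nt (within the range where one bound protein excludes others),
and consecutive inter-domain distances uniformly from 1 to 5 nm, expanded
to a collinear rigid geometry. Property tests over these draws exercise
the enumeration, the network simulation and the polymer mechanics across
the physically relevant parameter space. They do *not* probe: RNA
secondary structure, linker-protein interactions, sequence-dependent
flexibility, anisotropic short-chain statistics, multi-protein
competition, or oligomerization -- all real phenomena excluded from the
model by assumption. Passing tests therefore certify the thermodynamic
bookkeeping, not predictive accuracy on structured or crowded RNAs.

## Known limitations

* Short linkers (under ~30 nt of ssRNA) are outside the Gaussian regime;
  expect order-of-magnitude rather than factor-two accuracy there.
* The one-protein-per-RNA assumption fails for long RNAs at high protein
  concentration, and the strict domain-site matching fails for repeat
  RNAs with a continuous interaction surface; `register_adjusted_ka()`
  offers only the simple state-counting correction for overlapping
  binding registers.
* Exact enumeration is exponential ($n \le 16$ enforced); the stochastic
  network is capped at $n \le 10$.
* The density model assumes equally spaced identical sites and neglects
  non-sequential placements beyond the $N - n + 1$ register count.

## Problem sizes used in the shipped tests

Unit and property tests run models with $n \le 5$ (100 random draws for
the enumeration oracle), 20 stochastic cross-checks with $n \le 3$ at
about $10^5$--$10^6$ SSA events each, and density scans at 80--200 grid
points; the whole suite completes in well under a minute on one core.
These sizes were chosen as the smallest that exercise every code path
with tight statistical margins.
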