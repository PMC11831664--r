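---
title: "Local-density potential Monte Carlo for mesoscopic water: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-density potential Monte Carlo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Simulating water at mesoscopic length scales requires coarse-grained models
whose interactions are soft enough for large Monte Carlo displacements, yet
still reproduce real thermodynamics. Pairwise coarse-grained potentials
struggle with this: soft DPD-style potentials give unrealistic equations of
state (no vapour--liquid coexistence), while realistic pair potentials have
hard cores that throttle sampling.

`ldpmc` implements the local-density potential route: the potential energy of
a configuration is not a sum over pairs but a functional of per-particle
*weighted local densities*,

$$
U^{\mathrm{LDP}} \;=\; \sum_{i=1}^{N} a^{\mathrm{ex}}(\bar\rho_i),
\qquad
\bar\rho_i \;=\; \sum_{j \neq i} w(r_{ij}),
$$

where $a^{\mathrm{ex}}(\rho)$ is the excess Helmholtz free energy per
particle of an equation of state (EoS) of choice and $w$ is a normalized,
compact-support kernel. The construction is top--down: if the kernel range
$r_c$ resolves enough neighbours, $\bar\rho_i \approx \rho$ in the bulk and
the simulated fluid inherits the bulk thermodynamics of the chosen EoS,
while remaining able to form interfaces and other inhomogeneities that the
bare EoS cannot describe. The kernel is the Lucy function

$$
w(r) = \frac{105}{16\pi r_c^3}
       \left(1 + 3\frac{r}{r_c}\right)\left(1 - \frac{r}{r_c}\right)^3,
\qquad r < r_c,
$$

normalized to unit three-dimensional integral and continuously
differentiable at the cutoff. The self term is excluded from $\bar\rho_i$,
so an isolated particle has $\bar\rho = 0$ and zero excess energy,
consistent with $a^{\mathrm{ex}}(0) = 0$.

Because the underlying EoS is parametrized for bulk properties, the
interfacial tension of the bare LDP fluid is generally wrong. A
square-gradient (SG) correction with coefficient $\kappa$ is added,

$$
U \;=\; U^{\mathrm{LDP}} + U^{\mathrm{SG}},
\qquad
U^{\mathrm{SG}} = \frac{\kappa}{2} \sum_i |\nabla \bar\rho_i|^2,
\qquad
\nabla\bar\rho_i = \sum_{j\neq i} w'(r_{ij})\,\hat{\mathbf r}_{ij},
$$

which is concentrated at interfaces (where the density gradient is large)
and nearly inert in the bulk. The surface tension rises approximately
linearly with $\kappa$ at fixed temperature and cutoff, which makes
calibration against a target surface-tension table a simple linear
inversion. We use the simplest member of the general square-gradient family
($|\nabla\bar\rho_i|^2$ per particle, same kernel and same $r_c$ as the
density itself); any prefactor convention is absorbed into the calibrated
$\kappa$, so nothing is lost by this choice.

## Free-energy backends

Four kinds of $a^{\mathrm{ex}}(\rho, T)$ are provided (all with
$k_B = 1$: energies in kelvin, lengths in nm, densities in nm$^{-3}$):

* **ideal** --- $a^{\mathrm{ex}} \equiv 0$. Every estimator has an exact
  limit here (acceptance ratio 1, $\gamma = 0$, $\langle\rho\rangle = p/k_BT$,
  $\beta_T = 1/p$), which the test suite uses heavily.
* **van der Waals** --- $a^{\mathrm{ex}} = -k_BT\ln(1-b\rho) - a\rho$, with
  closed forms for pressure, chemical potential and compressibility. The
  registry ships `vdw-water` ($T_c = 647$ K, $\rho_c = 33.33$ nm$^{-3}$),
  the analytic oracle for most simulation-level tests.
* **Mie (SAFT-VR)** --- third-order Barker--Henderson perturbation theory
  for a fluid of single Mie segments: Carnahan--Starling hard-sphere
  reference at the temperature-dependent effective diameter
  $d(T) = \int_0^\sigma (1 - e^{-\beta\phi^{\mathrm{Mie}}})\,dr$, plus
  first-, second- and third-order attractive terms with the standard
  effective-packing-fraction and Padé $\alpha$-function machinery. Since the
  models here are single-site, the chain contribution is identically zero.
  The implementation reproduces the known critical point of the
  Lennard-Jones special case ($\lambda_r = 12$): $k_BT_c/\epsilon = 1.34$,
  $\rho_c\sigma^3 = 0.29$.
* **Mie + association** --- a four-site (2 hydrogen + 2 lone-pair)
  Wertheim TPT1 term for hydrogen bonding,
  $a^{\mathrm{assoc}}/k_BT = 4(\ln X - X/2) + 2$ with the closed-form
  unbonded fraction $X = 2/(1 + \sqrt{1 + 8\rho\Delta})$ (evaluated in this
  cancellation-free form). The association strength uses the textbook
  contact-value kernel
  $\Delta = g^{\mathrm{HS}}(d)\,[e^{\epsilon_{\mathrm{HB}}/k_BT}-1]\,K$.
  The published parametrization of this water model defines $\Delta$
  through a density--temperature polynomial correlation whose coefficients
  are not reproducible from the available text, so the registry keeps the
  published Mie parameters ($\sigma = 0.30555$ nm,
  $\epsilon/k_B = 266.68$ K, $\lambda_r = 17.02$) and association energy
  ($\epsilon_{\mathrm{HB}}/k_B = 1985.4$ K) but refits the bonding volume
  ($K = 1.008\times10^{-3}$ nm$^3$) against the saturation table described
  below; the resulting EoS reproduces water's saturated liquid density to
  ~3% and vapour pressure to ~10% over 300--620 K.

Two temperature-dependent $\lambda_r = 8$ models (`vle`, `ift`) complete the
registry. Their published polynomial coefficients live in supplementary
material that is likewise unavailable, so they were refit with this
package's own VLE solver: at each temperature $(\epsilon, \sigma)$ was
solved so the Mie monomer EoS reproduces the reference saturated liquid
density and vapour pressure exactly, and cubic polynomials
$\epsilon(T), \sigma(T)$ were fitted through the points (residuals 0.6 K and
$6\times10^{-4}$ nm). The `ift` entry is a labelled stand-in: it shares
$\sigma(T)$ and refits $\epsilon(T)$ to liquid density only, leaving the
vapour pressure unconstrained (mirroring the published model's known
weakness) and deferring surface tension to the $\kappa(T)$ calibration.
All provenance is recorded in the registry JSON files themselves.

The reference table (`inst/extdata/water_saturation_synthetic.csv`) holds
approximate water saturation properties on a 20 K grid from 300 to 640 K
(liquid/vapour densities, vapour pressure, and surface tension from the
standard $235.8\,(1-T/T_c)^{1.256}(1-0.625(1-T/T_c))$ mN/m correlation). It
is labelled synthetic: values are rounded literature-level numbers intended
for examples, fitting and %AAD scoring demonstrations, not metrological use.

## Bulk-property solvers

`pressure_from_eos` uses the identity
$p = \rho k_B T + \rho^2\,\partial a^{\mathrm{ex}}/\partial\rho$ (analytic
derivative for ideal/vdW, an $O(h^4)$ five-point stencil for the
perturbation models, validated against a plain central difference to
$10^{-6}$ relative). `solve_vle` equates pressure and chemical potential in
the two phases by nested iteration: a dense spinodal scan brackets the
vapour and liquid branches, inner `uniroot` calls find the density roots at
a trial pressure, and the outer iteration drives the chemical-potential
difference to zero (default $10^{-8}$ relative; the solution is invariant to
the bracketing resolution). `compressibility_from_eos` returns
$\beta_T = 1/(\rho\,\partial p/\partial\rho)$ and refuses mechanically
unstable states.

## Monte Carlo engine

Metropolis sampling in NVT or NpT with a compiled core. A cycle is $N$
single-particle displacement attempts; the incremental energy update touches
only particles within $r_c$ of the old or new position, and the cached
per-particle field is verified against a from-scratch recomputation at the
end of every run (typical agreement $10^{-14}$ relative). In NpT one volume
move per cycle performs a symmetric random walk in $\ln V$ with isotropic
rescaling, accepted with probability
$\min\{1, \exp(-[\Delta U + p\Delta V - (N{+}1)k_BT\ln(V'/V)]/k_BT)\}$;
moves that would shrink any edge below $2r_c$ are rejected and counted.
Displacement step sizes adapt towards 35% acceptance during equilibration
only (every 100 cycles by default) and are frozen for production to avoid
bias. All randomness flows through R's RNG, so a seed fixes the trajectory
bit-exactly.

$a^{\mathrm{ex}}$ is evaluated through a per-temperature lookup table
(uniform density grid, cubic Hermite interpolation from values and
derivatives, default 2048 nodes, verified to $10^{-6}$ relative accuracy
off-grid). Mandatory for the temperature-dependent models, it also removes
the cost asymmetry between the vdW oracle and the SAFT backends. Densities
beyond the table fall back to direct EoS evaluation (counted and reported);
beyond the model's density domain (vdW excluded volume, hard-sphere packing
bound) the free energy continues as a steep *finite* linear penalty
($5\times10^3$ K per nm$^{-3}$) --- effectively an impenetrable wall for
Metropolis, but one that keeps every energy finite so an unequilibrated
start relaxes smoothly and no $\infty-\infty$ indeterminacy can reach the
ghost-perturbation estimators. (A literal infinite wall was tried first and
produced exactly that failure: random slab packing puts a tail of initial
local densities beyond the vdW domain.) Roundoff in incremental updates can
also leave a vapour particle's $\bar\rho$ at $-10^{-20}$ when its last
neighbour leaves the cutoff; the table clamps this to zero.

Initial states come from two generators: `build_bulk_configuration`
(jittered simple-cubic lattice --- a random-overlap start can place local
densities beyond the free-energy domain) and `build_slab_configuration`
(random packing at the target liquid density in a central slab, lateral
edges $L_x = L_y = 3r_c$, $L_z$ set from an overall density chosen near
critical so the state point lies inside the two-phase region).

## Estimators

* **Density profile / coexistence.** Frame-averaged z-histograms; the
  coexistence fit recentres the slab (it may straddle the periodic
  boundary), fits the symmetric double-tanh profile, and reports plateau
  densities as *fitted plateau + mean residual over the bins deeper than
  the 10--90 interface bounds*. Raw bin averaging from the 10--90 bound
  folds in the ~1% tanh shoulder of the edge bins; the residual-corrected
  form is exact on a noiseless profile and keeps the noise-averaging of the
  bins. Profiles without two-plateau structure give an explicit
  "no coexistence" result.
* **Test-area surface tension.** Ghost (never accepted) deformations of
  each sampled frame at constant volume, $L_{x,y} \to L_{x,y}\sqrt{1\pm\xi}$,
  $L_z \to L_z/(1\pm\xi)$, positions following the box affinely.
  $\Delta A^\pm = -k_BT\ln\langle e^{-\Delta U^\pm/k_BT}\rangle$ and the
  central difference $\gamma = (\Delta A^+ - \Delta A^-)/(2\xi S_{0,tot})$
  with $S_{0,tot} = 2L_xL_y$ --- a periodic slab has two interfaces. Default
  $\xi = 5\times10^{-4}$ with an optional $\xi/2$ convergence re-estimate.
* **Test-volume pressure.** Ghost volume perturbations $\pm\zeta V$ along
  one direction (default $\zeta = 10^{-4}$), each branch giving
  $p^\pm = \frac{k_BT}{\pm\Delta V}[N\ln(V_1/V_0) +
  \ln\langle e^{-\Delta U^\pm/k_BT}\rangle]$, reported as the central
  average. This is the route used for vapour pressures: equilibrate a box
  of vapour at the coexisting vapour density and measure $p$.
* **Compressibility.** $\beta_T = (\langle V^2\rangle - \langle
  V\rangle^2)/(k_BT\langle V\rangle)$ from the NpT volume series. The
  volume walk must decorrelate well within the run: with a maximum $\ln V$
  step far below the equilibrium width $\sim 1/\sqrt{N}$ the fluctuation
  estimate biases low, so protocols for fluctuation measurements should set
  `max_lnV_step` accordingly.
* **%AAD.** $\frac{100}{n}\sum_i |(X^{sim}_i - X^{ref}_i)/X^{ref}_i|$, with
  zero reference entries rejected.

Uncertainties are 20-block averages throughout.

## Calibrating the square-gradient coefficient

`calibrate_kappa` runs the slab + test-area pipeline over a $\kappa$ grid
(at least 3 points; 4 values bracketing a pilot estimate is the intended
use), fits $\gamma = a + b\kappa$ by weighted least squares, flags
nonlinearity ($R^2 < 0.98$) and extrapolation, errors if the slope is not
positive, and returns $\kappa^\ast = (\gamma_{target} - a)/b$ with a
delta-method standard error. `fit_kappa_polynomial` fits the cubic
$\kappa(T)$ through at least four calibrated temperatures (the conventional
window is 280--520 K) and warns outside the fitted range. Calibrated
$\kappa$ values are tied to the cutoff they were calibrated with, so the
registry stores $r_c/\sigma$ alongside any $\kappa(T)$ coefficients.

## What the desk-scale fixtures establish --- and what they do not

The test suite's workhorse is the water-like van der Waals fluid, because
every quantity the simulation should reproduce then has a closed form. Its
"$4\sigma$-equivalent" cutoff is defined by corresponding states on the
critical density ($\rho_c\sigma^3 = 0.31$, the simple-Mie-fluid value),
which preserves the property the $4\sigma$ rule actually controls --- how
many neighbours the kernel resolves. The covolume mapping
$b = 2\pi\sigma^3/3$ under-resolves by a factor ~2 and was rejected for
that reason.

The dominant finite-resolution artefact is the fluctuation of
$\bar\rho_i$ about $\rho$: its variance scales as $1/(\rho r_c^3)$, and
through the curvature of $a^{\mathrm{ex}}$ it shifts measured pressures and
densities from the EoS values. Empirically (and consistent with this
scaling) the shift falls as $1/r_c^3$. Consequences accepted deliberately
at desk scale:

* pressure consistency is asserted in the *vapour* phase (the state at
  which the method's pressure route is actually used), where the
  ideal--excess cancellation is mild; at a vdW liquid state the
  cancellation amplifies the artefact so that 3% relative agreement would
  need $r_c \approx 3$ nm and $N \approx 14{,}000$;
* slab coexistence densities at desk resolution ($\rho_l r_c^3 \approx 40$,
  $N = 1000$, ~$2\times10^3$ cycles) carry a systematic of order 5--10% on
  $\rho_l$ (the a-priori acceptance bound is 12%), where the full-scale
  protocol ($N = 5000$, $\rho\sigma^3$-matched cutoff, $\sim10^5$ cycles)
  reaches ~1%;
* the SG bulk-neutrality check is run at a resolution matching the
  full-scale cutoff rule ($\rho r_c^3 \approx 78$), because the neutrality
  claim is explicitly a large-$r_c$ statement; at coarser resolution the SG
  term visibly *reduces* the fluctuation artefact (shifting bulk density
  toward the EoS value by a few percent) rather than leaving it unchanged.

A green suite therefore establishes: correctness of the energy functional
and its incremental updates (against independent double-loop oracles),
correctness of the samplers (exact ideal-gas limits, two-particle
detailed-balance check against direct integration of the Boltzmann weight),
correctness of the estimators (closed-form and constructed-input checks),
EoS-level fidelity (Maxwell-construction and analytic-derivative oracles),
and the method's defining bulk-consistency property at vapour states. It
does not certify experimental-accuracy water numbers; those require the
full-scale protocol and the published association kernel.

## Numerical choices

* Unit system $k_B = 1$, kelvin/nm throughout; conversions (18.015 g/mol,
  MPa, mN/m) only at the I/O boundary.
* Barker--Henderson diameter by adaptive quadrature at $10^{-12}$ relative
  tolerance; $\epsilon = 0$ short-circuits to the ideal limit.
* VLE tolerance $10^{-8}$ relative; spinodal scan at 600 points on a
  quadratically stretched grid (denser at low density), with the liquid
  spinodal taken at the first pressure upturn after the vapour spinodal so
  stencil noise near the packing bound cannot masquerade as a loop.
* Lookup tables clamp $a^{\mathrm{ex}}(0) = 0$ exactly; the derivative at
  $\rho = 0$ uses an interior stencil.
* Neighbour search is a flat $O(N)$ scan per move ($O(N^2)$ for full
  builds) rather than cell lists: at desk scale ($N \le 5000$,
  $r_c \sim L/3$, so cells would be $\sim3^3$) the constant-factor win of
  cell lists is small and not worth the bookkeeping.
* The registry and run configurations are JSON (no TOML parser is available
  in the supported environment); the schema keys match the documented
  interface otherwise.

## Run configuration schema

The `simulate` and `calibrate-kappa` CLI subcommands read a JSON file with
three sections (an example ships as `inst/extdata/example_run.json`):

```json
{
  "model":    { "name": "vdw-water", "r_c": 0.8412, "kappa": 0.01 },
  "system":   { "N": 1000, "T": 500, "liquid_density": 66.5,
                "overall_density": 33.3 },
  "protocol": { "ensemble": "nvt", "n_equil_cycles": 400,
                "n_prod_cycles": 1200, "sample_every": 10, "seed": 1 }
}
```

`model.name` is a registry name or a path to a model JSON; `r_c` defaults to
$4\sigma(T)$ for Mie models; `system` either names an XYZ file (`"xyz"`) or
gives slab-builder parameters; `system.p_MPa` selects NpT. Calibration
configs additionally carry `gamma_target` and `kappa_grid`. Outputs (frames
as multi-frame XYZ, observables as CSV, summaries as JSON) embed the seed
and an MD5 digest of the options so any artifact can be regenerated.

## Known limitations

Single component only; no forces (and deliberately so --- the estimators
avoid the virial route entirely); no grand-canonical or Gibbs ensembles;
$\kappa(T)$ must be recalibrated per cutoff and per model; the shipped
water parametrizations are labelled refits, not the published coefficient
sets; near-critical slabs (interface width approaching the slab thickness)
defeat the plateau analysis and are reported as "no coexistence" rather
than extrapolated.
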