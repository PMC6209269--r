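---
title: "Methods: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

polybundle simulates semi-flexible bead-spring polymers whose lateral
cohesion drives bundling, bundle melting, and -- out of equilibrium --
fiber-network gelation. Everything is in reduced units: energies in
$\varepsilon$, lengths in $\sigma$, $k_B = 1$, temperatures in
$\varepsilon/k_B$.

Three terms define the Hamiltonian:

* **Nonbonded pairs.** A force-shifted 12-6 Lennard-Jones potential,
  $U(r) = U_{LJ}(r) - U_{LJ}(r_c) - (r - r_c)\,U'_{LJ}(r_c)$ for
  $r < r_c = 2.5\sigma$ and exactly zero beyond, so energy *and* force are
  continuous at the cutoff. With $r_c = 2.5\sigma$ the attractive tail is
  present and all beads cohere; the cohesion strength is the sweepable
  $\varepsilon$ (typically $0.8$--$1.8$).
* **Backbone bonds.** A FENE spring,
  $U(r) = -\tfrac{1}{2} k_F R_0^2 \ln[1 - ((r - r_s)/R_0)^2]$ with
  $k_F = 30\,\varepsilon/\sigma^2$, $R_0 = 1.5\sigma$. The offset $r_s$ is
  not defined by the source model; we default to $r_s = 0$, the standard
  Kremer--Grest convention.
* **Bending.** $U(\theta) = k_{bend}(1 + \cos\theta)$ at every interior
  bead, $\theta$ the interior angle, minimized by straight chains.
  $k_{bend}$ spans $4$--$80\,\varepsilon$ in the bundle studies and
  $0.7\,\varepsilon$ in the network-formation study.

**Bonded pairs are included in the nonbonded sum.** This is a deliberate
design decision. The source model applies excluded volume "among all the
beads", and the combination FENE + shifted-LJ is what fixes the
equilibrium bond length near $0.97\sigma$. Excluding 1--2 pairs would
leave a bare FENE bond whose minimum sits at $r = r_s = 0$: the backbone
collapses, angles degenerate, and integration fails -- we verified this
numerically. `model_params(exclude_bonded_pairs = TRUE)` restores the
exclusion for sensitivity analysis.

# Dynamics

Velocity-Verlet integration at `dt = 0.005` reduced time units with bead
mass 1 (conventional for $k_F = 30$ bead-spring models; the source states
neither). Thermostats:

* **Nosé--Hoover** (single chain, $Q = 3N k_B T \tau^2$,
  $\tau = 0.5$): the replication default.
* **Langevin** via BAOAB splitting (damping time $1.0$): used by all
  desk-scale tests, because one- and two-chain systems are weakly ergodic
  under Nosé--Hoover. BAOAB also reproduces the target temperature of a
  free gas essentially exactly at finite `dt`.

Velocities are initialized from the Maxwell--Boltzmann distribution at the
starting temperature with the center-of-mass drift removed. Langevin noise
is drawn from R's RNG, so a seed makes trajectories bit-reproducible;
Nosé--Hoover runs are deterministic given the initial state.

`run_quench()` lowers the thermostat target linearly by `rate`
($\varepsilon/k_B$ per time step) from `T_start` to `T_end` -- "cooling
rate in inverse time steps" is read as a per-step temperature decrement,
the only reading under which all three production rates
($10^{-7}, 10^{-5}, 10^{-4}$) are usable between $T = 2$ and $0.1$.

Pair sums use a periodic cell list (bead-centric sweep) when the box
admits at least three cells per side, otherwise the $O(N_p^2)$ loop.
`compute_energies()` sorts cell-list pairs into the all-pairs loop order
before accumulating, so the accelerated result is **bit-identical** to the
brute-force oracle -- an invariant the suite checks on random frames.

# Persistence length

The projection estimator
$l_p = \langle \vec R_e \cdot \vec l_1 \rangle / \langle |\vec l_1| \rangle$
uses each chain's end-to-end vector and first bond. The denominator is the
mean first-bond *length*; the numerator keeps $\vec l_1$ unnormalized.
This convention makes the rigid-rod limit exact: a straight 99-bond chain
returns $l_p = 99\sigma$, the contour length, which is also the estimator's
upper bound. Chains are unwrapped through the periodic box (bond-walk
minimum image) before projecting.

Bundle values average the per-chain estimates *while embedded in the
bundle* -- the only reading under which bundling changes $l_p$ -- and the
relative rigidity $l_{pr} = l_p / l_{pc}$ divides by an isolated-chain
reference at matching $(k_{bend}, T)$, from a dedicated single-chain run
(or the analytic sampler when cohesion is absent).

**The exact-ensemble oracle.** `sample_wlc_ensemble()` draws chains whose
interior angles are independent Boltzmann samples under the bending term
alone (density $\propto e^{-k_{bend}(1+\cos\theta)/T}\sin\theta$, uniform
torsions, rigid unit bonds) by analytic inverse-CDF in $u = \cos\theta$.
For such chains the estimator has the closed form
$l_p = b\,(1 - c^n)/(1 - c)$ with $c = \langle\cos\theta'\rangle$
evaluated independently by 1D quadrature ($= \coth K - 1/K$,
$K = k_{bend}/T$). Estimator tests must match this closed form within
Monte-Carlo error at $K \in \{0, 1, 5, 20\}$; this is the hard correctness
surface for the analysis chain, reachable without any MD.

# Saturation and temperature fits

* **Crossover fit.** $l_{pr}(N) = l_{pr}^\infty N^2 / (l_{pr}^\infty - 1 + N^2)$
  is algebraically 1 at $N = 1$ and saturates at the plateau
  $l_{pr}^\infty$; the initial $N^2$ growth is the continuum uniform-fiber
  expectation. The single parameter is fitted by golden-section weighted
  least squares (robust to zero-residual data, where Gauss--Newton `nls`
  fails), with a Gauss--Newton standard error from the analytic gradient.
  Degenerate (constant) data are flagged as non-converged, never fitted.
* **Quasi-harmonic fit.** $l_p(N, T) = l_{p0} - A\,T\,e^{-T_D/T}$, fitted
  by bounded `nls` (port) initialized from the low-$T$ linear fit
  ($T \le 0.2$ by default, where $l_{p0} - AT$ dominates) and a small grid
  of $T_D$ starts. Points at or above a supplied melting temperature are
  masked and reported. *Identifiability:* $A$ and $T_D$ are nearly
  degenerate when $T_D$ sits at the edge of the scanned window; the
  synthetic recovery fixtures therefore place $T_D = 0.5$ inside a
  $0.02$--$1.5$ grid (the full production temperature span). With $T_D$
  near the top of the window, only $l_{p0}$ is robustly recoverable --
  a property of the model, not of the optimizer.
* **Scaling checks.** Log-log slope with a confidence interval; the
  small-$N$ $l_{p0} \sim N^2$ and $A \sim N^{-2}$ trends pass when the
  interval covers the exponent.

# Melting detection

$E_{bond}(T) = U_{bond}(T)/N_p$ with $U_{bond}$ the **interchain**
nonbonded energy: melting is interchain unbinding, and covalent FENE bonds
never break in this model (`which = "total"` switches to the
total-nonbonded reading). Heating is sequential -- the final frame at each
temperature seeds the next -- matching the annealed-continuation protocol,
and `n_replicas` independent scans are averaged, mirroring the production
practice of averaging three randomly initiated sets.

The transition is located by fitting a four-parameter logistic (two
baselines, center, width); $T_m$ is the center, where the fitted
$|dE_{bond}/dT|$ peaks with height $(\Delta e)/(4w)$. A smoothing-spline
derivative is the recorded fallback when the sigmoid fit fails. Curves
with no localizable step are flagged rather than given a fabricated
$T_m$: flat curves (spread indistinguishable from noise), fits whose
center leaves the scanned range or whose width exceeds it, and curves a
straight line explains as well as the sigmoid (nested RSS comparison,
5% margin). The last rule catches *strictly* linear data; a linear trend
plus noise can still admit a marginally better sigmoid and is outside the
contract. $\Delta E_{bond} = |E_{bond}(T_{min}) - E_{bond}(T_m)|$ uses the
fitted curve, with the lowest scanned temperature standing in for $T = 0$.

# Network morphology

The measurement protocol for chains-per-fiber and bundle diameter is not
fixed by the source study, so the package fixes and exposes one:
contact-graph edges require `m_contact = 3` interchain bead pairs within
`r_contact = 1.5` $\sigma$; fibers are the connected components. At every
interior bead the local axis is the averaged bond direction over a 5-bead
window; beads in an axial slab of thickness $\sigma$ within
`r_loc = 10` $\sigma$ give `local_n` (distinct chains) and the diameter
$2\sqrt{2}R_{g\perp} + \sigma$ (uniform-disk radius relation plus one bead
diameter). Beads whose `local_n` jumps by more than 2 against both
neighbors are flagged as junction/tie-chain regions and excluded from
means. Network means weight *fibers* equally (two disjoint ideal bundles
of 4 and 8 chains give `mean_n = 6`), since the observable of interest is
the typical fiber, not the typical bead.

On the ideal 7-chain hexagonal cross section the disk-radius relation
overestimates the direct max-extent diameter by about 21% -- discrete
shells are not a uniform disk. The formula is kept (it is unbiased in the
many-chain limit and monotone in $N$ throughout); the suite asserts the
actually derived geometric ratio.

# Synthetic data: the stated world

`make_synthetic_curves()` emits the three closed forms (logistic step,
crossover relation, quasi-harmonic decay) plus Gaussian noise with the
truth attached. Defaults are the production conditions where stated
($\phi = 2.61\times 10^{-3}$, 50 chains of $L = 100$, cooling rates,
$N$ and $k_{bend}$ sweeps) and field-realistic choices otherwise
(sigmoid center 0.6, width 0.05, 2% noise for melting; 5%-of-plateau
noise for recovery studies). What a green recovery test establishes is
that the estimators are calibrated on data *from the model they assume*;
it does not establish equilibration, ergodicity, or finite-size behavior
of real trajectories -- those are probed separately by the scaled-down
seeded MD checks.

Desk-scale MD worlds, chosen once: the rigidity check uses $N = 2$,
$L = 30$, $k_{bend} = 5$, $T = 0.2$ (chains flexible enough that
$l_{pc} \approx 17\sigma$ sits well below the $29\sigma$ contour, leaving
room for bundling to rigidify); the melting check uses $L = 20$,
$k_{bend} = 20$, $T \in [0.1, 1.9]$, because at $k_{bend} = 7$ and this
short length the bundle first collapses into a globule with *more*
interchain contacts, making $E_{bond}(T)$ non-monotone at desk scale --
the globular intermediate the full-scale study itself reports. The quench
check uses 10 chains of $L = 30$ at the production $\phi$ and the fastest
production rate.

# Numerical choices and limitations

* Timestep 0.005, thermostat couplings, and the low-$T$ window 0.2 are
  conventions (configurable), not source facts.
* Production run lengths ($\ge 10^8$ steps) are config defaults in the
  replication files only; tests run $10^3$--$10^5$ steps.
* The bundle builder fills a hexagonal lattice in spiral shell order at
  spacing $2^{1/6}\sigma$ (the pair-potential minimum), giving
  reproducible near-circular cross sections and a start near mechanical
  equilibrium; twist is emergent, never imposed.
* The volume fraction uses the bead sphere volume $(\pi/6)\sigma^3$, which
  reproduces the printed $\phi = 2.61\times10^{-3}$ in a $\approx
  100\sigma$ box.
* Alternative $l_p$ estimators (tangent-correlation decay), free-energy
  analysis of the transition, pressure control, electrostatics and
  hydrodynamics are out of scope.
* $T_m$ of small bundles at desk scale is a kinetic quantity: short
  sequential scans near coexistence under-sample unbind/rebind events,
  which is why replica averaging is on by default in the acceptance runs.
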