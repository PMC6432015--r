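---
title: "Conditioned dynamics of semiflexible Gaussian rings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditioned dynamics of semiflexible Gaussian rings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

knotbridge generates exact conditioned (bridge) trajectories of the overdamped
Langevin dynamics of semiflexible Gaussian ring polymers between two given
conformations in a preassigned time, and analyses the knotting--unknotting
pathways such trajectories traverse. This vignette records the model, the
conventions, and the design decisions, in the package's own words; every
empirical claim mentioned here is recomputed by the test suite or by
`scripts/acceptance.R`.

## The chain model

A ring of N beads moves under the quadratic potential (energies in kBT)

$$ U = \sum_{n=1}^{N} \frac{3}{2a^2}\,(r_{n+1}-r_n)^2
      + \frac{K}{2}\,(r_{n+1}-2r_n+r_{n-1})^2 , $$

with periodic indices ($r_{N+1}=r_1$). The first term is the entropic
elasticity of a Gaussian (phantom, extensible) chain with bare bond scale
`a`; the second is a discrete curvature penalty with rigidity `K`
(units 1/length$^2$). This is the standard mean-field representation of a
semiflexible polymer: the bond length is not fixed, and the contour length is
not conserved by the dynamics. Beads obey overdamped Langevin dynamics with
diffusion constant D (friction $\gamma = k_BT/D$) and independent white noise
of strength 2D per Cartesian component. Internally b = 1 sets the length unit
and $b^2/D$ the time unit.

### Calibrating (a, K) to a target bond length and persistence length

Users specify the root-mean-square bond length `b` and persistence length
`lP`. In mode space the equilibrium bond-vector correlation function of this
model is exactly

$$ C(s) = \langle u_n\!\cdot\!u_{n+s} \rangle \propto e^{-\mu s}, \qquad
   \cosh\mu = 1 + \frac{1}{2\kappa}, \qquad \kappa = \frac{K a^2}{3}, $$

(the pole of the discrete Ornstein--Zernike mode sum), so the decay length in
bonds is $1/\mu$, i.e. $\approx\sqrt\kappa$ for stiff chains. `knotbridge`
therefore calibrates the dimensionless stiffness by inverting the exact
relation, $\kappa = 1/(2(\cosh(b/l_P)-1)) \approx (l_P/b)^2$. A widely used
mean-field shortcut identifies $l_P$ with $\kappa b$ instead; that
identification does not reproduce the tangent-correlation decay this model
actually exhibits (it errs by a factor $\approx\sqrt\kappa$), and with it the
calibration--sampling--estimation round trip cannot close, so the package does
not use it. Note the consequence: the persistence length of this model grows
as $\sqrt K$, not linearly in K.

Given $\kappa$, the bond scale follows from the exact equilibrium identity

$$ b^2 = \frac{a^2}{N} \sum_{p=1}^{N-1}
         \bigl[\,1 + 2\kappa\,(1-\cos\omega_p)\,\bigr]^{-1},
   \qquad \omega_p = \frac{2\pi p}{N}, $$

whence $a = b/\sqrt S$ and $K = 3\kappa/a^2$. The sum excludes p = 0: the
centre-of-mass mode carries no bond-length fluctuation, and including its
unit summand would bias the realized $b^2$ by $O(1/(NS))$ — about 2% at
N = 240, $\kappa \approx 25$ — which the 3-sigma recovery tests would detect.

### Estimating the persistence length

`persistence_length_estimate()` fits the sampled bond-vector correlation to
$C(s) = A e^{-s/\xi} + B$. Two details matter on rings:

* the closure constraint $\sum_n u_n = 0$ forces $\sum_s C(s) = 0$, so the
  correlation is a geometric decay *shifted by a small negative offset*; a
  log-linear fit without B is biased by several percent.
* raw bond vectors are used rather than unit tangents: for Gaussian chains
  the bond-vector correlation is exactly exponential, whereas normalizing
  each bond to unit length multiplies the correlation by a slowly varying
  function of the correlation coefficient, curving the log-plot at short
  separations and biasing window fits.

Standard errors come from refitting on disjoint sample batches: the errors of
$\hat C(s)$ across s share the same samples and are strongly correlated, so
per-point weighted-least-squares errors would be understated several-fold.

## Mode space

The full complex Fourier basis
$\tilde\rho_p = N^{-1}\sum_n e^{-i\omega_p n} r_n$ is used (a cosine-only
transform cannot represent a general ring); Hermitian symmetry
$\tilde\rho_{N-p}=\overline{\tilde\rho_p}$ holds for real rings, and the pair
(p, N−p) is propagated as one complex degree of freedom. Under this
normalization

* the potential is diagonal: $U/k_BT = N\sum_p \Omega_p|\tilde\rho_p|^2$ with
  $\Omega_p = (3/a^2)(1-\cos\omega_p) + 2K(1-\cos\omega_p)^2$;
* the mode noises per Cartesian component carry total variance 2D dt/N per
  step: all of it in the real part for the real modes p = 0 (and N/2 for even
  N), split evenly (D dt/N each) between real and imaginary parts otherwise.
  Summed over modes this reproduces the 2D dt real-space variance (Parseval).
  In practice each step's mode noise is generated by transforming iid
  real-space Gaussian increments, which realizes all moments and exact
  Hermitian symmetry at once;
* the relaxation rate of mode p is $\lambda_p = 2D\Omega_p$. The factor 2D is
  the gradient-flow rate of the stated potential under the stated noise: with
  it (and only with it) the stationary mode variance is $1/(4N\Omega_p)$ per
  real component, which is what the $b^2$ identity above integrates to. The
  bridge formulas below therefore carry $\lambda_p$ wherever a relaxation
  rate appears.

## Bridge dynamics

A trajectory of the free dynamics conditioned to start at
$\{\tilde\rho_p(0)\}$ and end at $\{\tilde\rho_p(f)\}$ at time $t_f$ is
generated exactly by adding the conditioning drift
$2D\,\partial \log Q/\partial x$, where Q is the transition probability to
the target. For independent Ornstein--Uhlenbeck modes this is closed form:

* p = 0 (free diffusion): Brownian-bridge drift
  $(\tilde\rho_0^{(f)}-\tilde\rho_0)/(t_f-t)$;
* p > 0: $-\lambda_p \tilde\rho_p + \dfrac{\lambda_p}{\sinh \lambda_p\tau}
  \bigl(\tilde\rho_p^{(f)} - \tilde\rho_p e^{-\lambda_p\tau}\bigr)$, with
  $\tau = t_f - t$.

The drift is independent of the noise amplitude, identical for real and
imaginary parts, and reduces to the Brownian-bridge pull as
$\lambda_p \to 0$. Statistically the bridged ensemble is the free dynamics
conditioned on its endpoint — trajectories are unbiased, and the
time-reversed problem is an equally valid bridge.

Numerical choices:

* Euler--Maruyama with dt = 1e-4 (time unit $b^2/D$) and $t_f = 2$ as the
  standard run; dt must divide $t_f$. The endpoint-pinning error of the
  deterministic part is O(dt) (tested by dt-halving).
* $\lambda_p \tau$ spans roughly ten orders of magnitude across modes and
  times, so $\lambda/\sinh(\lambda\tau)$ is evaluated as
  $2\lambda e^{-\lambda\tau}/(-\mathrm{expm1}(-2\lambda\tau))$ — stable from
  $\lambda = 0$ (where it limits to $1/\tau$) to values where
  $e^{-\lambda\tau}$ underflows harmlessly.
* the $1/(t_f-t)$ drift is formally singular at the last step; the integrator
  instead sets the final frame exactly to the selected target (the
  permutation of maximal weight at the penultimate step), a standard
  bridge-endpoint regularization with O(dt) error.

### Circular-permutation conditioning

Two closed rings have no preferred bead-to-bead correspondence, so the
physically meaningful target is the set of all N cyclic relabellings
$\{r^{(f)}_{n+n_0}\}$. Because a cyclic shift only twists mode phases,
$\tilde\rho_p^{(n_0)} = e^{i\omega_p n_0}\tilde\rho_p^{(f)}$, the conditioned
drift becomes a weighted pull towards the P1-weighted average of the
permutation targets, with log-weights

$$ \log P_1(n_0) = -\frac{N}{2D}\sum_{p\ge1} \lambda_p\,
   \frac{\bigl|\tilde\rho^{(n_0)}_p - \tilde\rho_p e^{-\lambda_p\tau}\bigr|^2}
        {1-e^{-2\lambda_p\tau}} $$

(the p = 0 term is permutation independent and cancels on normalization).
All weights are computed in log space and normalized by log-sum-exp; the
$n_0$ dependence is a single inverse FFT, so the permuted bridge costs only
O(N log N) extra per step. A permuted run with a single listed permutation
follows the identical code path as the plain bridge and is bit-identical to
it under the same seed. All N permutations are included (no reflections or
orientation reversals).

Reproducibility: every source of randomness — integrator noise, Monte Carlo
moves, projection directions — consumes the single R RNG stream, seeded once
per run, so runs are exactly repeatable.

## Knot identification

The topology layer answers "which knot is this closed polygon?" cheaply and
robustly for the repertoire relevant here (prime knots through 7 crossings):

1. **Diagram**: project the oriented ring along a random direction; find all
   segment-pair crossings exactly (O(N²) tests); record over/under from depth
   and the sign from the right-hand rule,
   $\mathrm{sign}\,[(t_{over}\times t_{under})\cdot d]$. Degenerate
   projections (grazing intersections, depth ties, near-collinear parallels
   within 1e-9 of the projected scale) are retried with a perturbed
   direction (at most 100 times).
2. **Gauss-code reduction**: Reidemeister I/II simplification of the passage
   sequence, which typically shrinks diagrams of equilibrated rings several
   fold before any linear algebra.
3. **Alexander determinants**: from the Wirtinger presentation, Fox
   derivatives give one matrix row per crossing (over arc: $1-t$; incoming
   and outgoing under arcs: $t$ and $-1$ for positive crossings, $-1$ and $t$
   for negative). One row and column are deleted and the minor determinant is
   evaluated at t = −1 and t = −2 in exact integer arithmetic, implemented
   modularly: Gaussian elimination over two 26-bit prime fields (products
   stay exact in doubles) recombined by the Chinese remainder theorem. The
   minor determinant equals $\pm t^k \Delta(t)$; the unit $t^k$ is stripped
   by a modular polynomial interpolation that locates the lowest nonzero
   coefficient. This matters because $|\Delta(-2)|$ can be even (5_2 gives
   16), so naively dividing out factors of two would corrupt the invariant.
   $|\Delta(1)| = 1$ is verified on every evaluation as a diagram-consistency
   check.
4. **Lookup and chirality**: $(|\Delta(-1)|, |\Delta(-2)|)$ distinguishes all
   prime knots through 7 crossings (the table is checked for injectivity);
   pairs outside the table — composites, 8 or more crossings — are reported
   as `unresolved` with the raw determinants rather than as an error. Two
   independent projections must agree before a label is accepted. Alexander
   determinants are blind to mirror images, so chirality is reported from the
   sign of the exact Gauss writhe, with $|Wr| > 0.5$ required to call
   handedness (writhe + is right-handed).

**Writhe and average crossing number.** The writhe is computed either as the
exact discrete Gauss double integral over non-adjacent segment pairs
(variance free, the reference) or as the average signed crossing count over
uniformly random projection directions, whose expectation equals the Gauss
value; the average crossing number is the same average with all weights +1.
Per-frame pathway metrics default to 1000 projections.

## Endpoint generation

`parametric_knot()` supplies exact-topology initializers: a planar circle,
(2,q) torus curves for 3_1/5_1/7_1, the standard figure-eight curve, and a
trigonometric loop for 5_2 whose coefficients were found by a randomized
search and verified by the package's own knot identification at several
discretizations and both mirror images. Either chirality is produced by
z-mirroring when requested.

`mc_equilibrate()` equilibrates a self-avoiding cylinder ring (diameter
sigma, default b/4; minimum segment-segment distances below sigma rejected)
at fixed topology by Metropolis Monte Carlo. Moves mix:

* **crankshaft** rotations of a random sub-arc about the chord through its
  hinges — preserves every bond length, so only hinge bending terms enter the
  Metropolis ratio;
* **single-bead displacements** — crankshafts alone leave all bond lengths
  frozen, so an extensible chain would never equilibrate its bond statistics
  without them.

Every move's maximum displacement is capped below the cylinder diameter:
a finite rotation could otherwise carry a strand through another without any
overlap in the end state. The cap depends only on rotation invariants, so
proposals stay symmetric and detailed balance holds (verified against the
exact mode-space sampler on small phantom rings). The knot label is
re-verified after every equilibration and a mismatch is an error.

`sample_gaussian_equilibrium()` draws exact, independent equilibrium
conformations of the phantom model by equipartition in mode space; it is the
reference distribution for all calibration tests.

## Pathway reports and study conditions

`build_report()` evaluates per frame: absolute-frame RMSD to both endpoints
(the bridge pins absolute coordinates, so no superposition by default;
Kabsch superposition is available), knot label with determinants, exact Gauss
writhe and projection-averaged writhe/ACN. Knot bands are maximal runs of
constant label; with the default integration stride (every 100 steps of
dt = 1e-4) band boundaries are resolved to 0.01 time units — knot detection
is the cost bottleneck, and no smoothing is applied, so very short-lived
states between evaluation points can be missed. Contour-length rescaling is
available as a reporting-time convenience only.

The standard study conditions, fixed before any measurement, are the ones the
analyses in the tests and acceptance script use: N = 240 beads, b = 1,
Kuhn length 10b (lP = 5b), sigma = b/4, D = 1, dt = 1e-4, tf = 2.
Desk-scale choices made once for the automated checks: 2000 equilibrium
samples for the calibration recovery; 12 trajectories per endpoint setting
with 250 Monte Carlo sweeps per endpoint, with occurrence counts of
trefoil-mediated unknot--figure-eight routes and of 6-or-more-crossing
excursions in same-topology routes compared against exact 99% binomial
prediction intervals at the literature rates (10/32 and 6%), since at this
ensemble size those rates imply counts too small for a sharper comparison.

## What the generators emulate, and limitations

* The synthetic endpoints are equilibrated self-avoiding semiflexible rings;
  desk-scale Monte Carlo (hundreds of sweeps) equilibrates local structure
  thoroughly but retains some memory of the smooth parametric start at the
  longest wavelengths. Full-scale equilibration (10^5 sweeps) is hours of
  CPU and changes endpoint conformations, not the bridge law.
* Excluded volume acts only on endpoint preparation; it is switched off
  during bridging, which is the point (topology-unrestricted reconnections,
  as for crossable filaments or topoisomerase-mediated strand passage), but
  means bridge intermediates are not self-avoiding conformations.
* The quadratic model has no external forces, no hydrodynamics, uniform
  friction; contour length fluctuates.
* Knot labels outside the 7-crossing table are `unresolved`; in complexity
  statistics they are counted as "6 or more crossings", which is correct for
  every prime knot with 8+ crossings and for the composites reachable here
  (e.g. granny/square knots, 3_1 # 4_1), but is a convention, not a theorem.
* Band boundaries depend on the evaluation stride; no attempt is made to
  reproduce figure-level timings of any particular published trajectory,
  which depend on the (undeposited) endpoint conformations.
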