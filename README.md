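# knotbridge

Exact conditioned (bridge) Langevin dynamics of semiflexible Gaussian ring
polymers, with a full topology-analysis layer for studying
knotting–unknotting pathways.

## The problem

Ring polymers that cannot cross themselves are trapped in one knotted state.
Many filamentous systems *can* change topology — defect lines in liquid
crystals, vortex lines in fluids, and DNA rings acted on by topoisomerases —
and the central question is which reconnection routes between two given
shapes (and topologies) are physically viable. Free simulations are useless
here: a spontaneous trajectory essentially never ends in a prescribed target
conformation. `knotbridge` instead samples the conditioned dynamics exactly:
unbiased trajectories of the overdamped Langevin dynamics of a phantom
semiflexible ring that start at conformation A at time 0 and end at
conformation B (or any cyclic relabelling of its beads) at a preassigned
time, generated by local stochastic differential equations in Fourier-mode
space. Each mode p is an independent Ornstein–Uhlenbeck bridge:

    d rho_p/dt = -lambda_p rho_p
                 + lambda_p / sinh(lambda_p (tf - t)) * (rho_p^f - rho_p e^{-lambda_p (tf-t)})
                 + eta_p(t),

with the p = 0 (centre-of-mass) mode a plain Brownian bridge, and, for ring
targets, the pull directed at the P1-weighted combination of all N circular
permutations of the final state (weights computed in log space each step).
The chain model is the discrete Gaussian semiflexible ring
`U/kBT = sum 3/(2a^2) (r_{n+1}-r_n)^2 + K/2 (r_{n+1}-2r_n+r_{n-1})^2`,
calibrated so the root-mean-square bond length is `b` and the bond-direction
correlation decay length is `lP`.

The topology layer identifies knots from Alexander determinants
(|Δ(−1)|, |Δ(−2)|) evaluated in exact integer (modular) arithmetic from a
projected diagram — the pair separates all prime knots through 7 crossings —
plus chirality from the exact Gauss-integral writhe, and computes writhe and
average crossing number over random projections. Endpoints of prescribed knot
type come from parametric initializers equilibrated by crankshaft Monte Carlo
of self-avoiding cylinder rings (excluded volume acts only during endpoint
preparation; bridging is deliberately phantom so topology can change).

## Worked example: watching a ring tie itself into a 5_1 knot

```r
library(knotbridge)

params <- chain_parameters(N = 240, b = 1, lP = 5)  # Kuhn length 10 b
print(params)
#> chain_parameters: N=240  b=1  lP=5  (a=3.2359, K=7.13877, kappa=24.9168)  D=1

# endpoints: an equilibrated unknot and a left-handed 5_1 torus knot
set.seed(21)
unknot <- mc_equilibrate(parametric_knot("0_1", N = 240), params, n_sweeps = 400)
cinq   <- mc_equilibrate(parametric_knot("5_1", N = 240, chirality = "left"),
                         params, n_sweeps = 400)
print(cinq$knot)
#> knot 5_1 (|Delta(-1)|=5, |Delta(-2)|=31), chirality left, Wr=-6.832

# bridge conditioned on all circular permutations of the target
traj <- run_bridge(unknot$ring, cinq$ring, params, dt = 1e-4, tf = 2,
                   conditioning = "bridge_permuted", seed = 33)
print(traj)
#> bridge_trajectory: 201 frames, N=240, tf=2, dt=0.0001,
#>   conditioning=bridge_permuted, landed on permutation n0=74

set.seed(99)
report <- build_report(traj, stride = 2)
print(report$bands)
#>   label t_start t_end
#> 1   0_1    0.00  1.84
#> 2   3_1    1.86  1.94
#> 3   5_2    1.96  1.96
#> 4   5_1    1.98  2.00
```

Reading the output: the ring stays unknotted for 92% of the allotted time,
then knots up through a trefoil (3_1, unknotting number 1) — the 5_1 target
has unknotting number 2, so at least two strand passages are unavoidable and
the trefoil is the natural stepping stone — with a brief 5_2 excursion just
before the target topology locks in. The last report rows show the absolute
RMSD to the final state falling to exactly 0 at tf = 2 (the bridge pins the
endpoint to machine precision) while the Gauss writhe descends to ≈ −6.8,
consistent with the left-handedness of the target:

```r
tail(report$table[, c("time", "rmsd_initial", "rmsd_final", "knot", "writhe_gauss")], 4)
#>     time rmsd_initial rmsd_final knot writhe_gauss
#> 98  1.94     32.52812  1.1244661  3_1    -2.958797
#> 99  1.96     32.87773  0.7830658  5_2    -4.988273
#> 100 1.98     33.21591  0.4598804  5_1    -6.998751
#> 101 2.00     33.56814  0.0000000  5_1    -6.832057
```

`ensemble_experiment()` repeats this over independently seeded bridges and
aggregates which intermediate topologies occur and how often routes visit
knots more complex than both endpoints.

A thin command-line front end covers the same workflow on XYZ files:

```sh
Rscript inst/cli/knotbridge.R sample  --knot 5_1 --chirality left --n 240 --seed 1 --out b.xyz
Rscript inst/cli/knotbridge.R run     --initial a.xyz --final b.xyz --tf 2 --seed 2 --out traj.xyz
Rscript inst/cli/knotbridge.R analyze --traj traj.xyz --nproj 1000 --seed 3 --out metrics.csv
```

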