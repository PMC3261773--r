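# lactoburst

Slow-fast analysis of pseudo-plateau bursting in a pituitary lactotroph
model.

Anterior-pituitary cells such as lactotrophs secrete hormone in response
to electrical bursting: short depolarized plateaus carrying small
spikes, quite unlike the square-wave bursting of neurons.  This package
implements a three-variable conductance-based lactotroph model

C_m dV/dt = −(I_Ca + I_K + I_K(Ca) + I_BK),
dn/dt = (n∞(V) − n)/τ_n,
dc/dt = −f_c (α I_Ca + k_c c),

and the one-fast/two-slow (geometric singular perturbation) analysis
that explains its bursting as a **canard-induced mixed mode
oscillation**:

* the critical manifold f = 0, its fold curves L± and their vertical
  projections;
* the reduced and desingularized slow flows, ordinary and folded
  singularities, spectral classification, the folded-node eigenvalue
  ratio μ and the rotation bound S_max = ⌊(μ+1)/(2μ)⌋;
* singular periodic orbits with fold jumps and the funnel-entry
  distance δ — δ > 0 predicts bursting, δ < 0 spiking;
* one- and two-parameter scans in (g_K, g_BK): type I and type II
  folded saddle-nodes (SN1/SN2, TR1/TR2), focus–node transitions, the
  fold-merge line and its codimension-2 point, and the δ = 0 boundary
  of the mixed-mode region;
* stiff full-system simulation (compiled right-hand side) with burst
  feature extraction (regime, period, active-phase duration, spikes per
  burst), full-system Hopf detection, and a burst-feature map over the
  conductance plane;
* the complementary two-fast/one-slow "z-curve" analysis, for
  comparison;
* a synthetic-trace generator with known ground truth for validating
  the feature extractor.

It is aimed at researchers in computational neuroendocrinology and
slow-fast dynamics who want the full analysis pipeline — from ODE to
two-parameter bursting map — as tested, scriptable R functions.

## Worked example

```r
library(lactoburst)

p <- lacto_pars()            # reference parameters: gK = 4, gBK = 0.4 nS
fold_voltages(p)
#> [1] -61.03205 -22.80266    # the two fold levels V-, V+ (mV)

find_folded_singularities(p)
#> Singularities of the desingularized lactotroph flow:
#>     kind on_curve         V          c         class          mu s_max       flags
#> 1 folded       L- -61.03205 -0.3457470  folded_focus          NA    NA nonphysical
#> 2 folded       L- -61.03205  0.3361876  folded_focus          NA    NA
#> 3 folded       L+ -22.80266 -0.3907713 folded_saddle -0.12184123    NA nonphysical
#> 4 folded       L+ -22.80266  0.3041871   folded_node  0.03963499    13
```

There is a folded node on the upper fold at c ≈ 0.304 µM with
eigenvalue ratio μ ≈ 0.0396: trajectories entering its singular funnel
can make up to S_max = 13 small rotations — the spikes of the burst.
Whether the singular periodic orbit actually enters the funnel is the
distance δ:

```r
delta_of(pars = p)$delta                          # gK = 4
#> [1] 0.01350418                                  # inside: bursting
delta_of(pars = set_pars(p, gK = 5.1))$delta
#> [1] -0.004339067                                # outside: spiking
```

The full system honours the prediction:

```r
simulate_features(set_pars(p, gK = 6, gBK = 1, Cm = 5))
#> Burst features: bursting
#>   period 376.2 ms, active phase 218.2 ms, 3 spikes/burst
```

Bifurcations of the desingularized system along g_K at g_BK = 0.4 nS:

```r
find_TR(p, "gK", c(0.1, 1))$value      # type II folded saddle-node
#> [1] 0.5130821
find_SN(p, "gK", c(4, 10))$value       # type I folded saddle-node
#> [1] 7.588902
find_fold_merge(p)$value               # folds merge (any gK)
#> [1] 32.12236
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lactoburst.R", package="lactoburst"))')" \
    singularities --gK 4 --gBK 0.4 --out out/
```

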