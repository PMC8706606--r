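# cfrsim — cyclical fate restriction gene-network simulator

`cfrsim` simulates and analyses the generalized repressilator networks used
to model **cyclical fate restriction**: the idea that a multipotent
progenitor (the neural-crest-derived pigment/neural progenitor is the
motivating case) does not lose fates one by one, but *cycles* through
transient sub-states, each biased towards one fate, until an environmental
signal locks it into a single fate. The package is for modellers who want to
explore when small mutual-repression circuits produce that repertoire, and
to run the corresponding in-silico experiments: coupling ramps, fate-specific
signals, gene knockouts, and topology scans.

## The model

Each of $N$ fate-specifying transcription factors carries one expression
variable $x_i \ge 0$:

$$\dot x_i \;=\; \kappa_i\!\left[\alpha_0 +
\frac{\beta}{1 + g(t)\sum_j W_{ij} x_j^{h}}\right] - \delta\, x_i + s_i(t)$$

with relative coupling matrix $W$ (repressilator ring, nearest-neighbour
ring, or all-pairs "double repressilator" with strengths graded by cyclic
distance), global coupling schedule $g(t)$, Hill coefficient $h$, knockout
mask $\kappa$, and optional fate-specific signals $s_i(t)$. An AND-gate
variant combines repressors multiplicatively
($1 + g\,\bar w_i \prod_j x_j^{h m_{ij}}$), so repression requires *all*
inputs high. As $g$ grows, rotationally symmetric networks pass through
three regimes — **multipotent** (all factors equal), **oscillatory**
(cycling through fate-biased sub-states), **differentiated**
(winner-take-all) — and the package maps the two boundaries analytically
(symmetric-branch eigenvalues; Newton on the winner-take-all branch) plus
the empirical cycle-death coupling by continuation.

## A worked example

```r
library(cfrsim)

net <- cfr_preset("double-or")$network   # 3-gene double repressilator, OR gate
regime_boundaries(net, c(1e-3, 5))
#> <cfr_boundaries> g_lower = 0.053979, g_upper = 0.137846

traj <- simulate_network(net, coupling_schedule("constant", 0.15),
                         x0 = perturbed_start(net, 0.15, seed = 1),
                         t_max = 600, n_out = 5000)
classify_regime(traj)
#> <cfr_regime> oscillatory (g = 0.15)
#>   means: 2.751, 2.756, 2.752
#>   amplitudes: 3.532, 3.532, 3.532
#>   period: 6.113
#>   dwell fractions: 1=0.333 2=0.335 3=0.333

ens <- ramp_ensemble(net, n_runs = 300, seed = 1)
ens
#> <cfr_ensemble> 300 runs (0 undetermined), seed 1
#>   fate proportions: 1=0.320 2=0.373 3=0.307
#>   predictor agreement 0.970 | chi-square uniformity p = 0.326
#>   cycling order: 1 -> 3 -> 2
```

The boundary report says the multipotent state destabilizes at
$g \approx 0.054$ and stable winner-take-all states appear at
$g \approx 0.138$ (the cycle itself survives to $g \approx 0.37$; the
overlap is reported, not hidden). At $g = 0.15$ the cell cycles through the
three fate-biased sub-states with equal dwell (a third each). Under a slow
coupling ramp all 300 simulated cells differentiate, the three fates are
adopted uniformly, and the sub-state occupied when the ramp crosses the
oscillatory exit predicts the adopted fate (via its successor in the
measured cycling order) in 97% of runs.

Knockouts reproduce the mutant predictions — the mutant lingers in the
sub-state preceding the knocked-out gene's and, in networks with redundant
repression routes, keeps cycling:

```r
ko <- knockout_experiment(cfr_preset("penta-graded")$network, 1,
                          context = "dwell", g = 0.15, seed = 3)
ko
#> <cfr_knockout> gene 1, dwell context
#>   wild-type cycling order: 1 -> 5 -> 4 -> 3 -> 2 (preceding: 2)
#>   preceding dwell fraction: wt 0.201 -> mutant 0.523 (lingers: TRUE)
#>   mutant keeps cycling: TRUE
```

A command-line launcher (`inst/cli/cfrsim`) wraps the same operations:
`cfrsim simulate --preset repressilator --out DIR`, plus `sweep`,
`ramp-ensemble`, `knockout`, and `topology-scan` subcommands; every output
directory carries its config echo, seed, and manifest.

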