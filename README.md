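# threeprop

Semi-supervised node-label prediction on undirected weighted networks, for
problems like gene-function prediction from protein- or genetic-interaction
networks: given a handful of nodes known to carry a label, rank every other
node by how likely it is to carry the same label, with no negative examples.

## The method

Classic label propagation scores nodes by the series
*f* = Σ<sub>r</sub> λ<sup>r</sup> M<sup>r</sup> y, where *y* marks the known
positives and *M* is a degree-normalization of the affinity matrix *A* —
either the symmetric *S* = D<sup>−1/2</sup>AD<sup>−1/2</sup> or the
row-stochastic *P* = D<sup>−1</sup>A, under which
(P<sup>r</sup>y)<sub>i</sub> is the probability that a length-*r* random
walk from node *i* ends in a positive. The λ<sup>r</sup> weights are positive
and decaying, which hard-codes the assumption that closer nodes are more
alike. That assumption fails on disassortatively mixed networks (direct
links argue *against* sharing a label) and on shared-neighbour networks like
genetic-interaction maps (same-label nodes rarely touch but share partners).

**3Prop** drops the decay profile and keeps only the first three walk
lengths, with free, possibly negative weights:

&nbsp;&nbsp;&nbsp;&nbsp;*f* = w₁·My + w₂·M²y + w₃·M³y

The weights are fitted by linear discriminant analysis,
w = C<sup>−1</sup>(μ₊ − μ₋), on the walk-feature rows, with a 2/3–1/3 split
of the training positives (two-thirds drive the propagation, one-third are
scored for the class statistics) to keep a positive's own label from
inflating its features. Walks beyond length three are omitted because on
small-diameter networks the walk distribution is already close to its
stationary limit π<sub>i</sub> = d<sub>i</sub>/Σd after a few steps and
carries degree information, not label information — the package's mixing
diagnostics measure exactly this.

The package provides the fitting function `threeprop()` with the usual
`print`/`summary`/`coef`/`predict`/`plot` methods, the propagation toolbox
(`glp_truncated`, `glp_exact`, `slp_via_alp`, `walk_features`), rank metrics
and nested cross-validation (`auroc`, `average_precision`,
`cross_validate`, `nprop_sweep`), seeded generators for the three labelling
regimes (`synth_network`), walk-mixing diagnostics
(`stationary_distribution`, `tv_curve`, `mixing_report`), and a command-line
front end (`exec/threeprop`).

## Worked example

Generate a genetic-interaction-like network (positives share hub neighbours
but almost never link each other), fit 3Prop, and compare with classic
propagation under nested cross-validation:

```r
library(threeprop)

sim <- synth_network(pattern = "shared_neighbor", seed = 1)
fit <- threeprop(sim$graph, sim$positives, split_seed = 1)
fit
#> 3Prop fit (symmetric normalization)
#> Walk weights (unit norm):
#>      w1      w2      w3
#>  0.0594  0.8494 -0.5244
#> Training: 30 positives (20 propagation / 10 estimation), 270 non-positives; split_seed = 1
```

The fit reads the regime off the network: direct links get a negligible
weight (w₁ ≈ 0.06 — they carry no evidence here), hub-mediated two-step
walks dominate (w₂ ≈ 0.85), and three-step walks are *negative*
(w₃ ≈ −0.52), discounting the background nodes that merely sit near the
dense core. Held-out performance:

```r
cross_validate(sim$graph, sim$positives, method = "nprop", seed = 1)
#> NPROP (symmetric), 3-fold outer / 2-fold inner CV, 30 positives vs 270 non-positives
#>  fold              parameter     auroc       aup n_test_pos
#>     1 w=(0.065,0.901,-0.429) 0.9981481 0.9666667         10
#>     2 w=(0.040,0.828,-0.559) 1.0000000 1.0000000         10
#>     3 w=(0.067,0.737,-0.673) 0.9985185 0.9651515         10
#> Mean AUROC = 0.9989, mean AUP = 0.9773

cross_validate(sim$graph, sim$positives, method = "glp", seed = 1)$auroc
#> [1] 0.5177778
```

3Prop separates the held-out positives almost perfectly (AUROC 0.999) where
best-λ label propagation hovers at chance on the same graphs. The mixing
diagnostic shows why long walks cannot help — by ten steps a walk has
forgotten its start:

```r
head(mixing_report(sim$graph, n_starts = 100, r_max = 10, seed = 1), 4)
#>   r      median         q25         q75
#> 1 0 0.996596136 0.996205152 0.996964121
#> 2 1 0.874655014 0.859291628 0.887902484
#> 3 2 0.180733988 0.171311393 0.193086953
#> 4 3 0.050770319 0.048708655 0.053891773
```

The same workflow is available from the shell:

```sh
threeprop simulate --pattern shared_neighbor --seed 1 --edges net.tsv --labels pos.txt
threeprop cv  --edges net.tsv --labels pos.txt --method nprop --seed 1 --out cv.tsv
threeprop fit --edges net.tsv --labels pos.txt --seed 1 --out fit.json
threeprop score --edges net.tsv --labels pos.txt --weights fit.json --out scores.tsv
```

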