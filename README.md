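# pgpr: phylogenetic Gaussian process regression for function-valued traits

Many phenotypes of evolutionary interest are not scalars but curves: growth
trajectories, mortality schedules, reaction norms, distributions of gene or
protein properties. `pgpr` is an R package for analysing such function-valued
traits observed at the tips of a known phylogeny. It estimates how the curves
were generated, separates phylogenetic (heritable) from non-phylogenetic
(specific) variation, and reconstructs full posterior distributions of the
curves of unobserved ancestors.

## Model

Each taxon's curve is a linear mixture of a small set of fixed basis functions
`phi_1, ..., phi_k`:

    d_j(s) = sum_i  X_ij * phi_i(s)

The mixing coefficients `X_ij` — not the basis functions — evolve. Each row
`X_i` is an independent stationary Ornstein–Uhlenbeck Gaussian process indexed
by the phylogeny, plus i.i.d. noise at the extant tips, so that for taxa `j`,
`g` at patristic distance `D(t_j, t_g)`:

    cov(X_ij, X_ig) = sigma_f^2 * exp( -D(t_j, t_g) / (2 * ell) )
                      + sigma_n^2 * [j == g, extant]

Per component the hyperparameters `gamma = (sigma_f, ell, sigma_n)` are the
stationary phylogenetic standard deviation, the characteristic length-scale of
correlation decay (`ell = 1/(2*alpha)` for OU selection strength `alpha`), and
the non-phylogenetic standard deviation; `sigma_f^2 / (sigma_f^2 + sigma_n^2)`
is the proportion of variance attributable to the phylogeny (closely related
to Pagel's lambda).

The package provides the four stages of the framework and a generative
simulator used to validate them:

1. **Simulation** (`random_tree`, `synthesize_dataset`) — recursive OU
   simulation over a whole random tree, plus tip noise and basis mixing.
2. **Source separation** (`ipca`) — PCA for the effective dimension, then an
   independent component rotation (cumulant-based CubICA-style by default,
   FastICA-style optional) recovering basis functions and mixing coefficients
   from tip curves alone.
3. **Hyperparameter inference** (`mle_gamma`, `bagged_mle`) — maximum
   likelihood via the Gaussian marginal likelihood on the tree, aggregated
   over random 100-taxon subtrees (bagging), with diagnostics that flag absent
   phylogenetic signal via implausible length-scales.
4. **Ancestral reconstruction** (`reconstruct_all`, `autocovariance`) —
   closed-form Gaussian posteriors of each ancestor's curve with pointwise
   phylogenetic and non-phylogenetic uncertainty bands, and a positive
   semidefinite phylogeny-aware estimate of the trait autocovariance.

## Worked example

The full simulate-and-recover experiment at the standard study conditions —
a random 128-tip tree rescaled to maximum patristic distance 8.22, three
unimodal basis functions on 1024 grid points, components
`(sigma_f, ell, sigma_n)` = (2.5, 6.17, 0.5), (0, n.a., 1.0), (1.5, 2.06, 0.5),
bagged MLE with 100 bags of 100 taxa:

```r
library(pgpr)
report <- run_experiment(default_config(seed = 1))
print(report)
```

```
experiment report (seed 1): k_hat = 3
  matched coefficient |correlations|: 0.953, 0.886, 0.931
  hyperparameters (true -> bagged estimate (sd across bags)):
   component 1: sigma_f 2.50 -> 1.26 (0.16), ell 6.17 -> 1.72 (0.67), sigma_n 0.50 -> 0.58 (0.15)
   component 2: sigma_f 0.00 -> 0.76 (0.23), ell n.a. -> 0.27 (0.17), sigma_n 1.00 -> 0.39 (0.39)  [signal absent]
   component 3: sigma_f 1.50 -> 1.11 (0.09), ell 2.06 -> 0.55 (0.27), sigma_n 0.50 -> 0.40 (0.29)
  ancestral curves within +/-2 posterior sd: 95.8%
```

Reading this output: PCA correctly finds three components (`k_hat = 3`); the
ICA-rotated coefficient estimates track the true mixing coefficients with
|correlation| around 0.9; the bagged hyperparameter estimates recover the
right orders of magnitude from the estimated (not true) coefficients, with
the no-signal component correctly flagged by its implausibly small
length-scale; and 95.8% of true ancestral curve values lie inside the
reconstructed two-standard-deviation phylogenetic band, close to the nominal
95%.

The stages compose individually as well:

```r
tree <- rescale_tree(random_tree(128, seed = 1), 8.22)
sim  <- synthesize_dataset(tree, default_basis(1024),
                           default_gammas(8.22), seed = 1)
sep  <- ipca(sim$tips)                       # basis + coefficients from tips
bag  <- bagged_mle(sep$coeffs[1, ], tree)    # hyperparameters, component 1
post <- reconstruct_node(sep, lapply(1:3, function(i)
          bagged_mle(sep$coeffs[i, ], tree)$gamma_hat),
          tree, "node129")                   # posterior curve at the root
```

A command-line workbench wrapping these stages (subcommands `simulate`,
`decompose`, `fit`, `reconstruct`, `autocov`, `reproduce`; Newick, CSV and
JSON formats) is installed at `system.file("cli/fvgp.R", package = "pgpr")`.

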