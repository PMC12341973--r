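# bcrnn — Bayesian chemical reaction neural networks

`bcrnn` discovers mass-action reaction networks from time-resolved
species-concentration data and quantifies the uncertainty of everything
it learns. It is aimed at systems biology / quantitative systems
pharmacology settings where the species are measurable but the reaction
wiring and rate constants are unknown or incomplete.

## The model

A mass-action network evolves as

    dY_i/dt = sum_j (nu_p[j,i] - nu_r[j,i]) * r_j,
    r_j     = exp( ln k_j + sum_i nu_r[j,i] * ln C_i )

The chemical reaction neural network (CRNN) is this rate law written as
a one-hidden-layer network on log concentrations: input weights are
reaction orders `nu_r`, biases are log rate constants `ln k`, output
weights are net stoichiometric coefficients. A trained CRNN *is* a
reaction network. `bcrnn()` integrates the CRNN as a neural ODE from
each experiment's initial condition and trains the weights with
preconditioned stochastic gradient Langevin dynamics (pSGLD):

    V <- beta V + (1 - beta) g^2
    G <- 1 / (lambda + sqrt(V))
    theta <- theta - eps_t * g * G + N(0, eps_t * G) / n

Iterates collected after the validation loss stagnates form a posterior
over reaction networks, from which the package derives reactant
recovery probabilities `p_ij`, the score metric
`score_ij = p_ij * sum_w_ij / max_i(sum_w_ij)`, rate-constant
posteriors, percent deviations from a known truth, and
posterior-predictive trajectory fans.

## Worked example

Five species A–E, four reactions (`2A -> B` at 0.1, `A -> C` at 0.2,
`C -> D` at 0.13, `B + D -> E` at 0.3), 30 simulated experiments with
random initial A and B:

```r
library(bcrnn)

coll <- generate_case1(n_datasets = 30, noise_fraction = 0, seed = 11)
fit  <- bcrnn(coll, control = crnn_control(
  max_epochs = 200000, min_burn_in = 170000, detect_window = 1000,
  patience_stop = 3000, val_every = 5, noise_n = 90, tied = TRUE,
  seed = 7))
summary(fit)
```

```
Posterior summary (1000 samples, sampling from epoch 170173)

Reactant score metric (species x reactions):
     R1    R2    R3    R4
A 1.000 0.013 0.012 1.000
B 0.002 0.004 1.000 0.002
C 0.002 1.000 0.006 0.001
D 0.010 0.012 0.995 0.001
E 0.004 0.005 0.018 0.001

Rate-constant posteriors:
 reaction  mean       sd  q2.5 q97.5
       R1 0.179 0.002700 0.175 0.184
       R2 0.141 0.000869 0.139 0.142
       R3 0.311 0.003510 0.306 0.319
       R4 0.201 0.000928 0.200 0.203

Percent deviation from true rates (per true reaction):
 reaction hidden k_true mean_pct sd_pct
        1      1   0.10   79.100  2.700
        2      4   0.20    0.632  0.451
        3      2   0.13    8.480  0.669
        4      3   0.30    3.760  1.170
```

Reading the score matrix column-wise: reaction R1 has reactant A (the
dimerization `2A -> B`), R2 has C (`C -> D`), R3 has B and D
(`B + D -> E`), R4 has A (`A -> C`) — the four true reactant sets, each
with the top score in its column. The matched rate constants for three
of the four reactions sit within a few percent of the truth with
credible intervals attached; the dimerization rate lands on a nearby
local optimum about 80% high (its order compensates), the one known
hard spot of this landscape — see the limitations section of the
methods vignette.

`predict(fit, y0, times)` returns a 500-draw posterior-predictive fan,
`coef(fit)` the posterior-mean network, `system_from_crnn(coef(fit))`
the same object as a readable reaction system, and `plot(fit)` the
training/validation loss trace.

Two purely data-driven baselines ship for extrapolation comparisons
(`train_dense_node()`, an unconstrained 2x50-tanh neural ODE, and
`train_lstm()`, a 2x200 LSTM): trained on `t <= 30` and asked to
predict 30–40 s, they fail badly where the mechanism-constrained CRNN
stays accurate (`extrapolation_experiment()`).

A thin command-line wrapper over the same functions lives at
`inst/scripts/bcrnn.R` (subcommands `simulate`, `train`, `analyze`,
`baseline`, `report`; every run directory carries a manifest with
content hashes).

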