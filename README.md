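# hybridlr

Hybrid logistic regression via Shapley interaction screening.

## The problem

In low-dimensional biomedical settings (p < n) random forests often beat a
plain logistic regression — not because the logistic *family* is wrong, but
because the forest silently performs model building: its splits encode
interactions and threshold effects that a main-effects logistic model was
never offered. `hybridlr` implements a hybrid statistical–machine-learning
procedure that closes this gap while keeping the statistical model's
interpretability:

1. fit a random forest to the training data;
2. compute per-sample **pairwise Shapley interaction values** of the forest,
   `Φ[i, j, k]`, under the interventional value function
   `v(S) = E_b[f(x_S, b_{\bar S})]`;
3. score every unordered pair globally by
   `score(j, k) = Σ_i |Φ[i,j,k]| + |Φ[i,k,j]|`, rank, and select the top
   pairs;
4. append the selected products `x_j · x_k` as new design-matrix columns to
   **both** the train and test splits (the ranking never sees test rows);
5. refit an L2 logistic regression on the augmented design and report
   coefficients, odds ratios `exp(β)`, Wald p-values and held-out
   discrimination (C-statistic / AUROC).

When the forest really is closer to the true model the appended terms lift
the logistic model toward forest-level AUROC; when it is not, the appended
coefficients come out non-significant and the procedure "protects the null
hypothesis".

The package also ships the simulation data-generating processes used to
characterise when each model family wins (a linear-logit DGP, an
interval-membership DGP, a four-predictor DGP with a β-scaled product
interaction, and a two-locus pure-epistasis genotype model), a brute-force
coalition-enumeration Shapley oracle, a fast exact tree-path interaction
explainer, and evaluation machinery (stratified CV, AUROC, bootstrap CIs,
Savitzky–Golay-smoothed β sweeps).

## Worked example: rescuing logistic regression under epistasis

Two causal loci act through a pure XOR penetrance on carrier status (zero
marginal effects), buried among 18 noise loci, with a 10% label flip:

```r
library(hybridlr)

train <- gen_epistasis_dgp(2000, n_noise_loci = 18,
                           heritability_noise = 0.1, seed = 1)
test  <- gen_epistasis_dgp(2000, n_noise_loci = 18,
                           heritability_noise = 0.1, seed = 1001)

h <- fit_hybrid(train, test, k = 1, seed = 1)
h
#> <hybrid_result> 1 interaction term(s) appended (top_k)
#>   pairs: snp1 x snp2
#>   test scores:
#>                 auroc accuracy
#> logistic      0.5320   0.5140
#> hybrid        0.8975   0.8985
#> random_forest 0.8945   0.8690
```

The plain logistic regression is at chance (AUROC 0.53), the forest reaches
0.89, and the hybrid — logistic regression plus the single product term the
forest's interaction values point to — matches the forest (0.90) while
keeping an interpretable, strongly significant odds ratio for the appended
term:

```r
subset(h$coefficients, term == "snp1_x_snp2")
#>           term coefficient odds_ratio std_error   p_value
#> 22 snp1_x_snp2       -5.95     0.0026      0.24 1.52e-135
```

The forest's own global ranking puts `snp1 x snp2` at score 47.4, more
than twenty times the best noise pair (2.1) — the causal interaction is
unambiguous. Numbers above are what the code prints for these seeds.

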