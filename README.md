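# pltreg — partially linear tree-based regression

`pltreg` discovers outcome-associated subgroups defined by joint patterns
of many categorical explanatory variables — for example copy-number
alteration states across cytobands, with respect to a driver-mutation
status — **while adjusting for confounders** such as cohort or ancestry.
Classical recursive partitioning has no clean way to hold a confounder
out of the splits; `pltreg` fits the semi-parametric model

    logit P(Y = 1 | X, Z) = X'θ + β' F(T(Z))

in which the confounders X act linearly on the log-odds scale and the
explanatory variables Z enter only through a partition tree T, whose
leaf-membership indicators F(T(Z)) carry per-leaf intercepts β. The
package is aimed at biostatisticians and genomic epidemiologists working
with a binary outcome, a handful of confounders, and tens to hundreds of
binary/categorical features.

The procedure has four stages:

1. **Iterative fit** — alternate tree growth (deviance splits with the
   confounder contribution X'θ as a GLM offset), joint leaf-coefficient
   refits, and θ refits until θ stabilizes, producing a maximal tree.
2. **Nested subtree sequence** — forward construction of
   T₁ ⊂ T₂ ⊂ … ⊂ T_r, each step re-opening the frontier node whose
   jointly refitted model explains the most deviance.
3. **Selection** — choose the tree size by BIC
   (2L − δ·log N, δ = dim(θ) + j; argmax), AIC (2L − 2δ), or K-fold
   cross-validation of the whole pipeline.
4. **Test** — generalized likelihood ratio Λ = 2L(H₁) − 2L(H₀) against
   the confounder-only null, with a scaled chi-squared null law
   mΛ ~ χ²(b) whose constants are moment-matched from a conditional
   parametric bootstrap.

Simulation generators for three benchmark designs (a null model, a 4-leaf
interaction tree with noise variables, and a 6-leaf tree with
latent-factor-dependent predictors), a replicate-level experiment
harness, and a command-line interface (`inst/cli/pltr-cli.R`) are
included. See the vignette `vignettes/pltr-methodology.Rmd` for the full
methodology and design choices.

## A worked example

```r
library(pltreg)

# data from the 4-leaf benchmark design: confounder G1, informative
# G2-G4, ten noise variables G5-G14, n = 2000
d <- generate_scenario(2, n = 2000, seed = 1)

fit <- fit_pltr(d$y, d$X, d$Z)        # stage 1
sq  <- build_sequence(d$y, d$X, fit$tree, d$Z, r = 10)   # stage 2
sel <- select_by_criterion(sq, "bic") # stage 3
tst <- pltr_test(d$y, d$X, d$Z, sel, B = 100, seed = 1)  # stage 4

fit$theta
#>        G1
#> 0.8286789
sel$selected_j
#> [1] 5
split_variables(sel$selected_tree)
#> [1] "G2" "G3" "G4"
tst
#> Scaled chi-squared likelihood-ratio test
#>   Lambda = 167.9503, m = 1.7912, b = 30.5837 (B = 100)
#>   p-value: < 2.2e-16
```

The fitted confounder effect (0.83 on the log-odds scale) recovers the
generating θ = log 2 ≈ 0.69 up to sampling noise; BIC keeps a five-leaf
tree built only from the informative variables G2–G4, and the calibrated
test rejects the confounder-only null decisively, as it should under this
generating model. On null data (`generate_scenario(1, ...)`) the same
pipeline typically keeps the root tree and reports p = 1.

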