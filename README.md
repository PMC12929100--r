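# mmcalib

Multimodal attention-fusion classifiers with domain-aware probability
calibration, at desk scale.

## The problem

Diagnostic classifiers built on heterogeneous patient data — an imaging
(radiomics) feature block, a molecular (omics/clinical) feature block —
face three coupled problems: the informative interactions live *across*
modalities, the clinically critical classes are rare (class imbalance
ratios ρ = max_k N_k / min_k N_k of 5–10 are routine), and the raw softmax
confidences of a discriminative model are not trustworthy probabilities.
`mmcalib` is a compact, fully reproducible laboratory for studying this
pipeline end to end:

1. **Synthetic multimodal generator** with known ground truth: K-class
   labels with exact (largest-remainder) imbalance, Gaussian
   class-conditional modalities with controllable separation and a shared
   latent coupling factor, label noise through a row-stochastic transition
   matrix η (`Pr(obs = k | true = l) = η_lk`), missing-completely-at-random
   entries, and an *interaction label* mode where the label is the sign
   product of coordinates from two modalities — unlearnable by any additive
   single-modality model.
2. **Attention-fusion encoder**: one token per modality via a
   modality-specific embedding `h⁽ᵐ⁾ = φ_m(x⁽ᵐ⁾)`, a learnable positional
   encoding, L transformer layers (multi-head self-attention + feed-forward,
   each wrapped as `LayerNorm(x + sublayer(x))`), explicit pairwise
   cross-modality attention
   `C(i→j) = softmax(H⁽ⁱ⁾W_Q (H⁽ʲ⁾W_K)ᵀ / √d_k) H⁽ʲ⁾W_V`,
   additive fusion `H_fused = H^L + Σ_{i≠j} C(i→j)`, mean pooling and a
   linear head. Forward and analytic reverse-mode gradients are implemented
   in vectorized R and verified against finite differences.
3. **Imbalance-aware training**: weighted cross-entropy with
   `w_k = N/(K·N_k)`, minibatch Adam with decoupled weight decay, early
   stopping on validation loss.
4. **Monte-Carlo-dropout uncertainty**: dropout active at inference,
   per-sample predictive mean and per-class variance over stochastic
   passes; the scalar `u = mean_k Var_passes(p_k)` feeds the calibration.
5. **Three-stage recalibration** fit on the validation split only:
   class-conditioned temperature scaling `z_k / T_k` (NLL-optimal, global
   or per-class), uncertainty modulation `z̃ = z_T / (1 + γ_u·u)`
   (flattens uncertain predictions, preserves the arg-max), and smoothed
   prior injection `ẑ_k = z̃_k + λ·log(π̃_k/(1−π̃_k))` with
   `π̃ = β·π + (1−β)·π̂`.
6. **Evaluation**: accuracy, macro recall/F1/one-vs-rest AUC, NLL, Brier,
   expected calibration error (15 equal-width confidence bins), reliability
   diagrams, factorial component ablations, and paired t / exact Wilcoxon
   significance tests.

Everything is a tibble in, tibble out; results compose with the pipe, have
`tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

```r
library(mmcalib)

spec <- mm_spec(1000, class_proportions = c(0.85, 0.15),
                modality_dims = c(imaging = 8, molecular = 6),
                class_separation = 2, missing_rate = 0.05,
                label_noise = matrix(c(0.97, 0.03, 0.05, 0.95), 2, byrow = TRUE),
                seed = 42)
bundle <- simulate_multimodal(spec)
bundle
#> <mm_bundle> 1000 samples, 2 classes, 2 modalities
#>   class counts: 839, 161  (rho = 5.211 )
#>   splits: test=200, train=600, val=200

fit <- fit_encoder(bundle, seed = 42)
glance(fit)
#> # A tibble: 1 × 5
#>   n_params epochs_run best_epoch best_val_loss final_train_loss
#>      <int>      <int>      <int>         <dbl>            <dbl>
#> 1     5666         18          8         0.363            0.167
```

The observed class counts differ from the 850/150 apportionment because the
5%/3% label noise moves some labels across classes. Now estimate per-sample
uncertainty, fit the calibration on the validation split, and apply it to
the held-out test logits:

```r
imputed <- impute_missing(bundle)
val  <- imputed$data[imputed$data$split == "val", ]
test <- imputed$data[imputed$data$split == "test", ]

z_val <- as.matrix(predict(fit, val,  type = "logit")[, -1])
z_te  <- as.matrix(predict(fit, test, type = "logit")[, -1])
u_val <- batch_uncertainty(fit, val,  n_passes = 30, seed = 42)$u
u_te  <- batch_uncertainty(fit, test, n_passes = 30, seed = 42)$u

cal <- fit_calibration(z_val, val$observed_label, u = u_val,
                       train_class_counts = fit$class_counts,
                       prior = c(0.9, 0.1), beta = 0.5)
cal
#> <mm_calibration> T = 0.838, 1.377
#>   gamma_u = 0  lambda_prior = 0.5  beta = 0.5
#>   val NLL: uncalibrated=0.35437, temperature=0.34036, uncertainty=0.34036, prior=0.26106

out <- calibrate_pipeline(z_te, cal, u = u_te)
classification_metrics(predict_probs(z_te)[, 1:2], test$observed_label)
#> <mm_eval> 200 samples
#>   accuracy 0.8350  macro recall 0.8132  macro F1 0.7492  macro AUC 0.8876
#>   NLL 0.3778  Brier 0.2365  ECE 0.0511  MCE 0.1689
classification_metrics(out$probs[, 1:2], test$observed_label)
#> <mm_eval> 200 samples
#>   accuracy 0.9200  macro recall 0.7879  macro F1 0.8287  macro AUC 0.8977
#>   NLL 0.2479  Brier 0.1328  ECE 0.0378  MCE 0.3085
```

The temperature vector is fitted per class (here the minority class is
cooled, T₂ ≈ 1.38); the validation NLL falls at each pipeline stage; and on
the held-out test split the calibrated probabilities have substantially
lower NLL (0.38 → 0.25), Brier (0.24 → 0.13) and expected calibration
error, while the prior injection also lifts accuracy. `plot_reliability()`,
`autoplot(fit)` and `ablation_run()` provide the corresponding diagnostics.

A command-line pipeline (`simulate`/`train`/`predict`/`calibrate`/
`evaluate`/`ablate`) is available through `mm_cli()` or the installed
`inst/cli/mmcalib` script, driven by a single JSON config with one global
seed.

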