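# phytovolt

Plants respond electrically to chemical stress. When soil is salted (NaCl),
acidified (a dilute H₂SO₄ surrogate for acid rain) or the air is loaded with
ozone (O₃), the extracellularly recorded membrane-potential response — a slow,
minutes-to-hours drift of a few millivolts sampled at 10 Hz — carries a
stimulus-specific shape. `phytovolt` turns such whole-duration post-stimulus
recordings into a three-class chemical classifier, so a plant wired with a
pair of stem electrodes can act as a living environmental biosensor.

The package is for electrophysiologists and biosensor engineers who have
labeled single-channel recordings (or want to prototype against simulated
ones) and need a transparent, fully inspectable classification pipeline
rather than a black box.

## Method

1. **Curve-fit coefficients as features.** Each series is mapped onto
   normalized time x ∈ [0, 1] and fitted with four whole-series model
   families:
   - polynomial ŷ = Σᵢ Pᵢ xⁿ⁺¹⁻ⁱ (degree n = 1…9, at most 10 coefficients),
   - sum of Gaussians ŷ = Σᵢ aᵢ exp(−((x−bᵢ)/cᵢ)²) (1–4 peaks),
   - truncated Fourier series ŷ = a₀ + Σᵢ aᵢ cos(iωx) + bᵢ sin(iωx)
     (1–4 harmonics, ω free),
   - exponentials ŷ = a·e^(bx) (+ c·e^(dx)) (1–2 terms).

   The fitted coefficient vector of one (family, order) cell — always taken
   whole, never feature-selected — is the feature vector of the series.
   Fit quality is screened by R² = 1 − SSres/SStot (negative when the model
   is worse than the mean line).
2. **Five binary discriminants**, implemented from first principles: LDA
   (pooled covariance, explicit linear form y = wᵀf + b), QDA (per-class
   covariance), diaglinear/diagquadratic (naive-Bayes variants, off-diagonal
   covariances zeroed) and a Mahalanobis-distance rule
   rᵢ = (x−mᵢ)ᵀ Σᵢ⁻¹ (x−mᵢ) (smaller distance wins, no priors).
3. **Leave-one-out cross-validation** per class pair with per-fold z-score
   normalization (no leakage), scored by sensitivity, specificity, PPV, NPV
   and accuracy; the best (family, order, classifier) per pair is selected by
   accuracy with balance-aware tie-breaks.
4. **One-versus-one decision tree**: the three per-pair best models vote on a
   new series (majority of 3; a 1-1-1 cycle falls to the largest absolute
   margin), giving the three-class prediction for a prospective, held-out
   test.

Because the original recordings are not publicly deposited, the package
ships a seeded simulator of class-conditional post-stimulus signals
(polynomial trends, lognormal amplitude jitter, optional polarity reversal,
AR(1) noise) so the entire pipeline is testable end to end.

## Worked example

```r
library(phytovolt)

# three-class benchmark: 20 series per class, SNR 25, 10 Hz, 60-120 s
cfg     <- default_benchmark_config("high", n_per_class = 20, seed = 7)
signals <- simulate_signals(cfg)
label_counts(signals)
#>   stimulus     n
#> 1 H2SO4       20
#> 2 NaCl        20
#> 3 O3          20

# degree-9 polynomial coefficients -> QDA, one pair, LOOCV
fits  <- fit_sweep(signals, tibble::tibble(family = "polynomial", order = 9L))
feats <- build_features(fits[fits$stimulus %in% c("H2SO4", "O3"), ],
                        "polynomial", 9)
loocv(feats, kind = "qda", positive = "H2SO4")
#> <loocv_result> qda, H2SO4 positive, n = 40 folds
#>      tp    fp    tn    fn sensitivity specificity   ppv   npv accuracy
#> 1    20     0    20     0           1           1     1     1        1
```

Every series is predicted once while excluded from training; at this
signal-to-noise level all 40 folds are correct, so each confusion-matrix
measure is 1.

The full experiment — sweep, per-pair selection, one-versus-one tree,
prospective test on 4 held-out series per class — is one call:

```r
res <- run_experiment(cfg, out_dir = "run1",
                      grid = tibble::tibble(family = "polynomial",
                                            order = c(5L, 9L)),
                      classifiers = c("lda", "qda"),
                      heldout_per_class = 4, seed = 7)
res$best[, c("pair", "family", "order", "classifier", "accuracy")]
#>   pair          family     order classifier accuracy
#> 1 H2SO4 vs O3   polynomial     5 lda               1
#> 2 NaCl vs H2SO4 polynomial     5 lda               1
#> 3 NaCl vs O3    polynomial     5 lda               1
res$report
#>   stimulus n_heldout n_correct accuracy
#> 1 H2SO4            4         4        1
#> 2 NaCl             4         4        1
#> 3 O3               4         4        1
```

(`select_best` prefers the lower order and the simpler classifier on ties,
hence degree 5 + LDA here.) `run1/` holds `sweep.csv`, `best.json`,
`tree.json`, `report.csv` and a `log.txt` recording every setting and seed.
A thin command-line wrapper lives at `inst/cli/phytovolt.R`
(`Rscript phytovolt.R run-all --separation high --seed 7 --out run1`).

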