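# dttl — translation transfer learning for imbalanced cross-domain image classification

`dttl` is an R package for a hard but common situation in medical image
analysis: a labelled *source* cohort (say, a large pneumonia-screening
archive) and an unlabelled *target* cohort from a different device or site,
where the clinically relevant class is badly under-represented in both.
Plain transfer fails twice over — the *domain shift* (modelled here as a
global intensity/contrast change) invalidates the source-trained model, and
the *class imbalance* biases whatever survives towards the majority class.

The package implements a three-stage adaptation pipeline:

1. **Cross-domain discriminability adaptation (CDA).** Feature generator
   *F*, classifier *C* and domain discriminator *D* trained on the
   adversarial domain-invariant feature-learning loss
   `E_s log D(F(x)) + E_t log(1 − D(F(x)))` (min over F, max over D)
   together with the synthetic discriminability loss
   `−E_s y log C(F(x)) − λ E_t C(F(x)) log C(F(x))`
   (source cross-entropy + λ × target prediction entropy). The target is
   then pseudo-labelled by `argmax C(F(x))` and partitioned into
   pseudo-majority / pseudo-minority.
2. **Cross-domain minority translation (CMT).** A cycle GAN
   (`G: X_maj^s → X_min^t`, `G′: X_maj^t → X_min^s`, discriminators `D_t`,
   `D_s`) trained on `L_GAN + λ_DT L_DT + λ_MCC L_MCC + λ_IDE L_IDE`,
   then `X_gen^t = G(X_maj^s)` synthesises one target-minority candidate
   per source-majority image.
3. **Balanced target learning (BTL).** Candidates are scored with the
   minority probability `C(F(·))`; scores above `p_max` are discarded, the
   rest kept in descending order up to `⌊s·|X_min^t|⌋`. The balanced set
   `T′ = X_maj^t ∪ {X_min^t ∪ X_selected^t}` fine-tunes *F* and *C* by
   cross-entropy.

Evaluation is ROC/AUC (Mann–Whitney concordance; minority = positive class)
plus per-class recall on a stratified held-out 20% of the target whose
hidden labels never touch training. A seeded synthetic-cohort generator
(textured backgrounds, disc "lesions", global contrast/brightness shift,
0.25:1 imbalance) makes the whole pipeline testable end-to-end on one CPU,
and an ablation harness reruns it without the CDA or CMT stage.

## Worked example

```r
library(dttl)

cfg <- run_config(seed = 4)          # default synthetic cohort: 32x32,
                                     # 400 maj / 100 min per domain,
                                     # contrast 1.4, brightness 0.15
report <- run_dttl(cfg, out_dir = "run4")
report
#> <dttl_run_report> seed 4, ablation: none
#>   held-out AUC 0.9912 (n = 100), recall maj/min 0.912/0.950
#>   synthesized 400, selected 0

baseline <- run_source_only(cfg)
baseline
#> <dttl_run_report> seed 4, ablation: source_only
#>   held-out AUC 0.9681 (n = 100), recall maj/min 0.237/1.000
#>   synthesized 0, selected 0
```

The held-out AUC is the probability that a random lesion-bearing target
image outscores a random lesion-free one. The source-only baseline ranks
respectably (the intensity shift preserves much of the ordering) but its
decision threshold collapses — majority recall 0.24, i.e. it calls most of
the brighter target domain minority — while the adapted model keeps both
recalls high and a better AUC. All 400 source-majority images were
translated into synthetic minority candidates; on this seed every candidate
scored above the confidence threshold `p_max` (too far from the class
boundary to be informative), so none were retained — the selection rule
doing its job. `run4/` contains `metrics.json`,
`roc.csv`, the per-epoch `losses.csv`, the pseudo-partition and balanced-set
manifests, and a plain-JSON model checkpoint.

Cohorts can also be written to and read from disk as PNG trees
(`write_cohort()`, `load_image_dataset()`; layout `source/maj`,
`source/min`, `target/unlabeled` + `target_manifest.csv`), and a thin CLI
wraps the same functions:

```sh
Rscript inst/cli/dttl.R synth --out cohort/ --seed 1
Rscript inst/cli/dttl.R run --data cohort/ --out results/ --seed 1
Rscript inst/cli/dttl.R ablate --disable cmt --out results_nocmt/ --seed 1
```

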