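---
title: "Adapting imbalanced image classifiers across domains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapting imbalanced image classifiers across domains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dttl)
```

## The problem

A diagnostic image classifier trained on one labelled cohort (the *source*)
usually degrades on a second, unlabelled cohort (the *target*) for two
compounding reasons: a *domain shift* — here modelled as a global
intensity/contrast change such as arises from different acquisition devices —
and *class imbalance*, where the clinically relevant class (the minority,
e.g. pneumonia) is heavily under-represented. `dttl` implements a
transfer-learning pipeline that addresses both at once:

1. **CDA — cross-domain discriminability adaptation.** A feature generator
   $F$, classifier $C$ and domain discriminator $D$ are trained jointly. The
   domain-invariant feature-learning (DFL) loss is the adversarial
   domain-classification objective
   $$\mathcal{L}_{dfl} = \mathbb{E}_s \log D(F(x^s)) +
     \mathbb{E}_t \log\!\big(1 - D(F(x^t))\big),$$
   ascended by $D$ and descended by $F$. The synthetic discriminability (SD)
   loss adds the source cross-entropy and $\lambda$ times the target
   prediction entropy,
   $$\mathcal{L}_{sd} = -\mathbb{E}_s\, y \log C(F(x^s))
     - \lambda\, \mathbb{E}_t\, C(F(x^t)) \log C(F(x^t)),$$
   so minimisation sharpens target predictions while the adversary aligns the
   two feature distributions. Afterwards every target sample receives a
   pseudo-label $\hat{y} = \arg\max_k C(F(x))_k$ (ties to the majority
   class), partitioning the target into pseudo-majority and pseudo-minority.
2. **CMT — cross-domain minority translation.** A cycle GAN with generators
   $G$ (source-majority $\to$ target-minority) and $G'$ (target-majority
   $\to$ source-minority) plus discriminators $D_t$, $D_s$ whose real pools
   are the full target and source domains. The objective combines the
   adversarial loss with a direct-translation term
   $\mathbb{E}\lVert G(x) - x\rVert_1$ (evaluated on target-majority images
   by default; a config switch moves it to source-majority), a minority
   cycle-consistency term and an identity term:
   $\mathcal{L} = \mathcal{L}_{GAN} + \lambda_{DT}\mathcal{L}_{DT} +
   \lambda_{MCC}\mathcal{L}_{MCC} + \lambda_{IDE}\mathcal{L}_{IDE}$.
   Synthesis applies $G$ to every source-majority image.
3. **BTL — balanced target learning.** Each synthesised image is scored with
   the minority probability $C(F(\cdot))$; samples scoring above $p_{max}$
   are discarded as uninformatively far from the boundary, the rest are
   ranked by descending score and the top $\lfloor s \cdot
   |X^t_{min}|\rfloor$ retained. The balanced set $T' = X^t_{maj} \cup
   \{X^t_{min} \cup X^t_{selected}\}$ (selected samples labelled minority)
   then fine-tunes $F$ and $C$ by plain cross-entropy — balance is achieved
   by resampling, not by loss re-weighting.

The minority class is the positive class everywhere; evaluation is by
ROC/AUC (Mann–Whitney concordance, ties at one half) plus per-class recall
on a stratified 80:20 held-out target split whose hidden labels are used
only for splitting and scoring, never for training.

## The synthetic cohort generator

Real paired radiography cohorts are large, access-controlled downloads, so
the package ships a generator that emulates their structure at desk scale:

* background = a seeded, smoothed (circulant Gaussian kernel, $\sigma = 2$
  px), zero-mean Gaussian texture around base level 0.35 with amplitude
  0.08 — cheap, reproducible, and non-trivial for a classifier;
* minority images superimpose a hard disc "lesion" of amplitude
  `lesion_intensity` (default 0.4) and radius 3–5 px at a random interior
  position;
* the target domain applies `clip(1.4 x + 0.15 + noise, 0, 1)` — a global
  contrast/brightness shift with fresh Gaussian pixel noise (sd 0.05),
  the hypothesised shift mechanism between screening cohorts;
* default sizes: 32×32 grayscale, 400 majority / 100 minority per domain
  (imbalance ratio 0.25, matching the published pneumonia-screening ratio).

Two deliberate design choices deserve note. First, the pre-shift *latent*
image of the $j$-th sample of class $c$ is shared between the domains
(per-sample substreams keyed on class and index). This isolates the domain
shift as the only systematic difference between the cohorts: with the shift
at identity and zero noise, class-conditional means agree exactly, which the
test suite exploits as an invariant. Second, the texture field is zero-mean
per image, so image brightness is informative only through the lesion and
the shift. A fixed template-matching rule (maximum response to a zero-mean
disc kernel, `template_response()`) separates the classes with AUC 1.0 on
noise-free cohorts and serves as a training-free oracle.

What the generator does *not* emulate: anatomical structure, spatially
varying shifts, label noise in the source, multi-scale lesions, DICOM
artefacts. Passing tests on these cohorts therefore demonstrate the
pipeline's mechanics and its qualitative behaviour under a controlled
intensity shift — not clinical performance.

## Networks and optimisation

No deep-learning framework is assumed: all models are compact
fully-connected networks with hand-written backpropagation, trained by Adam
(weight decay 5e-4) — every forward/backward pass is a handful of BLAS
matrix products, so the whole pipeline runs in seconds per stage on one CPU.

* A fixed average-pooling front end (factor 4, parameter-free) feeds the
  feature generator and domain discriminator; pooling denoises and makes the
  desk-scale adversarial game far more stable without affecting the global
  intensity shift it must learn to remove.
* $F$: dense 64→64→32 with ReLU hidden units and tanh-bounded outputs
  (bounded features prevent the adversarial collapse where $F$ wins by
  exploding feature scale). $C$: 32→16→2 with softmax. $D$: 32→16→1 with
  ReLU and dropout 0.5, sigmoid output.
* Generators $G, G'$: residual maps `clip01(x + up(W2 tanh(W1 x + b1) + b2))`
  where the residual is emitted on a coarse 4-px block grid and upsampled —
  an encoder-decoder bottleneck that forces spatially coherent, lesion-scale
  edits rather than per-pixel noise (per-pixel residuals are available with
  `gen_grid = 1`). The output layer is zero-initialised, so an untrained
  generator is exactly the identity; the clip uses a straight-through
  subgradient. Image discriminators score the raw pixels through a 32-unit
  hidden layer (`disc_pool` optionally pools their input).
* Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ before every
  logarithm.

Adversarial stabilisation required three standard measures, each exposed in
`cda_config()`:

1. a smooth warm-up ramp of the adversarial gradient into $F$
   (`adv_weight`, default 0.5 at full ramp) — the classifier settles before
   alignment pressure peaks;
2. the $F$-step reads the discriminator *without* dropout, so the gradient
   that reaches the feature generator is not masked noise;
3. epoch-level Polyak averaging (`ema_decay = 0.9`) of $F$ and $C$: the
   returned model is the moving average, which damps the oscillation
   inherent to the min–max game. The same averaging is applied during
   balanced target learning.

The generator-side adversarial update uses the non-saturating form
$-\log D(G(x))$; the discriminator objective is the standard one above.
Training stops when the variation between consecutive 10-epoch means of the
monitored loss falls below `loss_tolerance` (5e-4) — after a 40-epoch floor,
because adversarial losses can transiently plateau in collapsed states — or
at `max_epochs`. The monitored quantity is the SD loss in CDA/BTL and the
weighted pixel-loss part (DT/MCC/IDE) in CMT, whose adversarial component
is intentionally excluded since it is non-monotone near equilibrium.

### Default hyperparameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `lambda` | 0.1 | ≥ 0 | entropy weight of the SD loss; small enough not to lock in a miscalibrated boundary |
| learning rate | 2e-4 (stage configs), 1e-3 for pipeline CDA/CMT | — | 2e-4 is the reference optimiser setting; the pipeline raises the adaptation stages to 1e-3 so they converge within desk-scale epoch budgets |
| batch size | 16 | samples/domain/step | reference mini-batch size |
| `adv_weight` | 0.5 (pipeline), 1 (config default) | ≥ 0 | full-ramp adversarial scale; 0.5 trades a slower alignment for stability |
| `ema_decay` | 0.9 | [0, 1) | ~10-epoch averaging window |
| λDT, λMCC, λIDE | 1, 10, 5 | ≥ 0 | cycle ≫ identity ≫ direct, the usual cycle-translation weighting |
| `p_max` | 0.95 | (0, 1] | discard synthesised samples the classifier already scores as confidently minority |
| `s` | 1.0 | > 0 | selection cap: roughly double the pseudo-minority pool |
| `pool` | 4 | pixels | average-pooling factor for classifier/domain-discriminator inputs |
| `gen_grid` | 4 | pixels | block size of the generators' coarse residual grid |
| epochs (pipeline) | 200 CDA / 60 CMT / 40 BTL | — | problem sizes chosen so a full run takes well under a minute on one CPU |
| `outer_iterations` | 1 | ≥ 1 | one pass of adapt→translate→select→train; the loop is exposed and pseudo-labels are recomputed each pass |

## Design decisions on genuinely open points

* **Balance weight values.** The reference description leaves $\lambda$ and
  the three translation weights unspecified; the defaults above are
  config-exposed so users can sweep them.
* **Direct-translation domain.** The DT loss is defined over
  target-majority images as printed, although its motivation ("output
  versus input instance") reads more naturally over source-majority; the
  `dt_on_source_majority` switch selects the alternative without changing
  the default.
* **Adversarial direction of the translation GAN.** The printed min/max
  assignment would make generators and discriminators cooperate;
  discriminators maximise and generators minimise here, the standard
  direction.
* **Discriminator real pools.** $D_t$ treats the *full* target domain as
  real (not just pseudo-minority), exactly per the adversarial-loss formula.
* **Selection order.** Candidates are ranked by descending minority score
  below $p_{max}$; ties break deterministically by pool index. The
  alternative (prefer scores near the boundary) is noted but not
  implemented, matching the selection formula.
* **Pseudo-label refresh.** With `outer_iterations > 1`, pseudo-labels are
  recomputed at each outer pass with the current (fine-tuned) model; the
  reference procedure does not say whether to refresh, so the recomputation
  is the documented interpretation.
* **"Adam with 5e-4".** Read as weight decay 5e-4 alongside learning rate
  2e-4; both are exposed.

## Degenerate inputs and numerical corners

Empty loss batches raise errors naming the offending side; an empty
pseudo-partition side skips translation for that pass (recorded in the run
report) rather than aborting the pipeline; a single-class balanced set
skips fine-tuning likewise. Ties in pseudo-labelling go to the majority
class. Selection uses `floor(s * n_min)` and caps at availability. AUC uses
mid-ranks, so tied scores receive exactly half credit, and the trapezoidal
area over the ROC points returned by `roc_curve()` reproduces the
concordance value to machine precision.

## Scale of the shipped experiments

The multi-seed experiment behind `scripts/acceptance.R` and the acceptance
tests uses the default cohort (500 images per domain, 32×32), five seeds for
the shifted-cohort comparison (full pipeline, both ablations, source-only
baseline) and three seeds for the no-shift sanity check; a full pipeline run
takes roughly a minute on one CPU. These sizes were chosen as the smallest at
which the seed-to-seed spread of held-out AUC (evaluated on 100 images) is
visibly smaller than the effects being compared; they are the package's
default experimental conditions, not a statement about the limits of the
method.

## Known limitations

* The desk-scale dense networks cannot represent spatial invariances a CNN
  would learn; named large backbones are accepted through the `arch`
  config in the sense of layer widths only, not as pretrained models.
* On cohorts where the source-trained model already ranks the target almost
  perfectly, the adaptation margin is necessarily within seed noise; the
  pipeline's guarantee in that regime is "no harm" (the no-shift sanity
  check), not improvement.
* Translation quality is limited: a residual dense generator learns a
  global intensity correction plus a diffuse minority pattern, not sharply
  localised lesions, so the confidence-based selection step is essential to
  keep only useful synthetic samples.
* Binary classes only; multi-class pseudo-labelling and translation are out
  of scope.
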