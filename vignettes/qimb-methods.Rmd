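---
title: "Reward-shaped Q-learning for imbalanced classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-shaped Q-learning for imbalanced classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qimb)
```

## The decision process

`qimb` treats a labelled `N x D` table as an episodic decision process. A
shuffled pass over the training data serves one sample per step; the agent's
action is a class label; the transition kernel is action-independent (the
next sample arrives whatever was predicted). Two mechanisms carry the
imbalance correction:

1. **Inverse-square-frequency reward.** Predicting class `a` for a sample of
   true class `l` earns `+lambda_l` if correct and `-lambda_l` if not, with
   `lambda_k = (1/N_k) / sum_i (1/N_i)^2`. The ratio law
   `lambda_j / lambda_i = N_i / N_j` means a 19:1 imbalance gives the
   minority class 19 times the reward magnitude: in expectation the optimal
   greedy policy becomes the *equal-prior* (maximum-likelihood) decision
   rule rather than the posterior-mode rule that collapses onto the
   majority. The normalisation `sum_k lambda_k / N_k = 1` holds by
   construction and is enforced to 1e-9 in the tests.

2. **Minority-termination.** An episode ends when a minority-class sample is
   misclassified. Because the `term` flag zeroes the bootstrap term of the
   learning target, a minority error also forfeits discounted future
   reward, giving the otherwise action-independent chain a genuine
   state–action coupling.

**Minority set for K > 2.** With more than two classes "the minority" is
ambiguous; the default rule takes every class whose count is strictly below
the maximum. Ties mean no strict minority, so termination never fires and
the rewards degenerate to uniform — the method gracefully reduces to
ordinary Q-learning classification on balanced data. An explicit set can be
supplied when domain knowledge says otherwise.

**Stream semantics.** When a pass is exhausted a fresh permutation is drawn
and iteration continues; episodes are truncations within a continuing
stream. Whether samples remaining after a termination are skipped or
re-encountered is not observable to the agent (transitions are
action-independent), so the continuing-stream reading was chosen for its
simplicity and for keeping per-epoch sample exposure uniform. Reward
weights are computed from the *training* split only and frozen into the
model; evaluation never re-derives them, so test prevalence cannot leak.

## Network and learning target

The dueling architecture is a shared fully-connected trunk (default two
hidden layers of 32 ReLU units) feeding a scalar value stream and a
length-K advantage stream (one hidden layer of 16 each):

```
Q(s, a) = V(s) + ( A(s, a) - m(s) ),   m(s) = sum_a softmax(A(s, .))_a A(s, a)
```

The aggregator subtracts a per-state *scalar* — the softmax-weighted mean of
the advantages. A scalar is the only choice consistent with the stated
property that the correction "does not change the relative rank" of the
advantages or the Q-values: subtracting a vector (e.g. the softmax itself)
would reorder actions. The constant-advantage case returns `V` in every
slot, and the greedy action under Q provably equals the greedy action under
A; both are tested against hand-evaluated values and random draws.

Training minimises the mean-squared error between `Q(s_t, a_t)` and the
double-Q target

```
y = r + (1 - term) * gamma * Q_target(s', argmax_a Q_online(s', a))
```

with gradients blocked through `y` (the target is a constant, as in
supervised regression). The plain-DQN ablation (`double = FALSE`) lets the
target network both select and evaluate, `y = r + (1-term) * gamma * max_a
Q_target(s', a)`. Forward, backward (including the softmax-weighted-mean
Jacobian `dm/dA_j = p_j (1 + A_j - m)`) and Adam are implemented directly in
vectorised R; the analytic gradients are verified against central finite
differences on both architectures in the test suite.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `total_steps` | 120,000 | environment steps (= gradient updates once the replay memory holds a batch); the documented full-scale budget |
| `epsilon_start/end` | 1 → 0.01 | linear annealing over the whole run |
| `gamma` | 0.1 | discount; transitions are action-independent, so long horizons carry little signal and the immediate classification reward dominates. Raising it to 0.5/0.9 was evaluated and improved nothing |
| `batch_size` | 64 | replay mini-batch |
| `memory_capacity` | 50,000 | FIFO replay buffer |
| `target_sync_interval` | 1,000 | hard target sync period |
| `learning_rate` | 1e-3 | Adam step size (Adam also absorbs the large reward scale that extreme imbalance induces, e.g. lambda ~ 250 at 5% prevalence) |

All randomness flows from one master seed split into named substreams
(initialisation, shuffling, exploration, replay sampling), so exploratory
draws never perturb the shuffle sequence and training is bit-reproducible.
Weight initialisation is fan-in/fan-out scaled uniform.

## What the synthetic generator emulates — and what it does not

The generator produces class-conditional Gaussian informative features with
shared spherical covariance, plus class-independent noise features, at
configurable prevalence. Two presets mirror the clinical regimes the method
targets:

- `covid_binary`: K = 2 at 5% prevalence (1 case : 19 controls), n = 5000,
  10 informative + 10 noise features, mean separation 2.5 SD. The
  separation was chosen so the task's achievable AUROC (~0.87–0.9) matches
  what strong tabular screeners reach on real emergency-department EHR data;
  the feature count is sized like a blood-test/vital-sign panel.
- `eicu_multiclass`: K = 5 with prevalences (0.336, 0.25, 0.18, 0.147,
  0.087), n = 6000, separation 3 SD — the 8.7%–33.6% prevalence span of a
  five-way acute-event diagnosis task.

Class counts are multinomial draws (resampled to guarantee two samples per
class), with an exact-count mode for deterministic tests. Because the
generating parameters are known, the Bayes-optimal labelling
`argmax_k pi_k N(x; mu_k, sigma^2 I)` is returned alongside, giving an
upper-bound oracle: zero separation pins best-achievable AUROC at 0.5, wide
separation pins the Bayes error near 0, and agreement with the truth is
monotone in separation.

What it deliberately does **not** emulate: real EHR feature semantics and
their correlation structure, missingness and imputation artefacts,
site-specific measurement shifts, or label noise. Passing the end-to-end
properties here shows the method does what its design intends on clean
imbalanced data of realistic difficulty — not that it will match any
particular clinical headline number.

## Problem sizes and empirical behaviour

The end-to-end checks train at a scale a laptop CPU handles in minutes:
20,000 steps on the binary preset and 30,000 on the multi-class preset
(medians over seeds 1–3), against an unweighted `nnet` baseline. Under
those conditions the dueling double-Q agent reaches median held-out
minority sensitivity 0.775 and G-mean 0.847 on the binary task with *no*
threshold adjustment (the unweighted baseline: 0.505 sensitivity), and on
the 5-class task its per-class sensitivity SD is less than half the
baseline's (0.033 vs 0.069) — the balanced-classification behaviour the
reward design aims for.

One documented full-scale finding does **not** reproduce at this scale: the
strict quality ordering DQN < DDQN < dueling among the RL variants. On
clean low-dimensional Gaussians all three variants learn essentially equally
well (median G within ~0.02), across discount factors 0.1–0.9. The
catastrophic specificity collapse of single-stream variants reported on real
high-dimensional EHR data appears to require a difficulty regime —
overlapping heterogeneous features, many more dimensions, far longer
training — that this generator intentionally does not fabricate. The
corresponding acceptance property is implemented faithfully and left to
fail rather than engineering the generator around it.

## Numerical and degenerate-case choices

- **F-measure at TP = 0**: precision is defined as 0 when no positive
  predictions exist, so F = 0 (the conservative limit of the geometric
  mean).
- **AUROC ties**: half credit — the midrank Mann–Whitney definition; exact
  agreement with all-pairs enumeration is asserted in tests.
- **Threshold adjustment** returns the *largest* observed-score threshold
  whose calibration sensitivity meets the target, and is fit on a
  calibration split (by default the training set), never on the test set.
- **Greedy ties** break toward the lowest class index, everywhere
  (selection, targets, prediction).
- **Equal class counts**: no minority, uniform rewards — supported, not an
  error.
- **Softmax** is computed with per-row max subtraction for overflow safety.

## Known limitations

- Pure-R training is vectorised but still ~1.5 ms per step; the documented
  120,000-step default takes a few minutes per model on one core.
- The SMOTE resampling hook delegates to an external backend and errors
  cleanly when none is installed; it is an adapter by design, and the
  package's own claims never depend on it.
- `nnet` baselines are single-hidden-layer; they are comparators, not a
  deep-learning benchmark suite.
- Multi-label samples, feature missingness and non-tabular inputs are out
  of scope.
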