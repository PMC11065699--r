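# qimb: deep Q-learning for classification under extreme class imbalance

Standard classifiers trained on heavily skewed data — one diseased patient
per twenty healthy controls, or rarer — tend to collapse onto the majority
class: overall accuracy looks fine while minority sensitivity is useless.
`qimb` addresses this by casting classification as a reinforcement-learning
problem and making the *reward*, rather than a differentiable loss, carry the
class-imbalance correction. It is aimed at tabular diagnostic tasks (e.g.
EHR-derived blood tests and vital signs) in both binary and multi-class
settings, but applies to any imbalanced tabular classification problem.

## The method

Classification becomes a finite Markov decision process: each sample's
feature vector is a state *s*, each candidate label an action *a*, and the
samples of a shuffled training batch are presented in order (the action does
not influence which sample comes next). Labelling a sample of true class *k*
earns a reward

    R(s, a, l) = +lambda_k  if a = l,   -lambda_k  otherwise,

with per-class magnitudes

    lambda_k = (1 / N_k) / sum_i (1 / N_i)^2,

so the reward magnitude is inversely proportional to class frequency
(`lambda_j / lambda_i = N_i / N_j`) and satisfies
`sum_k lambda_k / N_k = 1`. A training episode terminates when the agent
misclassifies a minority-class sample, coupling actions to future reward.

The Q-function is approximated by a dueling network — a shared trunk feeding
a scalar state-value stream V(s) and a vector advantage stream A(s, ·),
recombined as

    Q(s, a) = V(s) + ( A(s, a) - sum_a' softmax(A)_a' A(s, a') ),

i.e. the softmax-weighted mean of the advantages is subtracted so V and A
are identified without changing the advantage ranking. Training uses double
Q-learning on replayed transitions,

    y = r + (1 - term) * gamma * Q_target(s', argmax_a Q_online(s', a)),

with mean-squared-error loss, Adam, an epsilon-greedy policy annealed
linearly from 1 to 0.01, and a periodically synced target network. Setting
`architecture = "single_stream"` and/or `double = FALSE` reproduces the
DDQN and DQN ablations.

Evaluation follows the balanced-classification panel: sensitivity,
specificity, precision, the geometric-mean F-measure
`F = sqrt(sensitivity * precision)` and G-mean
`G = sqrt(sensitivity * specificity)`, AUROC with Hanley–McNeil confidence
intervals, sensitivity-targeted threshold adjustment, and one-vs-all
aggregation for multi-class tasks. Comparator baselines (a feed-forward
network via `nnet`, gradient boosting via `xgboost`, optional cost-sensitive
inverse-frequency weights) share the same score-matrix interface.

## Worked example

```r
library(qimb)

# binary screening task: 5% disease prevalence, 20 features, n = 5000,
# with an independently drawn held-out test set
sp <- generate_split(preset_config("covid_binary", seed = 1))

model <- fit_qimb(sp$train, cfg = train_config(total_steps = 20000, seed = 1))
base  <- fit_baseline(sp$train, baseline_spec(seed = 1))   # unweighted nnet

scores <- predict(model, sp$test)          # n x 2 softmax-of-Q scores
pred   <- predict(model, sp$test, type = "class")
cc     <- confusion(sp$test$labels, pred, positive_class = 1)
evaluate_binary(scores[, 2], sp$test$labels == 1)
```

With these settings the run above prints (your hardware will reproduce it
exactly — training is bit-reproducible from the seed):

```
  sensitivity specificity precision f_measure    g_mean     auroc auroc_lower
1   0.6842105   0.9354331 0.3457447 0.4863766 0.8000207 0.8666418   0.8197568
  auroc_upper threshold prevalence
1   0.9135268       0.5     0.0475
```

A minority sensitivity of 0.68 at specificity 0.93 *without any threshold
adjustment* — against 0.51 for the unweighted baseline on the same data
(seeds 2 and 3 give Q-imb sensitivities of 0.83 and 0.78; the median over
the three seeds is 0.775 with median G-mean 0.847). The multi-class preset
behaves analogously:

```r
spm <- generate_split(preset_config("eicu_multiclass", seed = 1))
m5  <- fit_qimb(spm$train, cfg = train_config(total_steps = 30000, seed = 1))
one_vs_all_report(spm$test$labels, predict(m5, spm$test))
```

which reports a mean one-vs-all sensitivity of 0.80 with a cross-class
standard deviation of 0.033 — under half the unweighted baseline's 0.069,
i.e. markedly more balanced performance across the five classes.

A thin command-line front end wraps the same functions:

```sh
inst/cli/qimb simulate --preset covid_binary --out train.csv --seed 1
inst/cli/qimb train    --data train.csv --out model.rds --steps 20000
inst/cli/qimb evaluate --model model.rds --data test.csv --out report.json \
                       --target-sensitivity 0.9 --calibration train.csv
```

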