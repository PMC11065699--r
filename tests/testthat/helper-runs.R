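# Trained-model fixtures shared across test files. Training is the dominant
# cost of the suite, so each study is computed once and memoised here.
#
# Study conditions: the generator presets at their default sizes
# (covid_binary n = 5000 at 5% prevalence; eicu_multiclass n = 6000 with
# prevalences 0.336..0.087), evaluation on an independently drawn held-out
# split, greedy (argmax) predictions with no threshold adjustment, and
# medians over seeds 1..3.

.run_cache <- new.env(parent = emptyenv())

memoise_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}

binary_metrics <- function(model, test) {
  pred <- predict(model, test, type = "class")
  cc <- confusion(test$labels, pred, 1L)
  sens <- cc$TP / (cc$TP + cc$FN)
  spec <- cc$TN / (cc$TN + cc$FP)
  c(sensitivity = sens, specificity = spec, g_mean = g_mean(cc),
    f_measure = f_measure(cc))
}

covid_runs <- function() memoise_run("covid", function() {
  lapply(1:3, function(seed) {
    sp <- generate_split(preset_config("covid_binary", seed = seed))
    tc <- function(double) train_config(total_steps = 20000L, double = double, seed = seed)
    single <- qnetwork_spec(sp$train$D, sp$train$K, architecture = "single_stream")
    list(
      qimb = binary_metrics(fit_qimb(sp$train, cfg = tc(TRUE)), sp$test),
      ddqn = binary_metrics(fit_qimb(sp$train, single, cfg = tc(TRUE)), sp$test),
      dqn = binary_metrics(fit_qimb(sp$train, single, cfg = tc(FALSE)), sp$test),
      baseline = binary_metrics(fit_baseline(sp$train, baseline_spec(seed = seed)), sp$test))
  })
})

eicu_runs <- function() memoise_run("eicu", function() {
  lapply(1:3, function(seed) {
    sp <- generate_split(preset_config("eicu_multiclass", seed = seed))
    tc <- train_config(total_steps = 30000L, seed = seed)
    qr <- one_vs_all_report(sp$test$labels,
                            predict(fit_qimb(sp$train, cfg = tc), sp$test))
    br <- one_vs_all_report(sp$test$labels,
                            predict(fit_baseline(sp$train, baseline_spec(seed = seed)), sp$test))
    list(qimb = qr$aggregate, baseline = br$aggregate)
  })
})

med <- function(runs, model, metric) {
  stats::median(vapply(runs, function(r) r[[model]][[metric]], numeric(1)))
}
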