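#' Cost-sensitive class weights
#'
#' `uniform` gives every class weight 1. `inverse_frequency` sets
#' \eqn{w_k \propto 1/N_k}, normalised so the weights sum to K, so the
#' expected per-class contribution to the loss is equalised.
#'
#' @param class_counts positive integer vector.
#' @param mode `"uniform"` or `"inverse_frequency"`.
#' @export
#' @examples
#' class_weights(c(90, 10), "inverse_frequency")  # c(0.2, 1.8)
class_weights <- function(class_counts, mode = c("uniform", "inverse_frequency")) {
  mode <- match.arg(mode)
  check_counts(class_counts)
  K <- length(class_counts)
  if (mode == "uniform") return(rep(1, K))
  w <- 1 / as.double(class_counts)
  K * w / sum(w)
}

#' Baseline classifier specification
#'
#' @param model `"nnet"` (single-hidden-layer feed-forward network via the
#'   nnet package) or `"xgboost"` (gradient boosting adapter; requires the
#'   xgboost package).
#' @param hidden hidden layer width (nnet).
#' @param class_weight_mode `"uniform"` or `"inverse_frequency"`.
#' @param resampler `"none"`, or `"smote"` to delegate minority oversampling
#'   to an installed SMOTE backend before fitting.
#' @param smote_ratio target minority/majority size ratio in `(0, 1]` (the
#'   conventional 0.2 oversamples the minority to 20% of the majority).
#' @param epochs maximum optimisation iterations (nnet maxit / xgboost
#'   rounds).
#' @param decay L2 weight decay (nnet).
#' @param seed RNG seed.
#' @return object of class `baseline_spec`.
#' @export
baseline_spec <- function(model = c("nnet", "xgboost"), hidden = 32L,
                          class_weight_mode = c("uniform", "inverse_frequency"),
                          resampler = c("none", "smote"), smote_ratio = 0.2,
                          epochs = 200L, decay = 1e-4, seed = 1L) {
  model <- match.arg(model)
  class_weight_mode <- match.arg(class_weight_mode)
  resampler <- match.arg(resampler)
  if (resampler == "smote" && (smote_ratio <= 0 || smote_ratio > 1))
    stop("smote_ratio must lie in (0, 1]")
  structure(list(model = model, hidden = as.integer(hidden),
                 class_weight_mode = class_weight_mode, resampler = resampler,
                 smote_ratio = smote_ratio, epochs = as.integer(epochs),
                 decay = decay, seed = as.integer(seed)),
            class = "baseline_spec")
}

# adapter: delegate SMOTE to an installed backend; never re-implemented here
apply_resampler <- function(dataset, spec) {
  if (spec$resampler == "none") return(dataset)
  if (min(dataset$class_counts) < 2L)
    stop("SMOTE requires at least 2 samples in every minority class")
  if (!requireNamespace("smotefamily", quietly = TRUE))
    stop("resampler = 'smote' requires the 'smotefamily' package; ",
         "install it or use resampler = 'none'")
  if (dataset$K != 2L) stop("the SMOTE adapter currently supports binary tasks only")
  n_min <- min(dataset$class_counts)
  n_maj <- max(dataset$class_counts)
  dup <- max(0L, as.integer(round(spec$smote_ratio * n_maj / n_min)) - 1L)
  res <- smotefamily::SMOTE(as.data.frame(dataset$features),
                            dataset$labels, dup_size = dup)
  labeled_dataset(as.matrix(res$data[, seq_len(dataset$D)]),
                  as.integer(res$data$class), K = dataset$K,
                  label_map = dataset$label_map)
}

#' Fit a comparator classifier
#'
#' The feed-forward baseline is a `nnet` single-hidden-layer softmax network;
#' cost-sensitive training applies per-sample case weights from
#' [class_weights()]. The gradient-boosting comparator is an adapter around
#' `xgboost`. Both emit `n x K` probability score matrices through
#' [predict.baseline_model()], interchangeable with [qimb_model][fit_qimb]
#' scores for the metrics module.
#'
#' @param dataset a [labeled_dataset] (training split).
#' @param spec a [baseline_spec].
#' @param standardize z-scale features on training statistics.
#' @return object of class `baseline_model`.
#' @export
fit_baseline <- function(dataset, spec = baseline_spec(), standardize = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(spec, "baseline_spec"))
  dataset <- apply_resampler(dataset, spec)
  sc <- NULL
  x <- dataset$features
  if (standardize) {
    sc <- zscale(x)
    x <- sc$x
  }
  w <- class_weights(dataset$class_counts, spec$class_weight_mode)
  case_w <- w[dataset$labels + 1L]
  set.seed(spec$seed)
  if (spec$model == "nnet") {
    y <- nnet::class.ind(factor(dataset$labels, levels = seq_len(dataset$K) - 1L))
    fit <- nnet::nnet(x, y, size = spec$hidden, softmax = TRUE,
                      weights = case_w, decay = spec$decay,
                      maxit = spec$epochs, MaxNWts = 100000, trace = FALSE)
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("model = 'xgboost' requires the 'xgboost' package")
    dtrain <- xgboost::xgb.DMatrix(x, label = dataset$labels, weight = case_w)
    params <- if (dataset$K == 2L)
      list(objective = "binary:logistic", eval_metric = "logloss")
    else
      list(objective = "multi:softprob", num_class = dataset$K,
           eval_metric = "mlogloss")
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = min(spec$epochs, 100L), verbose = 0)
  }
  structure(list(fit = fit, spec = spec, K = dataset$K,
                 label_map = dataset$label_map,
                 center = if (standardize) sc$center else NULL,
                 scale = if (standardize) sc$scale else NULL),
            class = "baseline_model")
}

#' @rdname fit_baseline
#' @param object a `baseline_model`.
#' @param newdata feature matrix or [labeled_dataset].
#' @param type `"score"` (n x K probabilities) or `"class"` (0-based labels).
#' @param ... unused.
#' @export
predict.baseline_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_dataset")) newdata$features else as.matrix(newdata)
  if (!is.null(object$center))
    x <- zscale(x, object$center, object$scale)$x
  if (object$spec$model == "nnet") {
    p <- stats::predict(object$fit, x)
  } else {
    raw <- stats::predict(object$fit, xgboost::xgb.DMatrix(x))
    p <- if (object$K == 2L) cbind(1 - raw, raw)
         else matrix(raw, ncol = object$K, byrow = TRUE)
  }
  if (type == "class") max.col(p, ties.method = "first") - 1L else unname(p)
}
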