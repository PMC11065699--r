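#' Inverse-square-frequency reward weights
#'
#' The per-class reward magnitude is
#' \deqn{\lambda_k = \frac{1/N_k}{\sum_i |1/N_i|^2},}
#' the inverse class count normalised by the sum of inverse squared counts.
#' Rarer classes earn proportionally larger rewards
#' (\eqn{\lambda_j/\lambda_i = N_i/N_j}), and the weights satisfy
#' \eqn{\sum_k \lambda_k / N_k = 1}: one full pass over a balanced-by-reward
#' dataset yields unit total normalised reward whatever the imbalance.
#' The absolute value in the denominator is kept as defined although it is
#' inert for the positive counts required here.
#'
#' @param class_counts positive integer vector of per-class sample counts.
#' @return numeric vector of reward magnitudes \eqn{\lambda_k}.
#' @export
#' @examples
#' compute_reward_weights(c(500, 500))  # balanced -> equal weights
#' compute_reward_weights(c(90, 10))    # 9x larger reward for the rare class
compute_reward_weights <- function(class_counts) {
  check_counts(class_counts)
  inv <- 1 / as.double(class_counts)
  inv / sum(abs(inv)^2)
}

check_counts <- function(class_counts) {
  if (length(class_counts) < 1L) stop("need at least one class")
  bad <- which(!is.finite(class_counts) | class_counts < 1)
  if (length(bad))
    stop("class count must be a positive integer; offending class index(es): ",
         paste(bad - 1L, collapse = ", "))
  invisible(class_counts)
}

#' Identify the minority class set
#'
#' The termination rule needs a set of "minority" classes. The default rule
#' treats every class whose count is strictly below the maximum count as
#' minority; with all counts equal no class is minority and termination never
#' fires. An explicit set overrides the rule.
#'
#' @param class_counts positive integer vector.
#' @param explicit optional integer vector of class indices (0-based) to use
#'   verbatim instead of the rule.
#' @return integer vector of 0-based minority class indices (possibly empty).
#' @export
identify_minority_set <- function(class_counts, explicit = NULL) {
  check_counts(class_counts)
  if (!is.null(explicit)) {
    explicit <- as.integer(explicit)
    if (any(explicit < 0L | explicit >= length(class_counts)))
      stop("explicit minority index out of range")
    return(sort(unique(explicit)))
  }
  which(class_counts < max(class_counts)) - 1L
}

#' Reward scheme: per-class reward magnitudes plus the minority set
#'
#' Frozen from the *training* split's class counts; evaluation never
#' re-derives it, so test-set prevalence cannot leak into the reward.
#'
#' @param class_counts training-split class counts.
#' @param minority explicit minority set (0-based indices), or NULL for the
#'   default strictly-below-maximum rule.
#' @return object of class `reward_scheme` with `lambda` and `minority_set`.
#' @export
reward_scheme <- function(class_counts, minority = NULL) {
  lambda <- compute_reward_weights(class_counts)
  structure(list(lambda = lambda,
                 minority_set = identify_minority_set(class_counts, minority),
                 class_counts = as.integer(class_counts)),
            class = "reward_scheme")
}

#' @export
print.reward_scheme <- function(x, ...) {
  cat("reward_scheme:\n  lambda:", signif(x$lambda, 5),
      "\n  minority classes:",
      if (length(x$minority_set)) paste(x$minority_set, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Start a classification episode stream
#'
#' Samples are served in a fresh random permutation; the choice of action
#' never influences which sample comes next (the transition kernel is
#' action-independent). When a pass over the data is exhausted a new
#' permutation is drawn and the stream continues, so episodes are truncations
#' within a continuing stream.
#'
#' @param dataset a [labeled_dataset].
#' @param seed integer seed for the shuffle stream, or NULL to reuse the
#'   caller's stream state via `streams`.
#' @param scheme a [reward_scheme]; defaults to one derived from the dataset.
#' @param streams optional [rng_streams()] environment with a `shuffle`
#'   stream (used by the training loop).
#' @return an environment of class `qimb_env`; read `$state` for the current
#'   sample's features.
#' @export
env_reset <- function(dataset, seed = NULL, scheme = NULL, streams = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(scheme)) scheme <- reward_scheme(dataset$class_counts)
  if (is.null(streams)) streams <- rng_streams(if (is.null(seed)) 0L else seed, "shuffle")
  e <- new.env(parent = emptyenv())
  e$features <- dataset$features
  e$labels <- dataset$labels
  e$n <- dataset$n
  e$K <- dataset$K
  e$lambda <- scheme$lambda
  e$is_minority <- seq_len(dataset$K) - 1L %in% scheme$minority_set
  e$streams <- streams
  e$perm <- with_stream(streams, "shuffle", sample.int(e$n))
  e$pos <- 1L
  e$state <- e$features[e$perm[1L], ]
  class(e) <- c("qimb_env", class(e))
  e
}

#' Advance the episode stream by one labelling action
#'
#' The reward is `+lambda[l]` when `action` equals the current sample's true
#' label `l` and `-lambda[l]` otherwise. The step is terminal when a
#' minority-class sample is misclassified, or when the pass over the data is
#' exhausted. The next state is the next permuted sample regardless of the
#' action taken.
#'
#' @param env a `qimb_env` from [env_reset()].
#' @param action 0-based predicted class index.
#' @return list with `reward`, `terminal`, `next_state`, and `label` (the
#'   true label that was scored).
#' @export
env_step <- function(env, action) {
  action <- as.integer(action)
  if (action < 0L || action >= env$K)
    stop("action ", action, " out of range 0..", env$K - 1L)
  l <- env$labels[env$perm[env$pos]]
  correct <- action == l
  reward <- if (correct) env$lambda[l + 1L] else -env$lambda[l + 1L]
  exhausted <- env$pos >= env$n
  terminal <- (!correct && env$is_minority[l + 1L]) || exhausted
  if (exhausted) {
    env$perm <- with_stream(env$streams, "shuffle", sample.int(env$n))
    env$pos <- 1L
  } else {
    env$pos <- env$pos + 1L
  }
  env$state <- env$features[env$perm[env$pos], ]
  list(reward = reward, terminal = terminal, next_state = env$state, label = l)
}
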