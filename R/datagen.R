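#' Synthetic imbalanced Gaussian-mixture generator configuration
#'
#' Emulates imbalanced tabular diagnostic data: class-conditional Gaussian
#' informative features (shared spherical covariance, class means a fixed
#' Mahalanobis distance apart) plus class-independent noise features. The
#' analytic class-conditional densities give a Bayes-optimal labelling for
#' oracle comparisons.
#'
#' @param K number of classes.
#' @param prevalence length-K vector of positive class prevalences summing
#'   to 1.
#' @param n_samples number of samples to draw.
#' @param n_informative number of class-informative features (>= 1).
#' @param n_noise number of pure-noise features.
#' @param separation pairwise distance between class means, in units of the
#'   within-class standard deviation. 2.5 is "moderate overlap" (binary
#'   equal-prior Bayes accuracy about 0.89); >= 6 is essentially separable.
#' @param sd within-class standard deviation (shared, spherical).
#' @param exact_counts draw exactly `round(prevalence * n)` per class instead
#'   of multinomial counts (deterministic composition for tests).
#' @param seed RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(K, prevalence, n_samples, n_informative = 10L,
                             n_noise = 10L, separation = 2.5, sd = 1,
                             exact_counts = FALSE, seed = 1L) {
  stopifnot(K >= 1, length(prevalence) == K, n_informative >= 1, n_noise >= 0,
            separation >= 0, sd > 0, n_samples >= 1)
  if (any(prevalence <= 0)) stop("prevalences must all be positive")
  if (abs(sum(prevalence) - 1) > 1e-8) stop("prevalences must sum to 1")
  structure(list(K = as.integer(K), prevalence = as.double(prevalence),
                 n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise), separation = separation,
                 sd = sd, exact_counts = isTRUE(exact_counts),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Named generator presets
#'
#' `covid_binary`: a binary screening task at 5% simulated disease prevalence
#' (1 case : 19 controls, the 1-in-20 regime of rare-disease screening),
#' n = 5000, 20 features. `eicu_multiclass`: a 5-class diagnosis task with
#' prevalences `[0.336, 0.25, 0.18, 0.147, 0.087]` spanning 8.7%-33.6%,
#' n = 6000, 20 features.
#'
#' @param name preset name.
#' @param n_samples override the preset's sample count.
#' @param seed RNG seed.
#' @return a [generator_config].
#' @export
preset_config <- function(name = c("covid_binary", "eicu_multiclass"),
                          n_samples = NULL, seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("covid_binary", "eicu_multiclass"))
    stop("unknown preset '", name[1], "'; available presets: covid_binary, eicu_multiclass")
  name <- match.arg(name)
  if (name == "covid_binary") {
    generator_config(K = 2L, prevalence = c(0.95, 0.05),
                     n_samples = if (is.null(n_samples)) 5000L else n_samples,
                     n_informative = 10L, n_noise = 10L, separation = 2.5,
                     seed = seed)
  } else {
    generator_config(K = 5L, prevalence = c(0.336, 0.25, 0.18, 0.147, 0.087),
                     n_samples = if (is.null(n_samples)) 6000L else n_samples,
                     n_informative = 10L, n_noise = 10L, separation = 3,
                     seed = seed)
  }
}

# class mean directions: orthogonal axes when they fit, otherwise random unit
# directions drawn under a seed fixed by the geometry (not the sampling seed),
# so train and test splits generated under different seeds share their means
class_means <- function(K, n_informative, separation, sd) {
  if (n_informative >= K) {
    M <- matrix(0, K, n_informative)
    for (k in seq_len(K)) M[k, k] <- 1
  } else {
    old <- get(".Random.seed", globalenv())
    set.seed(K * 10007L + n_informative)
    M <- matrix(stats::rnorm(K * n_informative), K)
    M <- M / sqrt(rowSums(M^2))
    assign(".Random.seed", old, globalenv())
  }
  # orthonormal rows at distance sqrt(2); rescale so pairwise distance is
  # `separation` within-class SDs
  M * separation * sd / sqrt(2)
}

#' Generate a synthetic imbalanced dataset
#'
#' Class counts are multinomial draws from the prevalence vector (resampled
#' until every class has at least 2 samples), or exact rounded counts when
#' `exact_counts = TRUE`. Returns the dataset together with the Bayes-optimal
#' labels `argmax_k pi_k N(x; mu_k, sigma^2 I)` computed from the true
#' generating parameters — the best any classifier can do.
#'
#' @param config a [generator_config].
#' @return list with `dataset` (a [labeled_dataset]), `bayes_labels`
#'   (0-based), `means` (true class means over informative features), and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  K <- config$K; n <- config$n_samples
  if (config$exact_counts) {
    counts <- round(config$prevalence * n)
    counts[1] <- n - sum(counts[-1])
  } else {
    repeat {
      counts <- as.vector(stats::rmultinom(1, n, config$prevalence))
      if (all(counts >= 2L)) break
    }
  }
  if (any(counts < 2L))
    stop("infeasible config: fewer than 2 samples for some class at n = ", n)
  mu <- class_means(K, config$n_informative, config$separation, config$sd)
  labels <- rep(seq_len(K) - 1L, counts)
  X_inf <- mu[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * config$n_informative, sd = config$sd), n)
  X <- if (config$n_noise > 0)
    cbind(X_inf, matrix(stats::rnorm(n * config$n_noise), n))
  else X_inf
  colnames(X) <- c(paste0("inf", seq_len(config$n_informative)),
                   if (config$n_noise > 0) paste0("noise", seq_len(config$n_noise)))
  # shuffle sample order so class blocks don't survive into splits
  ord <- sample.int(n)
  X <- X[ord, , drop = FALSE]
  labels <- labels[ord]
  bayes <- bayes_labels(X[, seq_len(config$n_informative), drop = FALSE],
                        mu, config$prevalence, config$sd)
  list(dataset = labeled_dataset(X, labels, K = K),
       bayes_labels = bayes, means = mu, config = config)
}

# Bayes rule for shared spherical covariance:
# argmax_k log pi_k - ||x - mu_k||^2 / (2 sigma^2)
bayes_labels <- function(X_inf, mu, prevalence, sd) {
  scores <- sapply(seq_len(nrow(mu)), function(k) {
    d2 <- rowSums(sweep(X_inf, 2, mu[k, ])^2)
    log(prevalence[k]) - d2 / (2 * sd^2)
  })
  max.col(scores, ties.method = "first") - 1L
}

#' Train/test split of a generated dataset
#'
#' Draws a fresh test set from the same generating configuration under a
#' derived seed, so evaluation is on truly held-out data with the same class
#' structure.
#'
#' @param config a [generator_config] (used for the training set).
#' @param n_test test-set size.
#' @return list with `train`, `test` (both [labeled_dataset]), and the
#'   generator outputs `train_gen`, `test_gen`.
#' @export
generate_split <- function(config, n_test = 2000L) {
  train_gen <- generate_dataset(config)
  test_cfg <- config
  test_cfg$n_samples <- as.integer(n_test)
  test_cfg$seed <- (config$seed + 777L) %% 2147483647L
  test_gen <- generate_dataset(test_cfg)
  list(train = train_gen$dataset, test = test_gen$dataset,
       train_gen = train_gen, test_gen = test_gen)
}
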