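test_that("epsilon anneals linearly from 1 to 0.01 with clamping past the budget", {
  cfg <- train_config()
  expect_identical(epsilon_at(0, cfg), 1)
  expect_identical(epsilon_at(cfg$total_steps, cfg), 0.01)
  expect_equal(epsilon_at(cfg$total_steps / 2, cfg), 0.505)
  expect_equal(epsilon_at(cfg$total_steps * 2, cfg), 0.01)
  steps <- seq(0, cfg$total_steps, length.out = 11)
  expect_equal(epsilon_at(steps, cfg), 1 + steps / cfg$total_steps * (0.01 - 1))
})

test_that("action selection is greedy at epsilon 0 (lowest-index ties) and uniform at epsilon 1", {
  expect_identical(select_action(c(1, 3, 2), 0), 1L)
  expect_identical(select_action(c(2, 2), 0), 0L)
  set.seed(88)
  draws <- replicate(10000, select_action(c(5, 1, 1), 1))
  freq <- tabulate(draws + 1L, 3)
  # each class ~ Binomial(1e4, 1/3); 3 sigma band
  expect_true(all(abs(freq - 10000 / 3) < 3 * sqrt(10000 * (1 / 3) * (2 / 3))))
})

test_that("the double-Q target matches brute-force evaluation and its identities", {
  expect_equal(ddqn_target(1, 0, c(1, 3, 2), c(5, 7, 4), 0.9), 7.3)
  expect_equal(ddqn_target(2, 1, c(9, 9), c(9, 9), 0.99), 2)      # terminal cuts bootstrap
  expect_equal(ddqn_target(-1.5, 0, c(1, 2), c(3, 4), 0), -1.5)   # gamma 0
  set.seed(17)
  for (i in 1:500) {
    K <- sample(2:6, 1)
    r <- rnorm(1); term <- sample(0:1, 1); gam <- runif(1)
    qo <- rnorm(K); qt <- rnorm(K)
    expect_identical(ddqn_target(r, term, qo, qt, gam),
                     oracle_ddqn_target(r, term, qo, qt, gam))
  }
})

test_that("replay memory is a bounded FIFO with uniform no-replacement sampling", {
  m <- replay_memory(5, 2)
  for (i in 1:7)
    memory_push(m, c(i, i), i %% 3, i * 10, c(i + 1, i + 1), 0)
  expect_equal(m$size, 5L)
  set.seed(1)
  b <- memory_sample(m, 5)
  # entries 1 and 2 were overwritten by 6 and 7
  expect_setequal(b$r, c(30, 40, 50, 60, 70))
  expect_equal(b$s[b$r == 60, ], c(6, 6))
  expect_equal(dim(b$s), c(5L, 2L))
})

test_that("target sync copies the online network exactly and is frozen between syncs", {
  net <- init_qnetwork(qnetwork_spec(3, 2), seed = 5)
  tgt <- sync_target(net)
  X <- matrix(rnorm(15), 5)
  expect_identical(qnet_forward(tgt, X), qnet_forward(net, X))
  net$params$trunk[[1]]$W <- net$params$trunk[[1]]$W + 1
  expect_false(identical(qnet_forward(tgt, X), qnet_forward(net, X)))
})

test_that("repeated updates on a single terminal transition drive Q(s,a) to r", {
  cfg <- train_config(total_steps = 1, batch_size = 1, learning_rate = 5e-2, seed = 2)
  net <- init_qnetwork(qnetwork_spec(2, 2), seed = 3)
  tgt <- sync_target(net)
  opt <- qimb:::adam_state(net$params)
  mem <- replay_memory(10, 2)
  memory_push(mem, c(0.3, -0.2), 1L, 4.2, c(0, 0), 1)
  last_loss <- Inf
  for (i in 1:400) {
    upd <- train_step(mem, net, tgt, opt, cfg)
    net <- upd$online; opt <- upd$opt
    expect_gte(upd$loss, 0)
    last_loss <- upd$loss
  }
  expect_equal(qnet_forward(net, c(0.3, -0.2))[1, 2], 4.2, tolerance = 1e-2)
})

test_that("train_step skips when memory holds fewer than batch_size transitions", {
  cfg <- train_config(batch_size = 8, seed = 1)
  net <- init_qnetwork(qnetwork_spec(2, 2), seed = 1)
  opt <- qimb:::adam_state(net$params)
  mem <- replay_memory(10, 2)
  memory_push(mem, c(1, 1), 0L, 1, c(0, 0), 1)
  upd <- train_step(mem, net, sync_target(net), opt, cfg)
  expect_null(upd$loss)
  expect_identical(upd$online$params, net$params)
})

test_that("training is bit-reproducible from the master seed", {
  set.seed(999)
  ds <- labeled_dataset(matrix(rnorm(300), 100), c(rep(0L, 85), rep(1L, 15)))
  cfg <- train_config(total_steps = 300, batch_size = 16, target_sync_interval = 100,
                      memory_capacity = 500, seed = 12)
  m1 <- fit_qimb(ds, cfg = cfg)
  m2 <- fit_qimb(ds, cfg = cfg)
  expect_identical(m1$net$params, m2$net$params)
  m3 <- fit_qimb(ds, cfg = train_config(total_steps = 300, batch_size = 16,
                                        target_sync_interval = 100,
                                        memory_capacity = 500, seed = 13))
  expect_false(identical(m1$net$params, m3$net$params))
})

test_that("a separable imbalanced task is learned to high per-class accuracy", {
  set.seed(7)
  n0 <- 450; n1 <- 50
  x <- matrix(c(rnorm(n0, -3), rnorm(n1, 3)), ncol = 1)
  ds <- labeled_dataset(x, c(rep(0L, n0), rep(1L, n1)))
  m <- fit_qimb(ds, cfg = train_config(total_steps = 5000, target_sync_interval = 250,
                                       seed = 4))
  pred <- predict(m, ds, type = "class")
  acc0 <- mean(pred[ds$labels == 0] == 0)
  acc1 <- mean(pred[ds$labels == 1] == 1)
  expect_gte(acc0, 0.95)
  expect_gte(acc1, 0.95)
})

test_that("single-class datasets are rejected", {
  ds <- labeled_dataset(matrix(rnorm(10), 5), rep(0L, 5))
  expect_error(fit_qimb(ds), "single class")
})

test_that("the majority-only policy earns strictly less expected reward than the oracle policy", {
  # closed form: oracle earns sum(N_k lambda_k)/N per step; always-majority earns
  # (N_M lambda_M - sum_{k != M} N_k lambda_k)/N
  for (counts in list(c(95, 5), c(60, 25, 15), c(6000, 3000, 2000, 1600, 1500))) {
    lam <- compute_reward_weights(counts)
    M <- which.max(counts)
    oracle <- sum(counts * lam) / sum(counts)
    majority <- (counts[M] * lam[M] - sum((counts * lam)[-M])) / sum(counts)
    expect_lt(majority, oracle)
  }
})

test_that("under extreme 1:50 overlap the agent recovers minority sensitivity the plain baseline misses", {
  sens <- sapply(1:3, function(seed) {
    cfg <- generator_config(K = 2, prevalence = c(50 / 51, 1 / 51), n_samples = 1800,
                            n_informative = 5, n_noise = 5, separation = 2.5,
                            seed = seed)
    sp <- generate_split(cfg, n_test = 1200)
    m <- fit_qimb(sp$train, cfg = train_config(total_steps = 6000, seed = seed))
    b <- fit_baseline(sp$train, baseline_spec(seed = seed))
    c(qimb = binary_metrics(m, sp$test)[["sensitivity"]],
      base = binary_metrics(b, sp$test)[["sensitivity"]])
  })
  expect_gt(median(sens["qimb", ]), median(sens["base", ]))
})
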