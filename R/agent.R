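#' Training configuration
#'
#' Defaults mirror the documented training regime: 120,000 environment steps
#' with the exploration probability annealed linearly from 1 to 0.01 over the
#' whole run, Adam updates on mini-batches replayed from a bounded FIFO
#' memory, and a hard target-network sync at a fixed interval. The discount
#' `gamma` defaults low (0.1): transitions are action-independent, so the
#' only inter-step signal is the minority-termination rule and the immediate
#' classification reward dominates.
#'
#' @param total_steps total environment steps T.
#' @param epsilon_start,epsilon_end linear annealing endpoints for epsilon.
#' @param gamma discount factor in `[0, 1)`.
#' @param batch_size replay mini-batch size.
#' @param memory_capacity replay memory capacity.
#' @param target_sync_interval steps between hard target syncs.
#' @param learning_rate Adam learning rate.
#' @param double use the double-Q target (online selects, target evaluates);
#'   `FALSE` gives the plain DQN target where the target network both selects
#'   and evaluates.
#' @param seed master seed; all substreams derive from it.
#' @return object of class `train_config`.
#' @export
train_config <- function(total_steps = 120000L, epsilon_start = 1, epsilon_end = 0.01,
                         gamma = 0.1, batch_size = 64L, memory_capacity = 50000L,
                         target_sync_interval = 1000L, learning_rate = 1e-3,
                         double = TRUE, seed = 1L) {
  stopifnot(epsilon_end >= 0, epsilon_start <= 1, epsilon_end <= epsilon_start,
            gamma >= 0, gamma < 1, total_steps >= 1)
  structure(list(total_steps = as.integer(total_steps),
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 gamma = gamma, batch_size = as.integer(batch_size),
                 memory_capacity = as.integer(memory_capacity),
                 target_sync_interval = as.integer(target_sync_interval),
                 learning_rate = learning_rate, double = isTRUE(double),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Exploration probability at a given step
#'
#' Linear interpolation from `epsilon_start` at step 0 to `epsilon_end` at
#' `total_steps`; steps beyond the budget clamp to `epsilon_end`.
#'
#' @param step 0-based step index.
#' @param cfg a [train_config].
#' @export
epsilon_at <- function(step, cfg) {
  frac <- pmin(pmax(step / cfg$total_steps, 0), 1)
  # convex combination: exact at both endpoints
  (1 - frac) * cfg$epsilon_start + frac * cfg$epsilon_end
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random class; otherwise the greedy
#' action `argmax_a Q`, ties broken toward the lowest index.
#'
#' @param qvalues length-K Q-vector.
#' @param epsilon exploration probability in `[0, 1]`.
#' @return 0-based class index.
#' @export
select_action <- function(qvalues, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon)
    sample.int(length(qvalues), 1L) - 1L
  else
    which.max(qvalues) - 1L
}

#' Double-Q learning target
#'
#' \eqn{y = r + (1 - term)\,\gamma\, Q_{target}(s', a^*)} with
#' \eqn{a^* = \arg\max_a Q_{online}(s', a)}: the online network selects the
#' next action, the target network evaluates it, decoupling selection from
#' evaluation to curb overestimation. Vectorised over rows.
#'
#' @param r reward(s).
#' @param term 0/1 terminal flag(s).
#' @param q_next_online,q_next_target length-K vectors or `n x K` matrices of
#'   next-state Q-values under the online and target networks.
#' @param gamma discount factor.
#' @return scalar or length-n vector of regression targets.
#' @export
#' @examples
#' ddqn_target(1, 0, c(1, 3, 2), c(5, 7, 4), 0.9)  # 1 + 0.9 * 7
ddqn_target <- function(r, term, q_next_online, q_next_target, gamma) {
  if (is.null(dim(q_next_online))) q_next_online <- matrix(q_next_online, 1L)
  if (is.null(dim(q_next_target))) q_next_target <- matrix(q_next_target, 1L)
  astar <- max.col(q_next_online, ties.method = "first")
  y <- r + (1 - term) * gamma * q_next_target[cbind(seq_len(nrow(q_next_target)), astar)]
  if (length(y) == 1L) y[[1L]] else y
}

dqn_target <- function(r, term, q_next_target, gamma) {
  if (is.null(dim(q_next_target))) q_next_target <- matrix(q_next_target, 1L)
  mx <- q_next_target[cbind(seq_len(nrow(q_next_target)),
                            max.col(q_next_target, ties.method = "first"))]
  r + (1 - term) * gamma * mx
}

#' Bounded FIFO replay memory
#'
#' Stores transitions `(s, a, r, s', term)` in a preallocated ring buffer
#' (one packed numeric vector per slot, so writes never copy the whole
#' store); [memory_sample()] draws a uniform subset without replacement.
#'
#' @param capacity maximum number of stored transitions.
#' @param D state dimensionality.
#' @return an environment of class `replay_memory`.
#' @export
replay_memory <- function(capacity, D) {
  m <- new.env(parent = emptyenv())
  m$capacity <- as.integer(capacity)
  m$D <- as.integer(D)
  m$chunk <- 512L
  m$buf <- lapply(seq_len(ceiling(capacity / m$chunk)),
                  function(i) vector("list", m$chunk))
  m$size <- 0L
  m$head <- 0L   # next write position (0-based)
  class(m) <- c("replay_memory", class(m))
  m
}

#' @rdname replay_memory
#' @param memory a `replay_memory`.
#' @param s,a,r,s_next,term one transition.
#' @export
memory_push <- function(memory, s, a, r, s_next, term) {
  h <- memory$head
  memory$buf[[h %/% memory$chunk + 1L]][[h %% memory$chunk + 1L]] <-
    c(s, s_next, a, r, term)
  memory$head <- (h + 1L) %% memory$capacity
  memory$size <- min(memory$size + 1L, memory$capacity)
  invisible(memory)
}

#' @rdname replay_memory
#' @param n number of transitions to draw (uniform, without replacement).
#' @export
memory_sample <- function(memory, n) {
  idx <- sample.int(memory$size, n) - 1L
  D <- memory$D
  cs <- memory$chunk
  buf <- memory$buf
  rows <- lapply(idx, function(i) buf[[i %/% cs + 1L]][[i %% cs + 1L]])
  M <- matrix(unlist(rows, use.names = FALSE), nrow = n, byrow = TRUE)
  list(s = M[, seq_len(D), drop = FALSE],
       s_next = M[, D + seq_len(D), drop = FALSE],
       a = as.integer(M[, 2L * D + 1L]), r = M[, 2L * D + 2L],
       term = M[, 2L * D + 3L])
}

#' Hard target-network sync
#'
#' Copies the online weights into the target network so their forward outputs
#' agree exactly; between syncs the target is frozen.
#'
#' @param online the online `qnetwork`.
#' @return a `qnetwork` to use as the target.
#' @export
sync_target <- function(online) online

# ---- gradients ----------------------------------------------------------

zero_like <- function(params) rapply(params, function(x) x * 0, how = "replace")

# backprop through a run_chain cache; dOut is gradient wrt chain output.
# Returns list(grads = per-layer list(W, b), dX = gradient wrt chain input).
chain_backward <- function(layers, cache, dOut, activate_last = FALSE) {
  L <- length(layers)
  grads <- vector("list", L)
  dH <- dOut
  for (i in rev(seq_len(L))) {
    if (i < L || activate_last) dH <- dH * (cache$pre[[i]] > 0)
    grads[[i]] <- list(W = crossprod(cache$act[[i]], dH), b = colSums(dH))
    dH <- tcrossprod(dH, layers[[i]]$W)
  }
  list(grads = grads, dX = dH)
}

# MSE loss on the chosen actions' Q-values; returns loss and full gradient set
qnet_loss_grads <- function(net, X, actions, y) {
  cache <- qnet_forward_cached(net, X)
  n <- nrow(X)
  sel <- cbind(seq_len(n), actions + 1L)
  qsel <- cache$Q[sel]
  diff <- qsel - y
  loss <- mean(diff^2)
  g <- 2 * diff / n
  p <- net$params
  if (net$spec$architecture == "dueling") {
    # Q_a = V + A_a - m,  m = sum_j p_j A_j,  dm/dA_j = p_j (1 + A_j - m)
    dM <- cache$P * (1 + cache$A - cache$m)
    dA <- -g * dM
    dA[sel] <- dA[sel] + g
    dV <- matrix(g, ncol = 1L)
    vb <- chain_backward(p$vstream, cache$vstream, dV)
    ab <- chain_backward(p$astream, cache$astream, dA)
    tb <- chain_backward(p$trunk, cache$trunk, vb$dX + ab$dX, activate_last = TRUE)
    grads <- list(trunk = tb$grads, vstream = vb$grads, astream = ab$grads)
  } else {
    dQ <- matrix(0, n, net$spec$output_dim)
    dQ[sel] <- g
    hb <- chain_backward(p$head, cache$head, dQ)
    tb <- chain_backward(p$trunk, cache$trunk, hb$dX, activate_last = TRUE)
    grads <- list(trunk = tb$grads, head = hb$grads)
  }
  list(loss = loss, grads = grads)
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      p2 <- p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps)
      list(p = p2, m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

#' One replayed gradient step
#'
#' Samples a mini-batch from memory, forms the regression target with
#' [ddqn_target()] (gradients blocked through the target), and takes one Adam
#' step on the mean squared error between the target and the online network's
#' Q-value of the stored action. Skips silently (returning `NULL` loss) when
#' the memory holds fewer than `batch_size` transitions.
#'
#' @param memory a [replay_memory].
#' @param online,target online and target `qnetwork`s.
#' @param opt Adam optimiser state from `adam_state()` (created on first use
#'   by [fit_qimb()]).
#' @param cfg a [train_config].
#' @return list with updated `online`, `opt`, and scalar `loss`.
#' @export
train_step <- function(memory, online, target, opt, cfg) {
  if (memory$size < cfg$batch_size) return(list(online = online, opt = opt, loss = NULL))
  b <- memory_sample(memory, cfg$batch_size)
  q_next_target <- qnet_forward(target, b$s_next)
  y <- if (cfg$double) {
    q_next_online <- qnet_forward(online, b$s_next)
    ddqn_target(b$r, b$term, q_next_online, q_next_target, cfg$gamma)
  } else {
    dqn_target(b$r, b$term, q_next_target, cfg$gamma)
  }
  lg <- qnet_loss_grads(online, b$s, b$a, y)
  upd <- adam_update(online$params, lg$grads, opt, cfg$learning_rate)
  online$params <- upd$params
  list(online = online, opt = upd$state, loss = lg$loss)
}

# ---- full training loop -------------------------------------------------

#' Train a Q-learning classifier on an imbalanced dataset
#'
#' Runs the episode loop: serve shuffled samples, pick a label with the
#' epsilon-greedy policy, score it with the class-weighted reward, store the
#' transition, and update the online network by replayed double-Q learning.
#' An episode ends when a minority-class sample is misclassified (the `term`
#' flag cuts the bootstrapped future value) or when a pass over the data is
#' exhausted; the stream then continues under a fresh permutation until the
#' step budget is spent.
#'
#' Ablations: `qnetwork_spec(..., architecture = "single_stream")` with
#' `double = TRUE` is the plain double DQN; `single_stream` with
#' `double = FALSE` is the classic DQN whose target network both selects and
#' evaluates.
#'
#' @param dataset a [labeled_dataset] (training split; K >= 2).
#' @param spec a [qnetwork_spec], or NULL for the default dueling
#'   architecture sized to the data.
#' @param cfg a [train_config].
#' @param minority explicit minority class set (0-based), or NULL for the
#'   default strictly-below-maximum-count rule.
#' @param standardize z-scale features using training-split statistics
#'   (stored in the model and re-applied at prediction).
#' @param verbose print episode summaries every `verbose` episodes (0 = quiet).
#' @return object of class `qimb_model`: the trained network plus the frozen
#'   reward scheme, label map, scaling, and a per-episode training log.
#' @export
fit_qimb <- function(dataset, spec = NULL, cfg = train_config(), minority = NULL,
                     standardize = TRUE, verbose = 0L) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(cfg, "train_config"))
  if (dataset$K < 2L) stop("dataset has a single class: no decision problem to learn")
  if (is.null(spec)) spec <- qnetwork_spec(dataset$D, dataset$K)
  if (spec$input_dim != dataset$D || spec$output_dim != dataset$K)
    stop("qnetwork_spec dimensions do not match the dataset")

  sc <- NULL
  if (standardize) {
    sc <- zscale(dataset$features)
    dataset <- labeled_dataset(sc$x, dataset$labels, K = dataset$K,
                               label_map = dataset$label_map)
  }
  scheme <- reward_scheme(dataset$class_counts, minority)
  streams <- rng_streams(cfg$seed, c("init", "shuffle", "epsilon", "replay"))

  online <- with_stream(streams, "init", init_qnetwork(spec))
  target <- sync_target(online)
  opt <- adam_state(online$params)
  memory <- replay_memory(cfg$memory_capacity, dataset$D)
  env <- env_reset(dataset, scheme = scheme, streams = streams)

  log_ep <- new.env(parent = emptyenv())
  log_ep$rows <- list()
  ep_reward <- 0; ep_len <- 0L; ep_id <- 1L
  s <- env$state
  losses <- numeric(0)

  for (t in seq_len(cfg$total_steps)) {
    eps <- epsilon_at(t - 1L, cfg)
    q <- qnet_forward(online, s)
    a <- with_stream(streams, "epsilon", select_action(drop(q), eps))
    res <- env_step(env, a)
    memory_push(memory, s, a, res$reward, res$next_state, as.numeric(res$terminal))
    upd <- with_stream(streams, "replay", train_step(memory, online, target, opt, cfg))
    online <- upd$online; opt <- upd$opt
    if (!is.null(upd$loss)) losses <- c(losses, upd$loss)
    if (t %% cfg$target_sync_interval == 0L) target <- sync_target(online)

    ep_reward <- ep_reward + res$reward
    ep_len <- ep_len + 1L
    if (res$terminal) {
      log_ep$rows[[ep_id]] <- c(episode = ep_id, length = ep_len,
                                reward = ep_reward, epsilon = eps,
                                loss = if (length(losses)) mean(losses) else NA_real_)
      if (verbose > 0L && ep_id %% verbose == 0L)
        message(sprintf("episode %d: len=%d reward=%.2f eps=%.3f", ep_id, ep_len, ep_reward, eps))
      ep_id <- ep_id + 1L; ep_reward <- 0; ep_len <- 0L; losses <- numeric(0)
    }
    s <- res$next_state
  }

  log_df <- if (length(log_ep$rows)) as.data.frame(do.call(rbind, log_ep$rows)) else NULL
  structure(list(net = online, spec = spec, scheme = scheme, cfg = cfg,
                 label_map = dataset$label_map,
                 center = if (standardize) sc$center else NULL,
                 scale = if (standardize) sc$scale else NULL,
                 log = log_df),
            class = "qimb_model")
}

#' @export
print.qimb_model <- function(x, ...) {
  cat(sprintf("qimb_model: %s Q-network, %d features -> %d classes, %d training steps\n",
              x$spec$architecture, x$spec$input_dim, x$spec$output_dim, x$cfg$total_steps))
  invisible(x)
}

#' Predict class scores or labels from a trained Q-network
#'
#' @param object a `qimb_model`.
#' @param newdata feature matrix or [labeled_dataset].
#' @param type `"score"` for an `n x K` softmax-of-Q score matrix, `"class"`
#'   for 0-based greedy labels.
#' @param ... unused.
#' @export
predict.qimb_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_dataset")) newdata$features else as.matrix(newdata)
  if (!is.null(object$center))
    x <- zscale(x, object$center, object$scale)$x
  q <- qnet_forward(object$net, x)
  if (type == "class") max.col(q, ties.method = "first") - 1L
  else scores_from_q(q)
}

#' Save / load a trained model checkpoint
#'
#' The network weights, architecture spec, frozen reward scheme, label map
#' and feature scaling are serialised together so a reloaded model reproduces
#' identical forward outputs.
#'
#' @param model a `qimb_model` (or `baseline_model`).
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
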