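# Independent brute-force oracles, deliberately written as literal loops so
# they share no code path with the package implementation.

# reward magnitudes: (1/N_k) normalised by the sum of squared inverse counts
oracle_lambda <- function(counts) {
  denom <- 0
  for (n_i in counts) denom <- denom + (1 / n_i) * (1 / n_i)
  out <- numeric(length(counts))
  for (k in seq_along(counts)) out[k] <- (1 / counts[k]) / denom
  out
}

# double-Q target by explicit argmax with lowest-index tie break
oracle_ddqn_target <- function(r, term, q_on, q_tg, gamma) {
  astar <- 1L
  for (j in seq_along(q_on)) if (q_on[j] > q_on[astar]) astar <- j
  r + (1 - term) * gamma * q_tg[astar]
}

# all-pairs AUROC with half credit for ties
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# confusion-derived metrics recomputed directly from raw label vectors
oracle_counts <- function(true, pred, pos) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(true)) {
    if (true[i] == pos && pred[i] == pos) tp <- tp + 1L
    else if (true[i] != pos && pred[i] == pos) fp <- fp + 1L
    else if (true[i] == pos && pred[i] != pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}
oracle_f <- function(cc) {
  if (cc$TP == 0) return(0)
  sqrt((cc$TP / (cc$TP + cc$FN)) * (cc$TP / (cc$TP + cc$FP)))
}
oracle_g <- function(cc) sqrt((cc$TP / (cc$TP + cc$FN)) * (cc$TN / (cc$TN + cc$FP)))

# softmax-weighted mean combine, written scalar-wise
oracle_dueling <- function(v, a) {
  w <- exp(a - max(a)); w <- w / sum(w)
  m <- 0
  for (j in seq_along(a)) m <- m + w[j] * a[j]
  v + (a - m)
}
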