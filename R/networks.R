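#' Q-network architecture specification
#'
#' Two architectures are supported. The dueling network routes a shared
#' fully-connected trunk into two streams — a scalar state-value stream and a
#' length-K advantage stream — recombined by [dueling_combine()]. The
#' single-stream network maps the trunk straight to K action values and is
#' used for the non-dueling ablations.
#'
#' @param input_dim feature dimensionality D.
#' @param output_dim number of classes K.
#' @param shared_layers integer vector of trunk widths.
#' @param stream_layers integer vector of per-stream hidden widths (dueling
#'   only).
#' @param architecture `"dueling"` or `"single_stream"`.
#' @param activation currently `"relu"`.
#' @return object of class `qnetwork_spec`.
#' @export
qnetwork_spec <- function(input_dim, output_dim,
                          shared_layers = c(32L, 32L),
                          stream_layers = 16L,
                          architecture = c("dueling", "single_stream"),
                          activation = "relu") {
  architecture <- match.arg(architecture)
  stopifnot(input_dim >= 1, output_dim >= 1, length(shared_layers) >= 1)
  if (activation != "relu") stop("only 'relu' activation is implemented")
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 shared_layers = as.integer(shared_layers),
                 stream_layers = as.integer(stream_layers),
                 architecture = architecture,
                 activation = activation),
            class = "qnetwork_spec")
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

new_layer <- function(n_in, n_out) list(W = glorot(n_in, n_out), b = numeric(n_out))

#' Initialise Q-network weights
#'
#' Fan-in/fan-out scaled uniform initialisation, drawn from the current RNG
#' state; pass `seed` for standalone reproducibility.
#'
#' @param spec a [qnetwork_spec].
#' @param seed optional integer seed.
#' @return object of class `qnetwork` (spec + weight list).
#' @export
init_qnetwork <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "qnetwork_spec"))
  if (!is.null(seed)) set.seed(seed)
  dims <- c(spec$input_dim, spec$shared_layers)
  trunk <- lapply(seq_len(length(dims) - 1L),
                  function(i) new_layer(dims[i], dims[i + 1L]))
  top <- spec$shared_layers[length(spec$shared_layers)]
  params <- list(trunk = trunk)
  if (spec$architecture == "dueling") {
    vdims <- c(top, spec$stream_layers, 1L)
    adims <- c(top, spec$stream_layers, spec$output_dim)
    params$vstream <- lapply(seq_len(length(vdims) - 1L),
                             function(i) new_layer(vdims[i], vdims[i + 1L]))
    params$astream <- lapply(seq_len(length(adims) - 1L),
                             function(i) new_layer(adims[i], adims[i + 1L]))
  } else {
    params$head <- list(new_layer(top, spec$output_dim))
  }
  structure(list(spec = spec, params = params), class = "qnetwork")
}

relu <- function(x) (x > 0) * x

affine <- function(X, layer) {
  Z <- X %*% layer$W
  Z + rep(layer$b, each = nrow(Z))
}

run_chain <- function(X, layers, activate_last = FALSE) {
  # returns list(out, pre = list of pre-activations, act = list of inputs)
  pre <- vector("list", length(layers)); act <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    act[[i]] <- H
    Z <- affine(H, layers[[i]])
    pre[[i]] <- Z
    H <- if (i < length(layers) || activate_last) relu(Z) else Z
  }
  list(out = H, pre = pre, act = act)
}

#' Combine value and advantage streams into Q-values
#'
#' \eqn{Q(s,a) = V(s) + (A(s,a) - m(s))} where the baseline
#' \eqn{m(s) = \sum_a \mathrm{softmax}(A(s,\cdot))_a A(s,a)} is the
#' softmax-weighted mean of the advantages. Subtracting a per-state scalar
#' identifies V and A uniquely while preserving the relative ranking of the
#' advantages — the greedy action under Q equals the greedy action under A.
#'
#' @param value scalar V(s), or a length-n vector for a batch.
#' @param advantages length-K advantage vector, or an `n x K` matrix.
#' @return Q-values with the same shape as `advantages`.
#' @export
#' @examples
#' dueling_combine(2, c(5, 5, 5))     # constant advantages -> Q = V everywhere
#' dueling_combine(1, c(1, 2, 3))
dueling_combine <- function(value, advantages) {
  if (is.null(dim(advantages))) {
    A <- matrix(advantages, 1L)
    drop_out <- TRUE
  } else {
    A <- advantages
    drop_out <- FALSE
  }
  stopifnot(length(value) == nrow(A))
  P <- softmax_rows(A)
  m <- rowSums(P * A)
  Q <- (value - m) + A
  if (drop_out) drop(Q) else Q
}

softmax_rows <- function(X) {
  mx <- X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]
  E <- exp(X - mx)
  E / rowSums(E)
}

#' Forward pass: Q-values for a batch of states
#'
#' @param net a `qnetwork` from [init_qnetwork()].
#' @param states numeric matrix (`n x D`) or a single length-D vector.
#' @return `n x K` matrix of Q-values.
#' @export
qnet_forward <- function(net, states) {
  if (is.null(dim(states))) states <- matrix(states, 1L)
  if (ncol(states) != net$spec$input_dim)
    stop("state dimensionality ", ncol(states), " does not match spec input_dim ",
         net$spec$input_dim)
  qnet_forward_cached(net, states)$Q
}

# forward keeping intermediate activations for backprop
qnet_forward_cached <- function(net, X) {
  p <- net$params
  tr <- run_chain(X, p$trunk, activate_last = TRUE)
  if (net$spec$architecture == "dueling") {
    vs <- run_chain(tr$out, p$vstream)
    as_ <- run_chain(tr$out, p$astream)
    V <- drop(vs$out)
    A <- as_$out
    P <- softmax_rows(A)
    m <- rowSums(P * A)
    Q <- (V - m) + A
    list(Q = Q, trunk = tr, vstream = vs, astream = as_, V = V, A = A, P = P, m = m)
  } else {
    hd <- run_chain(tr$out, p$head)
    list(Q = hd$out, trunk = tr, head = hd)
  }
}

#' Class scores from Q-values
#'
#' Softmax over the action values, giving a probability-like score vector for
#' ROC analysis and threshold adjustment; the argmax (greedy) action is
#' preserved.
#'
#' @param qvalues length-K vector or `n x K` matrix of Q-values.
#' @return non-negative scores summing to one per row.
#' @export
scores_from_q <- function(qvalues) {
  if (is.null(dim(qvalues))) drop(softmax_rows(matrix(qvalues, 1L)))
  else softmax_rows(qvalues)
}
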