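#' Named reproducible random-number substreams
#'
#' Training draws randomness for several unrelated purposes (weight
#' initialisation, sample shuffling, epsilon-greedy exploration, replay
#' sampling). Each purpose gets its own stream derived deterministically from
#' one master seed, so that e.g. taking an exploratory action never perturbs
#' the replay draws. A stream is a captured `.Random.seed` state that is
#' swapped in around each draw.
#'
#' @param seed master integer seed.
#' @param names character vector of stream names.
#' @return an environment mapping each name to an independent stream.
#' @keywords internal
rng_streams <- function(seed, names) {
  streams <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    # distinct sub-seed per stream, kept inside 32-bit integer range
    sub <- (as.double(seed) * 7919 + i * 104729) %% 2147483647
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(sub))
    streams[[names[i]]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  streams
}

#' Evaluate an expression under a named stream, advancing that stream only.
#' @keywords internal
with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams[[name]], globalenv())
  on.exit({
    streams[[name]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}
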