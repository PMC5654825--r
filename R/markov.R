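# Order-m Markov chain nucleotide generator.
#
# The next base repeats the current trailing base with probability delta^h,
# where h is the trailing homopolymer run length capped at min(m, k); each of
# the three alternatives has probability (1 - delta^h) / 3. delta = 1/4 with
# m = 1 recovers the uniform i.i.d. generator.

#' Markov generator parameters
#'
#' @param delta Repeat-decay parameter in \[0, 1\]. `delta = 1/4` with
#'   `order_m = 1` generates uniform random sequences; smaller `delta`
#'   suppresses homopolymer runs.
#' @param order_m Model order (integer >= 1); the trailing-run length that
#'   modulates the repeat probability is capped at `order_m`. In framework
#'   use this is shared with the homopolymer filter's `m`.
#' @param seed Optional integer seed applied before generation.
#' @return A `markov_params` object.
#' @export
markov_params <- function(delta = 0.25, order_m = 1L, seed = NULL) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1) {
    abort("`delta` must be a single number in [0, 1].",
          class = "barcodeforge_invalid_spec")
  }
  if (!is.numeric(order_m) || length(order_m) != 1 || order_m < 1 ||
      order_m != floor(order_m)) {
    abort("`order_m` must be a single integer >= 1.",
          class = "barcodeforge_invalid_spec")
  }
  structure(list(delta = as.numeric(delta), order_m = as.integer(order_m),
                 seed = seed),
            class = "markov_params")
}

#' @export
print.markov_params <- function(x, ...) {
  cat(sprintf("<markov_params> delta = %g, order m = %d\n", x$delta, x$order_m))
  invisible(x)
}

#' Trailing homopolymer run length, capped at the model order
#'
#' Returns `h = min(order_m, k, trailing run length)` where `k` is the prefix
#' length; 0 for the empty prefix. The cap at `min(order_m, k)` accounts for
#' the start of sequence generation.
#'
#' @param prefix A single DNA sequence (possibly empty).
#' @param order_m Model order (integer >= 1).
#' @return A non-negative integer.
#' @examples
#' trailing_run_length("ACGTT", 4) # 2
#' trailing_run_length("AAAA", 2)  # capped at 2
#' trailing_run_length("A", 3)     # 1
#' @export
trailing_run_length <- function(prefix, order_m) {
  prefix <- as_dna(prefix, "prefix")
  stopifnot(length(prefix) == 1)
  k <- nchar(prefix)
  if (k == 0) return(0L)
  chars <- strsplit(prefix, "", fixed = TRUE)[[1]]
  run <- 1L
  i <- k - 1L
  while (i >= 1 && chars[i] == chars[k]) {
    run <- run + 1L
    i <- i - 1L
  }
  as.integer(min(order_m, k, run))
}

#' Transition distribution of the Markov generator
#'
#' Probability vector over `A`, `C`, `G`, `T` for the base following
#' `prefix`: the trailing base repeats with probability `delta^h`
#' (`h = trailing_run_length(prefix, order_m)`) and each alternative has
#' probability `(1 - delta^h) / 3`.
#'
#' @param prefix A single non-empty DNA sequence.
#' @param params A [markov_params()].
#' @return Named numeric vector of probabilities summing to 1.
#' @examples
#' transition_distribution("ACG", markov_params(delta = 0.25, order_m = 1))
#' @export
transition_distribution <- function(prefix, params) {
  stopifnot(inherits(params, "markov_params"))
  prefix <- as_dna(prefix, "prefix")
  if (nchar(prefix) == 0) {
    abort("`prefix` must be non-empty (the first base is drawn uniformly).",
          class = "barcodeforge_invalid_spec")
  }
  h <- trailing_run_length(prefix, params$order_m)
  p_rep <- params$delta^h
  last <- substr(prefix, nchar(prefix), nchar(prefix))
  p <- setNames(rep((1 - p_rep) / 3, 4), DNA_BASES)
  p[last] <- p_rep
  p
}

#' Generate one sequence from the Markov model
#'
#' The first base is uniform over the alphabet; each subsequent base is drawn
#' from [transition_distribution()]. Reproducible given `params$seed`.
#'
#' @param n Sequence length (integer >= 0).
#' @param params A [markov_params()].
#' @return A single DNA sequence of length `n`.
#' @export
generate_sequence <- function(n, params) {
  generate_sequences(1L, n, params)
}

#' Generate many sequences from the Markov model
#'
#' @param n_seq Number of sequences.
#' @param length Length of each sequence (integer >= 0).
#' @param params A [markov_params()].
#' @return Character vector of `n_seq` sequences.
#' @export
generate_sequences <- function(n_seq, length, params) {
  stopifnot(inherits(params, "markov_params"))
  if (!is.numeric(length) || length < 0 || length != floor(length)) {
    abort("Sequence length must be a non-negative integer.",
          class = "barcodeforge_invalid_argument")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  cpp_markov_generate(as.integer(n_seq), as.integer(length),
                      params$delta, params$order_m)
}
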