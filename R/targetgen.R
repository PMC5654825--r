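# Target-code generation: every accepted target must pass all filters when
# postfixed to every linked batch code.

#' Check a single candidate target code
#'
#' Reports, without short-circuiting, whether `candidate`
#' (i) is at Hamming distance >= `budget$d_t` from every accepted target and
#' (ii) yields a concatenation `linked_batch + candidate` passing the
#' homopolymer, GC-content, and blacklist filters for *every* linked batch
#' code. Filters are evaluated on the full concatenation so junction-spanning
#' violations are caught.
#'
#' @param candidate A single DNA sequence of length `l_t`.
#' @param linked_batches Character vector of linked batch codes.
#' @param accepted_targets Character vector of already-accepted targets (may
#'   be empty).
#' @param spec A [filter_spec()].
#' @param budget A [distance_budget()].
#' @return One-row tibble with logical columns `hamming`, `homopolymer`,
#'   `gc_content`, `blacklist`, and `pass` (their conjunction).
#' @export
target_candidate_passes <- function(candidate, linked_batches,
                                    accepted_targets, spec, budget) {
  stopifnot(inherits(spec, "filter_spec"), inherits(budget, "distance_budget"))
  candidate <- as_dna(candidate, "candidate")
  stopifnot(length(candidate) == 1)
  linked_batches <- as_dna(linked_batches, "linked_batches")
  accepted_targets <- if (length(accepted_targets) == 0) character()
                      else as_dna(accepted_targets, "accepted_targets")
  hamming_ok <- length(accepted_targets) == 0 || budget$d_t == 0 ||
    all(hamming_distance(rep(candidate, length(accepted_targets)),
                         accepted_targets) >= budget$d_t)
  concats <- paste0(linked_batches, candidate)
  rep_ <- passes_composition_filters(concats, spec)
  tibble(hamming = hamming_ok,
         homopolymer = all(rep_$homopolymer),
         gc_content = all(rep_$gc_content),
         blacklist = all(rep_$blacklist),
         pass = hamming_ok && all(rep_$pass))
}

#' Generate target codes
#'
#' Iteratively proposes candidate target codes from the Markov model at
#' `delta` (order `spec$max_homopolymer`) and accepts a candidate iff it
#' passes [target_candidate_passes()]: pairwise Hamming distance >=
#' `budget$d_t` against accepted targets, and every concatenation
#' `linked_batch + candidate` passes the composition filters. Candidates are
#' generated from an empty Markov context since they must work with every
#' batch. The per-candidate evaluation order is Hamming, then homopolymer,
#' GC, blacklist per batch; order affects only speed and per-filter rejection
#' attribution.
#'
#' @param n_t Number of new target codes (integer >= 1).
#' @param l_t Target-code length in bp.
#' @param linked_batches Character vector of linked batch codes, each passing
#'   the composition filters.
#' @param spec A [filter_spec()].
#' @param budget A [distance_budget()].
#' @param delta Markov repeat parameter (e.g. 1/4 for Framework A, or the
#'   [select_delta()] optimum for Framework B).
#' @param order_m Markov model order for candidate generation. Defaults to
#'   the homopolymer filter's `m`; Framework A passes 1 so that
#'   `delta = 1/4` recovers uniform random generation.
#' @param max_attempts_per_code Proposal cap per accepted code (default 1e6).
#' @param existing Optional character vector of already-accepted targets to
#'   extend (counted in the Hamming screen but not regenerated).
#' @param seed Optional integer seed.
#' @return A `target_codes` object: `$codes` a tibble with column `target`;
#'   `$stats` a one-row generation-statistics tibble (including
#'   `attempts_per_code` as a list column used for difficulty diagnostics).
#' @export
generate_target_codes <- function(n_t, l_t, linked_batches, spec, budget,
                                  delta = 0.25,
                                  order_m = spec$max_homopolymer,
                                  max_attempts_per_code = 1e6,
                                  existing = NULL, seed = NULL) {
  stopifnot(inherits(spec, "filter_spec"), inherits(budget, "distance_budget"))
  if (!is.numeric(n_t) || n_t < 1) {
    abort("`n_t` must be >= 1.", class = "barcodeforge_invalid_argument")
  }
  if (!is.numeric(delta) || delta < 0 || delta > 1) {
    abort("`delta` must be in [0, 1].", class = "barcodeforge_invalid_argument")
  }
  linked_batches <- validate_linked_batches(linked_batches, spec)
  existing <- if (is.null(existing)) character() else as_dna(existing, "existing")
  if (!is.null(seed)) set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  raw <- cpp_generate_targets(as.integer(n_t), as.integer(l_t),
                              linked_batches, delta, as.integer(order_m),
                              spec$max_homopolymer, spec$gc_min, spec$gc_max,
                              spec$blacklist, budget$d_t,
                              max_attempts_per_code, existing)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!raw$completed) infeasible_stop("target", raw, max_attempts_per_code)
  stats <- new_generation_stats("target", raw, delta = delta,
                                elapsed = elapsed)
  stats$concat_checks <- raw$concat_checks
  structure(
    list(codes = tibble(target = raw$targets),
         attempts_per_code = raw$attempts_per_code,
         stats = stats, spec = spec, budget = budget, delta = delta),
    class = "target_codes")
}

#' @export
print.target_codes <- function(x, ...) {
  cat(sprintf("<target_codes> %d target codes (length %d), delta = %g\n",
              nrow(x$codes), nchar(x$codes$target[1]), x$delta))
  cat(sprintf("  acceptance rate %.3f (%d / %d proposals)\n",
              x$stats$acceptance_rate, as.integer(x$stats$accepted),
              as.integer(x$stats$proposed)))
  invisible(x)
}

#' @rdname generate_target_codes
#' @param x,object A `target_codes` object.
#' @param ... Unused.
#' @export
tidy.target_codes <- function(x, ...) x$codes

#' @rdname generate_target_codes
#' @export
glance.target_codes <- function(x, ...) x$stats
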