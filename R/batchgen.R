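# Linked batch-code generation by rejection sampling.

#' Draw a 2-bp linker for a batch code
#'
#' The first linker base is uniform over the three bases different from the
#' last base of the batch code; the second is uniform over the three bases
#' different from the first linker base. This guarantees that the trailing
#' homopolymer run of any linked batch code has length exactly 1, so no run
#' can propagate from a batch code into a target code.
#'
#' @param batch A single non-empty DNA sequence.
#' @return A 2-character DNA sequence.
#' @export
make_linker <- function(batch) {
  batch <- as_dna(batch, "batch")
  stopifnot(length(batch) == 1, nchar(batch) >= 1)
  last <- substr(batch, nchar(batch), nchar(batch))
  l1 <- sample(setdiff(DNA_BASES, last), 1)
  l2 <- sample(setdiff(DNA_BASES, l1), 1)
  paste0(l1, l2)
}

# Long proper prefixes (all but the last 1-2 bases) of blacklist entries;
# a linked batch code ending in one of these would let a target's first one
# or two bases complete the blacklisted word across the junction.
blacklist_prefix_tails <- function(blacklist) {
  out <- character()
  for (e in blacklist) {
    n <- nchar(e)
    for (j in c(n - 1L, n - 2L)) {
      if (j >= 1) out <- c(out, substr(e, 1, j))
    }
  }
  unique(out)
}

new_generation_stats <- function(phase, raw, delta = NA_real_, elapsed = NA_real_) {
  tibble(
    phase = phase,
    proposed = raw$proposed,
    accepted = raw$accepted,
    acceptance_rate = ifelse(raw$proposed > 0, raw$accepted / raw$proposed, NA_real_),
    rej_hamming = raw$rej_hamming,
    rej_homopolymer = raw$rej_homopolymer,
    rej_gc = raw$rej_gc,
    rej_blacklist = raw$rej_blacklist,
    hamming_comparisons = raw$comparisons,
    delta = delta,
    elapsed = elapsed)
}

dominant_filter <- function(raw) {
  rej <- c(hamming = raw$rej_hamming, homopolymer = raw$rej_homopolymer,
           gc = raw$rej_gc, blacklist = raw$rej_blacklist)
  names(rej)[which.max(rej)]
}

infeasible_stop <- function(phase, raw, max_attempts) {
  rej <- c(hamming = raw$rej_hamming, homopolymer = raw$rej_homopolymer,
           gc = raw$rej_gc, blacklist = raw$rej_blacklist)
  frac <- if (raw$proposed > 0) rej / raw$proposed else rej
  abort(sprintf(
    paste0("Infeasible constraints in %s phase: %d consecutive rejections. ",
           "Dominant failing filter: %s. Rejection fractions: ",
           "hamming %.3f, homopolymer %.3f, gc %.3f, blacklist %.3f."),
    phase, as.integer(max_attempts), dominant_filter(raw),
    frac[["hamming"]], frac[["homopolymer"]], frac[["gc"]],
    frac[["blacklist"]]),
    class = "barcodeforge_infeasible")
}

#' Generate linked batch codes
#'
#' Proposes batch-code cores uniformly at random (the Markov model at
#' `delta = 1/4`, `m = 1`), appends a [make_linker()] linker, and accepts a
#' candidate iff the *linked* code passes the composition filters and is at
#' Hamming distance >= `budget$d_b` from every previously accepted linked
#' code. An `existing` set of linked codes (e.g. read from a previous run's
#' file) may be extended; existing codes are validated first.
#'
#' @param n_b Number of new linked batch codes to generate (integer >= 1).
#' @param l_b Batch-code core length in bp.
#' @param spec A [filter_spec()].
#' @param budget A [distance_budget()].
#' @param max_attempts_per_code Proposal cap per accepted code before an
#'   infeasible-constraints error is raised (default 1e6).
#' @param existing Optional character vector of already-accepted linked batch
#'   codes to extend.
#' @param screen_tails If `TRUE`, additionally reject batch candidates whose
#'   linked code ends with a long proper prefix (all but the last one or two
#'   bases) of a blacklist entry. Junction scanning during target generation
#'   rejects any target whose first bases complete a blacklisted word across
#'   a batch--target junction; once the batch set is large (hundreds to
#'   thousands of codes), such near-complete tails collectively poison every
#'   possible target prefix and the target space becomes empty. Off by
#'   default; recommended for designs with many batch codes and short
#'   blacklist entries.
#' @param seed Optional integer seed.
#' @return A `batch_codes` object: `$codes` is a tibble with columns `batch`,
#'   `linker`, `linked`; `$stats` a one-row generation-statistics tibble.
#' @export
generate_batch_codes <- function(n_b, l_b, spec, budget,
                                 max_attempts_per_code = 1e6,
                                 existing = NULL, screen_tails = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(spec, "filter_spec"), inherits(budget, "distance_budget"))
  if (!is.numeric(n_b) || n_b < 1) {
    abort("`n_b` must be >= 1.", class = "barcodeforge_invalid_argument")
  }
  existing <- if (is.null(existing)) character() else as_dna(existing, "existing")
  if (length(existing) > 0) {
    if (any(nchar(existing) != l_b + 2)) {
      abort("Existing linked batch codes must have length l_b + 2.",
            class = "barcodeforge_invalid_argument")
    }
    rep_ <- passes_composition_filters(existing, spec)
    if (!all(rep_$pass)) {
      abort("Existing linked batch codes fail the composition filters.",
            class = "barcodeforge_invalid_argument")
    }
    if (length(existing) > 1 &&
        cpp_pairwise_min(existing)$min < budget$d_b) {
      abort("Existing linked batch codes violate the pairwise d_b minimum.",
            class = "barcodeforge_invalid_argument")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  forbidden <- if (isTRUE(screen_tails)) blacklist_prefix_tails(spec$blacklist)
               else character()
  t0 <- proc.time()[["elapsed"]]
  raw <- cpp_generate_batches(as.integer(n_b), as.integer(l_b),
                              spec$max_homopolymer, spec$gc_min, spec$gc_max,
                              spec$blacklist, budget$d_b,
                              max_attempts_per_code, existing, forbidden)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!raw$completed) infeasible_stop("batch", raw, max_attempts_per_code)
  structure(
    list(codes = tibble(batch = raw$batch, linker = raw$linker,
                        linked = raw$linked),
         existing = existing,
         stats = new_generation_stats("batch", raw, delta = 0.25,
                                      elapsed = elapsed),
         spec = spec, budget = budget),
    class = "batch_codes")
}

#' @export
print.batch_codes <- function(x, ...) {
  cat(sprintf("<batch_codes> %d linked batch codes (length %d)\n",
              nrow(x$codes), nchar(x$codes$linked[1])))
  cat(sprintf("  acceptance rate %.3f (%d / %d proposals)\n",
              x$stats$acceptance_rate, as.integer(x$stats$accepted),
              as.integer(x$stats$proposed)))
  invisible(x)
}

#' @rdname generate_batch_codes
#' @param x,object A `batch_codes` object.
#' @param ... Unused.
#' @export
tidy.batch_codes <- function(x, ...) x$codes

#' @rdname generate_batch_codes
#' @export
glance.batch_codes <- function(x, ...) x$stats
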