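# Top-level library generation workflow: batch phase, optional grid search,
# target phase.

#' Generate a complete barcode library
#'
#' Runs the full workflow: (1) generate `n_b` linked batch codes by rejection
#' sampling from the uniform generator; (2) for Framework B, select the
#' Markov repeat parameter delta by grid search against the accepted batch
#' codes (Framework A fixes `delta = 1/4`); (3) generate `n_t` target codes
#' from the Markov model at the chosen delta. The headline acceptance rate is
#' pooled over the batch and target phases (the target phase dominates when
#' `n_t >> n_b`); per-phase rates are also reported.
#'
#' @param design A [library_design()].
#' @param spec A [filter_spec()].
#' @param framework `"B"` (grid-searched delta, default) or `"A"`
#'   (`delta = 1/4`).
#' @param budget_mode Distance-budget policy passed to [distance_budget()].
#' @param grid A [grid_search_config()] (Framework B only).
#' @param max_attempts_per_code Proposal cap per accepted code.
#' @param screen_batch_tails Passed to [generate_batch_codes()] as
#'   `screen_tails`; recommended for large batch counts with short
#'   blacklist entries.
#' @param seed Optional integer seed; a single seed makes the whole run
#'   reproducible (all phases draw from R's RNG stream in a fixed order).
#' @return A `barcode_run` with fields `library` (a [barcode_library()]),
#'   `delta`, `grid` (the `grid_search_result`, Framework B only), `stats`
#'   (per-phase + pooled generation statistics tibble), `framework`.
#' @examples
#' \donttest{
#' design <- library_design(N = 200, n_b = 10, l_b = 6, L = 16)
#' spec <- filter_spec(min_distance = 2, max_homopolymer = 3,
#'                     gc_min = 0.25, gc_max = 0.75)
#' run <- generate_library(design, spec, framework = "A", seed = 1)
#' glance(run)
#' }
#' @export
generate_library <- function(design, spec, framework = c("B", "A"),
                             budget_mode = c("split", "strict"),
                             grid = grid_search_config(),
                             max_attempts_per_code = 1e6,
                             screen_batch_tails = FALSE, seed = NULL) {
  framework <- match.arg(framework)
  budget_mode <- match.arg(budget_mode)
  stopifnot(inherits(design, "library_design"), inherits(spec, "filter_spec"))
  budget <- distance_budget(spec$min_distance, design$l_b, design$l_t,
                            mode = budget_mode)
  if (!is.null(seed)) set.seed(seed)
  batches <- generate_batch_codes(design$n_b, design$l_b, spec, budget,
                                  max_attempts_per_code = max_attempts_per_code,
                                  screen_tails = screen_batch_tails)
  linked <- batches$codes$linked
  grid_result <- NULL
  if (framework == "B") {
    grid_result <- select_delta(linked, design, spec, config = grid)
    delta <- grid_result$delta
    order_m <- spec$max_homopolymer
  } else {
    # Framework A: uniform random candidates (delta = 1/4, order 1)
    delta <- 0.25
    order_m <- 1L
  }
  targets <- generate_target_codes(design$n_t, design$l_t, linked, spec,
                                   budget, delta = delta, order_m = order_m,
                                   max_attempts_per_code = max_attempts_per_code)
  stats <- dplyr::bind_rows(
    batches$stats,
    targets$stats,
    pooled_stats(batches$stats, targets$stats, delta))
  lib <- barcode_library(linked, targets$codes$target, spec, budget,
                         design = design)
  structure(
    list(library = lib, delta = delta, grid = grid_result, stats = stats,
         framework = framework,
         attempts_per_code = targets$attempts_per_code),
    class = "barcode_run")
}

pooled_stats <- function(batch_stats, target_stats, delta) {
  proposed <- batch_stats$proposed + target_stats$proposed
  accepted <- batch_stats$accepted + target_stats$accepted
  tibble(
    phase = "pooled",
    proposed = proposed, accepted = accepted,
    acceptance_rate = accepted / proposed,
    rej_hamming = batch_stats$rej_hamming + target_stats$rej_hamming,
    rej_homopolymer = batch_stats$rej_homopolymer + target_stats$rej_homopolymer,
    rej_gc = batch_stats$rej_gc + target_stats$rej_gc,
    rej_blacklist = batch_stats$rej_blacklist + target_stats$rej_blacklist,
    hamming_comparisons = batch_stats$hamming_comparisons +
      target_stats$hamming_comparisons,
    delta = delta,
    elapsed = batch_stats$elapsed + target_stats$elapsed)
}

#' @export
print.barcode_run <- function(x, ...) {
  pooled <- x$stats[x$stats$phase == "pooled", ]
  cat(sprintf("<barcode_run> Framework %s, delta = %g\n", x$framework, x$delta))
  print(x$library)
  cat(sprintf("  pooled acceptance rate %.3f (%s / %s proposals)\n",
              pooled$acceptance_rate,
              format(pooled$accepted, big.mark = ","),
              format(pooled$proposed, big.mark = ",")))
  invisible(x)
}

#' @rdname generate_library
#' @param x,object A `barcode_run`.
#' @param ... Unused.
#' @export
tidy.barcode_run <- function(x, ...) x$stats

#' @rdname generate_library
#' @export
glance.barcode_run <- function(x, ...) {
  pooled <- x$stats[x$stats$phase == "pooled", ]
  tibble(framework = x$framework, delta = x$delta,
         n_b = length(x$library$linked_batches),
         n_t = length(x$library$targets),
         L = x$library$design$L,
         acceptance_rate = pooled$acceptance_rate,
         proposed = pooled$proposed,
         hamming_comparisons = pooled$hamming_comparisons,
         elapsed = pooled$elapsed)
}

#' @rdname generate_library
#' @export
autoplot.barcode_run <- function(object, ...) {
  df <- tibble(code_index = seq_along(object$attempts_per_code),
               attempts = object$attempts_per_code)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code_index, y = .data$attempts)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "accepted target code", y = "proposals needed",
                  title = "Rejection-sampling effort during target generation") +
    ggplot2::theme_minimal()
}
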