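# Grid search for the Markov parameter delta used in target-code generation.

#' Grid-search configuration
#'
#' `r` grid points `i / (r - 1)` uniformly spaced over the unit interval;
#' at each point, `s` candidate target codes are sampled per trial and the
#' pass proportion is averaged over `t` trials.
#'
#' @param r Number of grid points (integer >= 2).
#' @param s Candidates sampled per point per trial (integer >= 1).
#' @param t Trials per point (integer >= 1).
#' @param seed Optional integer seed applied before the search.
#' @return A `grid_search_config` object.
#' @export
grid_search_config <- function(r = 11L, s = 200L, t = 3L, seed = NULL) {
  if (!is.numeric(r) || r < 2 || r != floor(r)) {
    abort("`r` must be an integer >= 2.",
          class = "barcodeforge_invalid_argument")
  }
  if (!is.numeric(s) || s < 1 || !is.numeric(t) || t < 1) {
    abort("`s` and `t` must be integers >= 1.",
          class = "barcodeforge_invalid_argument")
  }
  structure(list(r = as.integer(r), s = as.integer(s), t = as.integer(t),
                 seed = seed),
            class = "grid_search_config")
}

#' Grid points over the unit interval
#'
#' @param r Number of points (integer >= 2).
#' @return Strictly increasing numeric vector `c(0, 1/(r-1), ..., 1)`.
#' @examples
#' grid_points(5)
#' @export
grid_points <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || r < 2 || r != floor(r)) {
    abort("`r` must be a single integer >= 2.",
          class = "barcodeforge_invalid_argument")
  }
  (seq_len(r) - 1) / (r - 1)
}

validate_linked_batches <- function(linked_batches, spec) {
  linked_batches <- as_dna(linked_batches, "linked_batches")
  if (length(linked_batches) == 0) {
    abort("`linked_batches` must be non-empty.",
          class = "barcodeforge_invalid_argument")
  }
  rep_ <- passes_composition_filters(linked_batches, spec)
  if (!all(rep_$pass)) {
    abort(sprintf(
      "%d linked batch code(s) fail the composition filters; validate inputs first.",
      sum(!rep_$pass)),
      class = "barcodeforge_invalid_argument")
  }
  linked_batches
}

#' Estimate the candidate pass rate at a given delta
#'
#' For each of `config$t` trials, draws `config$s` candidate target codes of
#' length `design$l_t` from the Markov model at `delta` (order
#' `spec$max_homopolymer`) and counts the fraction that pass the composition
#' filters when postfixed to every linked batch code. Target-target Hamming
#' screening is excluded: no targets are accepted yet at grid-search time.
#'
#' @param delta Markov repeat parameter in \[0, 1\].
#' @param linked_batches Character vector of linked batch codes (each must
#'   itself pass the composition filters).
#' @param design A [library_design()] (supplies `l_t`).
#' @param spec A [filter_spec()].
#' @param config A [grid_search_config()].
#' @return The mean pass fraction over trials, with per-trial fractions in
#'   attribute `"trial_rates"`.
#' @export
estimate_pass_rate <- function(delta, linked_batches, design, spec,
                               config = grid_search_config()) {
  stopifnot(inherits(design, "library_design"), inherits(spec, "filter_spec"),
            inherits(config, "grid_search_config"))
  linked_batches <- validate_linked_batches(linked_batches, spec)
  if (!is.null(config$seed)) set.seed(config$seed)
  rates <- vapply(seq_len(config$t), function(i) {
    cpp_pass_rate_trial(linked_batches, config$s, design$l_t, delta,
                        spec$max_homopolymer, spec$max_homopolymer,
                        spec$gc_min, spec$gc_max, spec$blacklist) / config$s
  }, numeric(1))
  structure(mean(rates), trial_rates = rates)
}

#' Select the optimal delta by grid search
#'
#' Evaluates [estimate_pass_rate()] at every point of [grid_points()]
#' and returns the argmax; ties are broken toward the smallest delta (lower
#' delta additionally reduces homopolymer risk downstream). If every grid
#' point scores zero the result carries `all_zero = TRUE` and the smallest
#' delta.
#'
#' @inheritParams estimate_pass_rate
#' @return A `grid_search_result` with fields `delta` (the selected value),
#'   `summary` (tibble of per-point mean rates), `rates` (tibble of raw
#'   per-trial rates), `all_zero`, and `config`.
#' @export
select_delta <- function(linked_batches, design, spec,
                         config = grid_search_config()) {
  stopifnot(inherits(config, "grid_search_config"))
  linked_batches <- validate_linked_batches(linked_batches, spec)
  if (!is.null(config$seed)) set.seed(config$seed)
  deltas <- grid_points(config$r)
  raw <- lapply(deltas, function(d) {
    vapply(seq_len(config$t), function(i) {
      cpp_pass_rate_trial(linked_batches, config$s, design$l_t, d,
                          spec$max_homopolymer, spec$max_homopolymer,
                          spec$gc_min, spec$gc_max, spec$blacklist) / config$s
    }, numeric(1))
  })
  rates <- tibble(
    delta = rep(deltas, each = config$t),
    trial = rep(seq_len(config$t), times = config$r),
    rate = unlist(raw))
  means <- vapply(raw, mean, numeric(1))
  all_zero <- all(means == 0)
  if (all_zero) {
    warn("All grid points scored a zero pass rate; returning the smallest delta.",
         class = "barcodeforge_all_zero_grid")
  }
  best <- which(means == max(means))[1] # ties toward smallest delta
  structure(
    list(delta = deltas[best],
         summary = tibble(delta = deltas, mean_rate = means),
         rates = rates, all_zero = all_zero, config = config),
    class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> selected delta = %g (mean pass rate %.3f)\n",
              x$delta, x$summary$mean_rate[x$summary$delta == x$delta]))
  print(x$summary)
  invisible(x)
}

#' @rdname select_delta
#' @param x A `grid_search_result`.
#' @param ... Unused.
#' @export
tidy.grid_search_result <- function(x, ...) x$summary

#' @rdname select_delta
#' @export
glance.grid_search_result <- function(x, ...) {
  tibble(delta = x$delta,
         mean_rate = x$summary$mean_rate[x$summary$delta == x$delta][1],
         r = x$config$r, s = x$config$s, t = x$config$t,
         all_zero = x$all_zero)
}

#' @rdname select_delta
#' @param object A `grid_search_result`.
#' @export
autoplot.grid_search_result <- function(object, ...) {
  ggplot2::ggplot(object$rates, ggplot2::aes(x = .data$delta, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(y = .data$mean_rate)) +
    ggplot2::geom_vline(xintercept = object$delta, linetype = 2) +
    ggplot2::labs(x = expression(delta), y = "candidate pass rate",
                  title = "Grid search for the Markov repeat parameter") +
    ggplot2::theme_minimal()
}
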