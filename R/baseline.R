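# Naive single-piece baseline, benchmark harness, and runtime extrapolation.

#' Generate barcodes with the naive single-piece framework
#'
#' Candidates of full length `L` are drawn uniformly at random and accepted
#' iff they pass the composition filters and are at Hamming distance >=
#' `spec$min_distance` from every previously accepted barcode. The run may be
#' budgeted with `max_candidates`; on budget exhaustion it returns the
#' partial library with `completed = FALSE` (a reported state, not an error),
#' together with progress checkpoints suitable for
#' [extrapolate_completion()].
#'
#' @param N Library size goal (integer >= 1).
#' @param L Barcode length in bp.
#' @param spec A [filter_spec()].
#' @param max_candidates Proposal budget (default unbounded).
#' @param seed Optional integer seed.
#' @return A `naive_codes` object: `$codes` character vector, `$stats`
#'   generation-statistics tibble, `$completed`, `$checkpoints` tibble of
#'   `(codes_generated, elapsed_time)` progress points.
#' @export
generate_naive <- function(N, L, spec, max_candidates = Inf, seed = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.numeric(N) || N < 1) {
    abort("`N` must be >= 1.", class = "barcodeforge_invalid_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_generate_naive(as.integer(N), as.integer(L),
                            spec$max_homopolymer, spec$gc_min, spec$gc_max,
                            spec$blacklist, spec$min_distance,
                            max_candidates)
  stats <- new_generation_stats("naive", raw, delta = 0.25,
                                elapsed = raw$elapsed)
  structure(
    list(codes = raw$codes, stats = stats, completed = raw$completed,
         checkpoints = tibble(codes_generated = raw$checkpoint_codes,
                              elapsed_time = raw$checkpoint_secs),
         spec = spec),
    class = "naive_codes")
}

#' @export
print.naive_codes <- function(x, ...) {
  cat(sprintf("<naive_codes> %d barcodes (completed: %s)\n",
              length(x$codes), x$completed))
  cat(sprintf("  acceptance rate %.4f (%d / %d proposals)\n",
              x$stats$acceptance_rate, as.integer(x$stats$accepted),
              as.integer(x$stats$proposed)))
  invisible(x)
}

#' Extrapolate completion time on a double-logarithmic scale
#'
#' Ordinary least squares of `log(elapsed_time)` on `log(codes_generated)`;
#' the predicted completion time for `N_goal` codes is
#' `exp(intercept + slope * log(N_goal))`. With points from an exact power
#' law the fit passes through them exactly.
#'
#' @param progress A data frame (or `naive_codes` checkpoints tibble) with
#'   positive columns `codes_generated` and `elapsed_time`.
#' @param N_goal Library size for which to predict the completion time.
#' @return One-row tibble with `predicted_time`, `slope`, `intercept`,
#'   `n_points`.
#' @export
extrapolate_completion <- function(progress, N_goal) {
  if (inherits(progress, "naive_codes")) progress <- progress$checkpoints
  progress <- as.data.frame(progress)
  if (!all(c("codes_generated", "elapsed_time") %in% names(progress))) {
    abort("`progress` needs columns codes_generated and elapsed_time.",
          class = "barcodeforge_invalid_argument")
  }
  if (nrow(progress) < 2) {
    abort("At least 2 progress points are required.",
          class = "barcodeforge_invalid_argument")
  }
  if (any(progress$codes_generated <= 0) || any(progress$elapsed_time <= 0) ||
      N_goal <= 0) {
    abort("Progress coordinates and `N_goal` must be positive.",
          class = "barcodeforge_invalid_argument")
  }
  fit <- lm(log(elapsed_time) ~ log(codes_generated), data = progress)
  cf <- coef(fit)
  tibble(predicted_time = exp(cf[[1]] + cf[[2]] * log(N_goal)),
         slope = cf[[2]], intercept = cf[[1]], n_points = nrow(progress))
}

#' Benchmark the generation frameworks
#'
#' Executes the requested frameworks on each `(m, L)` configuration and
#' records the pooled acceptance rate and elapsed time, one row per
#' (framework, configuration). Naive runs are budgeted via
#' `naive_max_candidates` and, when incomplete, the completion time is
#' extrapolated from progress checkpoints on the log-log scale.
#'
#' @param configs Data frame with columns `m` and `L` (one row per
#'   configuration).
#' @param frameworks Subset of `c("naive", "A", "B")`.
#' @param n_b,n_t,l_b Component geometry shared by all configurations
#'   (`l_t = L - l_b - 2` per row).
#' @param d,gc_min,gc_max,blacklist Filter parameters shared by all
#'   configurations (`m` varies per row).
#' @param budget_mode Distance-budget policy.
#' @param grid A [grid_search_config()] for Framework B.
#' @param naive_max_candidates Proposal budget per naive run.
#' @param seed Optional integer seed (one stream for the whole benchmark).
#' @return A tibble with columns `framework`, `m`, `L`, `acceptance_rate`,
#'   `batch_rate`, `target_rate`, `delta`, `proposed`, `accepted`,
#'   `hamming_comparisons`, `elapsed`, `completed`, `extrapolated_time`.
#' @export
run_benchmark <- function(configs, frameworks = c("A", "B"),
                          n_b = 100, n_t = 10000, l_b = 10,
                          d = 4, gc_min = 0.35, gc_max = 0.65,
                          blacklist = blacklist_preset("pcomb3x"),
                          budget_mode = "split",
                          grid = grid_search_config(),
                          naive_max_candidates = 1e5, seed = NULL) {
  configs <- as.data.frame(configs)
  stopifnot(all(c("m", "L") %in% names(configs)))
  frameworks <- match.arg(frameworks, c("naive", "A", "B"),
                          several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(configs))) {
    m <- configs$m[i]
    L <- configs$L[i]
    spec <- filter_spec(min_distance = d, max_homopolymer = m,
                        gc_min = gc_min, gc_max = gc_max,
                        blacklist = blacklist)
    design <- library_design(n_b = n_b, n_t = n_t, l_b = l_b, L = L)
    for (fw in frameworks) {
      if (fw == "naive") {
        t0 <- proc.time()[["elapsed"]]
        nv <- generate_naive(design$N, L, spec,
                             max_candidates = naive_max_candidates)
        elapsed <- proc.time()[["elapsed"]] - t0
        extrap <- if (!nv$completed && nrow(nv$checkpoints) >= 2) {
          extrapolate_completion(nv$checkpoints, design$N)$predicted_time
        } else NA_real_
        rows[[length(rows) + 1]] <- tibble(
          framework = "naive", m = m, L = L,
          acceptance_rate = nv$stats$acceptance_rate,
          batch_rate = NA_real_, target_rate = NA_real_,
          delta = 0.25, proposed = nv$stats$proposed,
          accepted = nv$stats$accepted,
          hamming_comparisons = nv$stats$hamming_comparisons,
          elapsed = elapsed, completed = nv$completed,
          extrapolated_time = extrap)
      } else {
        t0 <- proc.time()[["elapsed"]]
        run <- generate_library(design, spec, framework = fw,
                                budget_mode = budget_mode, grid = grid)
        elapsed <- proc.time()[["elapsed"]] - t0
        s <- run$stats
        rows[[length(rows) + 1]] <- tibble(
          framework = fw, m = m, L = L,
          acceptance_rate = s$acceptance_rate[s$phase == "pooled"],
          batch_rate = s$acceptance_rate[s$phase == "batch"],
          target_rate = s$acceptance_rate[s$phase == "target"],
          delta = run$delta,
          proposed = s$proposed[s$phase == "pooled"],
          accepted = s$accepted[s$phase == "pooled"],
          hamming_comparisons = s$hamming_comparisons[s$phase == "pooled"],
          elapsed = elapsed, completed = TRUE,
          extrapolated_time = NA_real_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Render a benchmark table
#'
#' @param bench A tibble from [run_benchmark()].
#' @return A character vector of table lines (also printed).
#' @export
format_benchmark <- function(bench) {
  lines <- c(sprintf("%-10s %3s %8s %15s %10s", "Framework", "m",
                     "Length", "Acceptance rate", "Time (s)"),
             strrep("-", 52))
  for (i in seq_len(nrow(bench))) {
    time <- if (!bench$completed[i] && !is.na(bench$extrapolated_time[i])) {
      sprintf("%.0f*", bench$extrapolated_time[i])
    } else sprintf("%.1f", bench$elapsed[i])
    lines <- c(lines, sprintf("%-10s %3d %8d %15.3f %10s",
                              bench$framework[i], bench$m[i], bench$L[i],
                              bench$acceptance_rate[i], time))
  }
  if (any(!bench$completed)) {
    lines <- c(lines, "* extrapolated from log-log progress checkpoints")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
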