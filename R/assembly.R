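# Library splitting, cross-product assembly, and validation.

#' Split a library size into batch and target counts
#'
#' If both `n_b` and `n_t` are given, verifies `n_b * n_t >= N`. If one is
#' given, the other is `ceiling(N / given)`. If neither, `n_b = ceiling(sqrt(N))`
#' and `n_t = ceiling(N / n_b)` — the comparison-count advantage of the
#' two-component construction is maximized when the two counts are balanced.
#'
#' @param N Total library size (integer >= 1).
#' @param n_b,n_t Optional fixed component counts.
#' @return A list with integer fields `n_b` and `n_t`.
#' @examples
#' split_library_size(1e6, n_b = 100) # 100 x 10,000
#' split_library_size(9)              # 3 x 3
#' @export
split_library_size <- function(N, n_b = NULL, n_t = NULL) {
  if (!is.numeric(N) || length(N) != 1 || N < 1) {
    abort("`N` must be a single integer >= 1.",
          class = "barcodeforge_invalid_argument")
  }
  if (!is.null(n_b) && n_b < 1 || !is.null(n_t) && n_t < 1) {
    abort("Component counts must be positive.",
          class = "barcodeforge_invalid_argument")
  }
  if (!is.null(n_b) && !is.null(n_t)) {
    if (n_b * n_t < N) {
      abort(sprintf("Infeasible split: n_b * n_t = %g < N = %g.",
                    n_b * n_t, N),
            class = "barcodeforge_infeasible")
    }
  } else if (!is.null(n_b)) {
    n_t <- ceiling(N / n_b)
  } else if (!is.null(n_t)) {
    n_b <- ceiling(N / n_t)
  } else {
    n_b <- ceiling(sqrt(N))
    n_t <- ceiling(N / n_b)
  }
  list(n_b = as.integer(n_b), n_t = as.integer(n_t))
}

#' Assemble the cross-product library in memory
#'
#' Emits `linked_batch + target` for all pairs in batch-major order (batch 1
#' with every target, then batch 2, ...), truncated to the first `N` barcodes
#' when `N` is given. For file-scale libraries use the streaming
#' [expand_library()] instead.
#'
#' @param linked_batches Character vector of linked batch codes.
#' @param targets Character vector of target codes.
#' @param N Optional truncation size.
#' @return Character vector of assembled barcodes.
#' @export
assemble_library <- function(linked_batches, targets, N = NULL) {
  linked_batches <- as_dna(linked_batches, "linked_batches")
  targets <- as_dna(targets, "targets")
  total <- length(linked_batches) * length(targets)
  if (is.null(N)) N <- total
  if (N > total) {
    abort("`N` exceeds n_b * n_t.", class = "barcodeforge_infeasible")
  }
  out <- as.vector(t(outer(linked_batches, targets, paste0)))
  head(out, N)
}

#' Barcode library container
#'
#' Bundles the two component sets with their design, constraint spec, and
#' distance budget.
#'
#' @param linked_batches Character vector of linked batch codes.
#' @param targets Character vector of target codes.
#' @param spec A [filter_spec()].
#' @param budget A [distance_budget()].
#' @param design Optional [library_design()]; derived from the components
#'   when missing.
#' @return A `barcode_library` object.
#' @export
barcode_library <- function(linked_batches, targets, spec, budget,
                            design = NULL) {
  linked_batches <- as_dna(linked_batches, "linked_batches")
  targets <- as_dna(targets, "targets")
  stopifnot(length(linked_batches) >= 1, length(targets) >= 1)
  if (length(unique(nchar(linked_batches))) != 1 ||
      length(unique(nchar(targets))) != 1) {
    abort("Component sequences must have uniform lengths.",
          class = "barcodeforge_malformed_library")
  }
  if (is.null(design)) {
    design <- library_design(
      n_b = length(linked_batches), n_t = length(targets),
      l_b = nchar(linked_batches[1]) - 2L, l_t = nchar(targets[1]))
  }
  if (nchar(linked_batches[1]) + nchar(targets[1]) != design$L) {
    abort("Component lengths are inconsistent with the design's L.",
          class = "barcodeforge_malformed_library")
  }
  structure(list(linked_batches = linked_batches, targets = targets,
                 design = design, spec = spec, budget = budget),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("<barcode_library> %d x %d = %s barcodes of length %d bp\n",
              length(x$linked_batches), length(x$targets),
              format(length(x$linked_batches) * as.numeric(length(x$targets)),
                     big.mark = ","),
              x$design$L))
  invisible(x)
}

#' Validate a barcode library
#'
#' Computes the minimum pairwise Hamming distance within each pair class of
#' the assembled library — pairs sharing a batch code, pairs sharing a target
#' code, and pairs differing in both components — and scans every assembled
#' concatenation for composition-filter violations.
#'
#' `mode = "structured"` exploits the additive decomposition
#' `d(B_i + t_a, B_j + t_b) = d(B_i, B_j) + d(t_a, t_b)`: the three minima
#' follow from the component pairwise minima, so the Hamming side costs
#' O(n_b^2 + n_t^2) instead of O((n_b n_t)^2). `mode = "exhaustive"`
#' computes all pairwise full-barcode distances directly (small libraries
#' only). Both modes agree wherever both run.
#'
#' @param library A [barcode_library()].
#' @param mode `"structured"` (default) or `"exhaustive"`.
#' @param max_report Maximum number of located violations to return.
#' @return A `validation_report` with fields `minima` (tibble of the three
#'   class minima and the overall minimum), `violations` (tibble locating
#'   composition failures), `n_violations`, and logical summary fields
#'   `composition_ok`, `global_distance_ok` (overall minimum >= spec d),
#'   `budget_ok` (component minima >= `d_b`, `d_t`).
#' @export
validate_library <- function(library, mode = c("structured", "exhaustive"),
                             max_report = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "barcode_library"))
  lb <- library$linked_batches
  tg <- library$targets
  spec <- library$spec
  budget <- library$budget
  if (mode == "structured") {
    min_b <- cpp_pairwise_min(lb)$min
    min_t <- cpp_pairwise_min(tg)$min
    same_batch <- min_t               # batch shared, targets differ
    same_target <- min_b              # target shared, batches differ
    diff_both <- if (is.finite(min_b) && is.finite(min_t)) min_b + min_t
                 else Inf
    overall <- min(same_batch, same_target, diff_both)
  } else {
    mins <- cpp_exhaustive_minima(lb, tg)
    same_batch <- mins$same_batch
    same_target <- mins$same_target
    diff_both <- mins$diff_both
    overall <- mins$overall
  }
  scan <- cpp_scan_library(lb, tg, spec$max_homopolymer, spec$gc_min,
                           spec$gc_max, spec$blacklist,
                           as.integer(max_report))
  filters <- c("homopolymer", "gc_content", "blacklist")
  violations <- tibble(
    batch_index = as.integer(scan$batch_index),
    target_index = as.integer(scan$target_index),
    filter = filters[scan$filter_code],
    barcode = paste0(lb[scan$batch_index], tg[scan$target_index]))
  minima <- tibble(
    pair_class = c("same_batch", "same_target", "diff_both", "overall"),
    min_distance = c(same_batch, same_target, diff_both, overall))
  structure(
    list(minima = minima, violations = violations,
         n_violations = scan$violations,
         composition_ok = scan$violations == 0,
         global_distance_ok = is.finite(overall) &&
           overall >= spec$min_distance,
         budget_ok = (!is.finite(same_target) || same_target >= budget$d_b) &&
           (!is.finite(same_batch) || same_batch >= budget$d_t),
         mode = mode, spec = spec, budget = budget),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> (%s mode)\n", x$mode))
  print(x$minima)
  cat(sprintf("  composition violations: %g\n", x$n_violations))
  cat(sprintf("  budget satisfied (d_b = %d, d_t = %d): %s\n",
              x$budget$d_b, x$budget$d_t, x$budget_ok))
  cat(sprintf("  global minimum >= d = %d: %s\n",
              x$spec$min_distance, x$global_distance_ok))
  invisible(x)
}

#' @rdname validate_library
#' @param x,object A `validation_report`.
#' @param ... Unused.
#' @export
tidy.validation_report <- function(x, ...) x$minima

#' @rdname validate_library
#' @export
glance.validation_report <- function(x, ...) {
  tibble(mode = x$mode, n_violations = x$n_violations,
         composition_ok = x$composition_ok,
         global_distance_ok = x$global_distance_ok,
         budget_ok = x$budget_ok)
}
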