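# Sequence alphabet, constraint specification, and filter primitives.

DNA_BASES <- c("A", "C", "G", "T")

#' Canonicalize DNA sequences
#'
#' Upper-cases character input and verifies that every character is one of
#' `A`, `C`, `G`, `T`. Empty strings are permitted (a zero-length sequence).
#'
#' @param x Character vector of sequences.
#' @param arg Name used in error messages.
#' @return The canonicalized character vector.
#' @export
as_dna <- function(x, arg = "x") {
  if (length(x) == 0) return(character())
  if (!is.character(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a character vector without NA.", arg),
          class = "barcodeforge_invalid_sequence")
  }
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("`%s` contains non-ACGT characters (first offender: '%s').",
                  arg, x[which(bad)[1]]),
          class = "barcodeforge_invalid_sequence")
  }
  x
}

#' Hamming distance between equal-length sequences
#'
#' Counts mismatching positions. Vectorized elementwise over `a` and `b`
#' (recycling length-1 inputs).
#'
#' @param a,b Character vectors of DNA sequences with equal per-pair lengths.
#' @return Integer vector of distances.
#' @examples
#' hamming_distance("ACGT", "ACGT")
#' hamming_distance("AAAAA", "TTTTT")
#' @export
hamming_distance <- function(a, b) {
  a <- as_dna(a, "a")
  b <- as_dna(b, "b")
  if (length(a) != length(b)) {
    if (length(a) == 1) a <- rep(a, length(b))
    else if (length(b) == 1) b <- rep(b, length(a))
    else abort("`a` and `b` must have the same length (or length 1).",
               class = "barcodeforge_length_mismatch")
  }
  if (any(nchar(a) != nchar(b))) {
    abort("Hamming distance requires equal-length sequences.",
          class = "barcodeforge_length_mismatch")
  }
  cpp_hamming(a, b)
}

#' Longest homopolymer run
#'
#' Length of the longest run of identical consecutive bases; 0 for the
#' empty sequence.
#'
#' @param a Character vector of DNA sequences.
#' @return Integer vector of run lengths.
#' @examples
#' max_homopolymer_run(c("ACGT", "AATTTG", "GGGG"))
#' @export
max_homopolymer_run <- function(a) {
  a <- as_dna(a, "a")
  cpp_max_run(a)
}

#' GC fraction
#'
#' Fraction of G or C bases, as an exact rational count / length.
#'
#' @param a Character vector of non-empty DNA sequences.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' gc_fraction(c("GCGC", "ATAT", "ACGT"))
#' @export
gc_fraction <- function(a) {
  a <- as_dna(a, "a")
  if (any(nchar(a) == 0)) {
    abort("GC fraction is undefined for the empty sequence.",
          class = "barcodeforge_undefined_input")
  }
  cpp_gc_count(a) / nchar(a)
}

#' Blacklist substring screen
#'
#' `TRUE` iff any blacklist entry occurs as a contiguous substring (forward
#' strand, exact match). Set `revcomp = TRUE` to additionally scan for the
#' reverse complement of each entry (off by default).
#'
#' @param a Character vector of DNA sequences.
#' @param blacklist Character vector of proscribed subsequences.
#' @param revcomp Also match reverse complements of blacklist entries.
#' @return Logical vector.
#' @examples
#' contains_blacklisted("TTTCTAGAA", "TCTAGA")
#' @export
contains_blacklisted <- function(a, blacklist, revcomp = FALSE) {
  a <- as_dna(a, "a")
  blacklist <- as_dna(blacklist, "blacklist")
  if (isTRUE(revcomp)) blacklist <- unique(c(blacklist, reverse_complement(blacklist)))
  cpp_contains_blacklisted(a, blacklist)
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- as_dna(x)
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Constraint specification
#'
#' Bundles the four filter parameters: minimum pairwise Hamming distance `d`,
#' maximum homopolymer length `m`, inclusive GC-content bounds, and a
#' blacklist of proscribed subsequences.
#'
#' @param min_distance Minimum pairwise Hamming distance `d` (integer >= 0).
#' @param max_homopolymer Maximum allowed homopolymer run `m` (integer >= 1).
#' @param gc_min,gc_max GC-content bounds as fractions in \[0, 1\].
#' @param blacklist Character vector of proscribed subsequences.
#' @return A `filter_spec` object.
#' @examples
#' filter_spec(min_distance = 4, max_homopolymer = 2,
#'             gc_min = 0.35, gc_max = 0.65,
#'             blacklist = blacklist_preset("pcomb3x"))
#' @export
filter_spec <- function(min_distance = 4, max_homopolymer = 2,
                        gc_min = 0, gc_max = 1, blacklist = character()) {
  if (!is.numeric(min_distance) || length(min_distance) != 1 ||
      min_distance < 0 || min_distance != floor(min_distance)) {
    abort("`min_distance` must be a single integer >= 0.",
          class = "barcodeforge_invalid_spec")
  }
  if (!is.numeric(max_homopolymer) || length(max_homopolymer) != 1 ||
      max_homopolymer < 1 || max_homopolymer != floor(max_homopolymer)) {
    abort("`max_homopolymer` must be a single integer >= 1.",
          class = "barcodeforge_invalid_spec")
  }
  if (!is.numeric(gc_min) || !is.numeric(gc_max) ||
      gc_min < 0 || gc_max > 1 || gc_min > gc_max) {
    abort("GC bounds must satisfy 0 <= gc_min <= gc_max <= 1.",
          class = "barcodeforge_invalid_spec")
  }
  blacklist <- as_dna(blacklist, "blacklist")
  structure(
    list(min_distance = as.integer(min_distance),
         max_homopolymer = as.integer(max_homopolymer),
         gc_min = as.numeric(gc_min), gc_max = as.numeric(gc_max),
         blacklist = blacklist),
    class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec>\n")
  cat("  min Hamming distance d:", x$min_distance, "\n")
  cat("  max homopolymer m:     ", x$max_homopolymer, "\n")
  cat(sprintf("  GC bounds:              [%.3g, %.3g]\n", x$gc_min, x$gc_max))
  cat("  blacklist entries:     ", length(x$blacklist), "\n")
  invisible(x)
}

#' Composition-filter report
#'
#' Evaluates the homopolymer, GC-content, and blacklist filters for each
#' sequence (the Hamming filter operates on pairs and is handled by the
#' generators/validator, not here). Returns one row per sequence with a
#' logical column per filter and `pass` as their conjunction.
#'
#' @param a Character vector of non-empty DNA sequences.
#' @param spec A [filter_spec()].
#' @return A tibble with columns `sequence`, `homopolymer`, `gc_content`,
#'   `blacklist`, `pass`.
#' @export
passes_composition_filters <- function(a, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  a <- as_dna(a, "a")
  if (any(nchar(a) == 0)) {
    abort("Composition filters require non-empty sequences.",
          class = "barcodeforge_undefined_input")
  }
  n <- nchar(a)
  homopolymer <- cpp_max_run(a) <= spec$max_homopolymer
  gc <- cpp_gc_count(a)
  gc_content <- gc >= spec$gc_min * n - 1e-9 & gc <= spec$gc_max * n + 1e-9
  blacklist <- !cpp_contains_blacklisted(a, spec$blacklist)
  tibble(sequence = a, homopolymer = homopolymer, gc_content = gc_content,
         blacklist = blacklist,
         pass = homopolymer & gc_content & blacklist)
}

#' Library design geometry
#'
#' Fixes the library size and the decomposition of the barcode length
#' `L = l_b + l_t + 2` into batch code, 2-bp linker, and target code.
#' Missing counts are resolved with [split_library_size()]; a missing `L` or
#' `l_t` is derived from the length identity.
#'
#' @param N Total number of barcodes (defaults to `n_b * n_t`).
#' @param n_b,n_t Numbers of batch and target codes (resolved from `N` when
#'   missing).
#' @param L Barcode length in bp.
#' @param l_b,l_t Batch-code and target-code lengths in bp.
#' @return A `library_design` object.
#' @examples
#' library_design(N = 1e6, n_b = 100, l_b = 10, L = 25)
#' @export
library_design <- function(N = NULL, n_b = NULL, n_t = NULL,
                           L = NULL, l_b = NULL, l_t = NULL) {
  if (is.null(l_b)) {
    abort("`l_b` (batch-code length) is required.",
          class = "barcodeforge_invalid_spec")
  }
  if (is.null(l_t) && is.null(L)) {
    abort("Provide `l_t` or `L` (L = l_b + l_t + 2).",
          class = "barcodeforge_invalid_spec")
  }
  if (is.null(l_t)) l_t <- L - l_b - 2L
  if (is.null(L)) L <- l_b + l_t + 2L
  if (L != l_b + l_t + 2) {
    abort("Length identity violated: L must equal l_b + l_t + 2.",
          class = "barcodeforge_invalid_spec")
  }
  if (l_b < 1 || l_t < 1) {
    abort("Component lengths must be >= 1 bp.",
          class = "barcodeforge_invalid_spec")
  }
  if (is.null(N) && (is.null(n_b) || is.null(n_t))) {
    abort("Provide `N`, or both `n_b` and `n_t`.",
          class = "barcodeforge_invalid_spec")
  }
  if (is.null(N)) N <- n_b * n_t
  counts <- split_library_size(N, n_b = n_b, n_t = n_t)
  structure(
    list(N = N, n_b = counts$n_b, n_t = counts$n_t,
         L = as.integer(L), l_b = as.integer(l_b), l_t = as.integer(l_t),
         linker_len = 2L),
    class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>\n")
  cat(sprintf("  N = %s barcodes (%s batch x %s target)\n",
              format(x$N, big.mark = ","), x$n_b, x$n_t))
  cat(sprintf("  L = %d bp = %d (batch) + 2 (linker) + %d (target)\n",
              x$L, x$l_b, x$l_t))
  invisible(x)
}

#' Per-component minimum-distance budget
#'
#' Splits the library-wide minimum Hamming distance `d` into per-component
#' minima. Batch codes use the halving rule
#' `d_b = floor(d/2)` when `l_b <= l_t`, else `floor((d-1)/2)`. The target
#' threshold `d_t` is not determined by the batch rule; two policies are
#' offered:
#'
#' * `mode = "split"` (default): `d_t = d - d_b`, consistent with the
#'   halving rule for `d_b` — barcodes differing in both components are
#'   >= `d` apart by the additive decomposition.
#' * `mode = "strict"`: `d_t = d`, so any two barcodes sharing a batch code
#'   are >= `d` apart, at the cost of far heavier target-phase rejection.
#'
#' The validator reports the minima realized under both regimes.
#'
#' @param d Library-wide minimum Hamming distance (integer >= 0).
#' @param l_b,l_t Component lengths in bp.
#' @param mode Budget policy, `"strict"` or `"split"`.
#' @return A `distance_budget` object with fields `d_b`, `d_t`, `mode`.
#' @examples
#' distance_budget(4, l_b = 10, l_t = 13, mode = "split")
#' distance_budget(5, l_b = 10, l_t = 13, mode = "strict")
#' @export
distance_budget <- function(d, l_b, l_t, mode = c("split", "strict")) {
  mode <- match.arg(mode)
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d != floor(d)) {
    abort("`d` must be a single integer >= 0.",
          class = "barcodeforge_invalid_spec")
  }
  if (l_b < 1 || l_t < 1) {
    abort("Component lengths must be >= 1 bp.",
          class = "barcodeforge_invalid_spec")
  }
  d_b <- if (l_b <= l_t) floor(d / 2) else floor((d - 1) / 2)
  d_b <- max(0L, as.integer(d_b))
  d_t <- if (mode == "split") as.integer(d - d_b) else as.integer(d)
  if (d_b > l_b + 2 || d_t > l_t) {
    abort(sprintf(
      "Infeasible distance budget: d_b = %d (max %d), d_t = %d (max %d).",
      d_b, l_b + 2, d_t, l_t),
      class = "barcodeforge_infeasible")
  }
  structure(list(d_b = d_b, d_t = d_t, mode = mode),
            class = "distance_budget")
}

#' @export
print.distance_budget <- function(x, ...) {
  cat(sprintf("<distance_budget> d_b = %d, d_t = %d (mode = %s)\n",
              x$d_b, x$d_t, x$mode))
  invisible(x)
}
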