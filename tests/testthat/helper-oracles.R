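# Independent reference implementations used as oracles. These deliberately
# use plain character-level R (strsplit loops, grepl) and never call the
# package's computational path.

oracle_hamming <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  sum(x != y)
}

oracle_max_run <- function(s) {
  if (nchar(s) == 0) return(0L)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

oracle_gc <- function(s) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(x %in% c("G", "C")) / length(x)
}

oracle_blacklisted <- function(s, blacklist) {
  any(vapply(blacklist, function(b) grepl(b, s, fixed = TRUE), logical(1)))
}

oracle_comp_pass <- function(s, spec) {
  n <- nchar(s)
  oracle_max_run(s) <= spec$max_homopolymer &&
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C")) >=
      spec$gc_min * n - 1e-9 &&
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C")) <=
      spec$gc_max * n + 1e-9 &&
    (length(spec$blacklist) == 0 || !oracle_blacklisted(s, spec$blacklist))
}

oracle_min_pairwise <- function(codes) {
  if (length(codes) < 2) return(Inf)
  best <- Inf
  for (i in seq_along(codes)) {
    for (j in seq_len(i - 1)) {
      best <- min(best, oracle_hamming(codes[i], codes[j]))
    }
  }
  best
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Probability of a full sequence under the order-m Markov model (uniform
# first base, repeat probability delta^h with h the trailing run capped at
# min(m, k)).
oracle_markov_prob <- function(s, delta, order_m) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  p <- 1 / 4
  if (length(x) >= 2) {
    run <- 1L
    for (k in seq(2, length(x))) {
      h <- min(order_m, run)
      p_rep <- delta^h
      if (x[k] == x[k - 1]) {
        p <- p * p_rep
        run <- run + 1L
      } else {
        p <- p * (1 - p_rep) / 3
        run <- 1L
      }
    }
  }
  p
}

# All 4^len DNA sequences of a given (small) length.
all_kmers <- function(len) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), len),
                              stringsAsFactors = FALSE))
}

# A small deterministic clean batch set for grid-search/targetgen tests.
fixture_batches <- function() {
  c("ACGTAG", "TGCACT", "GATCGA", "CTAGTC")
}
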