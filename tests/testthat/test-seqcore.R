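test_that("hamming_distance matches the character-level oracle and its axioms", {
  expect_identical(hamming_distance("ACGT", "ACGT"), 0L)
  expect_identical(hamming_distance("AAAAA", "TTTTT"), 5L)
  expect_error(hamming_distance("ACG", "ACGT"),
               class = "barcodeforge_length_mismatch")

  set.seed(101)
  for (len in c(1, 7, 32, 33, 64, 65)) {
    a <- random_dna(40, len)
    b <- random_dna(40, len)
    expect_identical(hamming_distance(a, b),
                     mapply(oracle_hamming, a, b, USE.NAMES = FALSE))
    # symmetry
    expect_identical(hamming_distance(a, b), hamming_distance(b, a))
  }
  # triangle inequality on random triples
  a <- random_dna(200, 20); b <- random_dna(200, 20); c <- random_dna(200, 20)
  expect_true(all(hamming_distance(a, c) <=
                    hamming_distance(a, b) + hamming_distance(b, c)))
  # zero iff equal
  expect_true(all((hamming_distance(a, b) == 0) == (a == b)))
})

test_that("full-barcode distance decomposes additively over components", {
  set.seed(102)
  batches <- random_dna(6, 12)
  targets <- random_dna(6, 9)
  for (r in seq_len(50)) {
    i <- sample(6, 2, replace = TRUE)
    j <- sample(6, 2, replace = TRUE)
    full <- hamming_distance(paste0(batches[i[1]], targets[j[1]]),
                             paste0(batches[i[2]], targets[j[2]]))
    expect_identical(full,
                     hamming_distance(batches[i[1]], batches[i[2]]) +
                       hamming_distance(targets[j[1]], targets[j[2]]))
  }
})

test_that("max_homopolymer_run and gc_fraction agree with oracles", {
  expect_identical(max_homopolymer_run(c("ACGT", "AATTTG", "GGGG")),
                   c(1L, 3L, 4L))
  expect_identical(max_homopolymer_run(""), 0L)
  expect_equal(gc_fraction(c("GCGC", "ATAT", "ACGT")), c(1, 0, 0.5))
  expect_error(gc_fraction(""), class = "barcodeforge_undefined_input")

  set.seed(103)
  x <- random_dna(300, 17)
  expect_identical(max_homopolymer_run(x),
                   vapply(x, oracle_max_run, integer(1), USE.NAMES = FALSE))
  expect_equal(gc_fraction(x),
               vapply(x, oracle_gc, numeric(1), USE.NAMES = FALSE))
})

test_that("blacklist screening is exact forward-strand substring matching", {
  expect_true(contains_blacklisted("TTTCTAGAA", "TCTAGA"))
  expect_false(contains_blacklisted("ACGTACGT", character()))
  expect_false(contains_blacklisted("ACG", "ACGT")) # pattern longer than text
  # junction-free equivalence with grepl on random inputs
  set.seed(104)
  bl <- c("TCTAGA", "GAAGAC", "AGGAGG")
  x <- random_dna(500, 30)
  expect_identical(contains_blacklisted(x, bl),
                   vapply(x, oracle_blacklisted, logical(1), blacklist = bl,
                          USE.NAMES = FALSE))
  # reverse-complement option is off by default
  expect_false(contains_blacklisted("TCTAGC", "GCTAGA"))
  expect_true(contains_blacklisted("TCTAGC", "GCTAGA", revcomp = TRUE))
})

test_that("sequences are canonicalized to uppercase; other characters error", {
  expect_identical(as_dna("acgt"), "ACGT")
  expect_identical(hamming_distance("acgt", "ACGT"), 0L)
  expect_error(as_dna("ACGN"), class = "barcodeforge_invalid_sequence")
  expect_error(as_dna("ACG-T"), class = "barcodeforge_invalid_sequence")
})

test_that("composition report equals recomputation from the three primitives", {
  spec <- filter_spec(min_distance = 4, max_homopolymer = 3,
                      gc_min = 0.35, gc_max = 0.65,
                      blacklist = c("TCTAGA", "GAGCTC"))
  seq_with_run <- "AACCCCGT" # run of 4 > m = 3
  rep1 <- passes_composition_filters(seq_with_run, spec)
  expect_false(rep1$homopolymer)
  expect_false(rep1$pass)

  spec25 <- filter_spec(4, 2, 0.35, 0.65)
  rep2 <- passes_composition_filters("ACGTACGTACGTAGCTAGCTAGCTA", spec25)
  expect_true(rep2$gc_content) # 25 bp at GC 0.48, bounds [0.35, 0.65]

  set.seed(105)
  x <- random_dna(5000, 18)
  rep_ <- passes_composition_filters(x, spec)
  expect_equal(rep_$homopolymer, max_homopolymer_run(x) <= spec$max_homopolymer)
  expect_equal(rep_$gc_content,
               gc_fraction(x) >= spec$gc_min - 1e-12 &
                 gc_fraction(x) <= spec$gc_max + 1e-12)
  expect_equal(rep_$blacklist, !contains_blacklisted(x, spec$blacklist))
  expect_equal(rep_$pass, rep_$homopolymer & rep_$gc_content & rep_$blacklist)
})

test_that("relaxing constraints never turns a composition pass into a fail", {
  set.seed(106)
  x <- random_dna(400, 15)
  tight <- filter_spec(4, 2, 0.4, 0.6, blacklist = c("TCTAGA", "GAAGAC", "ACTAGT"))
  relaxed_m <- filter_spec(4, 4, 0.4, 0.6, blacklist = tight$blacklist)
  relaxed_gc <- filter_spec(4, 2, 0.2, 0.8, blacklist = tight$blacklist)
  relaxed_bl <- filter_spec(4, 2, 0.4, 0.6, blacklist = "TCTAGA")
  p0 <- passes_composition_filters(x, tight)$pass
  for (relaxed in list(relaxed_m, relaxed_gc, relaxed_bl)) {
    p1 <- passes_composition_filters(x, relaxed)$pass
    expect_true(all(p1[p0])) # pass set can only grow
  }
})

test_that("distance budget follows the halving rule in both modes", {
  b <- distance_budget(4, l_b = 10, l_t = 13, mode = "split")
  expect_identical(c(b$d_b, b$d_t), c(2L, 2L))
  b <- distance_budget(4, l_b = 38, l_t = 13, mode = "split")
  expect_identical(c(b$d_b, b$d_t), c(1L, 3L))
  b <- distance_budget(5, l_b = 10, l_t = 13, mode = "strict")
  expect_identical(c(b$d_b, b$d_t), c(2L, 5L))
  # infeasible: d_t exceeds the target length
  expect_error(distance_budget(8, l_b = 10, l_t = 5, mode = "strict"),
               class = "barcodeforge_infeasible")
  # default is split
  expect_identical(distance_budget(4, 10, 13)$mode, "split")
})

test_that("filter_spec and library_design validate their invariants", {
  expect_error(filter_spec(gc_min = 0.7, gc_max = 0.3),
               class = "barcodeforge_invalid_spec")
  expect_error(filter_spec(max_homopolymer = 0),
               class = "barcodeforge_invalid_spec")
  d <- library_design(N = 1e6, n_b = 100, l_b = 10, L = 25)
  expect_identical(d$l_t, 13L)
  expect_identical(d$n_t, 10000L)
  expect_error(library_design(N = 100, l_b = 10, l_t = 13, L = 26),
               class = "barcodeforge_invalid_spec")
})
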