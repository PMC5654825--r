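test_that("library sizes split per the ceiling-sqrt rule and truncate correctly", {
  expect_identical(split_library_size(1e6, n_b = 100),
                   list(n_b = 100L, n_t = 10000L))
  expect_identical(split_library_size(9), list(n_b = 3L, n_t = 3L))
  s <- split_library_size(10)
  expect_identical(s, list(n_b = 4L, n_t = 3L))
  expect_error(split_library_size(100, n_b = 5, n_t = 5),
               class = "barcodeforge_infeasible")
  # truncation in assembly
  lib <- assemble_library(c("AAAA", "CCCC", "GGGG", "TTTT"),
                          c("AC", "GT", "CA"), N = 10)
  expect_identical(length(lib), 10L)
})

test_that("assembly enumerates batch-major with uniform barcode lengths", {
  lib <- assemble_library(c("ACGTAG", "TGCACT"), c("AAC", "GGT", "CTA"))
  expect_identical(lib, c("ACGTAGAAC", "ACGTAGGGT", "ACGTAGCTA",
                          "TGCACTAAC", "TGCACTGGT", "TGCACTCTA"))
  expect_true(all(nchar(lib) == 9))
})

test_that("structured and exhaustive validation agree on random small libraries", {
  spec <- filter_spec(min_distance = 2, max_homopolymer = 4,
                      gc_min = 0.2, gc_max = 0.8)
  set.seed(601)
  for (rep in 1:6) {
    n_b <- sample(2:20, 1)
    n_t <- sample(2:20, 1)
    batches <- unique(random_dna(n_b, 8))
    targets <- unique(random_dna(n_t, 6))
    budget <- distance_budget(2, l_b = 6, l_t = 6)
    lib <- barcode_library(batches, targets, spec, budget)
    st <- validate_library(lib, mode = "structured")
    ex <- validate_library(lib, mode = "exhaustive")
    expect_identical(st$minima, ex$minima)
    expect_identical(st$n_violations, ex$n_violations)
  }
})

test_that("validation minima honor the generated budget and locate injected faults", {
  spec <- filter_spec(min_distance = 4, max_homopolymer = 2,
                      gc_min = 0.35, gc_max = 0.65,
                      blacklist = "TCTAGA")
  design <- library_design(n_b = 10, n_t = 50, l_b = 8, L = 20)
  run <- generate_library(design, spec, framework = "A", seed = 602)
  report <- validate_library(run$library, mode = "structured")
  expect_true(report$composition_ok)
  expect_true(report$budget_ok)
  minima <- setNames(report$minima$min_distance, report$minima$pair_class)
  expect_gte(minima[["same_target"]], run$library$budget$d_b)
  expect_gte(minima[["same_batch"]], run$library$budget$d_t)

  # corrupt one target to create a forbidden run: detected and located
  bad <- run$library
  bad$targets[7] <- paste0(strrep("A", spec$max_homopolymer + 1),
                           substr(bad$targets[7], spec$max_homopolymer + 2,
                                  nchar(bad$targets[7])))
  bad_report <- validate_library(bad, mode = "structured")
  expect_false(bad_report$composition_ok)
  expect_true(all(bad_report$violations$target_index == 7))
  expect_true(all(bad_report$violations$filter == "homopolymer"))

  # inject a blacklist hit instead (GC bounds widened so the attribution
  # is unambiguous)
  bad2 <- run$library
  bad2$spec <- filter_spec(min_distance = 4, max_homopolymer = 2,
                           gc_min = 0, gc_max = 1, blacklist = "TCTAGA")
  bad2$targets[3] <- paste0("TCTAGA", substr(bad2$targets[3], 7,
                                             nchar(bad2$targets[3])))
  rep2 <- validate_library(bad2, mode = "structured")
  expect_false(rep2$composition_ok)
  expect_true(all(rep2$violations$filter == "blacklist"))
  expect_true(all(rep2$violations$target_index == 3))
})

test_that("component length mismatches raise a malformed-library error", {
  spec <- filter_spec(min_distance = 0, max_homopolymer = 10)
  budget <- distance_budget(0, 4, 4)
  expect_error(
    barcode_library(c("ACGTAG", "TGCACTA"), c("AAC", "GGT"), spec, budget),
    class = "barcodeforge_malformed_library")
})

test_that("the two-phase generator does asymptotically fewer Hamming comparisons", {
  spec <- filter_spec(min_distance = 4, max_homopolymer = 2,
                      gc_min = 0.35, gc_max = 0.65)
  design <- library_design(n_b = 40, n_t = 1000, l_b = 10, L = 25)
  run <- generate_library(design, spec, framework = "A", seed = 603)
  s <- run$stats
  n_b <- design$n_b
  proposals_t <- s$proposed[s$phase == "target"]
  accepted_t <- s$accepted[s$phase == "target"]
  comparisons <- s$hamming_comparisons[s$phase == "pooled"]
  # defensible bound: batch pairwise work + per-proposal target comparisons
  bound <- s$proposed[s$phase == "batch"] * n_b + proposals_t * accepted_t
  expect_lte(comparisons, bound)
  # and far below the naive single-set requirement N(N-1)/2
  N <- design$N
  expect_gt((N * (N - 1) / 2) / comparisons, 10)
})
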