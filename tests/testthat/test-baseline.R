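test_that("naive generation passes the exhaustive oracle on a small instance", {
  spec <- filter_spec(min_distance = 3, max_homopolymer = 3,
                      gc_min = 0.25, gc_max = 0.75)
  nv <- generate_naive(50, 12, spec, seed = 701)
  expect_true(nv$completed)
  expect_identical(length(nv$codes), 50L)
  expect_true(all(nchar(nv$codes) == 12))
  expect_gte(oracle_min_pairwise(nv$codes), 3)
  expect_true(all(vapply(nv$codes, oracle_comp_pass, logical(1), spec = spec)))
})

test_that("d = 0 disables the Hamming screen; permissive filters accept everything", {
  spec <- filter_spec(min_distance = 0, max_homopolymer = 50)
  nv <- generate_naive(30, 8, spec, seed = 702)
  expect_equal(nv$stats$acceptance_rate, 1)
  expect_equal(nv$stats$hamming_comparisons, 0)
})

test_that("small-N naive acceptance approaches the composition pass probability", {
  spec <- filter_spec(min_distance = 3, max_homopolymer = 2,
                      gc_min = 0.35, gc_max = 0.65)
  # with N = 40 accepted codes in a 4^15 space, Hamming rejections are
  # negligible, so the acceptance rate estimates the composition pass rate
  nv <- generate_naive(40, 15, spec, seed = 703)
  set.seed(704)
  mc <- random_dna(4000, 15)
  p_mc <- mean(vapply(mc, oracle_comp_pass, logical(1), spec = spec))
  se <- sqrt(p_mc * (1 - p_mc) * (1 / 4000 + 1 / nv$stats$proposed))
  expect_lt(abs(nv$stats$acceptance_rate - p_mc), 3 * se + 0.01)
})

test_that("budget exhaustion is a reported state with usable checkpoints", {
  spec <- filter_spec(min_distance = 2, max_homopolymer = 2,
                      gc_min = 0.4, gc_max = 0.6)
  nv <- generate_naive(1e6, 20, spec, max_candidates = 3000, seed = 705)
  expect_false(nv$completed)
  expect_lt(length(nv$codes), 1e6)
  expect_gte(nrow(nv$checkpoints), 2)
  expect_true(all(diff(nv$checkpoints$codes_generated) > 0))
})

test_that("log-log extrapolation recovers exact and noisy power laws", {
  # exact power law t = 3 k^2: OLS through collinear log points is exact
  prog <- data.frame(codes_generated = c(10, 100, 1000),
                     elapsed_time = 3 * c(10, 100, 1000)^2)
  fit <- extrapolate_completion(prog, 1e4)
  expect_equal(fit$predicted_time, 3e8, tolerance = 1e-10)
  expect_equal(fit$slope, 2, tolerance = 1e-12)

  # two points: the fit passes through both
  prog2 <- data.frame(codes_generated = c(5, 50),
                      elapsed_time = c(2, 11))
  fit2 <- extrapolate_completion(prog2, 50)
  expect_equal(fit2$predicted_time, 11, tolerance = 1e-10)

  # multiplicative lognormal noise, generating slope 2: recovered within 0.1
  set.seed(706)
  k <- round(exp(seq(log(10), log(1e5), length.out = 50)))
  t <- 0.004 * k^2 * exp(rnorm(50, sd = 0.2))
  fit3 <- extrapolate_completion(
    data.frame(codes_generated = k, elapsed_time = t), 1e6)
  expect_lt(abs(fit3$slope - 2), 0.1)

  expect_error(extrapolate_completion(prog[1, , drop = FALSE], 10),
               class = "barcodeforge_invalid_argument")
  expect_error(
    extrapolate_completion(data.frame(codes_generated = c(0, 10),
                                      elapsed_time = c(1, 2)), 10),
    class = "barcodeforge_invalid_argument")
})

test_that("the benchmark harness is reproducible and correctly shaped", {
  configs <- data.frame(m = c(3, 3), L = c(16, 18))
  b1 <- run_benchmark(configs, frameworks = c("A", "B"),
                      n_b = 8, n_t = 60, l_b = 6, d = 3,
                      gc_min = 0.25, gc_max = 0.75,
                      blacklist = character(),
                      grid = grid_search_config(r = 5, s = 40, t = 2),
                      seed = 707)
  expect_identical(nrow(b1), 4L)
  expect_setequal(b1$framework, c("A", "B"))
  expect_true(all(b1$acceptance_rate > 0 & b1$acceptance_rate <= 1))
  b2 <- run_benchmark(configs, frameworks = c("A", "B"),
                      n_b = 8, n_t = 60, l_b = 6, d = 3,
                      gc_min = 0.25, gc_max = 0.75,
                      blacklist = character(),
                      grid = grid_search_config(r = 5, s = 40, t = 2),
                      seed = 707)
  expect_identical(b1$acceptance_rate, b2$acceptance_rate)
  expect_identical(b1$delta, b2$delta)
  # naive rows report budgeted state
  b3 <- run_benchmark(data.frame(m = 3, L = 16), frameworks = "naive",
                      n_b = 4, n_t = 50, l_b = 6, d = 3,
                      gc_min = 0.25, gc_max = 0.75,
                      blacklist = character(),
                      naive_max_candidates = 400, seed = 708)
  expect_identical(b3$framework, "naive")
  expect_true(is.finite(b3$extrapolated_time) || b3$completed)
})
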