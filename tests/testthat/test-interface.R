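test_that("run configurations round-trip losslessly through YAML", {
  cfg <- run_config(N = 1e6, n_b = 100, L = 25, l_b = 10,
                    framework = "B", min_distance = 4, max_homopolymer = 2,
                    gc_min = 35, gc_max = 65, blacklist = "pcomb3x",
                    seed = 7, out_prefix = "x")
  expect_equal(cfg$gc_min, 0.35) # percentages normalized to fractions
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(unclass(cfg2)[!vapply(unclass(cfg2), is.null, logical(1))],
               unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))])
  expect_error(run_config(gc_min = 0.7, gc_max = 0.3),
               class = "barcodeforge_invalid_spec")
})

test_that("cli_generate writes component files and stats; identical seeds give identical bytes", {
  dir <- withr::local_tempdir()
  cfg <- run_config(n_b = 5, n_t = 40, l_b = 6, L = 16, framework = "B",
                    min_distance = 3, max_homopolymer = 3,
                    gc_min = 0.25, gc_max = 0.75,
                    grid_r = 5, grid_s = 30, grid_t = 2, seed = 11,
                    out_prefix = file.path(dir, "run1"))
  cli_generate(cfg)
  batches <- readLines(file.path(dir, "run1_batches.txt"))
  targets <- readLines(file.path(dir, "run1_targets.txt"))
  expect_identical(length(batches), 5L)
  expect_identical(length(targets), 40L)
  expect_true(all(nchar(batches) == 8))
  stats <- jsonlite::read_json(file.path(dir, "run1_stats.json"))
  expect_identical(stats$framework, "B")
  expect_true(stats$delta %in% grid_points(5))

  cfg2 <- cfg
  cfg2$out_prefix <- file.path(dir, "run2")
  cli_generate(cfg2)
  expect_identical(readLines(file.path(dir, "run2_batches.txt")), batches)
  expect_identical(readLines(file.path(dir, "run2_targets.txt")), targets)
})

test_that("expansion streams the batch-major cross product in both formats", {
  dir <- withr::local_tempdir()
  bf <- file.path(dir, "b.txt"); tf <- file.path(dir, "t.txt")
  write_codes(c("ACGTAG", "TGCACT"), bf)
  write_codes(c("AAC", "GGT", "CTA"), tf)

  out <- file.path(dir, "lib.txt")
  n <- expand_library(bf, tf, out)
  expect_identical(n, 6)
  lines <- readLines(out)
  expect_identical(lines, assemble_library(c("ACGTAG", "TGCACT"),
                                           c("AAC", "GGT", "CTA")))
  expect_true(all(nchar(lines) == 9))

  # truncation
  expand_library(bf, tf, out, N = 4)
  expect_identical(length(readLines(out)), 4L)

  # FASTA headers carry b{i}_t{j} ids
  fa <- file.path(dir, "lib.fa")
  expand_library(bf, tf, fa, format = "fasta")
  fl <- readLines(fa)
  expect_identical(fl[1], ">b1_t1")
  expect_identical(fl[2], "ACGTAGAAC")
  expect_identical(fl[11], ">b2_t3")
  expect_identical(fl[12], "TGCACTCTA")
})

test_that("malformed component lines are reported with file and line number", {
  dir <- withr::local_tempdir()
  bf <- file.path(dir, "bad.txt")
  writeLines(c("ACGTAG", "ACGXAG"), bf)
  err <- expect_error(read_codes(bf), class = "barcodeforge_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("blacklists load from plain text, FASTA, and shipped presets", {
  dir <- withr::local_tempdir()
  txt <- file.path(dir, "bl.txt")
  writeLines(c("TCTAGA", "gaagac"), txt)
  expect_identical(read_blacklist(txt), c("TCTAGA", "GAAGAC"))

  fa <- file.path(dir, "bl.fa")
  writeLines(c(">site1", "TCTAGA", ">site2", "GAAGAC"), fa)
  expect_identical(read_blacklist(fa), c("TCTAGA", "GAAGAC"))

  pc <- blacklist_preset("pcomb3x")
  expect_true("TCTAGA" %in% pc)
  expect_identical(length(pc), 7L)
  expect_identical(length(blacklist_preset("restriction_sites")), 8L)
})

test_that("cli_validate reports status 0 for clean libraries and locates faults", {
  dir <- withr::local_tempdir()
  spec <- filter_spec(min_distance = 3, max_homopolymer = 3,
                      gc_min = 0.25, gc_max = 0.75)
  design <- library_design(n_b = 5, n_t = 30, l_b = 6, L = 16)
  run <- generate_library(design, spec, framework = "A", seed = 21)
  bf <- file.path(dir, "b.txt"); tf <- file.path(dir, "t.txt")
  write_codes(run$library$linked_batches, bf)
  write_codes(run$library$targets, tf)
  rep_ <- cli_validate(bf, tf, spec, report_file = file.path(dir, "rep.json"))
  expect_identical(attr(rep_, "status"), 0L)
  js <- jsonlite::read_json(file.path(dir, "rep.json"))
  expect_identical(length(js$minima), 4L) # one row per pair class
  expect_identical(js$minima[[1]]$pair_class, "same_batch")

  # corrupt a target: nonzero status
  targets <- run$library$targets
  targets[2] <- strrep("A", nchar(targets[2]))
  write_codes(targets, tf)
  rep2 <- cli_validate(bf, tf, spec)
  expect_identical(attr(rep2, "status"), 1L)
  expect_true(nrow(rep2$violations) > 0)
})

test_that("the CLI dispatcher runs expand end to end and rejects bad input", {
  dir <- withr::local_tempdir()
  bf <- file.path(dir, "b.txt"); tf <- file.path(dir, "t.txt")
  write_codes(c("ACGTAG", "TGCACT"), bf)
  write_codes(c("AAC", "GGT"), tf)
  out <- file.path(dir, "lib.txt")
  status <- cli_main(c("expand", bf, tf, out))
  expect_identical(status, 0L)
  expect_identical(length(readLines(out)), 4L)
  expect_identical(suppressMessages(cli_main(c("nonsense"))), 1L)
})
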