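# Run configuration and command-line entry points.

#' Run configuration
#'
#' A flat, file-serializable bundle of every knob a generation run needs.
#' Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param N,n_b,n_t,L,l_b,l_t Library geometry (see [library_design()]).
#' @param framework `"A"` or `"B"`.
#' @param min_distance,max_homopolymer,gc_min,gc_max Filter parameters. GC
#'   bounds may be given as percentages (e.g. 35, 65); values > 1 are
#'   divided by 100.
#' @param blacklist Character vector of subsequences, a preset name
#'   (`"pcomb3x"`, `"restriction_sites"`), or a file path.
#' @param budget_mode `"strict"` or `"split"`.
#' @param grid_r,grid_s,grid_t Grid-search parameters (Framework B).
#' @param seed Integer seed for the whole run.
#' @param out_prefix Output-file prefix used by [cli_generate()].
#' @param max_attempts_per_code Proposal cap per accepted code.
#' @return A `run_config` object.
#' @export
run_config <- function(N = NULL, n_b = NULL, n_t = NULL, L = NULL,
                       l_b = NULL, l_t = NULL, framework = "B",
                       min_distance = 4, max_homopolymer = 2,
                       gc_min = 0.35, gc_max = 0.65,
                       blacklist = character(), budget_mode = "split",
                       grid_r = 11, grid_s = 200, grid_t = 3,
                       seed = 1, out_prefix = "barcodes",
                       max_attempts_per_code = 1e6) {
  if (is.numeric(gc_min) && gc_min > 1) gc_min <- gc_min / 100
  if (is.numeric(gc_max) && gc_max > 1) gc_max <- gc_max / 100
  if (gc_min > gc_max) {
    abort("Invalid GC bounds: gc_min > gc_max.",
          class = "barcodeforge_invalid_spec")
  }
  if (!framework %in% c("A", "B")) {
    abort("`framework` must be 'A' or 'B'.",
          class = "barcodeforge_invalid_spec")
  }
  structure(
    list(N = N, n_b = n_b, n_t = n_t, L = L, l_b = l_b, l_t = l_t,
         framework = framework, min_distance = min_distance,
         max_homopolymer = max_homopolymer, gc_min = gc_min, gc_max = gc_max,
         blacklist = blacklist, budget_mode = budget_mode,
         grid_r = grid_r, grid_s = grid_s, grid_t = grid_t,
         seed = seed, out_prefix = out_prefix,
         max_attempts_per_code = max_attempts_per_code),
    class = "run_config")
}

resolve_blacklist <- function(blacklist) {
  if (length(blacklist) == 1 &&
      blacklist %in% c("pcomb3x", "restriction_sites")) {
    return(blacklist_preset(blacklist))
  }
  if (length(blacklist) == 1 && file.exists(blacklist) &&
      grepl("[^ACGT]", toupper(blacklist))) {
    return(read_blacklist(blacklist))
  }
  as_dna(blacklist, "blacklist")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path (YAML).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))], path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_to_objects <- function(config) {
  design <- library_design(N = config$N, n_b = config$n_b, n_t = config$n_t,
                           L = config$L, l_b = config$l_b, l_t = config$l_t)
  spec <- filter_spec(min_distance = config$min_distance,
                      max_homopolymer = config$max_homopolymer,
                      gc_min = config$gc_min, gc_max = config$gc_max,
                      blacklist = resolve_blacklist(config$blacklist))
  grid <- grid_search_config(r = config$grid_r, s = config$grid_s,
                             t = config$grid_t)
  list(design = design, spec = spec, grid = grid)
}

#' Generate a library from a run configuration and write its artifacts
#'
#' Runs [generate_library()] and writes three files:
#' `<prefix>_batches.txt` (linked batch codes, linker included, one per
#' line), `<prefix>_targets.txt`, and `<prefix>_stats.json` (per-phase
#' acceptance statistics, the chosen delta and per-grid-point rates, the
#' seed, and timings). Identical configurations and seeds produce
#' byte-identical output.
#'
#' @param config A [run_config()] (or path to a YAML config file).
#' @return Invisibly, the `barcode_run`.
#' @export
cli_generate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  obj <- config_to_objects(config)
  run <- generate_library(obj$design, obj$spec,
                          framework = config$framework,
                          budget_mode = config$budget_mode,
                          grid = obj$grid,
                          max_attempts_per_code = config$max_attempts_per_code,
                          seed = config$seed)
  prefix <- config$out_prefix
  write_codes(run$library$linked_batches, paste0(prefix, "_batches.txt"))
  write_codes(run$library$targets, paste0(prefix, "_targets.txt"))
  stats <- list(
    framework = run$framework,
    delta = run$delta,
    seed = config$seed,
    design = unclass(run$library$design),
    budget = unclass(run$library$budget),
    phases = as.data.frame(run$stats))
  if (!is.null(run$grid)) {
    stats$grid <- as.data.frame(run$grid$summary)
  }
  jsonlite::write_json(stats, paste0(prefix, "_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' Expand component files into a library file
#'
#' Thin wrapper over the streaming [expand_library()].
#'
#' @inheritParams expand_library
#' @return Invisibly, the number of barcodes written.
#' @export
cli_expand <- function(batch_file, target_file, path, N = NULL,
                       format = c("text", "fasta")) {
  expand_library(batch_file, target_file, path, N = N, format = format)
}

#' Validate component files against a constraint specification
#'
#' Reads the two component files, runs [validate_library()], optionally
#' writes the report as JSON, and returns the report with an exit `status`
#' attribute: 0 iff there are no composition violations and the distance
#' budget holds.
#'
#' @param batch_file,target_file Component files (plain text or FASTA).
#' @param spec A [filter_spec()].
#' @param budget_mode `"strict"` or `"split"`.
#' @param mode Validation mode, `"structured"` or `"exhaustive"`.
#' @param report_file Optional path for a JSON report.
#' @return The `validation_report` (invisibly), with attribute `status`.
#' @export
cli_validate <- function(batch_file, target_file, spec,
                         budget_mode = "split",
                         mode = "structured", report_file = NULL) {
  batches <- read_codes(batch_file)
  targets <- read_codes(target_file)
  budget <- distance_budget(spec$min_distance, nchar(batches[1]) - 2L,
                            nchar(targets[1]), mode = budget_mode)
  lib <- barcode_library(batches, targets, spec, budget)
  report <- validate_library(lib, mode = mode)
  if (!is.null(report_file)) {
    jsonlite::write_json(
      list(minima = as.data.frame(report$minima),
           n_violations = report$n_violations,
           violations = as.data.frame(report$violations),
           composition_ok = report$composition_ok,
           global_distance_ok = report$global_distance_ok,
           budget_ok = report$budget_ok),
      report_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  status <- if (report$composition_ok && report$budget_ok) 0L else 1L
  attr(report, "status") <- status
  invisible(report)
}

#' Command-line dispatcher
#'
#' Entry point for the `inst/cli/barcodeforge` Rscript. Subcommands:
#' `generate <config.yaml>`, `expand <batches> <targets> <out> [N] [format]`,
#' `validate <batches> <targets> [d] [m] [gc_min] [gc_max]`,
#' `benchmark <m,L;m,L;...>`, `grid-search <config.yaml>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: barcodeforge <generate|expand|validate|benchmark|grid-search> ...",
    sep = "\n")
  if (length(args) < 1) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
      "generate" = {
        cli_generate(rest[1])
        0L
      },
      "expand" = {
        n <- if (length(rest) >= 4) as.numeric(rest[4]) else NULL
        fmt <- if (length(rest) >= 5) rest[5] else "text"
        cli_expand(rest[1], rest[2], rest[3], N = n, format = fmt)
        0L
      },
      "validate" = {
        spec <- filter_spec(
          min_distance = if (length(rest) >= 3) as.numeric(rest[3]) else 4,
          max_homopolymer = if (length(rest) >= 4) as.numeric(rest[4]) else 2,
          gc_min = if (length(rest) >= 5) as.numeric(rest[5]) / 100 else 0,
          gc_max = if (length(rest) >= 6) as.numeric(rest[6]) / 100 else 1)
        rep_ <- cli_validate(rest[1], rest[2], spec)
        print(rep_)
        attr(rep_, "status")
      },
      "benchmark" = {
        pairs <- strsplit(strsplit(rest[1], ";", fixed = TRUE)[[1]], ",")
        configs <- data.frame(m = as.integer(vapply(pairs, `[`, "", 1)),
                              L = as.integer(vapply(pairs, `[`, "", 2)))
        bench <- run_benchmark(configs,
                               seed = if (length(rest) >= 2)
                                 as.integer(rest[2]) else 1L)
        format_benchmark(bench)
        0L
      },
      "grid-search" = {
        config <- read_run_config(rest[1])
        obj <- config_to_objects(config)
        set.seed(config$seed)
        budget <- distance_budget(obj$spec$min_distance, obj$design$l_b,
                                  obj$design$l_t, mode = config$budget_mode)
        batches <- generate_batch_codes(obj$design$n_b, obj$design$l_b,
                                        obj$spec, budget)
        gs <- select_delta(batches$codes$linked, obj$design, obj$spec,
                           config = obj$grid)
        print(gs)
        0L
      },
      {
        message(usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
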