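# Plain-text / FASTA I/O and streaming library expansion.

#' Write sequences to a plain-text code file
#'
#' One uppercase sequence per line, LF-terminated, no header — the component
#' file format consumed by [expand_library()].
#'
#' @param codes Character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codes <- function(codes, path) {
  codes <- as_dna(codes, "codes")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(codes, con, sep = "\n")
  invisible(path)
}

#' Read sequences from a plain-text or FASTA file
#'
#' Plain text is one sequence per line; files whose first non-empty line
#' starts with `>` are parsed as FASTA (via Biostrings). A malformed line
#' (non-ACGT) raises a parse error naming the file and line number.
#'
#' @param path Input file path.
#' @return Character vector of uppercase sequences.
#' @export
read_codes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "barcodeforge_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonempty <- lines[nzchar(lines)]
  if (length(nonempty) > 0 && startsWith(nonempty[1], ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("Reading FASTA requires the Biostrings package.",
            class = "barcodeforge_io_error")
    }
    seqs <- as.character(Biostrings::readDNAStringSet(path))
    return(as_dna(unname(seqs), "sequences"))
  }
  keep <- nzchar(lines)
  seqs <- toupper(lines[keep])
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    line_no <- which(keep)[which(bad)[1]]
    abort(sprintf("Malformed sequence (non-ACGT) at %s line %d.",
                  path, line_no),
          class = "barcodeforge_parse_error")
  }
  seqs
}

#' Read a blacklist from plain text or FASTA
#'
#' @param path Input file path (one sequence per line, or FASTA).
#' @return Character vector of uppercase subsequences.
#' @export
read_blacklist <- function(path) read_codes(path)

#' Shipped blacklist presets
#'
#' * `"pcomb3x"`: sequences that interfere with cloning barcodes into the
#'   pComb3x phagemid (XbaI site, a 27-bp tag region, BbsI, a Shine-Dalgarno
#'   motif, a His-tag repeat, SacI, SpeI).
#' * `"restriction_sites"`: the package's own compilation of canonical
#'   recognition sequences for EcoRI, EcoRV, SalI, SmaI/XmaI, HindIII, BbsI,
#'   XhoI, and BglII — common enzymes a general-purpose library should avoid.
#'
#' @param name Preset name.
#' @return Character vector of blacklisted subsequences.
#' @examples
#' blacklist_preset("pcomb3x")
#' @export
blacklist_preset <- function(name = c("pcomb3x", "restriction_sites")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".txt"),
                      package = "barcodeforge", mustWork = TRUE)
  read_blacklist(path)
}

#' Expand two component files into a barcode library file (streaming)
#'
#' Streams the cross product of a linked-batch-code file and a target-code
#' file to `path` in batch-major order, as plain text (one barcode per line)
#' or FASTA with headers `>b{i}_t{j}` (1-based indices in file order).
#' Output is written one batch at a time, so memory use is bounded by the
#' target set regardless of the library size — libraries up to billions of
#' barcodes stream through unchanged.
#'
#' @param batch_file File of linked batch codes (one per line, or FASTA).
#' @param target_file File of target codes.
#' @param path Output file path.
#' @param N Optional truncation: emit only the first `N` barcodes.
#' @param format `"text"` or `"fasta"`.
#' @return Invisibly, the number of barcodes written.
#' @export
expand_library <- function(batch_file, target_file, path, N = NULL,
                           format = c("text", "fasta")) {
  format <- match.arg(format)
  batches <- read_codes(batch_file)
  targets <- read_codes(target_file)
  if (length(unique(nchar(batches))) > 1 || length(unique(nchar(targets))) > 1) {
    abort("Component sequences must have uniform lengths.",
          class = "barcodeforge_malformed_library")
  }
  total <- length(batches) * as.numeric(length(targets))
  n_emit <- if (is.null(N)) total else min(N, total)
  con <- file(path, open = "wb")
  on.exit(close(con))
  written <- 0
  for (i in seq_along(batches)) {
    if (written >= n_emit) break
    take <- min(length(targets), n_emit - written)
    block <- paste0(batches[i], targets[seq_len(take)])
    if (format == "fasta") {
      block <- as.vector(rbind(
        sprintf(">b%d_t%d", i, seq_len(take)), block))
    }
    writeLines(block, con, sep = "\n")
    written <- written + take
  }
  invisible(written)
}
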