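#' Load sequences from FASTA or plain text
#'
#' FASTA files (first non-blank character '>') are parsed with
#' \code{Biostrings::readDNAStringSet}; anything else is read as a single
#' plain-text sequence with whitespace stripped. Sequences are uppercased and
#' record ids preserved as names.
#'
#' @param path file path.
#' @return named character vector, one element per record.
#' @export
loadFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) stop("empty input file: ", path)
  if (startsWith(trimws(nonblank[1]), ">")) {
    set <- Biostrings::readDNAStringSet(path, format = "fasta")
    if (!length(set) || any(Biostrings::width(set) == 0L))
      stop("FASTA record with no sequence in ", path)
    out <- toupper(as.character(set))
    names(out) <- names(set)
    out
  } else {
    seqs <- toupper(gsub("\\s", "", paste(nonblank, collapse = "")))
    if (!nzchar(seqs)) stop("no sequence content in ", path)
    stats::setNames(seqs, basename(path))
  }
}

#' Load query patterns, one per line
#'
#' @param path file path; blank lines and lines starting with '#' skipped.
#' @return character vector of uppercased patterns.
#' @export
loadPatterns <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  pats <- toupper(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (!length(pats)) stop("no patterns in ", path)
  pats
}

#' Write a multiple-pattern run to TSV and JSON
#'
#' Emits \code{results.tsv} (one row per pattern: core, wave, assumed t,
#' found indices, Grover applications, aborted flag), \code{results.json}
#' with the same content plus the parallel cost, and one gate-log text file
#' per pattern.
#'
#' @param result an [MPMResult-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(result@reports, function(r) data.frame(
    pattern = r@patternId, core = r@core, wave = r@wave,
    t_assumed = r@tAssumed,
    found = paste(r@found, collapse = ","),
    grover_applications = r@groverApplications,
    aborted = r@aborted, stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tsv <- file.path(dir, "results.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "results.json")
  jsonlite::write_json(list(
    algorithm = result@algorithm,
    parallel_cost = result@parallelCost,
    patterns = lapply(result@reports, function(r) list(
      pattern = r@patternId, core = r@core, wave = r@wave,
      t_assumed = r@tAssumed, found = r@found,
      grover_applications = r@groverApplications, aborted = r@aborted))),
    js, auto_unbox = TRUE, digits = NA)
  logs <- character(0)
  for (r in result@reports) {
    lg <- file.path(dir, paste0("gatelog_", r@patternId, "_core",
                                r@core, ".txt"))
    writeLines(paste(names(r@gateCounts), r@gateCounts, sep = "\t"), lg)
    logs <- c(logs, lg)
  }
  invisible(c(tsv, js, logs))
}
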