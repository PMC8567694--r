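#' Read a flat key = value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are kept
#' as character; multi-valued keys use comma separation.
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  out <- lapply(kv, function(m) trimws(m[3]))
  names(out) <- vapply(kv, function(m) trimws(m[2]), character(1))
  out
}

#' Run the screen from input files
#'
#' File-level orchestration of [rmsScreen()]: reads the TE annotation,
#' the mapped-fraction table and one or more deletion call sets, runs
#' the screen, writes the per-subfamily result TSV, the pMEI BED and the
#' deletion catalogue, and returns the result together with a run
#' manifest (input digests, parameters, stage-by-stage record counts).
#'
#' @param config named list (or path to a `key = value` file, see
#'   [readPipelineConfig()]) with entries:
#'   `te` (annotation path), `mappings` (TSV path), `indels`
#'   (comma-separated BED/VCF paths), `chrom_lengths` (two-column TSV:
#'   chrom, length), optional `tandem_repeats` (BED), optional numeric
#'   overrides `q`, `pseudo`, `min_size`, `max_mapped_fraction`, and
#'   `out_dir` (default `"."`).
#' @return list with `result` (an [RmsScreenResult-class]) and
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  need <- c("te", "mappings", "indels", "chrom_lengths")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing required field(s): ",
         paste(miss, collapse = ", "))
  indelPaths <- trimws(strsplit(config$indels, ",")[[1]])
  inputs <- c(config$te, config$mappings, indelPaths, config$chrom_lengths,
              config$tandem_repeats)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))

  tes <- readRepeatMasker(config$te)
  mappings <- readMappings(config$mappings)
  indels <- readDeletions(indelPaths)
  cl <- utils::read.delim(config$chrom_lengths, header = FALSE,
                          col.names = c("chrom", "length"))
  chromLengths <- stats::setNames(as.numeric(cl$length),
                                  as.character(cl$chrom))
  tandem <- NULL
  if (!is.null(config$tandem_repeats))
    tandem <- rtracklayer::import(config$tandem_repeats, format = "BED")

  num <- function(key, default) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  res <- rmsScreen(tes, mappings, indels, chromLengths = chromLengths,
                   tandemRepeats = tandem,
                   maxMappedFraction = num("max_mapped_fraction", 0.20),
                   minSize = num("min_size", 50),
                   nPseudo = num("pseudo", 500),
                   qThreshold = num("q", 0.001))

  outDir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  resPath <- file.path(outDir, "rms_results.tsv")
  utils::write.table(resultTable(res), resPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeBed(pmeis(res), file.path(outDir, "pmeis.bed"))

  manifest <- list(
    tool = paste("rmscan", as.character(utils::packageVersion("rmscan"))),
    inputs = as.list(tools::md5sum(inputs)),
    parameters = list(q = num("q", 0.001), pseudo = num("pseudo", 500),
                      min_size = num("min_size", 50),
                      max_mapped_fraction = num("max_mapped_fraction", 0.20)),
    funnel = as.list(screenFunnel(res)),
    outputs = c(resPath, file.path(outDir, "pmeis.bed"))
  )
  flat <- unlist(manifest)
  writeLines(paste(names(flat), flat, sep = "\t"),
             file.path(outDir, "manifest.tsv"))
  list(result = res, manifest = manifest)
}
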