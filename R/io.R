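#' Read a RepeatMasker annotation
#'
#' Parses either the native RepeatMasker `.out` dialect (whitespace
#' delimited, three header lines, 1-based inclusive coordinates) or a
#' simplified tab-separated table with a header line containing at least
#' `chrom`, `start`, `end`, `subfamily` (coordinates 0-based half-open,
#' BED-like; optional columns `family`, `divergence`, `strand`,
#' `instance_id`). Both are returned as a GRanges in the package's internal
#' convention (1-based closed, as native to GRanges), one range per
#' annotation row; fragmented hits of one element are treated as
#' independent instances.
#'
#' @param path path to the annotation file.
#' @return GRanges with metadata columns `subfamily`, `family`,
#'   `divergence` (percent substitutions from the subfamily consensus),
#'   `instance_id` (unique within the file) and `human_specific`
#'   (initialised to `NA`; see [classifyHumanSpecific()]).
#' @examples
#' out <- tempfile(fileext = ".out")
#' writeLines(c(
#'   "   SW  perc perc perc  query      position in query     matching",
#'   "score  div. del. ins.  sequence   begin  end   (left)   repeat",
#'   "",
#'   "  463   1.3  0.6  1.7  chr1        101    400  (248856) +  AluYa5  SINE/Alu  1 300 (0) 1"
#' ), out)
#' te <- readRepeatMasker(out)
#' GenomicRanges::start(te)  # 101 (1-based; [100, 400) in 0-based terms)
#' @export
readRepeatMasker <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(.emptyTeGRanges())
  first <- trimws(lines[1])
  if (grepl("\t", lines[1]) && grepl("chrom", lines[1])) {
    return(.readRepeatMaskerTsv(path))
  }
  if (grepl("^SW\\b", first) || grepl("^score\\b", first) ||
      grepl("^SW\\s+perc", first)) {
    return(.readRepeatMaskerOut(lines, path))
  }
  stop("unknown RepeatMasker dialect in '", path,
       "': expected a native .out header or a TSV header naming 'chrom'")
}

.emptyTeGRanges <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(subfamily = character(0), family = character(0),
                         divergence = numeric(0), instance_id = character(0),
                         human_specific = logical(0))
  gr
}

.readRepeatMaskerOut <- function(lines, path) {
  body <- lines[-seq_len(min(3L, length(lines)))]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineNo <- (seq_along(lines)[-seq_len(min(3L, length(lines)))])[keep]
  if (length(body) == 0L) return(.emptyTeGRanges())
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed RepeatMasker row(s) at line(s) ",
         paste(lineNo[nf < 11L], collapse = ", "), " of '", path,
         "': fewer than 11 fields")
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  begin <- suppressWarnings(as.integer(getf(6)))
  end <- suppressWarnings(as.integer(getf(7)))
  div <- suppressWarnings(as.numeric(getf(2)))
  bad <- is.na(begin) | is.na(end) | is.na(div) | begin > end | div < 0
  if (any(bad))
    stop("malformed RepeatMasker row(s) at line(s) ",
         paste(lineNo[bad], collapse = ", "), " of '", path, "'")
  strand <- getf(9)
  strand <- ifelse(strand == "+", "+", ifelse(strand %in% c("C", "-"), "-", "*"))
  classFam <- getf(11)
  family <- sub("^[^/]*/", "", classFam)
  gr <- GRanges(getf(5), IRanges(begin, end), strand = strand)
  mcols(gr) <- DataFrame(
    subfamily = getf(10),
    family = family,
    divergence = div,
    instance_id = sprintf("te_%06d", seq_along(gr)),
    human_specific = NA
  )
  gr
}

.readRepeatMaskerTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("chrom", "start", "end", "subfamily")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TSV annotation '", path, "' lacks columns: ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(.emptyTeGRanges())
  bad <- which(!(df$start < df$end) | is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop("malformed annotation row(s) at data line(s) ",
         paste(bad, collapse = ", "), " of '", path, "'")
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = strand)
  ids <- if ("instance_id" %in% names(df)) as.character(df$instance_id)
         else sprintf("te_%06d", seq_len(nrow(df)))
  if (anyDuplicated(ids))
    stop("instance_id values in '", path, "' are not unique")
  mcols(gr) <- DataFrame(
    subfamily = as.character(df$subfamily),
    family = if ("family" %in% names(df)) as.character(df$family)
             else as.character(df$subfamily),
    divergence = if ("divergence" %in% names(df)) as.numeric(df$divergence)
                 else NA_real_,
    instance_id = ids,
    human_specific = NA
  )
  gr
}

#' Read deletion call sets from BED and/or VCF files
#'
#' Pools deletion calls from any mix of BED files (each line is the
#' deleted span, 0-based half-open) and VCF files. From VCFs, only
#' deletions relative to the reference are emitted: sequence-resolved
#' records where REF is longer than ALT (deleted span starts one base
#' after POS, per the VCF padding convention) and symbolic `<DEL>` records
#' with an `END` or `SVLEN` annotation. Insertions and SNVs are dropped;
#' symbolic records whose length cannot be resolved are skipped and
#' counted in a warning. Duplicate calls across files are intentionally
#' kept — deduplication is the catalogue-pruning step's job
#' ([buildIndelCatalog()]).
#'
#' @param paths character vector of file paths.
#' @param formats optional per-path format override ("bed" or "vcf");
#'   default: inferred from the file extension.
#' @param sources optional per-path dataset labels; default: file base
#'   names.
#' @return GRanges of deletions with metadata columns `indel_id` (unique),
#'   `svtype` ("DEL"), `source` and `retained` (`NA` until pruning).
#' @export
readDeletions <- function(paths, formats = NULL, sources = NULL) {
  if (is.null(formats)) {
    formats <- ifelse(grepl("\\.vcf(\\.gz)?$", paths, ignore.case = TRUE),
                      "vcf", "bed")
  }
  formats <- rep_len(tolower(formats), length(paths))
  if (is.null(sources))
    sources <- sub("\\.(bed|vcf)(\\.gz)?$", "",
                   basename(paths), ignore.case = TRUE)
  sources <- rep_len(sources, length(paths))
  parts <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    gr <- switch(formats[i],
      bed = .readDeletionsBed(paths[i]),
      vcf = .readDeletionsVcf(paths[i]),
      stop("unknown deletion format '", formats[i], "'")
    )
    if (length(gr)) mcols(gr)$source <- sources[i]
    parts[[i]] <- gr
  }
  out <- suppressWarnings(do.call(c, parts))
  if (length(out)) {
    mcols(out)$indel_id <- sprintf("%s_del_%06d", mcols(out)$source,
                                   seq_along(out))
    mcols(out)$svtype <- "DEL"
    mcols(out)$retained <- NA
    mcols(out) <- mcols(out)[, c("indel_id", "svtype", "source", "retained")]
  } else {
    out <- GRanges()
    mcols(out) <- DataFrame(indel_id = character(0), svtype = character(0),
                            source = character(0), retained = logical(0))
  }
  out
}

.readDeletionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr) <- NULL
  gr
}

.readDeletionsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- nrow(vcf)
  if (n == 0L) return(GRanges())
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- start(rr)
  chrom <- as.character(seqnames(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_len(n), function(i) {
    a <- altList[[i]]
    if (length(a) == 0L) NA_character_ else as.character(a[[1]])
  }, character(1))
  info <- VariantAnnotation::info(vcf)
  endInfo <- if ("END" %in% names(info)) suppressWarnings(as.numeric(info$END))
             else rep(NA_real_, n)
  svlen <- if ("SVLEN" %in% names(info)) {
    sl <- info$SVLEN
    if (is.list(sl) || is(sl, "List"))
      vapply(sl, function(v) if (length(v)) as.numeric(v[[1]]) else NA_real_,
             numeric(1))
    else suppressWarnings(as.numeric(sl))
  } else rep(NA_real_, n)

  delStart <- rep(NA_real_, n)
  delEnd <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    a <- alt[i]
    if (is.na(a)) { skipped <- skipped + 1L; next }
    if (startsWith(a, "<")) {
      if (!grepl("^<DEL", a)) next  # other SV classes: not deletions
      if (!is.na(endInfo[i]) && endInfo[i] > pos[i]) {
        delStart[i] <- pos[i] + 1
        delEnd[i] <- endInfo[i]
      } else if (!is.na(svlen[i]) && abs(svlen[i]) >= 1) {
        delStart[i] <- pos[i] + 1
        delEnd[i] <- pos[i] + abs(svlen[i])
      } else {
        skipped <- skipped + 1L
      }
    } else {
      dl <- nchar(ref[i]) - nchar(a)
      if (dl <= 0) next  # insertion or SNV relative to the reference
      delStart[i] <- pos[i] + 1
      delEnd[i] <- pos[i] + dl
    }
  }
  if (skipped > 0L)
    warning(skipped, " VCF record(s) in '", path,
            "' had unresolvable deletion length and were skipped")
  keep <- !is.na(delStart)
  GRanges(chrom[keep], IRanges(delStart[keep], delEnd[keep]))
}

#' Write genomic ranges as BED
#'
#' Plain BED output (0-based half-open); `chrom`, `start` and `end` are
#' preserved exactly through a [readDeletions()] round trip.
#'
#' @param gr GRanges to write; range names or an `indel_id`/`instance_id`
#'   metadata column become the BED name field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  nm <- names(gr)
  if (is.null(nm)) {
    for (col in c("indel_id", "instance_id", "name")) {
      if (col %in% names(mcols(gr))) { nm <- mcols(gr)[[col]]; break }
    }
  }
  if (is.null(nm)) nm <- rep(".", length(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1L, scientific = FALSE,
                                  trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE),
                   name = nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-instance cross-genome mapped fractions
#'
#' Three-column TSV (`instance_id`, `genome`, `mapped_fraction`) summarising,
#' per non-human genome, the fraction of each human TE interval that maps
#' across (e.g. a LiftOver summary). The table may be sparse: instances
#' absent for a genome are treated as mapped fraction 0 by
#' [classifyHumanSpecific()].
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
readMappings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "genome", "mapped_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mapping table '", path, "' lacks columns: ",
         paste(miss, collapse = ", "))
  if (any(df$mapped_fraction < 0 | df$mapped_fraction > 1, na.rm = TRUE))
    stop("mapped_fraction outside [0, 1] in '", path, "'")
  df
}

#' Read gene models from a simplified TSV
#'
#' Columns: `gene_id`, `chrom`, `start`, `end` (gene body, 0-based
#' half-open), `strand` (+/-), `exon_starts`, `exon_ends` (comma-separated,
#' 0-based half-open). The TSS is the strand-aware 5' end of the gene body.
#'
#' @param path TSV path.
#' @return list with `genes` (GRanges, mcols `gene_id`) and `exons`
#'   (GRanges, mcols `gene_id`).
#' @export
readGeneModels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene model table '", path, "' lacks columns: ",
         paste(miss, collapse = ", "))
  genes <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                   strand = df$strand)
  mcols(genes)$gene_id <- df$gene_id
  exons <- GRanges()
  mcols(exons)$gene_id <- character(0)
  if (all(c("exon_starts", "exon_ends") %in% names(df))) {
    es <- strsplit(as.character(df$exon_starts), ",")
    ee <- strsplit(as.character(df$exon_ends), ",")
    nEx <- lengths(es)
    if (any(nEx != lengths(ee)))
      stop("exon_starts/exon_ends length mismatch in '", path, "'")
    has <- nEx > 0 & vapply(es, function(x) all(nzchar(x)), logical(1))
    if (any(has)) {
      exons <- GRanges(rep(df$chrom[has], nEx[has]),
                       IRanges(as.integer(unlist(es[has])) + 1L,
                               as.integer(unlist(ee[has]))))
      mcols(exons)$gene_id <- rep(df$gene_id[has], nEx[has])
    }
  }
  list(genes = genes, exons = exons)
}
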