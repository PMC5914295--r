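# Sequence file IO.  FASTA/FASTQ parsing and writing delegate to Biostrings;
# the package-internal representation of a reference is a plain named
# character vector (name -> uppercase sequence), and of a read set a
# data.frame with columns id / seq / qual.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to an uncompressed or gzipped FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  # Biostrings keeps the full description line; reference names are the
  # first whitespace-delimited token, as in SAM/BAM headers.
  names(out) <- sub("[[:space:]].*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (length(sequences) > 0 &&
      (is.null(names(sequences)) || anyDuplicated(names(sequences))))
    stop_input("sequences must have unique names")
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path Path to a FASTQ file (Sanger Phred+33 qualities).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings <= 2.70 warns about dropped (empty) metadata columns here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(id = sub("[[:space:]].*$", "", unname(names(x))),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$seq) != nchar(reads$qual)))
    stop_input("sequence and quality lengths differ")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a BED-like site mask
#'
#' Masks come in two shapes, auto-detected by column count:
#' * BED3+ (>= 3 columns): tab-separated `chrom start end` with 0-based
#'   half-open intervals; every covered position is masked.
#' * 2 columns: `chrom pos` with a 1-based position per row (the shape of
#'   many dbSNP exports).
#'
#' @param path Path to the mask file.  Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @return data.table with columns `chrom`, `pos` (0-based), one row per
#'   distinct masked position.
#' @export
read_site_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  empty <- data.table(chrom = character(0), pos = numeric(0))
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- lengths(fields)
  if (any(ncol1 < 2L))
    stop_input("mask line %d has fewer than 2 columns", which(ncol1 < 2L)[1])
  two_col <- all(ncol1 == 2L)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (two_col) {
      p <- suppressWarnings(as.numeric(f[2]))
      if (is.na(p) || p < 1)
        stop_input("mask line %d: invalid 1-based position '%s'", i, f[2])
      out[[i]] <- data.table(chrom = f[1], pos = p - 1)
    } else {
      s <- suppressWarnings(as.numeric(f[2]))
      e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e))
        stop_input("mask line %d: non-numeric interval", i)
      if (s >= e)
        stop_input("mask line %d: start %s >= end %s", i, f[2], f[3])
      out[[i]] <- data.table(chrom = f[1], pos = seq(s, e - 1))
    }
  }
  unique(rbindlist(out))
}

#' Read a sample design table
#'
#' A tab-separated table with header `sample_id`, `genotype` and optionally
#' `path` (per-sample reads or alignments).  Sample ids must be unique and
#' every genotype level must have at least one sample.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `sample_id`, `genotype` (and `path` if
#'   present).
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  validate_design(d)
}

validate_design <- function(d) {
  if (!all(c("sample_id", "genotype") %in% names(d)))
    stop_input("design table needs columns 'sample_id' and 'genotype'")
  d$sample_id <- as.character(d$sample_id)
  d$genotype <- as.character(d$genotype)
  if (anyDuplicated(d$sample_id))
    stop_input("duplicate sample_id in design: %s",
               d$sample_id[duplicated(d$sample_id)][1])
  if (nrow(d) == 0L) stop_input("design table is empty")
  d
}
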