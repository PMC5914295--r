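# A deliberately minimal SAM dialect reader/writer.  Accepted: optional
# `@` header lines, records with the 11 mandatory columns, CIGAR ops
# restricted to M/I/D/S/N/=/X.  Anything else is rejected loudly rather
# than silently misread.  Binary BAM/CRAM are out of scope (use
# Rsamtools/samtools upstream and feed SAM text here).

SAM_FLAG_UNMAPPED <- 4L
SAM_FLAG_REVERSE <- 16L

#' Read alignments from a SAM file
#'
#' Parses a minimal SAM dialect into the package's alignment table.  Per
#' SAM convention the stored sequence of a reverse-strand record is already
#' the reference-forward orientation.  Unmapped records are skipped and
#' counted; malformed records are skipped with a warning and counted.
#' A record naming a reference absent from `reference` is a hard error.
#'
#' @param path Path to a SAM file.
#' @param reference Named character vector of reference sequences (see
#'   [read_fasta()]).
#' @return data.frame with columns `qname`, `chrom`, `start` (0-based),
#'   `strand`, `seq`, `qual`, `cigar`, `mapped`; attributes `n_unmapped`
#'   and `n_skipped` carry the tallies.
#' @export
read_alignments <- function(path, reference) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "@")]
  n_unmapped <- 0L
  n_skipped <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      warning(sprintf("skipping malformed SAM record at line-ish %d (%d columns)",
                      i, length(f)))
      n_skipped <- n_skipped + 1L
      next
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos1 <- suppressWarnings(as.numeric(f[4]))
    if (is.na(flag) || is.na(pos1)) {
      warning(sprintf("skipping malformed SAM record %s (non-numeric flag/pos)", f[1]))
      n_skipped <- n_skipped + 1L
      next
    }
    if (bitwAnd(flag, SAM_FLAG_UNMAPPED) != 0L || f[3] == "*" || pos1 == 0) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    if (!f[3] %in% names(reference))
      stop_input("SAM record %s maps to unknown reference '%s'", f[1], f[3])
    if (!grepl("^([0-9]+[MIDSN=X])+$", f[6]))
      stop_input("SAM record %s has unsupported CIGAR '%s' (dialect allows M/I/D/S/N/=/X)",
                 f[1], f[6])
    recs[[i]] <- data.frame(
      qname = f[1], chrom = f[3], start = pos1 - 1,
      strand = if (bitwAnd(flag, SAM_FLAG_REVERSE) != 0L) "-" else "+",
      seq = toupper(f[10]), qual = f[11], cigar = f[6],
      mapped = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(qname = character(0), chrom = character(0),
                      start = numeric(0), strand = character(0),
                      seq = character(0), qual = character(0),
                      cigar = character(0), mapped = logical(0))
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write an alignment table as SAM
#'
#' @param alignments Alignment table as produced by [read_alignments()] or
#'   [align_fixture_reads()].
#' @param reference Named character vector of reference sequences (used for
#'   `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (length(reference))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)), con)
  a <- alignments
  mapped <- if ("mapped" %in% names(a)) a$mapped else rep(TRUE, nrow(a))
  flag <- ifelse(mapped, ifelse(a$strand == "-", 16L, 0L), 4L)
  lines <- sprintf("%s\t%d\t%s\t%.0f\t%d\t%s\t*\t0\t0\t%s\t%s",
                   a$qname, flag,
                   ifelse(mapped, a$chrom, "*"),
                   ifelse(mapped, a$start + 1, 0),
                   ifelse(mapped, 255L, 0L),
                   ifelse(mapped, a$cigar, "*"),
                   a$seq, a$qual)
  writeLines(lines, con)
  invisible(path)
}
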