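#' Genomic interval
#'
#' A lightweight interval record.  All internal coordinates in this package
#' are 0-based half-open; region strings at user-facing boundaries are
#' 1-based inclusive (`chr:start-end`), matching the convention of genome
#' browsers and PCR primer reports.
#'
#' @param chrom Reference sequence name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop_input("`chrom` must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop_input("invalid interval [%s, %s): need 0 <= start < end", start, end)
  if (!strand %in% c("+", "-", "*"))
    stop_input("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
length.genomic_interval <- function(x) {
  as.integer(x$end - x$start)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s (%d bp, %s)\n",
              format_region(x), length(x), x$strand))
  invisible(x)
}

#' Parse a 1-based inclusive region string
#'
#' Parses `"chrX:147169590-147169767"`-style strings into a 0-based
#' half-open [genomic_interval].  A region `chrom:a-b` with 1-based
#' inclusive bounds maps to `start = a - 1`, `end = b`, so its length is
#' `b - a + 1`.
#'
#' @param text A string of the form `<chrom>:<a>-<b>`, `a <= b`, both
#'   positive 1-based inclusive coordinates.  Thousands separators (`,`)
#'   are tolerated.
#' @return A [genomic_interval].
#' @examples
#' parse_region("chrX:147169590-147169767")  # 178 bp
#' @export
parse_region <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop_input("region must be a single string")
  m <- regmatches(text, regexec("^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L)
    stop_input("malformed region string: '%s' (expected <chrom>:<start>-<end>)", text)
  a <- suppressWarnings(as.numeric(gsub(",", "", m[3], fixed = TRUE)))
  b <- suppressWarnings(as.numeric(gsub(",", "", m[4], fixed = TRUE)))
  if (is.na(a) || is.na(b))
    stop_input("non-numeric coordinate in region '%s'", text)
  if (a < 1)
    stop_input("non-positive start coordinate '%s' in region '%s'", m[3], text)
  if (a > b)
    stop_input("start %s exceeds end %s in region '%s'", m[3], m[4], text)
  genomic_interval(m[2], a - 1, b)
}

#' Format an interval as a 1-based inclusive region string
#'
#' The inverse of [parse_region()] on valid inputs.
#'
#' @param interval A [genomic_interval].
#' @return A string `<chrom>:<a>-<b>` with 1-based inclusive bounds.
#' @export
format_region <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  sprintf("%s:%.0f-%.0f", interval$chrom, interval$start + 1, interval$end)
}
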