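# Strand-resolved pileup engine.  The unit of evidence downstream is the
# per-position observation: (base, phred quality, in-read offset, distance
# to nearest read end, strand).  Offsets are counted in sequencing order
# (machine cycles), so for a reverse-strand alignment the stored-sequence
# index is reversed; distance-to-end is min(offset, readlen - 1 - offset)
# and therefore orientation-free.

#' Build a strand-resolved pileup from alignments
#'
#' @param alignments Alignment table from [align_fixture_reads()] or
#'   [read_alignments()]; unmapped rows are ignored.
#' @param reference Named character vector of reference sequences.
#' @param min_base_quality Observations below this phred score are excluded
#'   from base counts but kept with `filtered = TRUE` so coverage is
#'   conserved.
#' @return A `pileup` object: a data.table of observations with columns
#'   `chrom`, `pos` (0-based), `base`, `qual` (phred), `strand`, `offset`,
#'   `dist_end`, `filtered`, plus the reference and threshold as attributes.
#' @export
build_pileup <- function(alignments, reference, min_base_quality = 20L) {
  a <- alignments[alignments$mapped %||% TRUE, , drop = FALSE]
  mk <- function(chrom, pos, base, qual, strand, offset, dist_end) {
    data.table(chrom = chrom, pos = pos, base = base, qual = qual,
               strand = strand, offset = offset, dist_end = dist_end)
  }
  if (nrow(a) == 0L) {
    obs <- mk(character(0), numeric(0), character(0), integer(0),
              character(0), integer(0), integer(0))
  } else {
    simple <- grepl("^[0-9]+M$", a$cigar) & nchar(a$seq) == nchar(a$qual)
    parts <- list()
    if (any(simple)) {
      s <- a[simple, , drop = FALSE]
      l <- nchar(s$seq)
      if (length(unique(l)) == 1L) {
        rl <- l[1]
        n <- nrow(s)
        if (any(s$start + rl > nchar(reference[s$chrom])))
          stop_input("alignment of read %s walks off the reference end",
                     s$qname[which(s$start + rl > nchar(reference[s$chrom]))[1]])
        j <- rep(seq_len(rl), times = n)                 # stored index
        ridx <- rep(seq_len(n), each = rl)
        offset <- ifelse(s$strand[ridx] == "+", j - 1L, rl - j)
        parts[[length(parts) + 1L]] <- mk(
          chrom = s$chrom[ridx],
          pos = s$start[ridx] + j - 1L,
          base = unlist(strsplit(s$seq, ""), use.names = FALSE),
          qual = utf8ToInt(paste(s$qual, collapse = "")) - 33L,
          strand = s$strand[ridx],
          offset = as.integer(offset),
          dist_end = as.integer(pmin(offset, rl - 1L - offset)))
      } else simple[] <- FALSE   # mixed lengths: fall through to generic path
    }
    if (any(!simple)) {
      g <- a[!simple, , drop = FALSE]
      for (i in seq_len(nrow(g))) {
        pr <- cigar_aligned_pairs(g$cigar[i], g$start[i])
        if (nrow(pr) == 0L) next
        rl <- nchar(g$seq[i])
        if (max(pr$refpos) >= nchar(reference[[g$chrom[i]]]))
          stop_input("alignment of read %s walks off the reference end", g$qname[i])
        offset <- if (g$strand[i] == "+") pr$readpos - 1L else rl - pr$readpos
        parts[[length(parts) + 1L]] <- mk(
          chrom = g$chrom[i], pos = pr$refpos,
          base = substring(g$seq[i], pr$readpos, pr$readpos),
          qual = utf8ToInt(substring(g$qual[i], 1, rl))[pr$readpos] - 33L,
          strand = g$strand[i],
          offset = as.integer(offset),
          dist_end = as.integer(pmin(offset, rl - 1L - offset)))
      }
    }
    obs <- rbindlist(parts)
  }
  obs[, filtered := qual < min_base_quality]
  setkey(obs, chrom, pos)
  setattr(obs, "reference", reference)
  setattr(obs, "min_base_quality", as.integer(min_base_quality))
  setattr(obs, "class", c("pileup", class(obs)))
  obs[]
}

# (refpos 0-based, readpos 1-based) aligned pairs for one CIGAR string.
cigar_aligned_pairs <- function(cigar, start) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDSN=X]", cigar))[[1]]
  if (!length(ops) || paste(ops, collapse = "") != cigar)
    stop_input("unsupported CIGAR '%s'", cigar)
  lens <- as.integer(sub("[MIDSN=X]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  refpos <- start
  readpos <- 1L
  out <- list()
  for (i in seq_along(ops)) {
    l <- lens[i]
    k <- kinds[i]
    if (k %in% c("M", "=", "X")) {
      out[[length(out) + 1L]] <- data.frame(refpos = refpos + 0:(l - 1L),
                                            readpos = readpos + 0:(l - 1L))
      refpos <- refpos + l
      readpos <- readpos + l
    } else if (k %in% c("D", "N")) {
      refpos <- refpos + l
    } else {                      # I, S consume read only
      readpos <- readpos + l
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(refpos = integer(0),
                                                       readpos = integer(0))
}

#' Summarize a pileup into per-position strand-resolved base counts
#'
#' @param pileup A `pileup` from [build_pileup()].
#' @return data.table with one row per covered position: `chrom`, `pos`,
#'   `ref`, counts `A_plus ... T_minus`, `N_plus`, `N_minus`, and
#'   `filtered` (observations excluded by the quality threshold).
#' @export
pileup_counts <- function(pileup) {
  reference <- attr(pileup, "reference")
  bases <- c("A", "C", "G", "T", "N")
  cnt <- pileup[filtered == FALSE,
                .N, by = .(chrom, pos, base, strand)]
  cnt[, col := paste0(base, ifelse(strand == "+", "_plus", "_minus"))]
  wide <- if (nrow(cnt)) {
    dcast(cnt, chrom + pos ~ col, value.var = "N", fill = 0L)
  } else {
    data.table(chrom = character(0), pos = numeric(0))
  }
  for (col in c(t(outer(bases, c("_plus", "_minus"), paste0))))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  filt <- pileup[, .(filtered = sum(filtered)), by = .(chrom, pos)]
  out <- merge(wide, filt, by = c("chrom", "pos"), all = TRUE)
  for (col in setdiff(names(out), c("chrom", "pos")))
    set(out, which(is.na(out[[col]])), col, 0L)
  out[, ref := substring(reference[chrom], pos + 1, pos + 1)]
  setcolorder(out, c("chrom", "pos", "ref",
                     paste0(rep(bases, each = 2), c("_plus", "_minus")),
                     "filtered"))
  setkey(out, chrom, pos)
  out[]
}

#' Extract one pileup column
#'
#' @param pileup A `pileup`.
#' @param chrom,pos Position of interest (0-based).
#' @return A `pileup_column`: the position's observations plus reference
#'   base, usable by the bias tests.
#' @export
pileup_column <- function(pileup, chrom, pos) {
  reference <- attr(pileup, "reference")
  .chrom <- chrom
  .pos <- pos
  obs <- pileup[chrom == .chrom & pos == .pos]
  obs <- obs[!is.na(base)]
  structure(list(chrom = .chrom, pos = .pos,
                 ref = substring(reference[[.chrom]], .pos + 1, .pos + 1),
                 obs = obs),
            class = "pileup_column")
}

#' Write a pileup counts table as TSV (1-based positions)
#'
#' @param pileup A `pileup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  counts <- pileup_counts(pileup)
  counts <- as.data.frame(counts)
  counts$pos_1based <- counts$pos + 1
  counts$pos <- NULL
  counts <- counts[, c("chrom", "pos_1based",
                       setdiff(names(counts), c("chrom", "pos_1based")))]
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
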