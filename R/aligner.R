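# Minimal ungapped fixture aligner.  Reads are expected to be substitution-
# only copies of reference substrings (exactly what the simulator emits);
# gapped alignment of real data is delegated to external aligners via SAM
# input.  Placement works by exact-match anchor (k-mer) lookup over both
# strands, followed by full ungapped scoring of every candidate placement;
# the placement maximizing matches wins, ties and anchorless reads are
# emitted unmapped.

# k-mer index of the concatenated reference ("global" coordinates with a
# run of '#' separators so no k-mer or scoring window spans two sequences).
build_ref_index <- function(reference, k, pad) {
  sep <- strrep("#", pad)
  lens <- nchar(reference)
  offsets <- cumsum(c(0, head(lens + pad, -1)))   # global 0-based start per chrom
  names(offsets) <- names(reference)
  glob <- paste(reference, collapse = sep)
  n <- nchar(glob)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(glob, starts, starts + k - 1L)
  keep <- !grepl("#", kmers, fixed = TRUE)
  index <- split(starts[keep] - 1L, kmers[keep])  # kmer -> global 0-based starts
  list(env = list2env(index, hash = TRUE, size = max(length(index), 1L)),
       glob = glob, offsets = offsets, lens = lens)
}

#' Align fixture reads to a reference by anchored ungapped placement
#'
#' Each read is tried in both orientations.  Non-overlapping `anchor_len`
#' k-mers of the read are looked up in an exact-match index of the
#' reference; every hit proposes an ungapped placement, all proposals are
#' scored by match count, and the best one is reported.  Reads with no
#' anchor hit are unmapped (`noanchor`); reads whose best score is attained
#' at two distinct placements are unmapped (`ambiguous`).
#'
#' @param reads Read table (columns `id`, `seq`, `qual`) or a FASTQ path.
#' @param reference Named character vector of reference sequences.
#' @param anchor_len Anchor k-mer length; must not exceed the read length.
#'   By the pigeonhole principle a read with at most
#'   `floor(read_len / anchor_len) - 1` substitutions always retains one
#'   clean disjoint anchor, so placement never fails for it; the default
#'   of 12 tolerates 4 substitutions on a 60 bp read (several edited sites
#'   plus sequencing error) while keeping spurious k-mer hits rare.
#' @return Alignment table with columns `qname`, `chrom`, `start` (0-based),
#'   `strand`, `seq` (reference-forward orientation, SAM convention),
#'   `qual`, `cigar`, `mapped`, `reason`; attribute `n_unmapped`.
#' @export
align_fixture_reads <- function(reads, reference, anchor_len = 12L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  empty <- data.frame(qname = character(0), chrom = character(0),
                      start = numeric(0), strand = character(0),
                      seq = character(0), qual = character(0),
                      cigar = character(0), mapped = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (n == 0L) { attr(empty, "n_unmapped") <- 0L; return(empty) }
  rl <- nchar(reads$seq)
  if (length(unique(rl)) != 1L)
    stop_input("fixture aligner expects uniform read length")
  rl <- rl[1]
  if (anchor_len > rl) stop_input("anchor_len exceeds read length")
  ridx <- build_ref_index(reference, anchor_len, pad = rl)

  # candidate placements: (read, orientation, global start)
  offs <- unique(c(seq(1L, rl - anchor_len + 1L, by = anchor_len),
                   rl - anchor_len + 1L))
  oriented <- list(`+` = toupper(reads$seq),
                   `-` = reverse_complement(reads$seq))
  cand <- vector("list", 2L * length(offs))
  ci <- 0L
  for (strand in c("+", "-")) {
    for (off in offs) {
      kmers <- substr(oriented[[strand]], off, off + anchor_len - 1L)
      hits <- mget(kmers, envir = ridx$env, ifnotfound = list(NULL))
      nh <- lengths(hits)
      if (!any(nh > 0L)) next
      ci <- ci + 1L
      cand[[ci]] <- data.table(
        read = rep.int(seq_len(n), nh),
        strand = strand,
        gstart = unlist(hits, use.names = FALSE) - (off - 1L))
    }
  }
  if (ci == 0L) {
    out <- data.frame(qname = reads$id, chrom = NA_character_, start = NA_real_,
                      strand = NA_character_, seq = reads$seq, qual = reads$qual,
                      cigar = "*", mapped = FALSE, reason = "noanchor",
                      stringsAsFactors = FALSE)
    attr(out, "n_unmapped") <- n
    return(out)
  }
  cand <- unique(rbindlist(cand[seq_len(ci)]))
  cand <- cand[gstart >= 0L]
  # drop placements running off the global string or into a separator pad
  cand <- cand[gstart + rl <= nchar(ridx$glob)]

  # vectorized scoring: column-wise compare of read vs reference window
  rseq <- oriented$`+`[cand$read]
  rseq[cand$strand == "-"] <- oriented$`-`[cand$read[cand$strand == "-"]]
  wins <- substring(ridx$glob, cand$gstart + 1L, cand$gstart + rl)
  a <- matrix(utf8ToInt(paste(rseq, collapse = "")), nrow = rl)
  b <- matrix(utf8ToInt(paste(wins, collapse = "")), nrow = rl)
  cand[, score := colSums(a == b)]
  cand <- cand[!grepl("#", wins, fixed = TRUE)]

  best <- cand[, {
    m <- max(score)
    top <- .SD[score == m]
    if (nrow(top) > 1L)
      list(strand = NA_character_, gstart = NA_integer_, score = m, amb = TRUE)
    else
      list(strand = top$strand, gstart = top$gstart, score = m, amb = FALSE)
  }, by = read]

  out <- data.frame(qname = reads$id, chrom = NA_character_, start = NA_real_,
                    strand = NA_character_, seq = reads$seq, qual = reads$qual,
                    cigar = "*", mapped = FALSE, reason = "noanchor",
                    stringsAsFactors = FALSE)
  hit <- best[amb == FALSE]
  if (nrow(hit)) {
    i <- hit$read
    chrom_idx <- findInterval(hit$gstart, ridx$offsets)
    out$chrom[i] <- names(ridx$offsets)[chrom_idx]
    out$start[i] <- hit$gstart - ridx$offsets[chrom_idx]
    out$strand[i] <- hit$strand
    ineg <- i[hit$strand == "-"]
    out$seq[ineg] <- oriented$`-`[ineg]
    out$qual[ineg] <- vapply(strsplit(out$qual[ineg], ""),
                             function(q) paste(rev(q), collapse = ""),
                             character(1))
    out$cigar[i] <- paste0(rl, "M")
    out$mapped[i] <- TRUE
    out$reason[i] <- "mapped"
  }
  amb <- best[amb == TRUE]
  if (nrow(amb)) out$reason[amb$read] <- "ambiguous"
  attr(out, "n_unmapped") <- sum(!out$mapped)
  out
}
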