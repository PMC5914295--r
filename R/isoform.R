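# Combinatorial multi-site editing isoform quantification.  For k editable
# adenosines on one amplicon there are 2^k phased editing haplotypes; each
# gets an "artificial chromosome" (the amplicon with G substituted at its
# edited sites) and reads are assigned by their base pattern at the k
# positions, a deterministic rule equivalent in intent to aligning against
# all 2^k references but with an explicit decision boundary.

#' The 5-HT2CR exon 5 editing motif and site metadata
#'
#' The serotonin 2C receptor is edited at five closely spaced adenosines in
#' exon 5 (sites A, B, E, C, D in genomic order); the motif carrying them
#' is `ATACGTAATCCTA`, whose adenosines are exactly those five sites.
#' These helpers expose the motif, the conventional amplicon region used
#' for targeted re-sequencing of the locus, and the site names.
#'
#' @return `ht2cr_exon5_motif()`: the motif string; `ht2cr_site_names()`:
#'   the five site names in genomic order; `ht2cr_amplicon_region()`: the
#'   1-based region string of the 178 bp PCR product.
#' @export
ht2cr_exon5_motif <- function() "ATACGTAATCCTA"

#' @rdname ht2cr_exon5_motif
#' @export
ht2cr_site_names <- function() c("A", "B", "E", "C", "D")

#' @rdname ht2cr_exon5_motif
#' @export
ht2cr_amplicon_region <- function() "chrX:147169590-147169767"

#' Positions of adenosines in a sequence
#'
#' @param sequence A DNA string.
#' @return Integer vector of 1-based positions carrying `A`.
#' @export
editable_adenosines <- function(sequence) {
  which(strsplit(toupper(sequence), "")[[1]] == "A")
}

#' Enumerate all 2^k editing haplotypes of an amplicon
#'
#' Haplotypes are ordered by bitmask 0 .. 2^k - 1 with site 1 (leftmost)
#' as the most significant bit, so labels run in dictionary order
#' (`aaa`, `aag`, ..., `ggg`) and haplotype 0 is the unedited amplicon.
#' The label has `g` at position i iff site i is edited; the sequence
#' differs from the amplicon exactly at the edited sites, A replaced by G.
#'
#' @param amplicon The unedited amplicon sequence; every editable position
#'   must carry `A`.
#' @param editable_positions Strictly increasing 1-based positions within
#'   the amplicon (default: every adenosine).
#' @return data.frame of class `editing_haplotypes` with columns `bitmask`,
#'   `label`, `seq`; attributes `positions` and `amplicon`.
#' @export
enumerate_haplotypes <- function(amplicon,
                                 editable_positions = editable_adenosines(amplicon)) {
  amplicon <- toupper(amplicon)
  pos <- as.integer(editable_positions)
  k <- length(pos)
  if (k > 0) {
    if (any(diff(pos) <= 0)) stop_input("editable positions must be strictly increasing")
    if (any(pos < 1L | pos > nchar(amplicon)))
      stop_input("editable position outside the amplicon")
    bases <- substring(amplicon, pos, pos)
    if (any(bases != "A"))
      stop_input("editable position %d carries '%s', expected 'A'",
                 pos[which(bases != "A")[1]], bases[bases != "A"][1])
  }
  if (k > 20L) stop_input("refusing to enumerate 2^%d haplotypes", k)
  masks <- 0:(2^k - 1)
  bit_of <- function(m, i) bitwAnd(m, 2^(k - i)) > 0          # site i = MSB order
  labels <- vapply(masks, function(m) {
    paste(ifelse(vapply(seq_len(k), bit_of, logical(1), m = m), "g", "a"),
          collapse = "")
  }, character(1))
  seqs <- vapply(masks, function(m) {
    s <- amplicon
    for (i in seq_len(k)) if (bit_of(m, i)) substr(s, pos[i], pos[i]) <- "G"
    s
  }, character(1))
  out <- data.frame(bitmask = masks, label = labels, seq = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "positions") <- pos
  attr(out, "amplicon") <- amplicon
  class(out) <- c("editing_haplotypes", "data.frame")
  out
}

#' Build the artificial-chromosome reference for a haplotype set
#'
#' One FASTA record per haplotype, named by its a/g label.
#'
#' @param haplotypes From [enumerate_haplotypes()].
#' @param path Optional path; when given the FASTA is written there.
#' @return Named character vector (label -> sequence).
#' @export
build_artificial_reference <- function(haplotypes, path = NULL) {
  stopifnot(nrow(haplotypes) >= 1L)
  if (anyDuplicated(haplotypes$label))
    stop_input("duplicate haplotype labels")
  ref <- stats::setNames(haplotypes$seq, haplotypes$label)
  if (!is.null(path)) write_fasta(ref, path)
  ref
}

#' Assign amplicon reads to editing haplotypes
#'
#' Each read is placed on the amplicon frame (both orientations, all
#' offsets; editable positions are wildcards during placement) and its
#' bases at the k editable positions are extracted.  A read is assigned to
#' the unique haplotype matching that base pattern when
#' * the placement is unique and spans all k sites,
#' * every site base is A or G, and
#' * off-site mismatches against the amplicon are at most
#'   `max_offsite_mismatches`.
#'
#' Reads with tied placements or not spanning all sites are tallied
#' `ambiguous`; non-A/G site bases, excess off-site mismatches or failed
#' placement are `unassigned`.  Per sample:
#' `assigned + ambiguous + unassigned == total`.
#'
#' @param reads Read table (columns `id`, `seq`, optionally `sample_id`) or
#'   a FASTQ path.
#' @param haplotypes From [enumerate_haplotypes()].
#' @param max_offsite_mismatches Sequencing-error allowance away from the
#'   editable sites.
#' @return A `haplotype_counts` object: list with `counts` (matrix,
#'   haplotype x sample), `assigned`, `ambiguous`, `unassigned`, `total`
#'   (per-sample vectors) and `haplotypes`.
#' @export
assign_reads <- function(reads, haplotypes, max_offsite_mismatches = 2L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  amplicon <- attr(haplotypes, "amplicon")
  pos <- attr(haplotypes, "positions")
  k <- length(pos)
  L <- nchar(amplicon)
  if (is.null(reads$sample_id)) reads$sample_id <- "sample1"
  samples <- unique(reads$sample_id)
  counts <- matrix(0L, nrow = nrow(haplotypes), ncol = length(samples),
                   dimnames = list(haplotypes$label, samples))
  ambiguous <- unassigned <- total <-
    stats::setNames(integer(length(samples)), samples)

  refv <- utf8ToInt(amplicon)
  wild <- seq_len(L) %in% pos
  gcode <- utf8ToInt("G"); acode <- utf8ToInt("A")

  for (s in samples) {
    rs <- reads[reads$sample_id == s, , drop = FALSE]
    total[s] <- nrow(rs)
    rl <- nchar(rs$seq)
    res_mask <- rep(NA_integer_, nrow(rs))   # NA = not assigned yet
    res_state <- rep("unassigned", nrow(rs))

    full <- which(rl == L)
    if (length(full)) {
      fwd <- matrix(utf8ToInt(paste(toupper(rs$seq[full]), collapse = "")), nrow = L)
      rev <- matrix(utf8ToInt(paste(reverse_complement(rs$seq[full]),
                                    collapse = "")), nrow = L)
      off_f <- colSums((fwd != refv) & !wild)
      off_r <- colSums((rev != refv) & !wild)
      site_f <- colSums(fwd[wild, , drop = FALSE] != refv[wild])
      site_r <- colSums(rev[wild, , drop = FALSE] != refv[wild])
      tot_f <- off_f + site_f
      tot_r <- off_r + site_r
      use_rev <- tot_r < tot_f
      tie <- tot_r == tot_f
      M <- fwd
      M[, use_rev] <- rev[, use_rev]
      offsite <- ifelse(use_rev, off_r, off_f)
      site_bases <- M[wild, , drop = FALSE]        # k x n, in position order
      ok_bases <- colSums(site_bases == gcode | site_bases == acode) == k
      assignable <- !tie & ok_bases & offsite <= max_offsite_mismatches
      if (k > 0) {
        bitvals <- 2^(k - seq_len(k))
        maskv <- as.integer(colSums((site_bases == gcode) * bitvals))
      } else maskv <- integer(ncol(M))
      res_state[full[tie]] <- "ambiguous"
      res_state[full[assignable]] <- "assigned"
      res_mask[full[assignable]] <- maskv[assignable]
    }
    partial <- which(rl != L)
    for (i in partial) {
      r <- place_partial_read(toupper(rs$seq[i]), amplicon, refv, wild, pos, k,
                              max_offsite_mismatches)
      res_state[i] <- r$state
      res_mask[i] <- r$mask
    }
    asn <- which(res_state == "assigned")
    if (length(asn)) {
      tab <- table(factor(res_mask[asn], levels = haplotypes$bitmask))
      counts[, s] <- counts[, s] + as.integer(tab)
    }
    ambiguous[s] <- sum(res_state == "ambiguous")
    unassigned[s] <- sum(res_state == "unassigned")
  }
  structure(list(counts = counts,
                 assigned = colSums(counts),
                 ambiguous = ambiguous,
                 unassigned = unassigned,
                 total = total,
                 haplotypes = haplotypes),
            class = "haplotype_counts")
}

# Slide a shorter-than-amplicon read over both orientations; wildcard the
# editable sites during scoring.  Returns state + bitmask.
place_partial_read <- function(seq, amplicon, refv, wild, pos, k, max_off) {
  rlen <- nchar(seq)
  L <- length(refv)
  if (rlen > L) return(list(state = "unassigned", mask = NA_integer_))
  best <- NULL; best_score <- -1L; best_n <- 0L
  for (orient in c("+", "-")) {
    rv <- utf8ToInt(if (orient == "+") seq else reverse_complement(seq))
    for (off in 0:(L - rlen)) {
      win <- (off + 1):(off + rlen)
      sc <- sum(rv == refv[win] | wild[win])
      if (sc > best_score) {
        best_score <- sc; best_n <- 1L
        best <- list(rv = rv, off = off, win = win)
      } else if (sc == best_score) best_n <- best_n + 1L
    }
  }
  if (is.null(best) || best_n > 1L)
    return(list(state = "ambiguous", mask = NA_integer_))
  if (!all(pos %in% best$win))
    return(list(state = "ambiguous", mask = NA_integer_))
  offsite <- sum(best$rv != refv[best$win] & !wild[best$win])
  if (offsite > max_off) return(list(state = "unassigned", mask = NA_integer_))
  site_bases <- best$rv[pos - best$off]
  if (!all(site_bases %in% c(utf8ToInt("A"), utf8ToInt("G"))))
    return(list(state = "unassigned", mask = NA_integer_))
  mask <- sum((site_bases == utf8ToInt("G")) * 2^(k - seq_len(k)))
  list(state = "assigned", mask = as.integer(mask))
}

#' Haplotype frequencies from counts
#'
#' @param counts A `haplotype_counts`.
#' @return Matrix haplotype x sample of `count / assigned`; samples with 0
#'   assigned reads get `NA` with a warning.
#' @export
haplotype_frequencies <- function(counts) {
  stopifnot(inherits(counts, "haplotype_counts"))
  asn <- counts$assigned
  if (any(asn == 0)) warning("sample(s) with zero assigned reads: frequencies NA")
  sweep(counts$counts, 2, ifelse(asn > 0, asn, NA), "/")
}

#' Per-site marginal editing frequencies from haplotype counts
#'
#' The marginal frequency of site i is the summed frequency of all
#' haplotypes with bit i set — on error-free reads this equals the pileup
#' frequency at the same position.
#'
#' @param counts A `haplotype_counts`.
#' @return Matrix site x sample of marginal editing frequencies.
#' @export
site_marginals <- function(counts) {
  stopifnot(inherits(counts, "haplotype_counts"))
  if (all(counts$assigned == 0)) stop_input("no assigned reads: marginals undefined")
  freq <- haplotype_frequencies(counts)
  hap <- counts$haplotypes
  k <- length(attr(hap, "positions"))
  bits <- vapply(seq_len(k), function(i) bitwAnd(hap$bitmask, 2^(k - i)) > 0,
                 logical(nrow(hap)))
  bits <- matrix(bits, nrow = nrow(hap))            # hap x site
  out <- t(bits) %*% freq
  rownames(out) <- paste0("site", seq_len(k))
  out
}

#' Grouped haplotype frequencies
#'
#' Aggregates haplotype frequencies into named transcript groups given by
#' bitmask predicates (e.g. "edited at both A and B").  The predicates
#' must partition the haplotype set: every haplotype in exactly one group.
#'
#' @param counts A `haplotype_counts`.
#' @param groups Named list of functions `f(bitmask, label) -> logical`.
#' @return Matrix group x sample of summed frequencies (columns sum to 1).
#' @export
group_frequencies <- function(counts, groups) {
  stopifnot(inherits(counts, "haplotype_counts"), length(groups) >= 1L,
            !is.null(names(groups)))
  hap <- counts$haplotypes
  member <- vapply(groups, function(f) {
    as.logical(mapply(f, hap$bitmask, hap$label))
  }, logical(nrow(hap)))
  member <- matrix(member, nrow = nrow(hap), dimnames = list(hap$label, names(groups)))
  hits <- rowSums(member)
  if (any(hits != 1L))
    stop_input("groups do not partition the haplotypes (haplotype %s in %d groups)",
               hap$label[which(hits != 1L)[1]], hits[hits != 1L][1])
  freq <- haplotype_frequencies(counts)
  out <- t(member) %*% freq
  out
}

#' One-way ANOVA of per-haplotype (or per-group) frequencies by genotype
#'
#' Standard fixed-effects one-way ANOVA of each row of `frequencies`
#' across the genotype levels of `design`.  With zero between-group and
#' zero within-group variance, F = 0 and p = 1 by convention; with zero
#' within-group variance but distinct means, p = 0.
#'
#' @param frequencies Matrix unit x sample (columns named by sample id).
#' @param design Sample design with >= 2 samples per genotype.
#' @return data.frame: `unit`, `F`, `p`.
#' @export
anova_across_genotypes <- function(frequencies, design) {
  design <- validate_design(design)
  if (any(table(design$genotype) < 2L))
    stop_input("need >= 2 samples per genotype")
  if (!all(design$sample_id %in% colnames(frequencies)))
    stop_input("frequency matrix lacks columns for some design samples")
  f <- frequencies[, design$sample_id, drop = FALSE]
  res <- t(apply(f, 1L, function(v) one_way_anova(v, design$genotype)))
  data.frame(unit = rownames(frequencies), F = res[, 1], p = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

one_way_anova <- function(values, groups) {
  g <- split(values, groups)
  n <- lengths(g)
  grand <- mean(values)
  ssb <- sum(n * (vapply(g, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- length(g) - 1L
  dfw <- length(values) - length(g)
  tol <- 1e-14 * max(1, sum(values^2))
  if (ssw <= tol) {
    if (ssb <= tol) return(c(F = 0, p = 1))
    return(c(F = Inf, p = 0))
  }
  F <- (ssb / dfb) / (ssw / dfw)
  c(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}
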