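# Candidate A-to-I editing site detection.  Editing appears as A>G on the
# forward letters for sites on + transcripts, and as T>C for sites on -
# transcripts (inosine pairs like guanosine; the antisense A>G is read on
# the forward strand as its complement).  No other mismatch pattern is
# ever a candidate.

#' Detect candidate editing sites across samples
#'
#' A position is a candidate editing site iff
#' * the reference base is A with G mismatches (reported strand `+`) or
#'   T with C mismatches (reported strand `-`),
#' * every sample has quality-passing coverage of at least `min_cov`
#'   (a site untestable in any sample is dropped), and
#' * the unweighted mean of the per-sample edited fractions is at least
#'   `min_mean_freq`.
#'
#' The pooled-count frequency is reported alongside the per-sample mean
#' (the mean is the filter).
#'
#' @param pileups Named list of per-sample `pileup` objects (names are
#'   sample ids); all must share one reference.
#' @param min_cov Minimum per-sample coverage (default 20 reads).
#' @param min_mean_freq Minimum mean edited fraction (default 5%).
#' @return data.frame with one row per candidate: `chrom`, `pos` (0-based),
#'   `strand`, `ref`, `alt`, per-sample `cov_*` / `edit_*` columns,
#'   `mean_freq`, `pooled_freq`.
#' @export
detect_candidates <- function(pileups, min_cov = 20L, min_mean_freq = 0.05) {
  stopifnot(length(pileups) >= 1L)
  if (min_cov <= 0 || min_mean_freq <= 0)
    stop_input("thresholds must be positive")
  if (is.null(names(pileups)))
    names(pileups) <- paste0("s", seq_along(pileups))
  samples <- names(pileups)

  per_sample <- lapply(samples, function(s) {
    cnt <- pileup_counts(pileups[[s]])
    cnt[, cov := A_plus + A_minus + C_plus + C_minus + G_plus + G_minus +
          T_plus + T_minus + N_plus + N_minus]
    cnt[, edit := fifelse(ref == "A", G_plus + G_minus,
                  fifelse(ref == "T", C_plus + C_minus, 0L))]
    out <- cnt[, .(chrom, pos, ref, cov, edit)]
    setnames(out, c("cov", "edit"), paste0(c("cov_", "edit_"), s))
    out
  })
  merged <- Reduce(function(x, y) {
    m <- merge(x, y, by = c("chrom", "pos"), all = TRUE,
               suffixes = c("", ".y"))
    if ("ref.y" %in% names(m)) {
      bad <- m[!is.na(ref) & !is.na(ref.y) & ref != ref.y]
      if (nrow(bad))
        stop_input("inconsistent reference base across samples at %s:%.0f",
                   bad$chrom[1], bad$pos[1])
      m[, ref := fifelse(is.na(ref), ref.y, ref)]
      m[, ref.y := NULL]
    }
    m
  }, per_sample)
  cov_cols <- paste0("cov_", samples)
  edit_cols <- paste0("edit_", samples)
  for (col in c(cov_cols, edit_cols))
    set(merged, which(is.na(merged[[col]])), col, 0L)

  covm <- as.matrix(merged[, ..cov_cols])
  editm <- as.matrix(merged[, ..edit_cols])
  freq <- editm / ifelse(covm > 0, covm, NA)
  mean_freq <- rowMeans(freq, na.rm = TRUE)
  mean_freq[is.nan(mean_freq)] <- 0
  pooled_freq <- rowSums(editm) / pmax(rowSums(covm), 1L)

  keep <- merged$ref %in% c("A", "T") &
    rowSums(editm) > 0L &
    apply(covm >= min_cov, 1L, all) &
    mean_freq >= min_mean_freq
  out <- as.data.frame(merged[keep, c("chrom", "pos", "ref", cov_cols,
                                      edit_cols), with = FALSE])
  out$strand <- ifelse(out$ref == "A", "+", "-")
  out$alt <- ifelse(out$ref == "A", "G", "C")
  out$mean_freq <- mean_freq[keep]
  out$pooled_freq <- pooled_freq[keep]
  out <- out[order(out$chrom, out$pos),
             c("chrom", "pos", "strand", "ref", "alt",
               cov_cols, edit_cols, "mean_freq", "pooled_freq")]
  rownames(out) <- NULL
  out
}

#' Flag candidates at known variant positions
#'
#' Candidates whose position is in the mask (e.g. common dbSNP sites) are
#' flagged `masked_snp = TRUE`; downstream filtering and differential
#' testing exclude them.
#'
#' @param candidates Candidate table from [detect_candidates()].
#' @param mask Position set from [read_site_mask()] (columns `chrom`,
#'   `pos`, 0-based), or `NULL` for no masking.
#' @return `candidates` with a `masked_snp` column.
#' @export
mask_known_variants <- function(candidates, mask) {
  if (is.null(mask) || nrow(mask) == 0L) {
    candidates$masked_snp <- FALSE
    return(candidates)
  }
  key <- paste(candidates$chrom, candidates$pos)
  candidates$masked_snp <- key %in% paste(mask$chrom, mask$pos)
  candidates
}

#' Per-site editing frequencies for an amplicon pileup
#'
#' Amplicon deep re-sequencing mode: every position whose reference base
#' is A (or T for antisense) is reported when its quality-passing G (or C)
#' mismatch frequency reaches `min_freq` (default 1%).
#'
#' @param pileup A `pileup` of targeted amplicon reads.
#' @param min_freq Minimum edited fraction to report.
#' @return data.frame: `chrom`, `pos` (0-based), `strand`, `ref`, `alt`,
#'   `coverage`, `edited`, `freq`.
#' @export
amplicon_site_frequencies <- function(pileup, min_freq = 0.01) {
  cnt <- pileup_counts(pileup)
  if (nrow(cnt) == 0L || sum(cnt[, A_plus + A_minus + C_plus + C_minus +
                                   G_plus + G_minus + T_plus + T_minus]) == 0L) {
    warning("amplicon pileup has no quality-passing coverage")
    return(data.frame(chrom = character(0), pos = numeric(0),
                      strand = character(0), ref = character(0),
                      alt = character(0), coverage = integer(0),
                      edited = integer(0), freq = numeric(0)))
  }
  cnt[, coverage := A_plus + A_minus + C_plus + C_minus + G_plus + G_minus +
        T_plus + T_minus + N_plus + N_minus]
  cnt[, edited := fifelse(ref == "A", G_plus + G_minus,
                 fifelse(ref == "T", C_plus + C_minus, 0L))]
  cnt <- cnt[ref %in% c("A", "T") & coverage > 0L]
  cnt[, freq := edited / coverage]
  out <- as.data.frame(cnt[freq >= min_freq,
                           .(chrom, pos, ref, coverage, edited, freq)])
  out$strand <- ifelse(out$ref == "A", "+", "-")
  out$alt <- ifelse(out$ref == "A", "G", "C")
  out[, c("chrom", "pos", "strand", "ref", "alt", "coverage", "edited", "freq")]
}
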