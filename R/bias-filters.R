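# Artifact filters for candidate editing sites.  Each test compares
# quality-passing alternate-allele observations against reference
# observations at one position:
#   strand bias      — Fisher exact test on the {ref, alt} x {+, -} table;
#   read position    — two-sided rank-sum on in-read offsets;
#   variant distance — two-sided rank-sum on distance to nearest read end.
# Rank-sum tests use the normal approximation with tie correction; a
# position with fewer than 2 alt or 2 ref observations is untestable and
# passes by convention (p = 1).

column_ref_alt <- function(column) {
  ref <- column$ref
  alt <- if (ref == "A") "G" else if (ref == "T") "C" else NA_character_
  obs <- column$obs
  if ("filtered" %in% names(obs)) obs <- obs[obs$filtered == FALSE, ]
  list(ref = ref, alt = alt,
       ref_obs = obs[obs$base == ref, ],
       alt_obs = if (is.na(alt)) obs[0, ] else obs[obs$base == alt, ])
}

#' Strand bias test
#'
#' Two-sided Fisher exact test on the 2x2 table of {reference, alternate}
#' allele counts by {+, -} strand.  A table with an all-zero margin is
#' unbiased by convention (p = 1).
#'
#' @param column A `pileup_column` (see [pileup_column()]).
#' @return p-value.
#' @export
strand_bias_test <- function(column) {
  x <- column_ref_alt(column)
  tab <- matrix(c(sum(x$ref_obs$strand == "+"), sum(x$ref_obs$strand == "-"),
                  sum(x$alt_obs$strand == "+"), sum(x$alt_obs$strand == "-")),
                nrow = 2, byrow = TRUE)
  fisher_p(tab)
}

fisher_p <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Two-sided rank-sum test (normal approximation, tie-corrected)
#'
#' Mann-Whitney U comparing samples `x` and `y`.  The statistic is
#' `U = R_x - n_x (n_x + 1) / 2` with `R_x` the rank sum of `x` in the
#' pooled ranking (midranks for ties); the p-value is the two-sided normal
#' tail of `(U - n_x n_y / 2) / sd`, with the usual tie-corrected variance.
#' When the variance is 0 (all pooled values tied) p = 1.
#'
#' @param x,y Numeric vectors.
#' @return Named list `U`, `p`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  tie <- table(c(x, y))
  v <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs((U - n1 * n2 / 2) / sqrt(v)))
  list(U = U, p = min(p, 1))
}

ranksum_column <- function(column, field) {
  x <- column_ref_alt(column)
  if (nrow(x$alt_obs) < 2L || nrow(x$ref_obs) < 2L) {
    p <- 1
    attr(p, "untestable") <- TRUE
    return(p)
  }
  rank_sum_test(x$alt_obs[[field]], x$ref_obs[[field]])$p
}

#' Read position bias test
#'
#' Two-sided rank-sum comparing the in-read offsets (sequencing-cycle
#' coordinates) of alternate vs reference observations.
#'
#' @param column A `pileup_column`.
#' @return p-value; attribute `untestable` set when either allele has
#'   fewer than 2 observations.
#' @export
read_position_bias_test <- function(column) {
  ranksum_column(column, "offset")
}

#' Variant distance bias test
#'
#' Identical construction to [read_position_bias_test()] but on the
#' distance to the nearest read end.
#'
#' @param column A `pileup_column`.
#' @return p-value; attribute `untestable` set when either allele has
#'   fewer than 2 observations.
#' @export
variant_distance_bias_test <- function(column) {
  ranksum_column(column, "dist_end")
}

#' Apply the three bias filters to candidate sites
#'
#' Observations are pooled across samples at each candidate position and
#' the strand-bias, read-position-bias and variant-distance-bias tests are
#' run.  A candidate passes when it is not masked as a known variant and
#' all three p-values are at or above `p_threshold` (a small p is evidence
#' of artifact, so low p fails the site).
#'
#' @param candidates Candidate table from [detect_candidates()]
#'   (optionally after [mask_known_variants()]).
#' @param pileups Named list of per-sample `pileup` objects.
#' @param p_threshold Pass threshold on each p-value.
#' @return `candidates` with columns `strand_bias_p`, `read_position_p`,
#'   `variant_distance_p` and `pass` appended.
#' @export
apply_filters <- function(candidates, pileups, p_threshold = 0.01) {
  if (!"masked_snp" %in% names(candidates)) candidates$masked_snp <- FALSE
  n <- nrow(candidates)
  sb <- rp <- vd <- rep(1, n)
  pooled <- rbindlist(lapply(pileups, function(p) as.data.table(p)))
  reference <- attr(pileups[[1]], "reference")
  for (i in seq_len(n)) {
    .chrom <- candidates$chrom[i]; .pos <- candidates$pos[i]
    obs <- pooled[chrom == .chrom & pos == .pos]
    column <- structure(list(chrom = .chrom, pos = .pos,
                             ref = candidates$ref[i], obs = obs),
                        class = "pileup_column")
    sb[i] <- strand_bias_test(column)
    rp[i] <- as.numeric(read_position_bias_test(column))
    vd[i] <- as.numeric(variant_distance_bias_test(column))
  }
  candidates$strand_bias_p <- sb
  candidates$read_position_p <- rp
  candidates$variant_distance_p <- vd
  candidates$pass <- !candidates$masked_snp &
    sb >= p_threshold & rp >= p_threshold & vd >= p_threshold
  candidates
}
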