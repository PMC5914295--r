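#' Simulate amplicon deep re-sequencing reads from an editing-haplotype mix
#'
#' Each read covers the full amplicon (the merged-pair view of a short
#' amplicon sequenced with overlapping mates): its haplotype is drawn
#' i.i.d. from `pi`, uniform per-base substitution errors are applied, and
#' the read is reported in forward or reverse-complement orientation with
#' probability 1/2.
#'
#' @param haplotypes Haplotype table from [enumerate_haplotypes()].
#' @param pi Numeric frequency vector over the haplotypes (same order);
#'   must sum to 1 within 1e-12.
#' @param depth Number of reads, >= 1.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param sample_id Sample label stamped on the reads.
#' @param outdir Optional directory for FASTQ + truth output.
#' @return list with `reads` (read table: id, seq, qual, hap_truth,
#'   sample_id) and `truth` (`sim_truth` carrying the named frequency
#'   vector).
#' @export
simulate_amplicon <- function(haplotypes, pi, depth, error_rate = 0.001,
                              seed = 1L, sample_id = "amp1", outdir = NULL) {
  stopifnot(is.data.frame(haplotypes), all(c("label", "seq") %in% names(haplotypes)))
  if (length(pi) != nrow(haplotypes))
    stop_input("pi has length %d but there are %d haplotypes",
               length(pi), nrow(haplotypes))
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop_input("pi must be non-negative and sum to 1 (got %.15f)", sum(pi))
  if (depth < 1) stop_input("depth must be >= 1")
  L <- nchar(haplotypes$seq[1])

  reads <- with_seed(derive_seed(seed, sample_id), {
    hap_idx <- sample.int(nrow(haplotypes), depth, replace = TRUE, prob = pi)
    M <- matrix(unlist(strsplit(haplotypes$seq[hap_idx], "")),
                nrow = depth, byrow = TRUE)
    if (error_rate > 0) {
      err <- which(stats::runif(length(M)) < error_rate)
      if (length(err)) {
        others <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACGT")
        pick <- ceiling(stats::runif(length(err)) * 3)
        M[err] <- substr(others[M[err]], pick, pick)
      }
    }
    seqs <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
    rev <- stats::runif(depth) < 0.5
    seqs[rev] <- reverse_complement(seqs[rev])
    data.frame(id = sprintf("%s_%06d", sample_id, seq_len(depth)),
               seq = seqs, qual = strrep("I", L),
               hap_truth = haplotypes$label[hap_idx],
               sample_id = sample_id, stringsAsFactors = FALSE)
  })
  truth <- sim_truth(haplotype_freqs = stats::setNames(pi, haplotypes$label),
                     params = list(depth = depth, error_rate = error_rate,
                                   seed = seed))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads, file.path(outdir, paste0(sample_id, ".fastq")))
    write_truth(truth, outdir)
  }
  list(reads = reads, truth = truth)
}
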