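# Ground-truth container for simulations.  Truth is serialized to plain
# TSV next to the reads so tests recover it from files, never from logs.

sim_truth <- function(profile = NULL, snps = NULL, artifacts = NULL,
                      sample_seeds = NULL, design = NULL, params = list(),
                      haplotype_freqs = NULL) {
  if (!is.null(haplotype_freqs)) {
    if (abs(sum(haplotype_freqs) - 1) > 1e-12)
      stop_input("haplotype frequencies must sum to 1 (got %.15f)",
                 sum(haplotype_freqs))
    if (is.null(names(haplotype_freqs)))
      stop_input("haplotype frequencies must be named by label")
  }
  structure(list(profile = profile, snps = snps, artifacts = artifacts,
                 sample_seeds = sample_seeds, design = design, params = params,
                 haplotype_freqs = haplotype_freqs),
            class = "sim_truth")
}

#' Serialize simulation truth to TSV files
#'
#' Writes `truth_sites.tsv` (editing profile, 1-based positions),
#' `truth_snps.tsv`, `truth_artifacts.tsv` and `truth_haplotypes.tsv` into
#' `dir`, creating only the files whose component is present.
#'
#' @param truth A `sim_truth` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, file) {
    utils::write.table(d, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(truth$profile)) {
    p <- as.data.frame(truth$profile)
    p$pos_1based <- p$pos + 1
    p$pos <- NULL
    wr(p[, c("chrom", "pos_1based", "strand",
             grep("^eps_", names(p), value = TRUE))], "truth_sites.tsv")
  }
  if (!is.null(truth$snps)) {
    s <- truth$snps
    s$pos_1based <- s$pos + 1
    wr(s[, c("chrom", "pos_1based", "vaf")], "truth_snps.tsv")
  }
  if (!is.null(truth$artifacts)) {
    a <- truth$artifacts
    a$pos_1based <- a$pos + 1
    wr(a[, c("chrom", "pos_1based", "mode")], "truth_artifacts.tsv")
  }
  if (!is.null(truth$haplotype_freqs)) {
    wr(data.frame(label = names(truth$haplotype_freqs),
                  freq = format(truth$haplotype_freqs, digits = 17),
                  stringsAsFactors = FALSE), "truth_haplotypes.tsv")
  }
  invisible(dir)
}

#' Read serialized simulation truth
#'
#' Inverse of [write_truth()] for the components present in `dir`.
#'
#' @param dir Directory written by [write_truth()].
#' @return A `sim_truth` object (components absent on disk are `NULL`).
#' @export
read_truth <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  profile <- rd("truth_sites.tsv")
  if (!is.null(profile)) {
    profile$pos <- profile$pos_1based - 1
    profile$pos_1based <- NULL
    profile <- profile[, c("chrom", "pos", "strand",
                           grep("^eps_", names(profile), value = TRUE))]
    class(profile) <- c("editing_profile", "data.frame")
  }
  snps <- rd("truth_snps.tsv")
  if (!is.null(snps)) {
    snps$pos <- snps$pos_1based - 1
    snps <- snps[, c("chrom", "pos", "vaf")]
  }
  artifacts <- rd("truth_artifacts.tsv")
  if (!is.null(artifacts)) {
    artifacts$pos <- artifacts$pos_1based - 1
    artifacts <- artifacts[, c("chrom", "pos", "mode")]
  }
  hf <- rd("truth_haplotypes.tsv")
  haplotype_freqs <- if (!is.null(hf)) stats::setNames(as.numeric(hf$freq), hf$label)
  sim_truth(profile = profile, snps = snps, artifacts = artifacts,
            haplotype_freqs = haplotype_freqs)
}
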