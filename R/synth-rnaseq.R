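# Stranded RNA-seq read simulator with fully known editing truth.
# Fragments are placed uniformly on each transcript; editing is applied
# first (biology), sequencing error afterwards (machine noise), so
# error_rate = 0 isolates the editing signal exactly.

#' Simulate stranded RNA-seq reads with planted editing
#'
#' For every sample in `design`, reads are drawn as uniformly placed
#' `read_len`-substrings of uniformly chosen transcripts.  At each profiled
#' site, every covering read is independently edited with the genotype's
#' true rate: A>G on the forward letters for `+` sites, T>C for `-` sites
#' (antisense editing seen on the forward strand).  Optional heterozygous
#' SNPs are planted identically in all genotypes.  Uniform per-base
#' sequencing errors are applied last.  Each read is reported on the `+`
#' or `-` mapped strand with probability 1/2 (both physical strands of the
#' fragment are sequenced).
#'
#' Each sample has its own RNG stream derived from `(seed, sample_id)`, so
#' per-sample output is reproducible regardless of sample order.
#'
#' @param reference Named character vector of transcript sequences.
#' @param profile An [editing_profile()].
#' @param design Sample design (see [default_design()]); `genotype` values
#'   must match the profile's `eps_<genotype>` columns.
#' @param depth Target mean per-base coverage per sample, >= 1.
#' @param read_len Read length; every transcript must be at least this long.
#' @param error_rate Per-base substitution error probability, < 0.05.
#' @param seed Master integer seed.
#' @param snps Optional data.frame `chrom`, `pos` (0-based), `vaf` planting
#'   genotype-independent variants (A>G / T>C at the given allele fraction).
#' @param outdir Optional directory; when given, per-sample FASTQ files and
#'   the truth tables are written there.
#' @return list with `reads` (named list of per-sample read tables with
#'   columns id, seq, qual, chrom, start, strand, sample_id) and `truth`
#'   (a `sim_truth` object).
#' @export
simulate_rnaseq <- function(reference, profile, design = default_design(),
                            depth = 30, read_len = 75, error_rate = 0.001,
                            seed = 1L, snps = NULL, outdir = NULL) {
  design <- validate_design(design)
  if (depth < 1) stop_input("depth must be >= 1")
  if (error_rate < 0 || error_rate >= 0.05)
    stop_input("error_rate must be in [0, 0.05)")
  if (any(nchar(reference) < read_len))
    stop_input("every transcript must be at least read_len long")
  validate_profile(profile, reference)
  genos <- unique(design$genotype)
  missing_eps <- setdiff(paste0("eps_", genos), names(profile))
  if (length(missing_eps))
    stop_input("profile lacks rate column(s): %s", paste(missing_eps, collapse = ", "))
  if (!is.null(snps)) {
    stopifnot(all(c("chrom", "pos") %in% names(snps)))
    if (is.null(snps$vaf)) snps$vaf <- 0.5
  }

  seeds <- vapply(design$sample_id, function(s) derive_seed(seed, s), integer(1))
  names(seeds) <- design$sample_id
  reads <- vector("list", nrow(design))
  names(reads) <- design$sample_id
  for (i in seq_len(nrow(design))) {
    reads[[i]] <- with_seed(seeds[[i]], sim_sample_reads(
      reference, profile, design$genotype[i], design$sample_id[i],
      depth, read_len, error_rate, snps))
  }
  truth <- sim_truth(profile = profile, snps = snps, artifacts = NULL,
                     sample_seeds = seeds, design = design,
                     params = list(depth = depth, read_len = read_len,
                                   error_rate = error_rate, seed = seed))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(reads))
      write_fastq(reads[[s]], file.path(outdir, paste0(s, ".fastq")))
    write_truth(truth, outdir)
  }
  list(reads = reads, truth = truth)
}

# One sample's reads; assumes RNG already seeded by caller.
sim_sample_reads <- function(reference, profile, genotype, sample_id,
                             depth, read_len, error_rate, snps) {
  eps_col <- paste0("eps_", genotype)
  per_tx <- vector("list", length(reference))
  for (t in seq_along(reference)) {
    chrom <- names(reference)[t]
    refc <- strsplit(reference[[t]], "")[[1]]
    L <- length(refc)
    n <- ceiling(depth * L / read_len)
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
    idx <- outer(starts, seq_len(read_len), `+`)          # n x read_len, 1-based
    M <- matrix(refc[idx], nrow = n)

    plant <- function(pos, alt, prob) {
      cov <- which(starts <= pos & pos < starts + read_len)
      if (!length(cov)) return(invisible())
      hit <- cov[stats::runif(length(cov)) < prob]
      if (length(hit)) M[cbind(hit, pos - starts[hit] + 1L)] <<- alt
    }
    prof_t <- profile[profile$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(prof_t)))
      plant(prof_t$pos[j], if (prof_t$strand[j] == "+") "G" else "C",
            prof_t[[eps_col]][j])
    if (!is.null(snps)) {
      snp_t <- snps[snps$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(snp_t))) {
        ref_b <- refc[snp_t$pos[j] + 1L]
        plant(snp_t$pos[j], if (ref_b == "A") "G" else if (ref_b == "T") "C"
              else stop_input("SNP at %s:%.0f is not on an A/T", chrom, snp_t$pos[j]),
              snp_t$vaf[j])
      }
    }
    if (error_rate > 0) {
      err <- which(stats::runif(length(M)) < error_rate)
      if (length(err)) {
        others <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACGT")
        pick <- ceiling(stats::runif(length(err)) * 3)
        M[err] <- substr(others[M[err]], pick, pick)
      }
    }
    seqs <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
    rev <- stats::runif(n) < 0.5
    seqs[rev] <- reverse_complement(seqs[rev])
    per_tx[[t]] <- data.frame(
      id = sprintf("%s_%s_%06d", sample_id, chrom, seq_len(n)),
      seq = seqs,
      qual = strrep("I", read_len),
      chrom = chrom, start = as.numeric(starts),
      strand = ifelse(rev, "-", "+"),
      sample_id = sample_id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, per_tx)
  rownames(out) <- NULL
  out
}

#' Plant a strand-skew or end-cluster artifact into simulated reads
#'
#' Rewrites read bases at one position so the alternate allele shows the
#' signature the bias filters are designed to catch:
#' * `strand_skew`: alternate bases appear on `+` strand reads only
#'   (a fraction `alt_fraction` of them); `-` strand reads keep the
#'   reference base.
#' * `end_cluster`: every covering read whose distance to the nearest read
#'   end at this position is <= 5 bp gets the alternate base; all others
#'   keep the reference.
#'
#' @param reads A read table from [simulate_rnaseq()] (one sample).
#' @param reference Named character vector of reference sequences.
#' @param chrom,position Artifact site (0-based, must be a reference A or T).
#' @param mode `"strand_skew"` or `"end_cluster"`.
#' @param seed Integer seed (used by `strand_skew` subsampling).
#' @param alt_fraction Fraction of `+` strand covering reads made alternate
#'   in `strand_skew` mode.
#' @return list with `reads` (modified table) and `artifact` (one-row
#'   data.frame describing the planted site).
#' @export
plant_artifact <- function(reads, reference, chrom, position,
                           mode = c("strand_skew", "end_cluster"),
                           seed = 1L, alt_fraction = 0.5) {
  mode <- match.arg(mode)
  read_len <- nchar(reads$seq[1])
  cov <- which(reads$chrom == chrom &
               reads$start <= position & position < reads$start + read_len)
  if (length(cov) < 20L)
    stop_input("artifact site %s:%.0f covered by %d reads (< 20)",
               chrom, position, length(cov))
  ref_b <- substr(reference[[chrom]], position + 1, position + 1)
  alt <- if (ref_b == "A") "G" else if (ref_b == "T") "C"
         else stop_input("artifact site %s:%.0f is not on an A/T", chrom, position)

  fwd_off <- position - reads$start[cov]              # 0-based forward offset
  stored_idx <- ifelse(reads$strand[cov] == "+", fwd_off + 1, read_len - fwd_off)
  stored_base <- ifelse(reads$strand[cov] == "+", alt, complement_base(alt))
  stored_ref <- ifelse(reads$strand[cov] == "+", ref_b, complement_base(ref_b))

  set_base <- function(rows, bases) {
    for (k in seq_along(rows)) {
      r <- cov[rows[k]]
      substr(reads$seq[r], stored_idx[rows[k]], stored_idx[rows[k]]) <- bases[k]
    }
    reads
  }
  if (mode == "strand_skew") {
    plus <- which(reads$strand[cov] == "+")
    n_alt <- ceiling(alt_fraction * length(plus))
    hit <- with_seed(seed, sample(plus, n_alt))
    reads <- set_base(hit, stored_base[hit])
    reads <- set_base(setdiff(seq_along(cov), hit),
                      stored_ref[setdiff(seq_along(cov), hit)])
  } else {
    dist_end <- pmin(fwd_off, read_len - 1 - fwd_off)
    near <- which(dist_end <= 5)
    if (!length(near))
      stop_input("no covering read has %s:%.0f within 5 bp of an end", chrom, position)
    reads <- set_base(near, stored_base[near])
    reads <- set_base(setdiff(seq_along(cov), near),
                      stored_ref[setdiff(seq_along(cov), near)])
  }
  list(reads = reads,
       artifact = data.frame(chrom = chrom, pos = position, mode = mode,
                             stringsAsFactors = FALSE))
}
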