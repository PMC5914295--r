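# Programmatic fixtures: everything is built in code at test time.

# Assemble a pileup object directly from an observation table, bypassing
# alignment, for hand-built threshold-semantics fixtures.
make_pileup <- function(reference, obs, min_base_quality = 20L) {
  dt <- data.table::as.data.table(obs)
  need <- c("chrom", "pos", "base", "qual", "strand", "offset", "dist_end")
  for (col in setdiff(need, names(dt))) {
    dt[[col]] <- switch(col, qual = 40L, strand = "+", offset = 10L,
                        dist_end = 10L)
  }
  dt[, filtered := qual < min_base_quality]
  data.table::setkeyv(dt, c("chrom", "pos"))
  data.table::setattr(dt, "reference", reference)
  data.table::setattr(dt, "min_base_quality", as.integer(min_base_quality))
  data.table::setattr(dt, "class", c("pileup", class(dt)))
  dt[]
}

# n_ref + n_alt observations at one position with balanced strands and
# uniformly spread offsets: an unbiased column.
balanced_site_obs <- function(chrom, pos, ref, alt, n_ref, n_alt,
                              read_len = 60L) {
  n <- n_ref + n_alt
  offset <- (seq_len(n) * 7L) %% read_len
  data.frame(chrom = chrom, pos = pos,
             base = c(rep(ref, n_ref), rep(alt, n_alt)),
             qual = 40L,
             strand = rep_len(c("+", "-"), n),
             offset = offset,
             dist_end = pmin(offset, read_len - 1L - offset))
}

# Small end-to-end simulation shared by several tests: 1 transcript,
# two planted sites (one +, one -), error-free unless stated.
tiny_sim <- function(depth = 100, read_len = 60, error_rate = 0,
                     eps_wt = c(0.3, 0.5), eps_ko = c(0.1, 0.5), seed = 42) {
  ref <- make_reference(1, 300, 0.5, seed = 7)
  s <- strsplit(ref[[1]], "")[[1]]
  apos <- which(s == "A")
  tpos <- which(s == "T")
  # interior sites so every read placement can cover them
  site_a <- apos[apos > 80 & apos < 220][1]
  site_t <- tpos[tpos > 80 & tpos < 220][1]
  profile <- editing_profile(chrom = "tx1", pos = c(site_a, site_t) - 1,
                             strand = c("+", "-"),
                             eps_WT = eps_wt, eps_KO = eps_ko,
                             reference = ref)
  sim <- simulate_rnaseq(ref, profile, default_design(), depth = depth,
                         read_len = read_len, error_rate = error_rate,
                         seed = seed)
  list(ref = ref, profile = profile, sim = sim,
       sites = c(site_a, site_t) - 1)
}

align_all <- function(sim, ref, anchor_len = 12L, min_bq = 20L) {
  lapply(sim$reads, function(r) {
    build_pileup(align_fixture_reads(r, ref, anchor_len), ref, min_bq)
  })
}

# Realized edited fraction per site per sample, computed straight from the
# read table using placement truth (independent of aligner + pileup).
realized_freqs <- function(reads, pos0, alt_fwd, read_len) {
  vapply(reads, function(r) {
    cov <- r$start <= pos0 & pos0 < r$start + read_len
    rr <- r[cov, , drop = FALSE]
    if (!nrow(rr)) return(NA_real_)
    idx <- ifelse(rr$strand == "+", pos0 - rr$start + 1, read_len - (pos0 - rr$start))
    b <- substring(rr$seq, idx, idx)
    b <- ifelse(rr$strand == "+", b, chartr("ACGT", "TGCA", b))
    mean(b == alt_fwd)
  }, numeric(1))
}
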