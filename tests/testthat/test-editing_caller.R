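# Reference with known A/T layout for hand-built pileups: position 10 is A,
# position 30 is T, position 50 is A (0-based).
caller_ref <- function() {
  s <- strrep("C", 100)
  substr(s, 11, 11) <- "A"
  substr(s, 31, 31) <- "T"
  substr(s, 51, 51) <- "A"
  c(tx1 = s)
}

# per-sample pileup with given (coverage, edited) at one A site
site_pileup <- function(cov, edit, pos = 10, ref = "A", alt = "G") {
  make_pileup(caller_ref(),
              balanced_site_obs("tx1", pos, ref, alt, cov - edit, edit))
}

test_that("detect_candidates enforces the >=20 coverage / 5% mean thresholds", {
  # boundary case: coverage 20, 1 edited read in every sample -> 5% mean
  pi20 <- lapply(setNames(1:3, paste0("s", 1:3)), function(i) site_pileup(20, 1))
  cand <- detect_candidates(pi20)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$mean_freq, 0.05)
  expect_equal(cand$strand, "+")

  # coverage 19 in any sample excludes the site
  pi19 <- pi20
  pi19$s2 <- site_pileup(19, 1)
  expect_equal(nrow(detect_candidates(pi19)), 0L)

  # mean frequency just under 5% excludes (4.9% is not "on average 5%")
  pi49 <- lapply(setNames(1:3, paste0("s", 1:3)),
                 function(i) site_pileup(1000, 49))
  expect_equal(nrow(detect_candidates(pi49)), 0L)
  pi50 <- lapply(setNames(1:3, paste0("s", 1:3)),
                 function(i) site_pileup(1000, 50))
  expect_equal(nrow(detect_candidates(pi50)), 1L)
})

test_that("only A>G / T>C mismatch patterns are ever candidates", {
  # A>C at 50% is not an editing pattern
  pc <- lapply(setNames(1:2, c("s1", "s2")),
               function(i) site_pileup(40, 20, alt = "C"))
  expect_equal(nrow(detect_candidates(pc)), 0L)

  # T>C is reverse-strand editing
  pt <- lapply(setNames(1:2, c("s1", "s2")),
               function(i) site_pileup(40, 10, pos = 30, ref = "T", alt = "C"))
  cand <- detect_candidates(pt)
  expect_equal(cand$strand, "-")
  expect_equal(cand$alt, "C")

  # G>A (reverse of the editing pattern) is never returned
  pg <- lapply(setNames(1:2, c("s1", "s2")),
               function(i) make_pileup(c(tx1 = strrep("G", 100)),
                                       balanced_site_obs("tx1", 10, "G", "A", 30, 10)))
  expect_equal(nrow(detect_candidates(pg)), 0L)
})

test_that("mean frequency is the unweighted per-sample mean, pooled also reported", {
  pis <- list(s1 = site_pileup(100, 30), s2 = site_pileup(300, 9))
  cand <- detect_candidates(pis)
  expect_equal(cand$mean_freq, mean(c(30 / 100, 9 / 300)))
  expect_equal(cand$pooled_freq, 39 / 400)
})

test_that("candidate fixture bookkeeping: planted sites above thresholds retained", {
  ref <- caller_ref()
  # 3 sites; only pos 10 and 30 clear both thresholds; pos 50 fails frequency
  mk <- function() {
    make_pileup(ref, rbind(
      balanced_site_obs("tx1", 10, "A", "G", 22, 8),
      balanced_site_obs("tx1", 30, "T", "C", 25, 5),
      balanced_site_obs("tx1", 50, "A", "G", 29, 1)))
  }
  pis <- list(s1 = mk(), s2 = mk())
  cand <- detect_candidates(pis)
  expect_equal(cand$pos, c(10, 30))
})

test_that("mask_known_variants flags and excludes masked candidates", {
  pis <- lapply(setNames(1:2, c("s1", "s2")), function(i) site_pileup(40, 10))
  cand <- detect_candidates(pis)
  expect_false(mask_known_variants(cand, NULL)$masked_snp)

  mask <- data.frame(chrom = "tx1", pos = 10)
  cand2 <- mask_known_variants(cand, mask)
  expect_true(cand2$masked_snp)
  filt <- apply_filters(cand2, pis)
  expect_false(filt$pass)   # masked fails regardless of p-values
  expect_true(all(c(filt$strand_bias_p, filt$read_position_p,
                    filt$variant_distance_p) >= 0.01))
})

test_that("strand bias test matches hand-computed Fisher values", {
  col <- function(obs) structure(list(chrom = "tx1", pos = 10, ref = "A",
                                      obs = obs), class = "pileup_column")
  # perfect balance
  b <- balanced_site_obs("tx1", 10, "A", "G", 20, 20)
  expect_equal(strand_bias_test(col(b)), 1.0)
  # maximally imbalanced 5v5: p = 2/252
  obs <- data.frame(chrom = "tx1", pos = 10,
                    base = c(rep("A", 5), rep("G", 5)), qual = 40L,
                    strand = c(rep("+", 5), rep("-", 5)),
                    offset = 1:10, dist_end = 1:10)
  expect_equal(strand_bias_test(col(obs)), 2 / 252, tolerance = 1e-12)
  # all observations on one strand: degenerate margin, p = 1
  obs$strand <- "+"
  expect_equal(strand_bias_test(col(obs)), 1)
})

test_that("rank-sum bias tests agree with the brute-force U oracle", {
  set.seed(42)
  for (i in 1:50) {
    x <- sample(0:59, sample(2:12, 1), replace = TRUE)
    y <- sample(0:59, sample(2:12, 1), replace = TRUE)
    expect_equal(rank_sum_test(x, y)$U, brute_U(x, y))
  }
  # identical multisets: p = 1 exactly
  expect_equal(rank_sum_test(c(1, 5, 9), c(9, 1, 5))$p, 1)
  # complete separation 10v10: far below 0.001 under the normal approximation
  expect_lt(rank_sum_test(0:9, 20:29)$p, 0.001)
})

test_that("bias tests return untestable p = 1 with <2 observations per allele", {
  obs <- balanced_site_obs("tx1", 10, "A", "G", 30, 1)
  col <- structure(list(chrom = "tx1", pos = 10, ref = "A", obs = obs),
                   class = "pileup_column")
  p <- read_position_bias_test(col)
  expect_equal(as.numeric(p), 1)
  expect_true(isTRUE(attr(p, "untestable")))
})

test_that("filters pass unbiased sites at close to the nominal rate", {
  set.seed(7)
  passes <- replicate(200, {
    n <- 60
    offs <- sample(0:59, n, replace = TRUE)
    obs <- data.frame(chrom = "tx1", pos = 10,
                      base = sample(c("A", "G"), n, TRUE, prob = c(0.7, 0.3)),
                      qual = 40L,
                      strand = sample(c("+", "-"), n, TRUE),
                      offset = offs, dist_end = pmin(offs, 59 - offs))
    col <- structure(list(chrom = "tx1", pos = 10, ref = "A", obs = obs),
                     class = "pileup_column")
    strand_bias_test(col) >= 0.01 &&
      read_position_bias_test(col) >= 0.01 &&
      variant_distance_bias_test(col) >= 0.01
  })
  expect_gte(mean(passes), 0.95)
})

test_that("filter p-values are invariant under ref/alt label swap", {
  obs <- balanced_site_obs("tx1", 10, "A", "G", 24, 9)
  swapped <- obs
  swapped$base <- ifelse(obs$base == "A", "G", "A")
  col <- function(o, ref) structure(list(chrom = "tx1", pos = 10, ref = ref,
                                         obs = o), class = "pileup_column")
  expect_equal(strand_bias_test(col(obs, "A")), strand_bias_test(col(swapped, "A")))
  expect_equal(as.numeric(read_position_bias_test(col(obs, "A"))),
               as.numeric(read_position_bias_test(col(swapped, "A"))),
               tolerance = 1e-12)
})

test_that("amplicon mode applies the 1% frequency floor exactly", {
  ref <- caller_ref()
  # depth 10000: 90 edited reads = 0.9% (absent), 110 = 1.1% (present)
  low <- make_pileup(ref, balanced_site_obs("tx1", 10, "A", "G", 9910, 90))
  hi <- make_pileup(ref, balanced_site_obs("tx1", 10, "A", "G", 9890, 110))
  expect_equal(nrow(amplicon_site_frequencies(low)), 0L)
  tab <- amplicon_site_frequencies(hi)
  expect_equal(tab$freq, 0.011)
  expect_equal(tab$coverage, 10000L)

  # exactly 1% is "1% or greater": recorded
  at <- make_pileup(ref, balanced_site_obs("tx1", 10, "A", "G", 9900, 100))
  expect_equal(nrow(amplicon_site_frequencies(at)), 1L)

  empty <- make_pileup(ref, balanced_site_obs("tx1", 10, "A", "G", 5, 1)[0, ])
  expect_warning(out <- amplicon_site_frequencies(empty), "no quality-passing")
  expect_equal(nrow(out), 0L)
})
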