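toy_amplicon <- function() {
  # 40 bp non-repetitive amplicon, editable adenosines at 8, 19, 30 (1-based)
  set.seed(4088)
  b <- sample(c("C", "G", "T"), 40, replace = TRUE)
  b[c(8, 19, 30)] <- "A"
  s <- paste(b, collapse = "")
  stopifnot(editable_adenosines(s) == c(8, 19, 30))
  s
}

test_that("enumerate_haplotypes produces 2^k variants in bitmask order", {
  amp <- toy_amplicon()
  h <- enumerate_haplotypes(amp, c(8, 19, 30))
  expect_equal(nrow(h), 8L)
  expect_equal(h$label, c("aaa", "aag", "aga", "agg", "gaa", "gag", "gga", "ggg"))
  expect_equal(h$bitmask, 0:7)
  expect_equal(h$seq[1], amp)                      # haplotype 0 is unedited
  # sequence differs from the amplicon exactly at set bits, A -> G
  for (i in seq_len(8)) {
    d <- which(strsplit(h$seq[i], "")[[1]] != strsplit(amp, "")[[1]])
    expect_equal(d, c(8, 19, 30)[strsplit(h$label[i], "")[[1]] == "g"])
  }

  expect_equal(nrow(enumerate_haplotypes(amp, integer(0))), 1L)   # k = 0
  expect_error(enumerate_haplotypes(amp, c(8, 9)), "expected 'A'")
  expect_error(enumerate_haplotypes(amp, c(19, 8)), "strictly increasing")
})

test_that("the 5-site 5HT2CR motif yields 32 artificial chromosomes", {
  motif <- ht2cr_exon5_motif()
  sites <- editable_adenosines(motif)
  expect_equal(length(sites), 5L)
  h <- enumerate_haplotypes(motif, sites)
  expect_equal(nrow(h), 32L)
  ref <- build_artificial_reference(h)
  expect_equal(length(ref), 32L)
  expect_equal(length(unique(ref)), 32L)
  expect_equal(names(ref)[1], "aaaaa")

  fa <- withr::local_tempfile(fileext = ".fa")
  build_artificial_reference(h, fa)
  expect_identical(read_fasta(fa), ref)            # I/O identity

  h1 <- enumerate_haplotypes("CCACC", 3)
  expect_equal(names(build_artificial_reference(h1)), c("a", "g"))
  h_dup <- h1
  h_dup$label <- c("a", "a")
  expect_error(build_artificial_reference(h_dup), "duplicate")
})

test_that("assign_reads follows the site base pattern and tallies failures", {
  amp <- toy_amplicon()
  h <- enumerate_haplotypes(amp, c(8, 19, 30))
  mk_read <- function(seq, id = "r") data.frame(id = id, seq = seq,
                                                qual = strrep("I", nchar(seq)),
                                                stringsAsFactors = FALSE)
  # error-free unedited read
  cnt <- assign_reads(mk_read(amp), h)
  expect_equal(unname(cnt$counts["aaa", 1]), 1L)
  # reverse complement assigns identically
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(h$seq[6])))
  cnt <- assign_reads(mk_read(rc), h)
  expect_equal(unname(cnt$counts["gag", 1]), 1L)
  # C at an editable site -> unassigned
  bad <- amp
  substr(bad, 19, 19) <- "C"
  cnt <- assign_reads(mk_read(bad), h)
  expect_equal(unname(cnt$unassigned), 1L)
  expect_equal(sum(cnt$counts), 0L)
  # more than max_offsite_mismatches off-site errors -> unassigned
  noisy <- h$seq[8]
  for (p in c(2, 3, 4)) substr(noisy, p, p) <- "A"
  expect_equal(unname(assign_reads(mk_read(noisy), h)$unassigned), 1L)
  expect_equal(unname(assign_reads(mk_read(noisy), h,
                                   max_offsite_mismatches = 3)$counts["ggg", 1]), 1L)
  # a short read not spanning all sites is ambiguous
  partial <- substr(amp, 1, 25)
  cnt <- assign_reads(mk_read(partial), h)
  expect_equal(unname(cnt$ambiguous), 1L)
  # a spanning partial read assigns fine
  span <- substr(h$seq[4], 5, 35)
  cnt <- assign_reads(mk_read(span), h)
  expect_equal(unname(cnt$counts["agg", 1]), 1L)
})

test_that("count conservation holds on noisy simulated reads", {
  h <- enumerate_haplotypes(toy_amplicon(), c(8, 19, 30))
  pi <- c(0.4, 0.2, 0.1, 0.1, 0.05, 0.05, 0.05, 0.05)
  s <- simulate_amplicon(h, pi, depth = 2000, error_rate = 0.01, seed = 5)
  cnt <- assign_reads(s$reads, h)
  expect_equal(unname(cnt$assigned + cnt$ambiguous + cnt$unassigned),
               unname(cnt$total))
  expect_equal(unname(cnt$total), 2000L)
  f <- haplotype_frequencies(cnt)
  expect_equal(sum(f), 1)
  expect_true(all(abs(f - pi) < 0.05))
})

test_that("site marginals sum the frequencies of edited haplotypes", {
  h <- enumerate_haplotypes(toy_amplicon(), c(8, 19, 30))
  # hand-built counts: uniform over the 8 haplotypes in sample u,
  # delta at aaa in sample d
  counts <- structure(list(
    counts = matrix(c(rep(10L, 8), c(80L, rep(0L, 7))), ncol = 2,
                    dimnames = list(h$label, c("u", "d"))),
    assigned = c(u = 80L, d = 80L),
    ambiguous = c(u = 0L, d = 0L), unassigned = c(u = 0L, d = 0L),
    total = c(u = 80L, d = 80L), haplotypes = h),
    class = "haplotype_counts")
  m <- site_marginals(counts)
  expect_equal(unname(m[, "u"]), rep(0.5, 3))     # uniform: every marginal 1/2
  expect_equal(unname(m[, "d"]), rep(0, 3))       # delta(aaa): all zero
})

test_that("group frequencies partition and sum to 1", {
  h <- enumerate_haplotypes(toy_amplicon(), c(8, 19, 30))
  counts <- structure(list(
    counts = matrix(c(40L, 10L, 10L, 5L, 10L, 5L, 15L, 5L), ncol = 1,
                    dimnames = list(h$label, "s1")),
    assigned = c(s1 = 100L), ambiguous = c(s1 = 0L), unassigned = c(s1 = 0L),
    total = c(s1 = 100L), haplotypes = h), class = "haplotype_counts")
  groups <- list(
    unedited = function(mask, label) mask == 0,
    edited = function(mask, label) mask > 0)
  g <- group_frequencies(counts, groups)
  expect_equal(unname(g[, 1]), c(0.40, 0.60))
  expect_equal(sum(g), 1)

  # "edited at sites 1 and 2" vs "unedited at 1 and 2" vs remainder,
  # hand-summed from the count vector (site 1 = bit 4, site 2 = bit 2)
  both <- function(mask, label) bitwAnd(mask, 4L) > 0 & bitwAnd(mask, 2L) > 0
  neither <- function(mask, label) bitwAnd(mask, 4L) == 0 & bitwAnd(mask, 2L) == 0
  rest <- function(mask, label) xor(bitwAnd(mask, 4L) > 0, bitwAnd(mask, 2L) > 0)
  g2 <- group_frequencies(counts, list(both = both, neither = neither,
                                       rest = rest))
  expect_equal(unname(g2["both", 1]), (15 + 5) / 100)       # gga, ggg
  expect_equal(unname(g2["neither", 1]), (40 + 10) / 100)   # aaa, aag
  expect_equal(unname(g2["rest", 1]), 30 / 100)

  overlapping <- list(a = function(mask, label) TRUE,
                      b = function(mask, label) mask == 0)
  expect_error(group_frequencies(counts, overlapping), "partition")
})

test_that("one-way ANOVA across genotypes matches t^2 and handles degeneracy", {
  design <- default_design(3, 3)
  f <- matrix(c(0.30, 0.32, 0.28, 0.20, 0.22, 0.18), nrow = 1,
              dimnames = list("aaa", design$sample_id))
  res <- anova_across_genotypes(f, design)
  tt <- t.test(f[1, 1:3], f[1, 4:6], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # identical group means with nonzero within variance: F = 0, p = 1
  f0 <- matrix(c(0.3, 0.4, 0.2, 0.4, 0.2, 0.3), nrow = 1,
               dimnames = list("x", design$sample_id))
  res0 <- anova_across_genotypes(f0, design)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # all values identical: p = 1 by convention
  fc <- matrix(rep(0.25, 6), nrow = 1, dimnames = list("c", design$sample_id))
  expect_equal(anova_across_genotypes(fc, design)$p, 1)
})

test_that("ANOVA type-I error is near nominal under the null", {
  design <- default_design(3, 3)
  set.seed(21)
  rej <- replicate(1000, {
    f <- matrix(0.3 + rnorm(6, 0, 0.03), nrow = 1,
                dimnames = list("h", design$sample_id))
    anova_across_genotypes(f, design)$p <= 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})
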