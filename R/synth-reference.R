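#' Generate a random reference of transcript sequences
#'
#' Sequences are i.i.d. draws with per-base G/C probability `gc` (split
#' evenly between G and C) and A/T probability `1 - gc`.  To guarantee that
#' editing sites are plantable anywhere, every consecutive 20 bp window is
#' post-processed to contain at least one adenosine (the window midpoint is
#' set to A if the draw produced none).  Deterministic for a fixed seed.
#'
#' @param n_transcripts Number of transcript sequences (0 allowed).
#' @param length Length of each transcript, >= 50.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return Named character vector `tx1 ... txN`.
#' @export
make_reference <- function(n_transcripts, length, gc = 0.5, seed = 1L) {
  if (n_transcripts < 0) stop_input("n_transcripts must be >= 0")
  if (n_transcripts == 0) return(stats::setNames(character(0), character(0)))
  if (length < 50) stop_input("transcript length must be >= 50")
  if (gc <= 0 || gc >= 1) stop_input("gc must be strictly inside (0, 1)")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_transcripts), function(i) {
      b <- sample(names(probs), length, replace = TRUE, prob = probs)
      # enforce >= 1 A per 20 bp block so profiles are always plantable
      for (s in seq(1L, length, by = 20L)) {
        e <- min(s + 19L, length)
        if (!any(b[s:e] == "A")) b[s + ((e - s) %/% 2L)] <- "A"
      }
      paste(b, collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("tx", seq_len(n_transcripts)))
  })
}

#' Construct an editing profile
#'
#' An editing profile lists true per-site, per-genotype editing rates used
#' by the read simulator.  A `+` site must sit on a reference A (edited
#' reads carry G); a `-` site must sit on a reference-forward T (editing of
#' the antisense transcript shows up as T>C on the forward letters).
#'
#' @param chrom,pos,strand Site coordinates: reference name, 0-based
#'   position, `"+"` or `"-"`.
#' @param ... One numeric vector of true editing rates in `[0, 1]` per
#'   genotype, named `eps_<genotype>` (e.g. `eps_WT`, `eps_KO`).
#' @param reference Optional named character vector; when given, site base
#'   identity is validated immediately.
#' @return data.frame of class `editing_profile`.
#' @export
editing_profile <- function(chrom, pos, strand, ..., reference = NULL) {
  eps <- list(...)
  if (length(eps) == 0L || !all(grepl("^eps_", names(eps))))
    stop_input("supply per-genotype rates as named arguments eps_<genotype>")
  n <- max(lengths(c(list(chrom, pos, strand), eps)))
  p <- data.frame(chrom = rep_len(as.character(chrom), n),
                  pos = rep_len(as.numeric(pos), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  for (nm in names(eps)) {
    v <- rep_len(as.numeric(eps[[nm]]), n)
    if (any(v < 0 | v > 1)) stop_input("%s outside [0, 1]", nm)
    p[[nm]] <- v
  }
  if (!all(p$strand %in% c("+", "-")))
    stop_input("profile strand must be '+' or '-'")
  class(p) <- c("editing_profile", "data.frame")
  if (!is.null(reference)) validate_profile(p, reference)
  p
}

validate_profile <- function(profile, reference) {
  for (i in seq_len(nrow(profile))) {
    chrom <- profile$chrom[i]
    if (!chrom %in% names(reference))
      stop_input("profile site %s:%d on unknown reference", chrom, profile$pos[i])
    base <- substr(reference[[chrom]], profile$pos[i] + 1, profile$pos[i] + 1)
    want <- if (profile$strand[i] == "+") "A" else "T"
    if (base != want)
      stop_input("profile site %s:%.0f (%s) sits on reference '%s', expected '%s'",
                 chrom, profile$pos[i], profile$strand[i], base, want)
  }
  invisible(profile)
}

profile_genotypes <- function(profile) {
  sub("^eps_", "", grep("^eps_", names(profile), value = TRUE))
}

#' Default two-genotype design
#'
#' Three wild-type vs three knockout samples, the usual mouse cohort size
#' for this kind of comparison.
#'
#' @param n_wt,n_ko Samples per genotype.
#' @return data.frame with columns `sample_id`, `genotype`.
#' @export
default_design <- function(n_wt = 3L, n_ko = 3L) {
  data.frame(
    sample_id = c(paste0("WT", seq_len(n_wt)), paste0("KO", seq_len(n_ko))),
    genotype = c(rep("WT", n_wt), rep("KO", n_ko)),
    stringsAsFactors = FALSE)
}
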