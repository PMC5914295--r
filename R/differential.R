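# Differential editing between genotypes.  Per site, the edited read
# fraction is modeled as binomial with logit link and a two-level genotype
# predictor; significance is the chi-square likelihood-ratio (analysis of
# deviance) test of the genotype term, and multiplicity is handled by
# Benjamini-Hochberg step-up FDR across sites.

binom_loglik <- function(edited, coverage, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(edited * log(p) + (coverage - edited) * log(1 - p))
}

binom_deviance <- function(edited, coverage, p) {
  f <- edited / coverage
  2 * (binom_loglik(edited, coverage, f) - binom_loglik(edited, coverage, p))
}

#' Fit a per-site binomial logistic regression on genotype
#'
#' Iteratively reweighted least squares on the per-sample (edited,
#' unedited) counts with model `logit(p) = b0 + b1 * [genotype == level2]`.
#' The genotype factor's first level is the reference (WT if a level is
#' named "WT", otherwise first appearance order), so `b1` is the knockout
#' log-odds shift.  Convergence requires the largest coefficient change to
#' drop below 1e-8 within 50 iterations.  Complete separation (a genotype
#' with all-zero or all-saturated frequencies) drives coefficients to
#' infinity; they are capped at |b| <= 30, the fit is flagged `separated`,
#' and deviances stay finite so the LRT is still defined.
#'
#' @param edited,coverage Per-sample numeric vectors of edited counts and
#'   coverage (coverage > 0 everywhere).
#' @param genotype Per-sample genotype labels; exactly 2 levels, each with
#'   >= 2 samples.
#' @return A `site_glm_fit`: list with `beta0`, `beta1`, `deviance_full`,
#'   `deviance_null`, `converged`, `separated`, `levels`, `n`.
#' @export
fit_binomial_glm <- function(edited, coverage, genotype) {
  stopifnot(length(edited) == length(coverage),
            length(edited) == length(genotype))
  if (any(coverage <= 0)) stop_input("all samples need coverage > 0")
  if (any(edited < 0 | edited > coverage))
    stop_input("edited counts must lie in [0, coverage]")
  lv <- unique(as.character(genotype))
  if (length(lv) != 2L) stop_input("genotype must have exactly 2 levels")
  if ("WT" %in% lv) lv <- c("WT", setdiff(lv, "WT"))
  if (any(table(genotype) < 2L)) stop_input("need >= 2 samples per genotype")
  g <- as.numeric(genotype == lv[2])
  X <- cbind(1, g)
  y <- edited / coverage

  beta <- c(qlogis(min(max(sum(edited) / sum(coverage), 1e-6), 1 - 1e-6)), 0)
  converged <- FALSE
  for (it in seq_len(50L)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- coverage * mu * (1 - mu)
    if (any(w < 1e-10)) break                       # separation: weights vanish
    z <- eta + (y - mu) / (mu * (1 - mu))
    new <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(new)) break
    new <- drop(new)
    delta <- max(abs(new - beta))
    beta <- new
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  # complete separation: a genotype at an all-0 / all-1 boundary while the
  # other differs sends its logit to +-Inf; the saturated two-group MLE is
  # then the capped closed form (group logits clamped at +-30)
  f_grp <- vapply(lv, function(l) {
    sum(edited[genotype == l]) / sum(coverage[genotype == l])
  }, numeric(1))
  separated <- (any(f_grp %in% c(0, 1)) && f_grp[1] != f_grp[2]) ||
    any(abs(beta) > 30)
  if (separated) {
    lg <- pmin(pmax(qlogis(pmin(pmax(f_grp, 1e-13), 1 - 1e-13)), -30), 30)
    beta <- c(lg[1], lg[2] - lg[1])
  }
  beta <- unname(pmin(pmax(beta, -30), 30))
  p_full <- plogis(drop(X %*% beta))
  p_null <- plogis(min(max(qlogis(min(max(sum(edited) / sum(coverage),
                                          1e-13), 1 - 1e-13)), -30), 30))
  structure(list(beta0 = beta[1], beta1 = beta[2],
                 deviance_full = binom_deviance(edited, coverage, p_full),
                 deviance_null = binom_deviance(edited, coverage,
                                                rep(p_null, length(y))),
                 converged = converged, separated = separated,
                 levels = lv, n = length(y)),
            class = "site_glm_fit")
}

#' Likelihood-ratio (analysis of deviance) p-value for a site fit
#'
#' The upper chi-square tail with 1 degree of freedom at the deviance drop
#' between the intercept-only and genotype models — the statistical content
#' of running `anova()` on a binomial `glm` fit.
#'
#' @param fit A `site_glm_fit`.
#' @return Named list `stat` (the LRT statistic) and `p`.
#' @export
lrt_pvalue <- function(fit) {
  stopifnot(inherits(fit, "site_glm_fit"))
  stat <- fit$deviance_null - fit$deviance_full
  if (stat < -1e-6)
    stop_input("null deviance below full deviance (%.3g): numerical failure", stat)
  stat <- max(stat, 0)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q(i) = min over j >= i of m * p(j) / j` on the sorted p-values, mapped
#' back to input order and clipped at 1.  A site is significant at FDR
#' level alpha iff `q <= alpha`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_input("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- pmin(cummin(rev(m * pvalues[o] / seq_len(m))), 1)
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

#' Differential editing table across candidate sites
#'
#' Fits the per-site genotype logistic regression for every candidate that
#' passed filtering, computes LRT p-values, adjusts them with
#' Benjamini-Hochberg, and flags sites significant at FDR `alpha`.
#'
#' @param candidates Candidate table from [detect_candidates()] /
#'   [apply_filters()]; rows with `pass == FALSE` or `masked_snp == TRUE`
#'   (when present) are excluded.
#' @param design Sample design with exactly 2 genotype levels, >= 2
#'   samples each; `sample_id` values must match the candidate table's
#'   `cov_*` / `edit_*` columns.
#' @param alpha FDR threshold for the `significant` flag.
#' @return data.frame sorted by (q, p): `site`, `chrom`, `pos`, `strand`,
#'   `beta1`, `lrt_stat`, `pvalue`, `qvalue`, `significant`, `separated`.
#' @export
differential_editing_table <- function(candidates, design, alpha = 0.05) {
  design <- validate_design(design)
  lv <- unique(design$genotype)
  if (length(lv) != 2L) stop_input("design must have exactly 2 genotype levels")
  if (any(table(design$genotype) < 2L))
    stop_input("need >= 2 samples per genotype")
  keep <- rep(TRUE, nrow(candidates))
  if ("pass" %in% names(candidates)) keep <- keep & candidates$pass
  if ("masked_snp" %in% names(candidates)) keep <- keep & !candidates$masked_snp
  cand <- candidates[keep, , drop = FALSE]
  empty <- data.frame(site = character(0), chrom = character(0),
                      pos = numeric(0), strand = character(0),
                      beta1 = numeric(0), lrt_stat = numeric(0),
                      pvalue = numeric(0), qvalue = numeric(0),
                      significant = logical(0), separated = logical(0))
  if (nrow(cand) == 0L) return(empty)
  cov_cols <- paste0("cov_", design$sample_id)
  edit_cols <- paste0("edit_", design$sample_id)
  if (!all(c(cov_cols, edit_cols) %in% names(cand)))
    stop_input("candidate table lacks per-sample columns for the design")
  fits <- lapply(seq_len(nrow(cand)), function(i) {
    fit_binomial_glm(as.numeric(cand[i, edit_cols]),
                     as.numeric(cand[i, cov_cols]),
                     design$genotype)
  })
  lrt <- lapply(fits, lrt_pvalue)
  p <- vapply(lrt, `[[`, numeric(1), "p")
  out <- data.frame(
    site = sprintf("%s:%.0f", cand$chrom, cand$pos + 1),
    chrom = cand$chrom, pos = cand$pos, strand = cand$strand,
    beta1 = vapply(fits, `[[`, numeric(1), "beta1"),
    lrt_stat = vapply(lrt, `[[`, numeric(1), "stat"),
    pvalue = p,
    qvalue = bh_fdr(p),
    separated = vapply(fits, `[[`, logical(1), "separated"),
    stringsAsFactors = FALSE)
  out$significant <- out$qvalue <= alpha
  out <- out[order(out$qvalue, out$pvalue), ]
  rownames(out) <- NULL
  out[, c("site", "chrom", "pos", "strand", "beta1", "lrt_stat",
          "pvalue", "qvalue", "significant", "separated")]
}
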