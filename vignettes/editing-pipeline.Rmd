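---
title: "Detecting and quantifying A-to-I RNA editing with editscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying A-to-I RNA editing with editscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscope)
```

## The model and its assumptions

A-to-I editing is read out of sequencing data as an A→G mismatch between RNA
reads and the reference (inosine pairs like guanosine). For a transcript on
the minus strand the same event appears on the reference-forward letters as
T→C. `editscope` works strand-aware throughout: a candidate site is reported
with the strand implied by its mismatch pattern, and those are the *only*
two patterns ever called — any other mismatch is, by assumption, a variant
or an error, never editing.

Three nested questions structure the pipeline:

1. **Is this position edited at all?** Per position we tally
   strand-resolved, quality-filtered base observations (each with its
   in-read offset and distance to the nearest read end). A site is a
   candidate iff every sample covers it with at least `min_cov` reads and
   the unweighted mean of per-sample edited fractions reaches
   `min_mean_freq`. Genomic variants masquerade as 50%/100% "editing", so
   positions in a user-supplied mask (dbSNP-style) are flagged and excluded.
   Residual artifacts concentrate on one strand or at particular read
   positions; three filters test for that (below).
2. **Does editing differ between genotypes?** Per site, the edited count
   in sample $i$ is modeled as $y_i \sim \mathrm{Bin}(n_i, p_i)$ with
   $\operatorname{logit} p_i = \beta_0 + \beta_1 x_i$, $x_i$ the 0/1
   genotype indicator. The coverage-weighted binomial likelihood is the only
   defensible reading of "fit the substitution frequency": per-sample
   frequencies carry very different information at coverage 20 vs 2000.
   Significance is the analysis-of-deviance likelihood-ratio test
   ($\Delta\mathrm{dev} \sim \chi^2_1$), and multiplicity is controlled by
   Benjamini–Hochberg step-up FDR at 5%. No overdispersion correction is
   applied by default — with n = 3 per group there is little information to
   estimate a dispersion, and the reference workflow does not use one.
3. **Which combinations of sites co-occur on one molecule?** For an
   amplicon with $k$ editable adenosines the $2^k$ phased editing isoforms
   are enumerated explicitly ("artificial chromosomes", labels
   `aaaaa`…`ggggg` with `g` = edited, leftmost site most significant, so
   labels run in dictionary order and haplotype 0 is unedited). A read is
   assigned by the base it shows at each of the $k$ positions — a rule
   equivalent in intent to aligning against all $2^k$ references, but with
   an explicit, deterministic decision boundary: the $k$ observed bases
   determine exactly one bitmask, so ties are impossible by construction.

### The bias filters

The named artifact signatures are implemented as the standard constructions
those names denote in variant-calling practice:

* *Strand bias*: two-sided Fisher exact test on the 2×2 table of
  {reference, alternate} × {+, −} observations. An all-zero margin (e.g.
  single-strand coverage) is uninformative and passes with p = 1.
* *Read position bias* and *variant distance bias*: two-sided Mann–Whitney
  rank-sum tests (normal approximation with tie-corrected variance)
  comparing alternate vs reference observations on in-read offset and on
  distance to the nearest read end. Offsets are counted in sequencing
  order, so a reverse-strand alignment reverses the stored index; distance
  to end, $\min(\mathrm{off}, L-1-\mathrm{off})$, is orientation-free and
  serves both filters with one number. Fewer than two observations of
  either allele makes the test untestable; it passes by convention with an
  `untestable` attribute rather than silently failing a low-frequency site.

A *small* p-value is evidence of artifact, so a candidate passes at
threshold $t$ when all three p-values are $\ge t$ (default 0.01) and it is
not masked. Whether the original workflow used hard thresholds or manual
browser review is ambiguous; making the rule explicit and configurable is
the design choice here — it is testable, and a user can always loosen
`p_threshold` to 0 to recover unfiltered behavior.

## Tunable parameters

| Parameter | Default | Where | Why this default |
|---|---|---|---|
| `min_cov` | 20 reads | `detect_candidates` | detection threshold of the reference workflow; applied per sample (stricter reading) so the GLM never sees empty cells |
| `min_mean_freq` | 0.05 | `detect_candidates` | "on average 5% of the reads"; unweighted mean of per-sample fractions (the pooled fraction is also reported) |
| `min_base_quality` | Q20 | `build_pileup` | "high-quality score bases" read as the conventional Phred 20; a single knob |
| `p_threshold` | 0.01 | `apply_filters` | conservative artifact screen; three tests at 1% reject an unbiased site rarely (tests are conservative/discrete) |
| `min_freq` | 0.01 | `amplicon_site_frequencies` | amplicon mode records sites at "1% or greater" |
| `alpha` | 0.05 | `differential_editing_table` | FDR threshold of the reference workflow |
| `max_offsite_mismatches` | 2 | `assign_reads` | absorbs sequencing error away from the editable sites on a ~178 bp amplicon |
| `anchor_len` | 12 | `align_fixture_reads` | pigeonhole: $\lfloor L/k \rfloor$ disjoint seeds tolerate $\lfloor L/k \rfloor - 1$ substitutions; 12 on a 60 bp read tolerates 4 (several edited sites plus an error). 20 was observed to lose ~3% of heavily edited reads in dense-site simulations, biasing recovered frequencies downward — a defect fixed at the source rather than hidden behind wider tolerances |

Coordinates are 0-based half-open everywhere internally; region strings and
TSV outputs at user boundaries are 1-based inclusive
(`chrX:147169590-147169767` = 178 bp).

## What the simulator emulates — and what it does not

`simulate_rnaseq` draws uniformly placed, fixed-length substrings of
uniformly chosen transcripts; at each profiled site every covering read is
independently edited with the genotype's true rate *before* uniform
per-base sequencing error is applied (biology precedes machine noise, so
`error_rate = 0` isolates the editing signal exactly). Reads report either
physical strand with probability 1/2, heterozygous SNPs can be planted
identically across genotypes, and `plant_artifact` manufactures the two
artifact signatures the filters target (all alternate bases on one strand;
all alternate bases within 5 bp of read ends). Each sample has its own RNG
stream derived from `(seed, sample_id)`, so outputs are reproducible
independent of sample order, and truth is serialized to TSV next to the
reads.

It does **not** emulate: realistic coverage heterogeneity (no fragment-size,
GC or positional bias — uniform placement is a stated simplification),
splicing, indels, PCR duplicates or chimeras, mapping ambiguity of
repetitive genomic context, or base-quality degradation along the read.
A green parameter-recovery test therefore establishes that the pipeline's
*computation* is correct on data satisfying its assumptions; it does not
establish robustness to alignment artifacts of real genomes, which is what
the external-aligner SAM entry point and the bias filters are for.

`simulate_amplicon` draws full-amplicon reads i.i.d. from a haplotype
frequency vector $\pi$ — the merged-pair view of a short amplicon with
fully overlapping mates. Paired mates with a disagreeing overlap are not
simulated; in assignment, reads that fail to span all sites are tallied
`ambiguous` rather than guessed.

## Numerical choices and degenerate inputs

* **IRLS and separation.** The genotype model is saturated at group level,
  so the MLE is the pair of group logits. IRLS runs up to 50 iterations
  with tolerance 1e-8 on the largest coefficient change. With n = 3 per
  group, complete separation (a group pooled at 0 or 1 while the other
  differs) is common; it is detected directly from the group frequencies,
  coefficients are set to the closed-form group logits *capped at ±30*, the
  fit is flagged `separated`, and deviances stay finite so the LRT is still
  defined and deterministic. The cap (logit scale) is far beyond any
  observable frequency at realistic coverage.
* **Deviance ordering.** Null deviance ≥ full deviance is asserted to
  1e-8; a larger violation is a hard numerical error, not silently clipped.
* **Fisher degeneracies.** Any zero margin returns p = 1.
* **Rank-sum ties.** Midranks with the standard tie-corrected variance; if
  the variance is 0 (all pooled values identical) p = 1. No continuity
  correction — the two-sided normal tail is compared against a brute-force
  U oracle in the tests.
* **ANOVA degeneracies.** Zero within-group and zero between-group variance
  gives F = 0, p = 1 by convention; zero within-group variance with
  distinct means gives p = 0.
* **BH step-up.** $q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, clipped at 1,
  mapped back to input order; checked against a definitional
  smallest-rejecting-alpha oracle.
* **Aligner ties.** A read whose best ungapped placement is attained at two
  distinct positions/orientations is emitted unmapped-ambiguous, never
  arbitrarily placed; anchorless reads are unmapped-noanchor. Both are
  counted.

## Design choices where the design was open

* *Mean vs pooled frequency*: "on average 5% of the reads" is read as the
  unweighted mean of per-sample fractions; both statistics are computed and
  reported, the mean is the filter.
* *Per-sample coverage*: the coverage floor applies to every sample (a site
  untestable in any sample is dropped) so the downstream GLM never sees
  zero-coverage cells.
* *Pattern assignment vs best-alignment*: isoform reads are assigned by
  their explicit base pattern at the editable sites with an off-site
  mismatch cap, rather than by global alignment score against all $2^k$
  references — the same intent with a sharper, deterministic contract.
* *Masks*: any listed position is masked; no attempt is made to interpret
  "common" variant annotations.
* *Site names*: the five serotonin-receptor sites are named A, B, E, C, D
  in genomic order; names are metadata only and never enter any
  computation.
* *CLI config*: the simulator's CLI takes a JSON config (jsonlite is the
  structured-text parser available in the supported stack); the schema is
  the same one a YAML config would carry.

## Known limitations

* The internal aligner is ungapped and fixture-scale by design; real data
  should be aligned externally and supplied as SAM (the dialect parser
  rejects anything outside header + 11 mandatory columns + M/I/D/S/N/=/X
  CIGARs, loudly).
* Editing frequencies near the detection threshold are subject to sampling
  noise: a site with true rate exactly 5% is retained in about half of
  datasets. This is inherent to thresholding, not an implementation
  artifact; the tests therefore compare against thresholds applied to
  *realized* read compositions.
* No hyper-editing cluster detection, no repeat/Alu annotation, no
  known-editing-database cross-referencing, no covariate adjustment or
  multi-level genotype contrasts, no UMI or duplicate handling.
* With unstranded input the strand of a candidate is inferred from the
  mismatch pattern alone and both orientations of evidence are pooled;
  truly unstranded libraries lose the orientation guarantee the stranded
  protocol provides.
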