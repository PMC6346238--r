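---
title: "Methods: CIMP methylome subtyping and replicative-history analysis"
author: "methcimp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CIMP methylome subtyping and replicative-history analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`methcimp` analyses 450K-style methylation beta-value matrices of leukemia
cohorts (the motivating system is pediatric T-cell acute lymphoblastic
leukemia) in which samples split into CpG island methylator phenotype (CIMP)
subgroups. The pipeline covers six analysis surfaces:

1. **CIMP scoring and classification.** The CIMP score of a sample is the
   fraction of a fixed promoter-enriched CpG panel whose beta value exceeds
   0.4 (strictly); samples with a score strictly above 40% are CIMP+,
   otherwise CIMP-. Both inequalities are strict by design: the positive
   class is defined by "more than 40% methylated", which leaves equality to
   the negative side. Missing panel betas are removed from the denominator
   rather than counted as unmethylated, so probe dropout cannot deflate a
   score; scoring errors out if less than half the panel is present
   (configurable).
2. **Methylome landscape.** Mean promoter methylation is a two-stage mean
   (per-gene mean over TSS1500/TSS200 probes, then an unweighted mean over
   genes) so probe-dense genes do not dominate. Hyper-/hypomethylation is
   called per sample against the mean of a sorted-cell reference group at
   |delta beta| >= 0.4; category enrichment compares the category profile of
   a sample's hypermethylated sites with the array-wide profile (ratio 1
   under uniform sampling) and is summarized per group as median and SD.
   Group-level differentially methylated CpGs (DM-CpGs) require both
   |delta mean beta| > 0.4 and a Benjamini-Hochberg q below 0.05 from a
   two-sided Wilcoxon rank-sum test. The rank-sum choice is a deliberate
   stand-in — the source analysis does not name its per-site test in the
   main text — picked for robustness on bounded, bimodal beta values; both
   thresholds are configurable and recorded in the run log.
3. **Epigenetic clocks.** DNAm age is a linear predictor over clock CpGs
   passed through the adult-age anchored piecewise log-linear inverse
   transform (`exp(m + log(adult_age + 1)) - 1` below the anchor,
   `m (adult_age + 1) + adult_age` above; anchor 20 years); mitotic age is
   the plain mean beta over a mitotic-clock panel, reported on [0, 1].
   Published coefficient tables are accepted as drop-in TSV files but are
   not redistributed; the package ships matched synthetic clocks instead.
   Missing cells at a present clock site are imputed with the cohort mean
   beta of that site; sites absent from the matrix are dropped, with an
   error once more than 20% of the model is absent.
4. **Relative telomere length.** Standard delta-delta-Ct:
   `rtl = E_T^(CtT_ref - CtT_s) / E_S^(CtS_ref - CtS_s)` after averaging
   replicate Cts, with per-assay efficiencies (default 2.0, ideal
   doubling). The reference sample is 1 by construction, and adding a
   constant to every Ct cancels exactly.
5. **Expression.** Median-of-ratios size factors (log-scale median, the
   same estimator DESeq2 uses) and `log2(count / sf + 1)` replace the
   original rlog pipeline; differential expression is a Welch t-test on the
   normalized log values with LFC gates at +-1 (CIMP- as reference) and BH
   q < 0.05, yielding cluster A (higher in CIMP-) and cluster B (higher in
   CIMP+). This deliberately approximates, not replicates, a shrinkage-based
   DE engine; the substitution is the package's contract and the printed
   gate values are the defaults.
6. **Integration.** Per-gene Pearson correlation between mean promoter beta
   (TSS1500, TSS200, 5'UTR probes) and normalized log expression, BH across
   genes, with a signed direction call at q < 0.05; gene-set overlap of DEG
   clusters against named signatures is an upper-tail hypergeometric test
   within a stated universe — a set-overlap question, so no running-statistic
   enrichment is attempted.

# The synthetic cohort: a stated world

Every stage is exercised by `generate_cohort()`, whose defaults are the
study conditions: 25 CIMP-, 40 CIMP+, 3 CD34+-like reference samples; a
1293-site panel on a 20 000-site array (the array is scaled down from 450K
for tractability; the panel *fraction*, ~6.5%, is what matters for
placement feasibility); panel methylation fractions 0.20 vs 0.70;
island/TSS200 enrichment multiplier 3.0; mitotic means 0.27 vs 0.64; RTL
medians 1.13 (CIMP-) vs 0.85 (CIMP+); pediatric ages uniform on 1-16 years.
Where the stated world left a value open we chose once: Beta-state shapes
(2, 18) and (17, 3) (means 0.10/0.85, matching bimodal array data),
negative-binomial dispersion 0.1, per-sample mitotic SD 0.09 (between the
two reported group SDs), qPCR noise 0.05 cycles with 3 replicates, RTL
log-SD 0.4, LFC effect 2 for 100 designated DEGs, and a promoter-expression
coupling of -3 log2 units per unit beta for 50 coupled genes.

Two generator choices deserve emphasis:

* **Nested panel methylation.** Each sample methylates the lowest-ranked
  panel sites up to a Binomial(n_panel, frac_group) count, so methylated
  sets are nested across samples, mimicking the ratchet-like accumulation
  of CIMP hypermethylation. This keeps the per-sample score Binomial as
  stated *and* gives every panel site a closed-form true group delta
  (difference of Binomial survival functions times the state-mean gap), so
  the ground-truth DM set is exactly defined and false-discovery
  proportions are honestly measurable. Sites whose rank falls in the
  transition zones near the two group fractions have intermediate true
  deltas; they are the only sites where calls can legitimately disagree
  with truth.
* **Exact enrichment placement.** Panel sites receive Island (and TSS200)
  annotation with probability `E (1 - f) p0 / (1 - E f)` (`f` = panel
  fraction, `p0` = base category rate), the unique value for which the
  realized array-wide enrichment ratio equals the multiplier `E`; a naive
  `E * p0` under-recovers because the panel inflates the array denominator.
  The base island rate is 0.25 — slightly below the real platform's ~0.31 —
  because 0.31 makes a 3x enrichment infeasible (probability above 1) at
  the default panel fraction; infeasible placements raise the documented
  generation error rather than silently truncating.

What the generator does **not** emulate: probe cross-reactivity and
SNP-affected probes, batch and plate effects, copy-number contamination of
beta values, the correlation structure of neighboring CpGs, and any
group effect on DNAm age beyond chronological age (the synthetic clock
recovers chronological age only). A green recovery test therefore
establishes that the estimators invert the generating model at the stated
separations — not that they would reproduce the study's exact counts on
real arrays, which also depend on unpublished preprocessing.

# Numerical choices and degenerate inputs

* Beta values are validated to [0, 1] within 1e-9; table round-trips are
  exact to well under 1e-12.
* The rank-sum test uses the normal approximation with tie correction and
  continuity correction (identical to `wilcox.test(exact = FALSE)`); a
  zero-variance site returns p = 1 rather than NaN.
* BH adjustment is `stats::p.adjust`; it is verified against a sort/cummin
  oracle in the tests. Hypergeometric tails are `stats::phyper`, verified
  against direct pmf summation.
* Equality boundaries: beta exactly at the methylation threshold is *not*
  methylated; a score exactly at the CIMP cutoff is CIMP-; a delta exactly
  at the hyper/hypo threshold *is* a call (>= / <=), matching the
  "at least this much change" reading.
* Degenerate correlation inputs (zero variance, < 3 aged samples per
  group, genes without promoter probes) are reported as missing rather
  than dropped or errored, so output tables keep one row per requested
  unit.
* Pipeline determinism: one seed drives generation; analysis stages are
  RNG-free; the run log records seed, thresholds and versions, and result
  tables are byte-identical across reruns of the same config.

# Known limitations

* DM-CpG and DEG counts from the substituted tests will not numerically
  match a shrinkage-based or appendix-specified pipeline on real data; the
  gates (|delta beta| > 0.4, |LFC| > 1, q < 0.05) are the stable contract.
* The 1293-site panel, published clock coefficients and signature gene
  sets are inputs, not package data; only synthetic stand-ins ship.
* Recovery tests in the suite run on scaled-down cohorts (panel fraction
  preserved) except the DM criterion, which runs at the default scale
  because transition-zone blur at small panels shaves recall below its
  bound — a property of the stated world, not of the estimator.
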