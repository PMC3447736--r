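---
title: "Methods: replicate-calibrated developmental expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-calibrated developmental expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devexpr)
```

# The problem

Early developmental transcriptomes are often profiled as one deeply
sequenced library per life-cycle stage: biological material is limiting,
and the design question shifts from "is the difference larger than
biological variability?" to "is the difference larger than what the
sequencing process itself produces?". devexpr implements a complete
analysis built on that premise for a four-stage pelagobenthic life cycle —
two pelagic larval stages (precompetent, competent) followed by two benthic
stages (postlarva, adult) — and ships a synthetic-data generator with
planted ground truth so that every inference step can be validated without
external data.

# The noise model

For a gene observed with count $N$, technical replicate libraries of the
same RNA differ by an amount that scales as $\sqrt{N}$, and in practice the
difference stays below an envelope $k\sqrt{N}$ with $k = 5$. The relative
count error $k\sqrt{N}/N$ therefore shrinks with depth and is negligible
for well-sampled genes. Two design consequences:

* the envelope is treated as a **conservative bound to verify**, not a
  likelihood to fit — simulations use Poisson replicates by default
  (`noise_model(dispersion = 0)`), with an optional negative-binomial
  alternative for robustness checks;
* every decision rule that compares two single counts carries an explicit
  noise gate derived from this envelope.

For Poisson replicates the envelope is a $>5\sigma/\sqrt 2$ bound once the
`max(N1, N2)` inside it is accounted for; at the count distributions the
generator produces (log-normal baselines, median tens to hundreds of
reads) the observed violation rate over $10^5$ genes is below $10^{-4}$.
At extreme depths ($N \gtrsim 10^3$) the normal approximation puts the
asymptotic violation rate near $4\times10^{-4}$: the envelope is an
empirical bound for count distributions dominated by moderate counts, which
is exactly the regime the method is used in.

# Detection threshold

`calibrate_detection_threshold()` returns the smallest integer $c$ such
that every gene with count $\ge c$ in either of two technical replicates is
detected (count $\ge 1$) in the other. "Detected in the partner" is the
operative reading of mutual detection; the returned value is exact, not
rounded to a power of two. The calibration is performed on the
lowest-depth library; `detection_threshold_from_calibration()` converts it
to the normalized scale by the depth ratio (e.g. raw 32 at half depth
becomes 64 normalized). This conversion matters: a dropout (zero in one
replicate) requires a near-zero sampling mean, so the probability that a
gene reaches a threshold $T$ in one replicate while vanishing in the other
decays *doubly exponentially* in $T$. The rescaled threshold is therefore
strictly more conservative than the raw one, and fresh replicate pairs at
reference depth satisfy mutual detection above it in ≥ 99% of trials —
the property the acceptance suite verifies. Detection itself
(`detect_genes()`) is inclusive at the threshold, so the printed threshold
value detects.

# Differential expression

All log-scale statistics use $y = \log_2(\text{count} + 1)$; the +1
pseudocount keeps zeros defined and is applied uniformly (tests, extreme
statistic, relative-expression matrix). Fold cutoffs are inclusive
($\ge 4$-fold by default, $\ge 2$-fold as the common alternative), fixed
for determinism.

**Stage-specific test.** With one library per stage, the only available
t-test of one stage against the rest is the one-sample two-tailed test of
the three non-focal $y$ values against the focal value (df = 2). A call
requires both $|y_f - \bar y_{\text{others}}| \ge \log_2(\text{cutoff})$
and $p < \alpha$. When the three non-focal values are identical the test
degenerates; the p-value is defined as the limit (1 if the focal value
matches, 0 otherwise) and the record is flagged.

**Settlement test.** Pooled-variance two-sample t-test (2 vs 2, df = 2) of
the pelagic pair against the benthic pair; the sign convention reports
upregulation after settlement as "up".

**Transition classification.** Between successive stages a gene is up
(down) when the fold change reaches the cutoff *and* the count difference
clears the noise gate $|N_2 - N_1| > k\sqrt{\max(N_1, N_2)}$ — the
conservative symmetric instantiation of "sampling error between two
counts". Fold uses counts floored at 1 (not the +1 pseudocount) so that
64 → 256 is exactly four-fold at the boundary. Genes below the detection
threshold in both stages are excluded rather than reported as unchanged.

**Monte-Carlo fold cutoffs.** `fold_cutoff()` reconstructs, by simulation,
the fold change that technical replicates exceed with probability $\alpha$
at a given expression level: the $(1-\alpha)$ quantile of
$\max(X_1,X_2)/\min(X_1,X_2)$ with zeros floored at 1. At $n = 64$,
$\alpha = 0.05$ under Poisson noise it agrees with the normal-approximation
closed form $\exp(z_{0.975}\sqrt{2/n}) \approx 1.41$ within 0.05. The
published-style cutoffs at 5/1/0.1% false calling depend on the empirical
replicate distribution and are not asserted as constants of the method.

**Extreme upregulation.** The per-gene statistic is
$\max_s [y_s - \text{mean}(y_{\text{others}})]$; values at or above
$\log_2(100) \approx 6.644$ flag an extreme stage differential.

# Enrichment

Annotation is transferred from best hits (lowest e-value at or below
$10^{-4}$; ties broken toward the lexicographically smaller subject id).
The enrichment engine is vocabulary-agnostic — GO, PANTHER or any flat
gene→term table.

`resampling_enrichment()` draws $R$ gene sets of the observed size without
replacement from the universe of *detected annotated* genes and estimates
$p = (b + 1)/(R + 1)$, where $b$ counts resamples whose term overlap
reaches the observed one; the add-one estimator avoids literal zeros and
floors $p$ at $1/(R+1)$. $R$ defaults to 10,000 with a mandatory seed.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied across
tested terms, at the conventional 0.05 level. As $R \to \infty$ the
estimate converges to the hypergeometric upper tail, which the tests use
as the exact oracle.

The at-peak rule marks a gene in every stage whose count lies in the top
$1-q$ of the gene's own range ($\text{count} \ge \min + q(\max-\min)$,
$q = 0.75$), on **linear** normalized counts by default (a log-scale
variant is available via `log_scale = TRUE`; the choice matters only for
genes with very large ranges). Constant genes are at peak everywhere — the
degenerate limit of the inequality — and every gene is at peak in its
maximum stage. Stage enrichment/depletion of a gene family is then a
Fisher's exact 2×2 test (family × at-peak), with both one-sided tails
reported because directionality conventions differ between studies; the
family is excluded from its own background by construction of the 2×2
table.

# qPCR validation

`delta_delta_ct()` implements textbook ΔΔCt: per-replicate
$\Delta Ct = Ct_{\text{target}} - Ct_{\text{reference gene}}$, per-stage
mean and sd, $\Delta\Delta Ct$ against a reference stage, fold
$2^{-\Delta\Delta Ct}$. Replicates are independent biological pools, not
technical triplicates, so a plain one-way fixed-effects ANOVA with
Bonferroni-adjusted pairwise pooled-variance t-tests
(`anova_bonferroni()`) is the appropriate replicate-variance check; all
stage pairs are compared rather than only pairs against the reference.

`qpcr_concordance()` reports (i) per gene, the Pearson correlation between
the sequencing log2 fold profile and the qPCR log2 fold profile — log
folds, because expression trends are compared on a ratio scale and the
linear alternative is dominated by the largest stage; and (ii) pooled over
gene × stage points, the Spearman correlation between replicate-mean
$\Delta Ct$ and $\log_2(\text{count}+1)$, expected strongly negative. The
reference-normalized cycle count is used on the qPCR side because it is the
quantity the assay actually measures on a scale comparable across genes.

# The synthetic-data generator

`generate_dataset()` draws, from one seed, a complete dataset plus a truth
record. What it emulates, and the defaults chosen:

* **Depths** 112 500 / 82 500 / 50 000 / 100 000 for PRE/COMP/POST/ADULT —
  the study-like 45/33/20/40 million mapped reads scaled down 400× so a
  full dataset generates in seconds; the depth *ratios*, which drive
  normalization and the 64↔32 threshold equivalence, are preserved.
* **Expression classes** 50% constant, 15% stage-specific, 15% transition
  (a step change at one transition, persisting onward), 20% silent;
  baselines log-normal with mean 4 and sd 1.5 on the log2 scale; planted
  effects uniform on 2–7 log2 units. Counts are
  $X(g,s) \sim \text{Poisson}(\text{depth}_s \cdot p(g,s))$ with $p$ the
  true relative abundance (negative binomial when dispersion > 0).
* **Gene models** 2000 genes over 20 contigs, 1–6 exons of 150–400 bp,
  introns 200–1500 bp, intergenic gaps 2–15 kb, random strand.
* **Reads** 50 000 single-end 50-mers placed 80.7% in exons (genes sampled
  by expression), 5.7% in introns, 13.6% intergenic (uniform in gaps, read
  strand matching the nearer flanking gene's strand with probability 0.55).
  Placements are fully contained in their target feature, so every label is
  unambiguous under the ≥ 50%-overlap classification rule — deliberate, so
  that attribution can be graded exactly.
* **Annotation** 64% of genes carry a transferable best hit (e-values
  $10^{-50}..10^{-5}$); a slice of the rest get sub-cutoff hits
  ($> 10^{-4}$) to exercise the filter; 150-term vocabulary with ~3 terms
  per annotated gene. Three planted terms are attached to stage-specific
  genes at 25× the background rate (~50% penetration), chosen so the
  planted truth is unambiguously enriched — the generator's self-check
  requires a hypergeometric p < $10^{-3}$ for each planted term in its
  class.
* **qPCR** a 10-gene panel preferring dynamically expressed genes (as a
  validation panel would), 3 replicate pools per stage, replicate
  $\Delta Ct = 20 - \log_2(\text{abundance})$ plus Gaussian noise with
  sd 0.3 cycles; reference-gene Ct near 15 cycles.

What it does **not** emulate: spliced/junction reads and mapping bias,
overlapping or nested gene models, UTRs outside annotated spans, symbiont
contamination, amplification efficiency differences between qPCR primers,
and biological replicate variability. Passing tests therefore demonstrate
the correctness and calibration of the inference machinery under the
stated noise model, not robustness to misannotation or mapping artifacts.

# Numerical and design choices

* Internally all coordinates live in `GenomicRanges` (1-based, closed), the
  Bioconductor convention; GFF3 and BED conversion happens only inside
  rtracklayer at the I/O boundary, so no hand-written off-by-one arithmetic
  exists anywhere in the package.
* Locus dedup clusters transcripts by transitive span overlap per
  contig+strand (connected components; for intervals these coincide with
  merged-coverage clusters) and keeps the longest span; ties break toward
  the lexicographically smaller id. Opposite-strand overlap never
  clusters — the alternative (strand-blind loci) would merge convergent
  gene pairs, which is not how the gene catalogue treats them.
* Read classification: ≥ 50% of the aligned length decides exon/intron
  membership (robust for 50-mers straddling feature edges); gene
  assignment is strand-agnostic, and strand is used only for the
  intergenic sense/antisense call. Intergenic distance is measured from
  the read midpoint; exact TSS/TTS ties resolve toward the TSS. "In
  proximity" to a gene means within 10 kb by default (configurable) —
  an operational choice, not an asserted constant.
* Degenerate inputs have defined outcomes everywhere: zero-variance t-tests
  (p = 0/1 limits, flagged), constant genes in the relative-expression
  matrix (0.5), constant genes in at-peak (all stages), empty gene sets
  (empty results), zero counts in fold ratios (floored at 1).
* The pipeline fans one top-level seed out to per-stage seeds by a fixed
  affine derivation, so single stages can be re-run reproducibly; two runs
  of the same config produce byte-identical bundles, which the acceptance
  suite checks by hashing.

# Problem sizes

The shipped tests run the generator at 100–2000 genes and 1000–50 000
reads, the null-calibration checks at 10 000 genes, envelope and
fold-cutoff simulations at $10^5$ replicate pairs, and the resampling
oracle at $R = 20\,000$ — sizes at which the whole suite completes in about
a minute while keeping Monte-Carlo error well below the tolerances being
asserted.

# Limitations

The method calibrates against *technical* sampling noise only; with single
libraries per stage, biological variability is unidentifiable and calls
are statements about libraries, not populations. The df = 2 t-tests have
very coarse p-value resolution, which is why the fold cutoff — not the
p-value — carries most of the filtering burden. Resampling p-values are
bounded below by $1/(R+1)$, so BH-adjusted significance saturates for
strongly enriched terms. The transition classifier's noise gate assumes
depth-normalized counts keep Poisson-scale errors, which holds when depth
ratios are modest (≤ ~2.5 here) but becomes conservative for strongly
unequal depths.
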