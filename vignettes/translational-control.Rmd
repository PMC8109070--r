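---
title: "Models and methods for polysome-profiling TE analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for polysome-profiling TE analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysomeTE)
```

# Scope and model

`polysomeTE` quantifies translational control from paired total and
polysome-fraction RNA-seq counts over a factorial design: strains
(typically a wild type and an eIF2α-phosphorylation-deficient mutant),
timepoints (exponential growth and entry into stationary phase), two
fractions, and replicates. It starts from count matrices; alignment and
read counting are out of scope, as are curated annotation databases
(term maps and 5' leader definitions are user inputs).

The observation model treats counts as negative binomial,
$K_{gj} \sim \mathrm{NB}(s_j \mu_{gj},\ \phi_g)$ with
$\mathrm{Var} = \mu + \phi\mu^2$. Size factors $s_j$ use the
median-of-ratios estimator: over genes with strictly positive counts in
every sample, the median of $K_{gj}$ divided by the gene's geometric
mean across samples. Even-sized medians take the arithmetic midpoint.
If no gene is positive everywhere the estimator stops and asks for
pre-filtering rather than silently changing reference.

Translation efficiency per (strain, time) cell is the pseudocounted
ratio of normalized replicate means,
$\mathrm{TE} = (\bar Y_{\mathrm{poly}} + c)/(\bar Y_{\mathrm{total}} + c)$,
and the quantity tested is its log2 change over time,
$\Delta_g = \log_2 \mathrm{TE}(\mathrm{late}) - \log_2 \mathrm{TE}(\mathrm{early})$,
a difference of differences of four cell means. The strain interaction
is $\Delta\Delta_g = \Delta_g^{(1)} - \Delta_g^{(2)}$.

# The TE test

Published analyses of this kind often delegate inference to a
general-purpose DE package with default settings, which leaves the
actual TE statistic undefined. We instead use a transparent
delta-method Wald test:

* per cell, the replicate variance of $\log_2(Y + c)$;
* each cell variance moderated toward an expression-dependent trend:
  genes are ranked by mean log2 expression over the contrast's samples
  and cut into `n_bins` equal-occupancy bins (default 20; ties share a
  bin so results cannot depend on gene order); the gene's variance is
  shrunk toward its bin mean with weight
  $n_{\mathrm{prior}}/(n_{\mathrm{prior}} + n_{\mathrm{rep}} - 1)$,
  default $n_{\mathrm{prior}} = 5$ — at duplicate level the trend
  dominates (weight 5/6), which is what makes $n=2$ inference usable;
* combined as $SE^2 = \sum_{\mathrm{cells}} v_{\mathrm{cell}}/n_{\mathrm{cell}}$,
  $z = \Delta/SE$, two-sided normal p, and Benjamini–Hochberg adjustment
  across the genes that pass the expression filter.

Numerical safeguards: $SE^2$ is floored at the 5th percentile of the
moderated values among non-flagged genes, so degenerate replicates
(identical counts) can never produce an infinite z; flagged
low-expression genes (any required cell mean below `min_count`,
default 10 normalized counts) carry `NA` statistics and do not enter
the BH family; the pseudocount (default $c = 0.5$) keeps log-ratios
finite at zero cell means. Swapping the contrast's time labels negates
$\Delta$ and $z$ exactly and leaves p unchanged.

For duplicate-level designs where the normal reference is a concern, a
permutation mode relabels timepoints within each fraction (jointly over
fractions), with exhaustive enumeration whenever at most 20 distinct
relabellings exist and sampled permutations otherwise. The Wald mode is
the default: under the planted null its raw p-values are uniform to a
Kolmogorov–Smirnov statistic below 0.03 at 2,000 genes (the test suite
checks this), and it yields a continuous p scale that duplicate-level
permutation cannot.

# Gene sets, scatters, uORFs, enrichment

A gene is *translationally up-regulated* when its TE fold change is
strictly above `fold_threshold` (default 1.5) **and** its p-value is
strictly below `alpha` (default 0.05). Strictness matters at the
boundary: exactly 1.5-fold is not "higher than 1.5-fold". Whether the
raw or the BH-adjusted p-value is thresholded is an explicit argument
(`p_field`, default raw) because published threshold phrasing is often
ambiguous between the two; both are always reported. The
"much higher activation in the wild type" subset among genes up in both
strains uses a configurable excess margin on $\Delta$, default 1 log2
unit — a deliberately conservative two-fold excess, since no published
quantification of "much higher" exists to copy.

Scatter summaries (mRNA change versus TE change per strain; TE change
between strains) are ordinary least squares plus Pearson r, with
$R^2 = r^2$; constant inputs raise an "undefined correlation" error
rather than returning NaN.

The uORF scanner is ATG-dependent by construction: every ATG in the
leader opens a candidate ORF, read in frame; the first in-frame
TAA/TAG/TGA strictly before the CDS start closes a fully *upstream*
uORF (minimum two codons — an ATG immediately followed by a stop
counts), and a frame that reaches the CDS without a stop is recorded as
*overlapping*. Default proportions count only fully upstream uORFs,
with `mode = "any"` exposing the inclusive definition; codons containing
N never match a start or stop. The expected proportion $p_0$ for the
set-level test is always computed from the full supplied annotation,
never hard-coded, because genome-wide uORF frequencies are
annotation-version-dependent. The set test is the exact two-sided
binomial test (minimum-likelihood convention, as `binom.test`).

Term over-representation is the standard one-sided hypergeometric upper
tail with BH control. The default universe is the genes passing the
expression filter (an expression-conditioned background reduces
detection bias), configurable to all annotated genes; terms with fewer
than 3 in-universe genes are skipped by default.

# What the simulator emulates

`simulateCounts()` draws NB counts over the full factorial design with:
log-normal gene baselines (defaults: log-mean 5, log-sd 1.5); a
dispersion trend $\phi(\mu) = a/\mu + b$ with defaults $a = 1$,
$b = 0.005$, the low-dispersion regime of deeply sequenced yeast
libraries with clonal replicate cultures — chosen so that
well-expressed genes ($\mu > 100$) are in the regime where a
four-replicate design recovers planted log2 TE effects with correlation
above 0.9; log-normal library-size factors (log-sd 0.2, spanning about
±50%); and planted log2 effects, either normal draws
(`effect_log2_sd`) or fixed magnitude with random signs
(`effect_fixed_log2`). mRNA effects multiply both fractions at the
later timepoint; TE effects multiply the polysome fraction only at the
later timepoint — the cleanest operationalization of translational
regulation as distinct from transcription. Effect fractions can differ
per strain, and `frac_te_shared` plants one additional TE component
identically in both strains, which is how a strain-independent
translational program with a WT-amplified subset is expressed.

One master seed derives named substreams (counts, size factors,
leaders, terms), so adding or re-running one stage never perturbs
another's draws, and identical parameters give bit-identical output.

`simulateLeaders()` draws random-composition leaders of
Poisson-distributed length (mean 150 nt, a typical yeast leader scale).
With the gene-class probability (`uorf_prob_by_class`, defaults:
background 0.4 — roughly the genome-wide uORF frequency reported for
fission yeast annotations — 0.4 for WT-dependent up-genes, 0.2 for
mutant-dependent up-genes, encoding uORF depletion in the set that does
not require eIF2α phosphorylation) an intact upstream uORF is planted
at a random in-bounds position; otherwise every accidental upstream
uORF is destroyed by mutating its ATG's A to C, an edit that can create
neither a new ATG nor a new stop codon, so the loop provably
terminates. Leaders too short to host a planted uORF are redrawn, with
a capped retry count.

What the generator does **not** emulate: GC and length biases,
batch effects, correlated dispersion outliers, read-level artifacts,
multi-exon coordinate lifting, and any sequence realism beyond uniform
base composition. Passing the planted-truth tests therefore
demonstrates the statistical machinery is correct under the stated
noise model — not that real libraries meet that model.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use 2,000-gene simulations at
the 16-sample study design for calibration and recovery checks,
400–800 genes for Monte-Carlo repetitions over 20 seeds, and 250–500
genes for end-to-end pipeline runs — sizes at which every Monte-Carlo
bound checked has comfortable slack while a full run stays in the tens
of seconds. `runPipeline()` writes every intermediate table, the
configuration, and md5 checksums of all outputs into `manifest.json`;
two runs with the same configuration are byte-identical.

# Known limitations

* The Wald test relies on the delta-method normal approximation; at
  duplicate level its honesty comes from the strong variance
  moderation, and genuinely heavy-tailed per-gene variation will be
  over-shrunk. The permutation mode is the cross-check.
* TE ratios with pseudocounts are biased for very low counts; the
  expression filter (default 10 normalized counts per required cell) is
  the guard, and lowering it trades bias for coverage.
* The uORF scanner considers AUG starts only (no near-cognate starts)
  and single-exon, plus-strand transcript coordinates.
* GFF3 input is restricted to transcript-coordinate, single-CDS-row
  records; genomic multi-exon annotation must be resolved to transcript
  coordinates upstream.
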