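---
title: "Methods: calling and classifying aberrant ncRNA promoter methylation"
author: "ncMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and classifying aberrant ncRNA promoter methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncMeth)
```

# The data model

Capture-based methylome sequencing (MBDCap-seq and relatives) enriches
methylated DNA fragments; after alignment, the number of reads falling
in each fixed 100-bp genomic bin is a monotone proxy for the local
methylation level. `ncMeth` represents a cohort of such tracks as a
`BinMethylome`, a `RangedSummarizedExperiment` whose rows are the bin
grid, whose columns are samples labelled `tumor` or `normal`, and whose
single `counts` assay holds raw or normalized intensities. All other
region types (gene bodies, ±2-kb promoters, CGIs, 2-kb shores, DMRs)
are `GRanges` with documented metadata columns, so the standard
Bioconductor overlap machinery applies throughout.

# DMR calling

**Normalization.** Library sizes are equalized linearly: sample $j$ is
scaled by $\bar{T}/T_j$ where $T_j$ is its total count, after which all
totals equal the cohort mean. Capture data are not absolute
methylation measurements, so only this between-sample scaling is
attempted; no GC or CpG-density correction is in scope.

**Per-bin test.** Each bin passing a coverage floor is tested with a
two-sided Wilcoxon rank-sum test between tumor and normal sample
values. For pooled sizes up to `exactLimit = 12` the p-value comes
from exact enumeration of all $\binom{n+m}{n}$ assignments of the
pooled midranks — unlike the classical exact null this remains valid
under ties, which are ubiquitous in low counts. Above the limit a
normal approximation with tie correction and continuity correction is
used; the cohort scale this package targets (tens of samples) sits in
the approximation regime, while the enumeration branch keeps small
test fixtures exact.

**The dual criterion.** A bin is called `hyper` (`hypo`) when the
fold change of pseudocounted group means,
$(\bar{x}_T + c)/(\bar{x}_N + c)$ with $c = 0.5$ normalized units, is
$\ge 2$ ($\le 1/2$) *and* the BH-adjusted p-value is $< 0.01$.
Benjamini–Hochberg adjustment (`adjustBH`, the classical step-up) is
applied genome-wide across all tested bins; per-chromosome adjustment
was the other defensible reading and genome-wide was chosen as the
stricter, simpler family. Fold changes use group *means*; medians
were considered and rejected because with $n = 10$ controls a median
is noisier than a mean under negative-binomial counts of this
dispersion.

**Coverage floor.** Bins whose group means are both below
`minMean = 1` are excluded from testing *and from the BH family*.
Capture leaves most CpG-poor bins empty; carrying millions of
untestable bins in the family would deflate power without changing
any call. The floor is deliberately low — it removes only bins where
no test could ever reject.

**Merging.** Consecutive called bins of the same direction with no
intervening bin merge into a DMR; a gap of even one uncalled bin, or a
direction change, starts a new region. Singleton DMRs are allowed. A
DMR records its bin count, minimum q and maximal $|\log_2$ fold
change$|$.

**Zeros.** The pseudocount keeps fold changes finite on empty bins
without moving well-covered ratios; a sample with zero total count is
an error (it cannot be normalized), reported by name.

# Promoters, patterns, profiles

**Promoters** are the ±2-kb windows around the stranded TSS (gene
start on `+`, gene end on `-`). Pri-miRNA loci are anchored the same
way — the stranded 5′ end of the locus. The unstranded alternative
(always the genomic locus start) was considered; anchoring on the
stranded end keeps miRNA and lncRNA promoter semantics identical and
is what the TSS-relative profile analyses assume. Promoters running
off a chromosome start are clamped and flagged rather than dropped, so
the gene universe is stable.

**Promoter calls.** A gene is called in a direction when ≥ 50% of
some DMR of that direction lies inside its promoter. The threshold is
inclusive ("at least 50%"); boundary tests pin this down. A gene
supported by DMRs of both directions is reported in both lists and
flagged ambiguous; single-direction summaries exclude it.

**Five patterns.** For a called gene, its supporting DMRs are placed
in the promoter's CGI context in a fixed precedence order chosen to
make the five classes mutually exclusive and deterministic:

1. no promoter CGI → pattern 5 (`no_cgi`);
2. DMR–CGI overlap **strictly greater** than 50% of either region
   (the `either_max` overlap fraction) → pattern 1 (`cgi_confined`);
3. zero CGI overlap, DMR entirely 5′ of every promoter CGI and
   touching the 5′ shore → pattern 2; mirrored on the 3′ side →
   pattern 3;
4. everything else → pattern 4 (`partial_overlap`).

Note the asymmetry: promoter mapping is inclusive at 50% while the
CGI-confinement rule is strict ("greater than 50%") — a DMR covering
exactly half the CGI is pattern 4. Shores flank the CGI with no gap
(2 kb each side); 5′/3′ laterality follows the gene's strand, and in
multi-CGI promoters the CGI nearest the TSS anchors the laterality
decision. When several supporting DMRs disagree, the one with the
largest promoter overlap decides; exact ties take the lowest pattern
number and are flagged. On noiseless input (spike regions used
directly as DMRs) the classifier reproduces 100% of the generator's
manifest labels; under sampling noise a recovered DMR can fragment at
a CGI edge and a fragment may legitimately reclassify (typically
pattern 4 → 1), which is a property of the data, not the classifier.

**TSS profiles.** Promoters are divided into 10-bp windows in
stranded orientation (column 1 = −2 kb upstream); a window is 1 when
it intersects a DMR of the requested direction, and column means give
the average aberrant-methylation frequency curve. The profile is
invariant under genome reflection with strand flip, which the tests
assert on random fixtures.

# Expression integration and biomarker panels

lncRNA expression arrives as FPKM for one control and multiple tumor
cell lines; a gene is differentially expressed only when **every**
tumor line shows the same strict > 2-fold change against control
(pseudocount `minFpkm = 0.1` guards zero FPKM). miRNA expression
arrives as a cohort RPM matrix; each miRNA gets a pooled-variance
Student t-test on $\log_2(\mathrm{RPM}+1)$ — the transform stabilizes
the variance of count-derived values — with BH adjustment at 5%.
Candidates require opposing directions: hyper + down = silencing,
hypo + up = activating; concordant pairs are dropped and counted.

Biomarker panels Z-transform each feature across samples (sample sd,
ddof 1), flip the sign of features whose cancer-associated direction
is negative, and **average** the signed Z-scores into one score per
sample. The mean (rather than the sum) keeps scores comparable across
panel sizes. Hyper- and hypomethylated panels are evaluated
separately, on methylation or expression features alike; AUC uses the
Mann–Whitney identity with ties counted ½, so it is exact under heavy
ties.

# Functional similarity

Gene-level functional similarity is the Jaccard index of
annotation-term sets, set-level similarity the symmetric best-match
average, and group comparisons are normalized to the intra-class
scores, $2 S(A,B)/(S(A,A)+S(B,B))$. No published specification of
this similarity system exists at this level of detail, so these are
the package's own, deliberately simple, choices; they are stated in
output metadata, an information-content similarity over an ontology
DAG is an extension point, and only the qualitative ordering —
same-pool groups score above cross-pool groups — is claimed or
tested. Self-similarity of a multi-gene set excludes self-pairings
(a singleton set scores 1 by convention). Term enrichment is a
one-sided Fisher exact test per term with BH across terms; odds
ratios are sample odds ratios with Haldane correction when a cell is
zero.

# The synthetic-data generator

The generator emulates the study design the pipeline targets, at desk
scale: 2 chromosomes × 2 Mb, 100-bp bins, 60 coding genes, 100
lncRNAs, 40 pri-miRNAs, 20 tumor vs 10 normal samples, baseline 100
reads/bin, negative-binomial dispersion 10 (variance
$m + m^2/10$ — cohort methylomes are strongly overdispersed, so a
Poisson model would overstate power), CGI bins elevated 2-fold in
*both* groups (capture enriches CpG-dense DNA; the elevation cancels
in fold changes), and per-sample library-size factors log-uniform in
[0.8, 1.25]. Genes live on a 12-kb slot grid so that promoters,
shores and spikes never collide between genes; intragenic and
overlapping ncRNAs are placed inside or straddling coding hosts to
realize a 60/25/15 biotype mix.

Spikes multiply (hyper) or divide (hypo) the tumor-group mean by
fold 4 over bin-aligned stranded windows chosen per pattern: the CGI
body (+200..+1200 from the TSS) for pattern 1, −1000..−200 for
pattern 2 (5′ shore, clear of the CGI), +1300..+1900 for pattern 3,
−200..+500 for pattern 4 (300 bp CGI overlap, `either_max` 0.43 —
every pattern-defining fraction clears its threshold with ≥ 10%
margin so classifications are never knife-edge), and −400..+400 on
CGI-less promoters for pattern 5. CGIs sit downstream of the TSS,
matching the empirical observation that aberrant methylation
concentrates immediately downstream of the TSS. Expression coupling
divides (silencing) or multiplies (activating) tumor expression by
fold 4 with log-normal noise of sd 0.25 log2 units; histone tracks
reduce H3K4me3 and elevate H3K27me3 3-fold at silencing promoters.

Everything is deterministic given the config seed (annotation,
counts, expression and histone draws use distinct seed offsets), and
the truth manifest records every spike with its gene, direction,
pattern and coupling.

**What the generator does not emulate** — and hence what passing
tests do *not* show about real data: copy-number confounding,
fragment-size and MBD-affinity biases, CpG-density-dependent capture
efficiency beyond the flat CGI elevation, correlated neighbouring
bins, batch structure, and cohort heterogeneity (every tumor sample
shares one effect size). Recovery rates on this generator are
best-case; the pipeline's statistical machinery, not its field
performance, is what they validate.

# Numerical choices and degenerate inputs

* Exact-vs-approximate rank-sum switch at pooled size 12; continuity
  correction of 0.5 toward the null; all-tied bins give p = 1.
* BH inputs outside [0, 1] are errors, not clamped.
* Zero-variance panel features are dropped with a warning; an
  all-constant panel is an error.
* Fisher odds ratios use Haldane 0.5 correction only when a zero cell
  exists, so nonzero tables report the plain sample OR.
* t-tests with zero pooled variance return p = 1 when means agree and
  p = 0 otherwise.
* DMR BED scores are $-\log_{10}(\min q)$ capped at 300 to avoid
  infinities from underflowed q-values.
* Readers reject malformed input (grid misalignment with the
  offending line, negative intensities, unknown gene classes,
  duplicate ids, missing expression cells) rather than coercing.

# Problem sizes used by the tests

Unit tests run on constructed fixtures of a few dozen bins. The
end-to-end checks simulate the standard 2 × 2 Mb, 30-sample study: 20
spiked cohorts for DMR recovery, 20 spike-free cohorts for null
calibration, one cohort for integration and panel evaluation, and a
1 × 0.4 Mb, 22-sample configuration for the byte-identity check of
the file-level pipeline — sizes chosen so the full suite completes in
minutes while every stage still operates in its intended regime
(normal-approximation rank-sum branch, genome-wide BH family of
~40,000 bins).

# Known limitations

* The bin test treats bins independently; no smoothing or HMM
  segmentation, no covariates, no paired designs.
* Transcript-level isoform promoters are out of scope (one promoter
  per gene).
* A gene called in both directions is excluded from single-direction
  pattern summaries rather than adjudicated.
* The functional-similarity measure is a stated surrogate; only its
  ordering behaviour is validated.
* Heat-map rendering is out of scope; the package exports matrices.
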