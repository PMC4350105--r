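# ncMeth

Genome-wide analysis of aberrant DNA methylation at non-coding RNA
promoters, from bin-level capture-sequencing counts to classified
promoter methylation patterns, expression integration and biomarker
panels.

## The problem

Methylation capture sequencing (e.g. MBDCap-seq) summarises a sample's
methylome as read counts on fixed 100-bp genomic bins. Given such bin
tracks for a tumor cohort and a control cohort, plus a gene annotation
(protein-coding genes, lncRNAs, pri-miRNAs) and CpG-island (CGI)
coordinates, `ncMeth` answers, in order:

1. **Where is methylation different?** Each bin is tested between
   groups; a bin is differentially methylated when the fold change of
   the (linearly normalized, pseudocounted) group means is ≥ 2 (or
   ≤ 1/2) *and* the Benjamini–Hochberg-adjusted two-sided Wilcoxon
   rank-sum p-value is < 0.01. Gap-free runs of same-direction
   significant bins are merged into DMRs (differentially methylated
   regions).
2. **Which promoters are affected?** A gene's promoter is the ±2-kb
   window around its stranded TSS. A gene is called differentially
   methylated when at least 50% of some DMR lies inside its promoter.
3. **In what CGI context?** Each called promoter receives one of five
   patterns: (1) methylation confined to the CGI (DMR–CGI overlap
   > 50% of either region), (2) strictly 5′ of the CGI on its shore,
   (3) strictly 3′ on the shore, (4) partial CGI/shore overlap,
   (5) promoter lacking a CGI. Shores are the 2 kb flanking a CGI;
   5′/3′ laterality follows gene strand.
4. **Does expression respond?** Hypermethylated + downregulated genes
   are *silencing* candidates; hypomethylated + upregulated genes are
   *activating* candidates (cell-line lncRNA FPKM with a strict
   2-fold rule in every tumor line; cohort miRNA RPM with a Student
   t-test on log2(RPM+1), BH-adjusted at 5%).
5. **Can the candidates discriminate?** Per-feature Z-scores across
   samples are sign-oriented and averaged into one score per sample,
   evaluated by ROC/AUC (Mann–Whitney identity).

Supporting analyses: ncRNA biotype classification (intergenic /
intragenic / overlapping with host-gene concordance), TSS-centered
10-bp aberrant-methylation frequency profiles, Fisher-exact region-set
enrichment, histone-mark concordance, and best-match-average Jaccard
functional similarity between pattern groups with intra-class
normalization `2·S(A,B)/(S(A,A)+S(B,B))`.

Because real cohorts of this kind are large downloads, the package
bundles a synthetic-data generator (`simConfig()`,
`simulateAnnotation()`, `simulateMethylome()`, `simulateExpression()`,
`simulateHistoneTracks()`) that emits negative-binomial bin-count
cohorts with promoter spikes of every pattern class and a ground-truth
manifest, so the whole pipeline is testable end to end.

## Worked example

```r
library(ncMeth)

cfg <- simConfig(seed = 1L)       # the standard toy study
cfg
#> SimulationConfig: 2 x 2 Mb chromosomes, 100-bp bins
#>   genes: 60 coding, 100 lncRNA, 40 miRNA; CGI promoter fraction 0.70
#>   cohort: 20 tumor vs 10 normal; NB(mean 100, dispersion 10)
#>   spikes: 20; seed 1

ann <- simulateAnnotation(cfg)
sim <- simulateMethylome(ann, cfg)
sim$bm
#> BinMethylome: 40000 bins (100 bp) x 30 samples (20 tumor, 10 normal)

res <- callDmrs(sim$bm)           # normalize -> test bins -> merge
res$dmrs[1:3]
#> GRanges object with 3 ranges and 4 metadata columns:
#>       seqnames        ranges strand | direction    n_bins      min_q max_abs_l2fc
#>   [1]     chr1 279001-279800      * |     hyper         8 0.00375295      2.37703
#>   [2]     chr1 568801-569800      * |     hyper        10 0.00375295      2.40388
#>   [3]     chr1 605301-605900      * |     hyper         6 0.00375295      1.97161

calls <- mapDmrsToPromoters(res$dmrs, ann$promoters)
pat <- classifyPatterns(calls, ann$promoters, ann$cgis, res$dmrs)
table(direction = pat$direction, pattern = pat$patternName)
#>          pattern
#> direction cgi_confined five_prime_shore three_prime_shore partial_overlap no_cgi
#>     hyper            2                2                 2               2      2
#>     hypo             4                2                 2               0      2
```

All 20 spiked promoters are recovered with the right direction. The
two hypo `partial_overlap` spikes appear as `cgi_confined` here
because the recovered DMR fragmented at the CGI edge, leaving a piece
whose CGI overlap exceeds 50% — on noiseless input the classifier
reproduces all manifest labels exactly (see the methods vignette).

```r
meth <- promoterMethylation(normalizeLinear(sim$bm), ann$promoters)
panel <- evaluatePanel(meth[sim$truth$silencing, ],
                       rep("hyper", 4), sampleGroups(sim$bm))
panel$auc
#> [1] 1
round(panel$scores[c(1, 2, 21, 22)], 2)
#>  tumor01  tumor02 normal01 normal02
#>     0.72     0.75    -1.21    -1.33
```

Higher panel scores mean more tumor-like methylation at the silencing
candidates; here the toy cohorts separate perfectly (AUC 1).

`runPipeline(cfg, outdir)` executes the same analysis through the
on-disk formats (bedGraph tracks, BED annotation, TSV expression),
writing `dmrs.bed`, `pattern_calls.tsv`, TSS profile matrices,
`candidates.tsv` and panel AUCs; outputs are byte-identical for a
given config and seed.

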