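---
title: "Associating cis-regulatory mutations with gene-network dysregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating cis-regulatory mutations with gene-network dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysnet)
```

## The problem

Most somatic mutations in a tumor genome are passengers. Exome-centred
driver discovery asks whether a gene's coding mutations recur more often
than expected; `dysnet` instead asks whether mutations — in particular
*cis-regulatory* mutations falling in transcription factor binding sites
(TFBSs), and loss-of-function (LoF) coding mutations — co-occur with
*trans*-dysregulation: a shift away from neutral expression among the
mutated gene's network partners (for a protein-coding gene, its functional
interaction partners; for a miRNA, its predicted targets). A mutation that
silences an enhancer of a transcription factor, or destroys a miRNA's
promoter, leaves a footprint not in the gene's own sequence but in the
expression of the genes it regulates.

The package implements the full procedure on cohort data: interval
arithmetic over binding sites, exons and flanks; mutation-rate comparisons
against chromosome-preserving shuffles; expression normalization and
expressed-gene filtering; mutation-to-gene assignment through regulatory
elements or closest transcription start sites; network weight updating; a
hierarchical Bayesian dysregulation model; an empirical false discovery
rate built from shuffled controls; and enrichment and survival utilities.
A first-class synthetic-cohort simulator with planted drivers makes every
stage testable without any data download.

## The hierarchical dysregulation model

For one candidate gene $g$ the data are: the set $S_g$ of samples in which
$g$ carries a qualifying mutation (binary mutation matrix), and for each
network partner $p$ (edge weight $w_p \in (0,1]$) its normalized
expression $y_{p,s}$ in every mutated sample. The generative model has two
Bernoulli levels and a three-state observation layer:

* $D_g \sim \mathrm{Bern}(\pi_D)$ — the gene's mutations are functional at
  the cohort level;
* $F_{g,s} \mid D_g \sim \mathrm{Bern}(\pi_F)$ if $D_g = 1$, else
  $\mathrm{Bern}(\varepsilon)$ — the mutation in sample $s$ is functional;
* each partner's regulatory status
  $R_{p,s} \in \{\text{down}, \text{neutral}, \text{up}\}$ is non-neutral
  with probability $\alpha\, w_p$ (split equally between directions) when
  $F_{g,s} = 1$, and with the background probability $b$ otherwise;
* the observation $y_{p,s}$ is drawn from the status-specific Gaussian of
  the partner's fitted expression mixture.

Because the graph is a tree, the posteriors are computed exactly (no
sampling): partner statuses are marginalized against the mixture
densities, per-sample evidence is combined over partners in log space (no
underflow even for hundreds of partners), and $D_g$ is marginalized last.
The reported quantities are the *sample-specific dysregulation*
$\mathrm{SSD}_{g,s} = P(F_{g,s}=1 \mid \text{data})$, the
*dysregulation-across-cohort* $\mathrm{DAC}_g = P(D_g=1 \mid \text{data})$,
and the *gene regulatory status*
$\mathrm{GRS}_{p,s} = P(R_{p,s} \ne \text{neutral} \mid y_{p,s})$ under the
marginal mixture, signed negative for downregulation in the tables used
for heatmaps.

Partner observations whose copy-number call is non-neutral
($|\mathrm{GISTIC}| \ge 1$) are excluded from the evidence so that
CNA-driven cis-effects on a partner's own expression are not mistaken for
trans-dysregulation.

### Free parameters

| parameter | meaning | default |
|---|---|---|
| $\pi_D$ | cohort-level prior of functionality | 0.5 |
| $\pi_F$ | per-sample functional probability given $D=1$ | 0.8 |
| $\varepsilon$ | per-sample functional probability given $D=0$ | 0.01 |
| $\alpha$ | max partner dysregulation probability given $F=1$ | 0.9 |
| $b$ | background non-neutral probability given $F=0$ | 0.1 |

All are configurable through `dysnet_priors()`. The defaults encode an
uninformative cohort prior, a high within-sample penetrance for truly
functional mutations, and a background rate of apparent dysregulation well
below $\alpha$. The model is deliberately symmetric in direction: up- and
downregulated partners count equally, and per-partner directional
consistency across samples is not modeled.

## The expression observation model

Each partner's expression vector (log2 cpm across the cohort) is
decomposed into down/neutral/up Gaussian components by EM (quantile
initialization at the 10th/50th/90th percentiles, tolerance $10^{-8}$ on
the log-likelihood, at most 500 iterations, component sd floored at
$10^{-3}$ of the overall sd). EM is deterministic given the data — no
seeds are involved anywhere in fitting.

A free three-component fit is only meaningful when the distribution
actually is multimodal. On a unimodal gene the EM fragments the neutral
bulk into spurious tail components; every ordinary sample then looks
mildly dysregulated and the inference above loses its calibration — in
early experiments shuffled-control cohorts reached DAC near 1 through
exactly this route. The fit is therefore guarded by model selection: the
three-component solution is kept only when its BIC beats a single
Gaussian. Otherwise the status model collapses to a robust neutral
component (median location, MAD scale — a minority of genuinely shifted
samples cannot inflate the neutral spread) with canonical outlier tails at
$\pm 2$ robust standard deviations carrying 5% mass each, so that only
outlying expression counts as up- or downregulation. The offset of 2
follows the conventional two-sigma outlier boundary, one step stricter
than the $|z| > 1$ rule used to prefilter *potentially* dysregulated
genes. The same guarded fit is reused across the shuffled controls, which
never touch expression.

The expressed-gene prefilter fits a two-component mixture to the per-gene
90th percentile of expression and keeps genes whose posterior of the high
component is at least 0.8. Its EM is started from two deterministic
initializations (median split, and nearest-center assignment to the
10th/90th percentiles) and the better final likelihood is kept; the median
split alone is a known local-optimum trap when the low mode is small.

## Mutation channels

Three channels are analyzed independently and never merged:

* `cis_protein_coding` — mutations overlapping TFBSs assigned to
  protein-coding genes. Assignment prefers overlap with an annotated
  regulatory element (all linked genes, since element maps are
  multi-valued); otherwise the closest TSS wins, pooling protein-coding
  and miRNA TSSs, with deterministic tie-breaking (lowest coordinate, then
  lexicographic id). Entries additionally require the *mutated gene
  itself* to be potentially dysregulated in that sample ($|z| > 1$,
  strict), the cis footprint of a functional regulatory mutation.
* `cis_mirna` — TFBS mutations assigned to miRNA genes; every such
  mutation is kept (no z filter), both mature arms (5p/3p) are marked and
  analyzed separately against their own target networks, with weights
  equal to target-site context-score percentiles divided by 100 and
  targets supported by fewer than two predicted sites removed.
* `lof` — coding mutations whose consequence term falls in the fixed
  11-term whitelist of nonsense, frameshift and splice-site classes,
  assigned by exon overlap.

Before fitting, network weights are updated against the cohort: for every
source gene with at least two mutated and two non-mutated samples, each
partner is tested for differential expression between the groups
(two-sided Wilcoxon rank-sum, Benjamini-Hochberg within the gene's partner
set; a flag switches to global adjustment). Where any partner is
significant at 0.05 the significant partners' weights become 1 and the
rest of that gene's edges are dropped; otherwise the original edges pass
through unchanged. The per-gene adjustment scope matches the framing of
the update as a within-network question; the weight $w$ is read throughout
as the prior probability that the partner is dysregulated given a
functional mutation.

## Empirical FDR and gene selection

One hundred control runs shuffle (i) the network — per-source degree kept,
partner slots resampled uniformly without replacement, the global weight
multiset permuted over edges — and (ii) the gene labels of the mutation
matrix; expression is never shuffled, so the fitted observation model is
reused and the controls are cheap. For a candidate threshold $t$ the FDR
estimate is the mean number of null DAC values at or above $t$ per
control, divided by the observed count at or above $t$; the threshold is
the smallest observed DAC achieving FDR $\le 0.05$, floored at 0.5, and
$+\infty$ (nothing selected) when no grid value achieves the level. A gene
is selected when its DAC reaches the threshold *and* its SSD is at least
0.5 in at least two samples. Control seeds derive from the master seed by
a counter, so results are independent of execution order.

## The synthetic cohorts

The simulator generates everything the pipeline reads, in the formats it
reads (BED, TSV, chrom.sizes, YAML), deterministically from one seed. The
default configuration is the reference study condition: 60 samples, 200
protein-coding genes and 20 pre-miRNAs on two 1-Mb chromosomes, three
binding sites per gene (half covered by element-gene records, half
resolved by closest TSS), five planted drivers each mutated in eight
samples, networks of degree 20 with 70% of a driver's partners shifted by
two neutral standard deviations (directions balanced), background
mutations at $10^{-5}$ per nucleotide per sample, CNA entries non-zero at
rate 0.02, and exponential survival with log-hazard linear in one
designated miRNA arm's standardized expression.

Baseline counts are negative binomial (dispersion 0.2) with log-normal
per-gene means; 15% of genes are drawn from a lowly-expressed mode (mean
counts scaled by 0.02), reproducing the bimodal low/high structure of real
RNA-seq on which the expressed-gene filter relies — without it the filter
faces a unimodal distribution that no two-component decomposition
separates sensibly. Planted drivers are drawn from the expressed mode;
partners are drawn from all genes, so a realistic fraction of planted
signal is lost to the filter. Effects are injected on the log2 scale as
multiplicative count factors ($2^{\pm\Delta\hat\sigma_p}$), keeping
ground-truth effect sizes exact rather than re-sampling counts; the
driver's own expression is shifted likewise in its mutated samples (the
cis consequence that the $|z|>1$ prefilter expects to see — disabling
`driver_cis_shift` starves the protein-coding cis channel by design, as it
would in real data for mutations without a cis-effect).

What the simulator does *not* emulate: mutational signatures and
trinucleotide context, linked structural variants, expression batch
effects, correlated networks (edges are sampled independently), or
realistic linkage between CNA and expression. Passing tests therefore
demonstrate correctness and calibration of the procedure under the stated
generative assumptions, not performance on real tumor data.

## Numerical and design choices

* Intervals are held as `GRanges` (1-based, closed) and converted at the
  BED boundary; merging collapses book-ended intervals, matching the
  standard merge tool. An indel overlaps a region when any base of its
  reference span does; insertions occupy their one-base anchor.
* Flank sets at different widths are full flanks (the 100-nt set is a
  subset of the 500-nt set before exclusion), not annuli; both always
  exclude all TFBS and exonic bases.
* Mutation shuffles preserve chromosome, variant class and reference-span
  length, so indels never run off chromosome ends.
* "Mutated nucleotides" in rate computations are distinct mutated
  reference positions; an indel contributes the overlapping part of its
  span. The TFBS-versus-exon comparison uses a paired two-tailed Wilcoxon
  signed-rank across samples, since the rates are per-sample measurements
  in matched region sets.
* z-values use the sample (n-1) standard deviation and are computed on
  log2 cpm, the matrix used everywhere else; features with zero variance
  have undefined z and are never flagged.
* Median-split survival dichotomization sends ties to the low group.
* The hypergeometric enrichment tail and the log-rank test delegate to
  `stats::phyper` and `survival::survdiff`; Benjamini-Hochberg adjustment
  delegates to `stats::p.adjust`.

## Problem sizes

The bundled tests and the acceptance script run entirely on simulated
cohorts at the reference condition (60 samples, 200 genes, 100 shuffled
controls per run); a full end-to-end run takes a few seconds on one core
because the observation model is fitted once and shared across controls.
Driver recovery is evaluated over ten seeds and null calibration over
twenty; the mutation-rate null uses the full 150 shuffles.

## Limitations

The model treats partners as conditionally independent given the sample's
functional status; co-regulated partners therefore contribute
pseudo-replicated evidence. Direction consistency across samples is not
rewarded. The canonical-tail observation model trades sensitivity to
shifts smaller than about one robust standard deviation for calibration
on null genes. The empirical FDR inherits the usual granularity of
100 controls, and the DAC floor of 0.5 makes selection conservative in
cohorts with few mutated genes. The cis-analysis mode of the original
dysregulation tool (mutation effects on the gene's own expression as the
evidence) and empirical-Bayes learning of the priors are out of scope.
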