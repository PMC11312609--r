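---
title: "Models and methods behind riboshift"
author: "riboshift maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`riboshift` analyses TRAP-seq (translating ribosome affinity purification)
studies of the arterial endothelium under low and disturbed flow (LDF).
The experimental design it models has three crossed factors: the mRNA
**fraction** (total intimal mRNA from a Trizol flush, ribosome-bound mRNA
from the GFP-L10a pulldown, and the unbound flow-through), the
**condition** (the ligated low-flow artery vs the contralateral
normal-flow artery of the same animal) and the **genotype** (wild type vs
an endothelial-specific knockout of an RNA-binding protein such as
Elavl1/HuR).

The package implements six analysis stages, each validated against a
seeded synthetic-data generator that plants every effect it is later
asked to recover:

1. TpM quantification and fraction-purity QC by marker depletion;
2. negative-binomial Wald differential expression;
3. the ribosome-vs-total *delta* statistic that ranks translational
   shifts;
4. an LFC-thresholded concordance analysis of the knockout response
   against the flow response;
5. PSI estimation for skipped exons with a beta-binomial delta-PSI test;
6. 6-mer RBP motif enrichment in exon flanks against an
   expression-matched background, plus hypergeometric
   over-representation analysis.

# The synthetic-data generator

The generator is first-class, tested code: its defaults *are* the study
conditions every validation result refers to. Counts for gene $g$ in
sample $j$ are negative binomial with

$$\mu_{gj} = s_j\left[(1-c_{f(j)})\, q_g\, 2^{\sum_k \beta_{gk} x_{jk}}
 + c_{f(j)}\, m_g\right], \qquad
\operatorname{Var} = \mu + \alpha \mu^2,$$

where $s_j$ is a log-normal size factor (sd(log) 0.15), $q_g$ a
log-uniform baseline mean (20–2000 by default), $\alpha = 0.1$ a shared
dispersion ($\alpha = 0$ gives the Poisson limit), $c_f$ a
fraction-specific contaminant admixture (10% into the total flush, 1%
into the pulldown — the two-stage purification the protocol aims for) and
$m_g$ a contaminant profile concentrated on mural/myeloid markers (Smtn,
Cd68, Adgre1). Contamination is mixed at the mean level, which is
sufficient to exercise the depletion QC. Five animals per arm are
simulated by default (the deposited design varies between 4 and 6 per
assay; both are reachable through `repsPerArm`).

Planted effects come in blocks: 100 genes with a transcriptional LDF
response in both fractions (+1 log2), 100 with −1, and 50
"translational-shift" genes that respond only in the ribosomal fraction —
the signal the delta statistic exists to find. The knockout effect is
confined to the ribosomal fraction and planted with a concordance
structure: 80% of ribosome-up responders gain a further +1 under the
knockout and 86% of down responders a further −1, mirroring the kind of
directional reinforcement the concordance stage quantifies. An
Icam2-like endothelial transcript is planted 2.4-fold higher in the
pulldown than in the flow-through as a positive binding control.

## Splicing arm

Cassette exons are laid out on a synthetic uniform-i.i.d. DNA chromosome
with introns wide enough to host the 200-bp flank window. For sample $j$
the cluster junction coverage is $T \sim \mathrm{NB}(100, \alpha)$ reads.
An included isoform carries **two** inclusion junctions where a skipped
isoform carries one, so at inclusion level $\psi$ the read-level fraction
of inclusion-supporting reads is $2\psi/(1+\psi)$. The generator draws
inclusion reads beta-binomially out of $T$ at that fraction
(overdispersion $\rho = 0.05$), splits them fairly between the two
inclusion junctions, and assigns the rest to the exclusion junction. This
read-level construction makes the standard SE-event estimator

$$\hat\psi = \frac{(i_1+i_2)/2}{(i_1+i_2)/2 + e}$$

consistent — a simpler "draw inclusion reads at fraction $\psi$" scheme
would make $\hat\psi$ converge to $\psi/(2-\psi)$ instead, i.e. a planted
$\psi = 0.5$ would be "recovered" as 1/3. One consequence worth knowing:
cluster coverage $T$ maps to roughly $0.7\,T$ effective binomial trials
for the inclusion/exclusion decision.

Sixty of 400 events receive a planted $\Delta\psi = \pm 0.4$ under LDF
(the magnitude of the Irf2-like exon-inclusion change the analysis should
detect), and the flanks of regulated exons receive an AU-rich 6-mer
(TTTATT) with probability 0.6 per flank, inserted in transcript
orientation at a uniform offset; every insertion is recorded in the truth
tables. Because the genome is uniform i.i.d. DNA, the background
frequency of any 6-mer is analytically $4^{-6}$, which makes
motif-enrichment power predictable.

What the generator deliberately does *not* emulate: read-level artifacts
(FASTQ, positional or GC bias), isoform-level expression, gene-gene
correlation, outlier samples, or gene-specific dispersions. Passing
parameter-recovery tests on these data therefore demonstrates the
correctness of the estimators under their stated model, not robustness to
every pathology of real libraries.

# Differential expression

Normalization is DESeq-style median-of-ratios, rescaled to geometric mean
one and used as GLM offsets. Per gene, the dispersion is estimated by
method of moments on normalized counts pooled within condition levels,
floored at $10^{-8}$, and shrunk 50/50 toward a fitted mean-dispersion
trend $\alpha(m) = a_0 + a_1/m$ (coefficients clamped non-negative). The
two-group NB GLM with log link is solved by Fisher scoring — for a
saturated two-group design this reduces to one Newton iteration per
group-level mean — and the Wald statistic is
$z = \hat\beta / \mathrm{se}(\hat\beta)$ with
$p = 2\Phi(-|z|)$ and Benjamini–Hochberg adjustment. Raw MLE fold
changes are reported; no shrinkage is applied anywhere, because the
downstream thresholds (±0.5 log2) are applied to reported LFCs and should
mean what they say.

Numerical choices: genes with all-zero counts in one level get a
0.5-count continuity correction and a `zero_level` flag rather than an
infinite LFC; non-converged fits (100 iterations) are flagged with
`p = NA` and excluded from the BH denominator; the optional TpM floor
excludes genes *before* testing and before BH.

A measurement that shaped the defaults: with a heavily one-sided design
(25% of genes all shifted up), median-of-ratios itself — not the
estimator — is biased by about −0.25 log2, because the within-sample
count median no longer tracks the null genes symmetrically. The
generator therefore plants balanced up/down response blocks, as the
biology it emulates does.

# The delta statistic and concordance

For a common condition comparison run separately in the two fractions,
`riboTotalDelta` computes $\delta = \beta_{\text{ribo}} -
\beta_{\text{total}}$ with $\mathrm{se}_\delta = \sqrt{\mathrm{se}_r^2 +
\mathrm{se}_t^2}$. The two contrasts involve different animals, so
treating them as independent is the honest default. The TpM ≥ 100 floor
is applied to this ranking (top-300 lists) and only here, matching the
analysis it reproduces; ranking ties break lexicographically by gene id
so results are reproducible.

`concordanceShift` selects flow-responsive genes in the wild-type TRAP
contrast, splits them by direction, and asks what fraction moves further
in the same direction under the knockout, using a ±0.5 log2 threshold on
the knockout LFC. Genes between the thresholds stay in the denominators
but in neither concordant class, and are excluded from the 2×2 Fisher
test. Two selector knobs matter: the significance column (`p` vs `padj`)
and an optional p filter on the knockout contrast. With unadjusted
p < 0.05 on a 2000-gene universe, roughly 50 null false positives enter
the responsive set and dilute a planted 80% concordance to about 60%;
the package's validation therefore selects on `padj`, and both options
are exposed.

# Splicing

Junctions sharing a splice-site coordinate (same chromosome and strand,
transitively) form clusters; clusters with fewer than 50 split reads
summed over all junctions and samples are removed, as are singleton
junctions. Per-sample PSI uses the symmetric estimator above with a
coverage floor of 10 (below which 0/0-type estimates are meaningless).

The delta-PSI test models per-sample inclusion successes
$k = \mathrm{round}((i_1+i_2)/2)$ out of $n = k + e$ trials as
beta-binomial with group mean $\psi$ and shared overdispersion $\rho$.
The shared $\rho$ is maximized once under the null (numerically on (0,1),
with a binomial fallback at the $\rho = 0$ boundary) and held fixed in
both profile fits; the likelihood ratio of group-specific vs common
$\psi$ is referred to $\chi^2_1$. This nuisance-under-the-null
construction is what keeps the small-sample test calibrated: re-maximizing
$\rho$ under both hypotheses measured a type-I error near 0.10 at the
design point ($\psi = 0.5$, $\rho = 0.05$, $T \approx 100$, 6 vs 6),
versus ≈ 0.06 for the implemented test. Reported group PSIs (and hence
$\Delta\psi$) are the pooled per-group estimates, which stay unbiased
under the alternative where the null-estimated $\rho$ is inflated; the
test statistic and the reported effect size are deliberately decoupled.
Both unadjusted p (the headline-count convention) and BH-adjusted
columns are emitted.

# Motif enrichment

Flanks are the 200 bp immediately up- and downstream of the cassette
exon in transcript orientation (minus-strand flanks are
reverse-complemented and swap roles), clipped at contig bounds and *not*
clipped at the neighbouring exons (a `--clip`-style option can be built
from the event coordinates if wanted). All 4096 6-mers are counted over
overlapping windows; windows containing N are excluded from both counts
and the scanned-position totals, so occurrences always sum to positions.

The background is the point of the design: candidate exons are unregulated
events "detected at a similar level", operationalized as mean
junction-cluster coverage, the detectability axis available before any
sequence is read. Regulated events are cut into coverage-quantile bins
and up to 3× each bin's count is sampled (seeded) from candidates in the
same bin; candidates outside the foreground's coverage range are never
used.

Each 6-mer gets a position-level 2×2 table (occurrences vs scanned
positions, foreground vs background) and a two-sided Fisher exact test;
a per-event presence/absence mode exists for users who prefer it.
Up- and downstream regions are tested separately by default with BH
spanning all 8192 tests. Because the exact statistic behind published
"relative enrichment" axes varies, the table carries the odds ratio
(Haldane-corrected when a cell is zero), a log2 rate ratio, a two-
proportion z-score and −log10 p side by side. The two-sided Fisher p is
computed by a vectorized conditional-hypergeometric routine (the same
relative-error tie rule as `stats::fisher.test`, which it is tested
against); per-RBP aggregation scores each motif set by its best BH q,
with mean −log10 p as tiebreaker and alphabetical order as the final,
deterministic tie-break.

# Problem sizes and validation design

The shipped validation suite runs entirely on generated data at sizes a
laptop handles in seconds: 2000 genes × 6 vs 6 replicates for DE
calibration and recovery, 1000 events for delta-PSI calibration, 300 for
recovery, 25 + 75 events × 20 seeded repetitions for motif recovery, and
the full 2000-gene/400-event walkthrough twice for byte-identical
determinism. Delta-ranking recovery is simulated with baseline means of
500–2000 so that every planted gene clears the TpM ≥ 100 floor the
ranking applies — planting signal below the detection floor would
measure censoring, not ranking. Calibration bands (e.g. type-I error in
[0.03, 0.07] at nominal 0.05 over 2000 genes) are Monte-Carlo intervals,
not exact identities.

# Known limitations

* Dispersion is method-of-moments with a parametric trend; no
  empirical-Bayes per-gene posterior, no outlier refitting
  (Cook's-style), no independent-filtering optimization.
* Contrasts are two-group within strata; interaction effects are handled
  by the delta statistic, not a multi-factor GLM.
* The splicing model covers skipped exons only; alternative 5'/3' sites,
  retained introns and per-intron effects within multi-intron clusters
  are out of scope.
* The delta-PSI $\chi^2_1$ reference is asymptotic; at very low coverage
  or 2-3 samples per group it drifts conservative/anticonservative, and
  the coverage floor exists partly to keep it in its working range.
* Motif enrichment treats 6-mers independently; overlapping k-mers of a
  true motif co-enrich, which the per-RBP aggregation absorbs but the
  per-k-mer table does not model.
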