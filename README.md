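# riboshift

Translatome analysis of TRAP-seq experiments in flow-perturbed
endothelium: who is translating what, and which of it is controlled at
the ribosome rather than at the transcript level.

## The problem

Partial carotid ligation exposes one artery to low and disturbed flow
(LDF) while the contralateral artery keeps normal flow. Translating
ribosome affinity purification (TRAP) from the endothelium yields three
mRNA fractions per artery — total intimal mRNA, ribosome-bound mRNA, and
the unbound flow-through — and, with an endothelial-specific knockout
(ECKO) of an RNA-binding protein such as Elavl1/HuR, a 2 × 2 × 2 design:
fraction × condition × genotype. `riboshift` provides the complete
analysis chain for such data:

* **Purity QC** — TpM quantification and marker-panel depletion checks
  (mural/myeloid markers should vanish from the pulldown; endothelial
  transcripts should not).
* **Differential expression** — a two-group negative-binomial Wald test
  with median-of-ratios offsets and method-of-moments dispersion shrunk
  toward a mean-dispersion trend:
  `z = β̂ / se(β̂)`, `p = 2Φ(−|z|)`, BH-adjusted.
* **Translational shift ranking** — the delta statistic
  `δ = β_ribo − β_total`, `se_δ = √(se_r² + se_t²)`, ranking genes whose
  ribosome association responds to flow more than their transcript level
  does (top-N lists with a TpM ≥ 100 floor).
* **Concordance analysis** — among flow-responsive genes in wild-type
  TRAP, the fraction pushed further in the same direction by the
  knockout (|log2FC| > 0.5 threshold, Fisher exact association).
* **Splicing** — intron clustering with a 50-split-read filter, skipped
  exon PSI `ψ̂ = ((i1+i2)/2) / ((i1+i2)/2 + e)`, and a beta-binomial
  likelihood-ratio ΔPSI test with the shared overdispersion estimated
  under the null.
* **Motif enrichment** — exhaustive 6-mer Fisher tests in the 200 bp
  flanks of regulated skipped exons against coverage-matched unregulated
  exons, aggregated to RNA-binding proteins.
* **A seeded synthetic-data generator** with machine-readable truth for
  every planted effect, so each stage is validated by parameter
  recovery.

## A worked example

```r
library(riboshift)

cfg <- simulationConfig(seed = 42)      # the default synthetic design
sim <- simulateCounts(cfg)

deRibo <- fitNBWald(sim$experiment,
    contrastSpec("condition", "LDF", "contralateral",
                 list(fraction = "ribosomal", genotype = "WT")))
deRibo
#> DEResult: condition LDF vs contralateral [fraction=ribosomal, genotype=WT]
#> 2004 genes; 172 with padj < 0.05
```

The generator planted a +1 log2 flow response in genes 0001–0100 (both
fractions) and 0201–0250 (ribosomal fraction only); the test recovers
them — e.g. gene0004 at log2FC 1.67 (padj 7e-8) — while the contamination
markers Smtn/Cd68/Adgre1 stay flat.

```r
deTotal <- fitNBWald(sim$experiment,
    contrastSpec("condition", "LDF", "contralateral",
                 list(fraction = "total", genotype = "WT")))
dl <- riboTotalDelta(deRibo, deTotal, minMeanTpm = 100)
head(as.data.frame(dl)[order(dl$rank),
     c("gene_id", "lfc_ribo", "lfc_total", "delta", "z", "padj")], 4)
#>           gene_id lfc_ribo  lfc_total    delta        z         padj
#> gene0237 gene0237 1.593780 -0.4382785 2.032058 5.032550 0.0003365240
#> gene0239 gene0239 1.461333 -0.5445051 2.005838 4.869661 0.0003658324
#> gene0226 gene0226 1.463667 -0.4820661 1.945733 4.942504 0.0003365240
#> gene0215 gene0215 1.438118 -0.4890125 1.927131 4.998395 0.0003365240
```

Every gene at the top of the delta ranking is a planted
translational-shift gene (the 02xx block: ribosomal response without a
total-mRNA response). The knockout concordance stage then asks whether
the flow response is reinforced by loss of the RNA-binding protein:

```r
deEcko <- fitNBWald(sim$experiment,
    contrastSpec("genotype", "ECKO", "WT",
                 list(fraction = "ribosomal", condition = "LDF")))
cc <- concordanceShift(deRibo, deEcko, useAdjusted = TRUE)
round(c(up = cc$frac_up_further_up, down = cc$frac_down_further_down), 3)
#>    up  down
#> 0.743 0.690
signif(cc$fisher_p, 3)
#> [1] 7.6e-13
```

74% of flow-up genes are pushed further up by the knockout and 69% of
flow-down genes further down (the generator planted 80%/86%, estimated
through 5-animal arms), with an unambiguous Fisher association.

The splicing and motif stages work the same way from
`simulateSplicing()` / `computePsi()` / `dpsiTest()` /
`extractFlanks()` / `kmerEnrichment()`, and `runAll(pipelineConfig(...))`
executes the whole walkthrough into a directory with a manifest of
checksums; reruns with the same seed are byte-identical.

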