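# capFL

Evaluation toolkit for full-length transcript capture in long-read cDNA
libraries (PacBio Iso-Seq style), written for the question: *does a
cap-dependent library chemistry actually enrich for reads that start at
genuine transcription start sites, compared to cap-blind template
switching?*

Long-read cDNA libraries contain 5'-truncated molecules from RNA
degradation, shearing and incomplete cDNA synthesis. Template-switch
chemistry (SMARTer-style) sequences them all; cap-dependent linker ligation
(TeloPrime-style) amplifies only molecules still carrying a 5' cap. capFL
measures the consequences from spliced alignments (PAF) against a GFF3
annotation:

* **Full-length classification** — a read is FL when
  `read_length >= spliced_length(target)`, with the target chosen by
  maximal same-strand exonic overlap after an inclusive `identity >= 0.90`
  filter and per-read multiplicity partitioning
  (unique / multi / filtered / unaligned).
* **End-offset profiling** — signed distances of the read's 5'/3' alignment
  ends to the annotated TSS/TES (negative = upstream), histogrammed within
  ±10 kb, and compared between two libraries per size fraction
  (1–2 / 2–3 / 3–6 kb) with a Mann-Whitney test:
  `U = min(U_a, U_b)` with ties counted ½, exact two-sided p by full
  enumeration of all `C(n+m, n)` labelings when feasible, otherwise the
  tie-corrected normal approximation with continuity correction.
* **Redundancy estimation** — single-linkage clustering of same-locus reads
  whose 5'/3' ends agree within 100 / 5 bp (inclusive);
  redundancy = `100 · (n_reads − n_clusters) / n_reads`.
* **Homeolog resolution** — reads hitting ≥ 2 members of a declared
  homeolog group are re-examined; the record minimizing
  `d = read_length − alignment_length` wins, exact ties stay ambiguous.
* **Isoform classes** — intron-chain comparison against the annotation:
  `known`, `novel_isoform` (with a `contained` flag for truncated
  sub-chains), `novel_locus`, `mono_exon_contained`, `other`.
* **A seeded simulator** of both chemistries over a toy multi-exon
  annotation (including ~97%-identical homeolog triplets) with per-read
  ground truth; fixed seed ⇒ byte-identical outputs.

## Worked example

```r
library(capFL)

cfg <- simConfig(n_genes = 20, n_reads_per_protocol = 500, seed = 42)
sim <- simulateExperiment(cfg)
asg <- lapply(sim$libraries, function(l)
  classifyReads(l$alignments, sim$annotation, manifest = l$truth$read_id))
compareProtocols(asg$cap_dependent, asg$template_switch)
```

```
Protocol comparison: cap_dependent vs template_switch
  overall FL%: 60.26 vs 26.37
   anchor size_fraction n_a n_b median_a median_b       U   p_value
1     TSS         sub1k   1  54   8129.0   8172.5    25.0 9.455e-01
2     TSS         1-2kb 137 125      0.0   2241.0  3480.5 6.100e-24
3     TSS         2-3kb   2  58      0.0   7591.5     1.0 2.825e-03
4     TSS         3-6kb 316 212      0.0      0.0 22480.0 1.233e-26
...
```

Reading it: 60% of cap-dependent reads are full length against 26% under
template switching; in the populated fractions the cap-dependent 5' offsets
sit at 0 (reads begin at the annotated TSS) while template-switch medians
are kilobases downstream, and the per-fraction Mann-Whitney p-values are
vanishingly small. TES rows (not shown) are null — both simulated
chemistries share the same oligo-dT 3' priming, so only the 5' end carries
signal.

```r
cl <- clusterEnds(asg$cap_dependent)
redundancyFraction(cl)
#> [1] 91.87817
```

On this deliberately tiny annotation (20 genes, 500 reads) most capped
reads start at the same base of the same few genes, so end-clustering
redundancy is high; at transcriptome scale the same statistic is a
sub-percent quantity.

An end-to-end run (`runPipeline()`) writes per-stage TSVs plus a
`summary.json`, either from a simulator config or from your own
GFF3 + PAF + homeolog files; `inst/scripts/capfl.R` wraps it for the shell.

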