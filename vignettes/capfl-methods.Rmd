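---
title: "Evaluating full-length transcript capture in long-read cDNA libraries"
author: "capFL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating full-length transcript capture in long-read cDNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capFL)
```

## The problem

Long-read cDNA sequencing (PacBio Iso-Seq and similar) reads a whole cDNA
molecule end to end, so in principle each read reports a complete
transcript, including its transcription start site (TSS) and end site (TES).
In practice a substantial fraction of the mRNA pool is 5'-truncated —
degraded, sheared, or incompletely reverse-transcribed — and a truncated
molecule still yields a perfectly good-looking read. The library chemistry
decides how much of that material ends up sequenced:

* **Template switching** (SMARTer-style): the reverse transcriptase adds an
  adapter at whatever 5' terminus it reaches. The chemistry is cap-blind; it
  sequences truncated and intact molecules alike, and its own incomplete
  first-strand synthesis adds further 5' loss.
* **Cap-dependent linker ligation** (TeloPrime-style): an adapter is ligated
  only to molecules still carrying the 5' cap, so amplification is
  restricted to 5'-intact mRNA, with a small leakage of uncapped material.

capFL quantifies the difference from spliced read alignments against an
annotation: full-length (FL) classification, signed end-offset profiles
around annotated TSS/TES, per-size-fraction rank tests between two
libraries, redundancy estimation, homeolog-aware multi-mapping resolution
for polyploids, and intron-chain isoform classes. A seeded simulator of both
chemistries provides libraries with per-read ground truth; every claim the
package makes is validated against that truth or against independent
brute-force oracles in the test suite.

## Read classification model

Reads enter as PAF alignment records (`readPAF()`); the annotation as
gene/mRNA/exon GFF3 (`readGFF3Genes()`). All internal coordinates are
1-based closed, the native convention of the GenomicRanges containers the
package is built on; PAF's 0-based half-open coordinates are converted on
read and write.

1. **Identity filter.** Nucleotide identity is residue matches divided by
   alignment block length (PAF columns 10/11). Records with identity `>=`
   0.90 are kept; the boundary is inclusive, so a record at exactly 0.90
   passes.
2. **Multiplicity.** After filtering, a read with one surviving record is
   *unique*; with several, *multi* (excluded from FL and offset analysis,
   but examined by the homeolog stage); a read whose records all fell to the
   filter is *filtered*; a manifest read with no alignment is *unaligned*.
   Multiplicity is counted per read, not per alignment path.
3. **Target assignment.** Candidate targets are same-chromosome,
   same-strand transcript models whose exons overlap the read's aligned
   blocks; the candidate maximizing exonic overlap in bases wins. Ties go to
   the lexicographically smaller gene id and are flagged, so the choice is
   deterministic and auditable. Antisense overlap is not assignment: Iso-Seq
   reads are orientation-resolved by primer classification, and a read on
   the wrong strand is reported unassigned rather than silently attached. A
   read overlapping only introns of a model has zero exonic overlap and is
   likewise unassigned.
4. **Offsets and the FL flag.** The 5' offset is the signed distance from
   the read's transcript-orientation 5' alignment end to the annotated TSS
   (negative upstream, positive downstream, i.e. truncated); the 3' offset
   is the analogue at the TES with positive downstream. Offsets are measured
   from alignment ends, not clipped read ends. A read is **full length when
   its length is at least the spliced (mRNA) length of its target**. The
   comparison uses spliced length, not genomic span: cDNA reads are spliced,
   and a genomic-span criterion would make FL unreachable for any
   intron-containing gene. The boundary is inclusive ("equal or larger").
   When a gene has several annotated mRNAs the comparison uses the assigned
   mRNA (the overlap maximizer), not a per-locus aggregate.
5. **Size fractions.** Read lengths are binned as in gel fractionation:
   `[1000, 2000)`, `[2000, 3000)`, `[3000, 6000]`, with `sub1k` and `over6k`
   catching the tails. Boundaries are half-open low-inclusive; no convention
   is universal here, this one is simply fixed and tested.

## Protocol comparison statistics

For each size fraction and each anchor (5' offsets, 3' offsets) the two
libraries are compared with a Mann-Whitney test (`mannWhitney()`). The
statistic is `U = min(U_a, U_b)` with ties counted one half. The two-sided
exact p-value is the permutation probability of an equally or more extreme
`U`, computed by full enumeration of all `choose(n + m, n)` labelings
whenever that count is at most `1e5`; the test suite checks this path
against an independent pair-counting oracle. For larger tie-free samples the
same exact null distribution is evaluated through `stats::pwilcox()`; with
ties at large sizes, and in `auto` mode, the tie-corrected normal
approximation with a 0.5 continuity correction is used (exact and normal
agree within 0.02 at `n = m = 30` on continuous data, a property the suite
asserts). Tests are two-sided; no multiple-testing correction is applied
across the fraction-by-anchor table by default (a Bonferroni column is
available via `bonferroni = TRUE`), because the table is a small, fixed
panel read as a whole, and the interesting p-values are many orders of
magnitude below any reasonable threshold.

Under the simulator's generative model the 3' chemistry (oligo-dT priming
with small jitter) is identical in both protocols, so TES tests are expected
to be null there; only the 5' contrast carries signal. Real libraries can
show 3' differences too (e.g. if surveillance pathways couple decapping to
3' degradation), which is exactly the kind of biology the simulator does not
encode — a null TES test on simulated data validates the machinery, not the
absence of 3' biology.

## Redundancy clustering

Residual redundancy (reads that are repeated observations of one molecule)
is estimated by end-tolerant clustering (`clusterEnds()`): within a locus
group, reads whose transcript-oriented 5' ends agree within 100 bp and 3'
ends within 5 bp (both inclusive — "allowing 100 bp" includes 100) are
linked, and clusters are the connected components of that graph, i.e.
single linkage. Ends are compared in transcript orientation so minus-strand
loci behave identically. Two consequences are documented rather than hidden:
chaining can produce clusters wider than one tolerance span end to end, so
the redundancy estimate `100 * (n_reads - n_clusters) / n_reads` is an upper
bound at the given tolerances; and the component definition makes the result
independent of input order, which the suite verifies along with equivalence
to a brute-force pairwise-graph oracle and monotonicity in both tolerances.
Assigned reads group by (gene, strand); unassigned unique reads are grouped
by genomic overlap on (chromosome, strand) first.

On the simulator's tiny annotation the absolute redundancy numbers are
large by construction — hundreds of reads share a few dozen genes, and
capped molecules all start at the same base — so they exercise the
machinery, not the sub-percent redundancy expected of a real
transcriptome-scale run.

## Homeolog resolution

In a polyploid, homeologous gene copies are so similar that a read from one
subgenome also aligns to its sisters. `flagHomeologHits()` marks reads
hitting two or more members of one declared homeolog group (reads hitting
members of different groups are ordinary multi-mappers). Resolution
(`resolveBestMatch()`) applies the identity filter, then keeps the record
minimizing `d = read length - alignment length` — the bases of the read the
locus failed to align. Exactly one minimizer resolves the read; an exact tie
is reported ambiguous, never guessed. `d` uses the read-side alignment
length by default because unaligned read bases are what sequence divergence
at the wrong locus costs; a target-side variant (summed genomic block
widths) is available via `lengthSide = "target"`. Resolved reads are
reported but not, by default, promoted back into the unique set — the main
FL/offset analysis keeps discarding multi-mappers, and resolution is
evaluated on its own.

## Isoform classes

`classifyIsoforms()` compares each unique read's intron chain (the gaps
between its aligned blocks) with the chains of the same-strand transcripts
it overlaps: exact chain equality is `known`; at least one shared junction
with a differing chain is `novel_isoform` (a contiguous sub-chain — the
signature of a 5'-truncated read — stays `novel_isoform` but is flagged
`contained`, matching strict "=" semantics); exonic overlap with no shared
junction is `other`; no exonic overlap is `novel_locus`; a single-block read
inside one annotated exon is `mono_exon_contained`. Junction coordinates
must match exactly by default; a `fuzz` parameter exists because long-read
aligners wobble at junctions, but it is 0 unless the user opts in. The five
classes are exhaustive and mutually exclusive, and the classifier is frozen
against a 32-case hand-enumerated truth table in the package.

## The simulator

`simulateExperiment()` generates the study conditions end to end; all
randomness derives from `seed`, and a fixed configuration reproduces
byte-identical GFF3/PAF/TSV outputs. Defaults (see `?SimConfig-class`):

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `exons_per_gene` | 60, 2–9 | toy annotation on two base chromosomes, both strands |
| `spliced_length_range` | 800–6500 bp | spans the 1–2 / 2–3 / 3–6 kb size fractions |
| `p_truncated` | 0.4 | share of pool molecules 5'-truncated (hence uncapped) |
| `truncation_extent` | U(0, 0.8] | fraction of 5' length a truncated molecule loses |
| `cap_capture` / `cap_leakage` | 0.95 / 0.02 | cap-dependent capture of capped / uncapped molecules |
| `p_incomplete_synthesis` | 0.3 | extra 5' loss probability under template switching |
| `three_prime_jitter_sd` (cap 10 bp) | 2 | symmetric oligo-dT end jitter around the TES |
| `n_reads_per_protocol` | 1000 | library size; both libraries draw from one shared pool |
| `homeolog_identity`, `n_homeolog_triplets` | 0.97, 5 | triplet copies on sister chromosomes |
| `p_homeolog_multi` | 0.25 | share of homeolog-derived reads with secondary hits |

Choices worth recording:

* **`p_truncated = 0.4`.** Chosen once as a realistic mid-range degradation
  level for total-RNA preparations: high enough that the chemistry contrast
  and the truncation-recovery checks have power at a thousand reads, low
  enough that both libraries keep all size fractions populated. It is a test
  condition, not an estimate of any particular tissue.
* **Truncation is transcript-coordinate.** A 5' loss removes spliced
  sequence; the emitted alignment's genomic start is recomputed by walking
  the exon chain, so a degraded read aligns downstream of the TSS across
  introns, as real degraded cDNA does. Consequently the genomic 5' offset
  equals the truncated bases only while the loss stays within the first
  exon — the offset histograms look like alignment coordinates, not like
  molecule bookkeeping.
* **3' jitter** is symmetric, rounded Gaussian, capped at 10 bp: small
  enough to respect the poly-A boundary, large enough to exercise the 5 bp
  3' clustering tolerance from both sides. Negative jitter shortens the
  read; positive jitter extends the terminal block past the annotated TES.
* **Homeolog secondaries.** A configurable share of reads from homeolog
  group members emits secondary alignments at the sister loci with the
  alignment length reduced by `(1 - homeolog_identity) * read_length` and
  identity set to `homeolog_identity` — the same signal, in kind, that a
  real aligner produces at a 97%-identical sister locus. The true locus
  therefore always has strictly minimal `d`, which is why the resolution
  accuracy check demands 100%.
* **Sequencing error is off by default** (identity 1.0): the 90% filter's
  boundary behaviour is tested explicitly with constructed records, not
  through noise. An `error_rate` slot exists for degraded-identity
  scenarios.
* **No base-level sequences** are emitted; alignments are generated
  directly. Aligner-specific artefacts (junction wobble, clipping,
  chimeras), poly-A tails, and expression-dependent degradation are outside
  the generative model, so passing tests demonstrate correctness of the
  evaluation machinery under the stated model — not robustness to every
  artefact of real data.

## Numerical and degenerate-input conventions

* Thresholds at stated boundaries are inclusive: identity 0.90 passes,
  `read_length == spliced_length` is FL, end differences of exactly 100/5 bp
  cluster.
* Offset histograms use half-open bins with an edge exactly at the anchor;
  the ±10 kb window applies to the histogram, while summary fractions and
  the rank tests use all offsets of assigned unique reads.
* Empty inputs: empty alignment sets filter to empty; a size fraction
  missing in one library yields an `NA` test row plus a warning rather than
  an error; an empty cluster set refuses to report a redundancy percentage.
* Ties are never broken by randomness: gene-assignment ties go to the
  lexicographically smaller id and are flagged; equal-`d` homeolog
  candidates stay ambiguous.
* The pipeline writes deterministic orderings everywhere, so identical
  config and seed give byte-identical run directories.

## Validation problem sizes

The shipped checks run the simulator at 1000 reads per protocol for the
chemistry contrast, 2000 reads per truncation level (0.1/0.3/0.5) for the
recovery check, 200 random instances each for the Mann-Whitney and
clustering oracle batteries (samples up to 7 + 7; up to 50 reads per
clustering instance), and roughly 900 multi-homeolog reads for the
resolution check. These sizes were chosen so the whole validation completes
in a few minutes on one core while keeping binomial errors of the stochastic
checks within the asserted three-standard-error bands.

## Known limitations

* FL classification is annotation-relative: an unannotated longer isoform
  makes genuinely full-length reads look extended, truncated annotations
  make degraded reads look full length. The offset profiles are the tool for
  spotting both.
* The redundancy estimate is tolerance- and linkage-dependent (see above);
  compare numbers only at identical settings.
* Intron-only overlap and antisense overlap both classify as unassigned
  (and `novel_locus` in the isoform table); a dedicated antisense/intronic
  category would require orientation-confidence input the PAF does not
  carry.
* The homeolog stage resolves reads against declared groups only; it does
  not discover homeology from sequence.
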