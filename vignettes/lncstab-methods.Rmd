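---
title: "Methods: detecting selective lncRNA stabilization after nuclear poly(A)-binding protein depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting selective lncRNA stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncstab)
```

## The analysis

PABPN1 is the nuclear poly(A)-binding protein. Depleting it from human
cells leaves most protein-coding mRNA levels untouched but selectively
raises the steady-state levels of a minority of long noncoding RNAs
(lncRNAs), through a polyadenylation-dependent decay pathway. `lncstab`
re-implements the computational side of that observation as a reusable,
tested pipeline: given gene annotations and a two-condition (control vs
depleted) RNA-seq experiment, it quantifies each gene, calls fold
changes, and asks three questions:

1. Is the lncRNA fold-change distribution right-skewed relative to the
   coding one (excess of upregulated lncRNAs)?
2. Do the upregulated lncRNAs cluster immediately upstream of coding-gene
   transcription start sites (TSSs), mostly in the antisense orientation?
3. Are the associated quantitative conventions — proximal/distal poly(A)
   usage, decay half-lives, qPCR/ChIP/RNA-IP enrichments — reproduced?

## Catalog construction

Gene sets are compiled from multiple annotation sources (GTF, BED6/12 via
`load_annotations()`), with ids source-prefixed to avoid collisions. All
coordinates are converted to a 0-based half-open convention at the I/O
boundary, which keeps length arithmetic unambiguous (`end - start` is the
length in nucleotides).

Redundancy removal (`deduplicate()`) drops any gene whose span is
completely contained within another retained gene's span. Containment is
span-based and strand-agnostic — the source definition speaks only of
genes "contained within another gene", and annotation databases mix
strand conventions enough that strand-aware containment would retain
near-duplicates. Identical spans tie-break by removing the
lexicographically larger id, making the operation deterministic and
idempotent.

The lncRNA set (`build_lncrna_set()`) unions the source catalogs,
deduplicates across sources, and keeps genes with *spliced*
(exonic-union) length strictly greater than 200 nt. Applying the cutoff
to the spliced rather than genomic length follows the standard definition
of a lncRNA as a *transcript* longer than 200 nucleotides; strict
inequality follows the ">200 nt" phrasing.

Each gene's counting territory is its *maximal genomic locus*
(`build_maximal_locus()`): the span covering all known isoforms together
with the exonic union. Genes on unplaced contigs are retained; filtering
is the caller's concern.

## Quantification

A fragment is counted for a gene when its outer span lies within the
maximal locus and at least one aligned block overlaps the exonic union by
one or more nucleotides (`count_exonic_fragments()`). Paired-end mates
are treated as one fragment: counting fragments instead of reads only
rescales the library size, to which RPKM *ratios* are invariant.
Fragments overlapping two genes' unions count once per gene; no
disambiguation scheme is imposed because none is defined by the source
analysis.

Expression is RPKM — `count / (exonic_length/1000) / (library_size/1e6)` —
with the exonic-union length standing in for the "mappable region"
(exact on synthetic data; no mappability track is modelled). Genes with
RPKM strictly above 1 in at least one sample pass the expression filter.
Fold changes are `(rpkm_depleted + c) / (rpkm_control + c)`; the
pseudocount `c` defaults to 0 for direction calls (a gene passing the
filter on one side alone yields an infinite or zero ratio, which is kept
and excluded from moment statistics) and to 0.1 in the pipeline's
distribution statistics so that log2 fold changes stay finite. "More than
a 2-fold change" is strict (`fc > 2` or `fc < 0.5`).

## Distribution statistics

Skewness is the moment estimator `g1 = m3 / m2^1.5` (the adjusted `G1` is
available by flag), because the accompanying normality test —
D'Agostino's K-squared — is defined on `g1`. `dagostino_k2()` implements
the omnibus statistic: D'Agostino's transformed skewness Z, the
Anscombe–Glynn transformed kurtosis Z, `K2 = Z1^2 + Z2^2` against
chi-squared with 2 df. No pre-installed R package provides this test, so
it is implemented here and its values are pinned in the test suite
against an independent implementation. A skewness-only Z test is exposed
alongside, since right-skew is the biologically meaningful direction.

The remaining tests delegate to the standard machinery behind the
module's interface: two-sample KS, chi-squared on two proportions
(Yates-corrected by default, matching R's convention; both variants
satisfy the reported significance bounds), Fisher's exact test with the
conventional two-sided rule (sum of tables no more probable than the
observed one), pooled-variance Student's t (Welch by flag), Gaussian KDE
with Silverman's bandwidth, and the ECDF. No multiple-testing correction
is applied anywhere, matching the source analysis.

## TSS neighborhood

For each lncRNA, `nearest_expressed_tss()` finds the expressed coding
gene whose TSS minimizes the gap to the lncRNA span (0 when the TSS falls
inside the span — the BEDTools-closest convention). *Upstream* is defined
in the coding gene's frame: the lncRNA sits on the promoter side of the
TSS. *Sense/antisense* compares strands. Ties break on the smaller gene
id. Window membership for the enrichment test is `0 < d <= 5000` nt —
"within 5 kb" read as inclusive, with overlapping genes excluded from
either window — and the asymmetry is tested with Fisher's exact test on
`[[n_up, n - n_up], [n_down, n - n_down]]`. The source analysis does not
print its 2x2 table; this construction is documented here and the
reported bound (p < 0.001) is robust to the plausible alternatives
(e.g. a direct binomial on 24 vs 1). Whether "within 5 kb" measures to
the lncRNA's own TSS or its nearest edge is likewise unstated;
nearest-edge is used.

A half-open-coordinate subtlety: reflecting the genome and flipping
strands preserves upstream/downstream labels exactly but can shift
span-to-TSS gaps by one nucleotide, because the TSS base of a
minus-strand gene is `end - 1`. The symmetry test asserts labels exactly
and distances to within 1 nt.

## Alternative polyadenylation and the poly(A) signal

`partition_utr()` splits a 3'UTR at the proximal poly(A) site: the
proximal segment runs from the stop codon to the proximal site, the
distal segment from there to the most distal site (mirrored on the minus
strand). Poly(A)-site coordinates are inputs; no de novo site calling is
done. Fragments are assigned to the segment containing their 3'-most
aligned base (the end most informative about which site was used), each
segment gets an RPKM, and the readout is the fold change of the
proximal/distal ratio between depleted and control — above 1 means
increased proximal usage. The ratio fold change is invariant to
library-size rescaling of either sample.

`scan_polya_signal()` scans a window (default 50 nt) upstream of a
cleavage site for the canonical AAUAAA hexamer and configured variants
(e.g. AAGAAA, AGUACU), with U and T treated identically; the motivating
case is a canonical hexamer ending 16 nt upstream of a lncRNA cleavage
site.

## Decay kinetics and enrichment conventions

Transcription-shutoff (actinomycin D) time courses are normalized to a
stable reference transcript and anchored at 1 for t = 0
(`normalize_timecourse()`). Decay is modelled as first-order — the
standard reading of an "RNA decay rate" — and fitted by log-linear least
squares through the origin (`ln(abundance) = -k t`), which is exact on
noiseless exponentials and robust at the 3–6 point scale of a typical
chase; `half_life = ln 2 / k`, with `k` clipped at zero and series below
`k = 1e-4`/min flagged stable (under 1% decay over a 72-h chase).
qPCR fold changes use the delta-delta-Ct convention with amplification
efficiency fixed at 2.0 (perfect doubling) unless overridden. ChIP
enrichment supports fold-over-no-antibody-control and
percent-of-input-normalized-to-control modes; RNA-IP enrichment is the
IP:input double ratio relative to a control IP, normalized to a
reference RNA.

## The synthetic experiment

`sim_config()` fixes the study conditions the generators emulate, chosen
once: 500 coding genes and 80 lncRNAs on a 50-Mb chromosome (a
desk-scale rendering of the genome-wide analysis, whose absolute counts
— 11,572 coding genes, 469 expressed lncRNAs — require the full HeLa
libraries and multi-source annotation and are out of reproduction
scope); 13% of lncRNAs truly upregulated with mean log2 effect 2
(the ">2-fold" excess); upstream placement bias 0.8 and antisense bias
20/24 (the reported orientation split); placement within 10 kb of the
paired TSS; negative-binomial counts (dispersion 0.05) around lognormal
baselines (mean 200); one library per condition, as in the original
experiment, which had no biological replicates.

Coding genes sit on a jittered grid with spacing large enough that each
lncRNA's paired TSS is provably its nearest — this is what makes exact
ground-truth recovery of (neighbor, side, orientation) labels a fair
test. Counts, fragments, APA fragments, decay curves and Ct tables all
come with truth manifests, and identical config + seed reproduces every
output exactly.

What the generators do *not* emulate: spliced fragments (fragments are
single-block and exon-contained, while multi-exon loci exercise the
union logic), sequencing error models, mappability variation, GC bias,
overlapping gene dense regions, and biological replication. Passing
recovery tests therefore demonstrates correctness of the computations
under the stated model, not robustness to every artefact of real
libraries.

Two deliberate noise-level choices in the test conditions: the
direction-call recovery check runs at dispersion 0.02 with a modest
changed-gene mass, because RPKM's total-count normalization compresses
observed ratios when a large fraction of the transcriptome truly changes
(composition bias — visible in any count-normalized measure), and the
stated condition concerns 4-fold effects at adequate counts, not
composition artefacts. The null-calibration check runs at dispersion
0.01, where sampling noise alone calls essentially nothing changed; at
the default dispersion 0.05 the two-library design itself produces a
~2–3% background of apparent >2-fold calls among unchanged genes —
which is in fact the same order as the coding-gene background in the
original data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scales above
(hundreds of genes, 100–500 simulation replicates, 2,000-replicate null
calibrations), chosen as the smallest sizes at which each statistical
property is stable. Degenerate inputs error early and descriptively:
zero variance for moment statistics, n < 20 for the K-squared validity
guard, degenerate margins for Fisher's test, non-positive abundances for
decay fits, non-monotonic coordinates for UTR partitions. All
tie-breaks (deduplication, nearest-TSS) are lexicographic and
deterministic.

## Limitations

- Biotypes come from annotation evidence only; no coding-potential
  scoring.
- No genome-build liftover; all sources must share a build.
- No spliced-alignment step: the pipeline starts from aligned fragments
  or count tables.
- The Fisher 2x2 for window enrichment and the group pairing of the
  t-test are documented conventions for quantities whose exact
  construction the source analysis leaves unstated.
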