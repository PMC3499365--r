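# lncstab

Depletion of PABPN1, the nuclear poly(A)-binding protein, leaves most
protein-coding mRNAs unchanged but selectively stabilizes a subset of
long noncoding RNAs (lncRNAs) through a polyadenylation-dependent decay
pathway. `lncstab` is an R package for the computational analysis behind
that observation, aimed at transcriptomics analysts who want to run the
same battery of tests on their own two-condition RNA-seq experiments:

- **Catalog construction** — compile coding and lncRNA gene sets from
  multiple GTF/BED sources, remove genes completely contained within
  another gene, keep lncRNAs with spliced length > 200 nt, and build each
  gene's *maximal locus* (span + exonic union of all isoforms).
- **Quantification** — count exonic fragments within maximal loci,
  compute RPKM = count / (L/10³) / (N/10⁶), filter at RPKM > 1 in ≥ 1
  sample, and call fold changes FC = RPKM_depleted / RPKM_control with
  `up` iff FC > 2 and `down` iff FC < 1/2.
- **Distribution statistics** — sample skewness g₁ = m₃/m₂^{3/2},
  D'Agostino's K² omnibus normality test (implemented here; pinned
  against an independent implementation), two-sample KS, χ² on two
  proportions, Fisher's exact test, Student's t, Gaussian KDE and ECDF.
- **TSS neighborhood** — strand-aware nearest expressed coding TSS per
  lncRNA, signed distance, upstream/downstream side in the coding gene's
  frame, sense/antisense orientation, 5-kb window enrichment (Fisher),
  and fold-change correlation diagnostics.
- **Alternative polyadenylation** — proximal/distal 3′UTR segment RPKMs
  and the usage-ratio fold change (proximal/distal)_depleted /
  (proximal/distal)_control, plus AAUAAA-family hexamer scanning upstream
  of cleavage sites.
- **Kinetics** — ΔΔCt qPCR fold changes, actinomycin-D chase
  normalization, first-order decay fits (t½ = ln2/k), ChIP and RNA-IP
  enrichment arithmetic.
- **Seeded simulators** — generators for annotations, counts, APA
  fragments, decay curves and Ct tables with ground-truth manifests, used
  by the parameter-recovery test suite.

## Worked example

Simulate a two-condition experiment under the package's default study
conditions (500 coding genes, 80 lncRNAs, 13% of lncRNAs upregulated
with mean log2 effect 2, upstream/antisense placement bias) and run the
full pipeline:

```r
library(lncstab)

cfg <- sim_config(seed = 11)
ann <- simulate_annotation(cfg)
sim <- simulate_counts(ann$catalog, ann$truth, cfg)
rep <- run_pipeline(ann$catalog, sim$counts)
print(rep)
#> coding: 500 expressed; 3 up (0.6%), 22 down (4.4%); skewness -0.283
#> lncRNA: 80 expressed; 15 up (18.8%), 1 down (1.2%); skewness 1.024
#> lncRNA up vs down: chi-squared p = 0.000613
#> within 5000 nt of a coding TSS: 8 upstream vs 3 downstream (of 15; Fisher p = 0.128)
```

Read: coding genes barely move (skewness ≈ 0) while the lncRNA log2
fold-change distribution is strongly right-skewed, with significantly
more lncRNAs up than down; the upregulated lncRNAs sit upstream of
coding TSSs more often than downstream (at this desk scale the Fisher
test on 15 genes is underpowered, as the p-value shows). Per-stage
tables and a JSON summary can be written with
`run_pipeline(..., out_dir = "out/")`.

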