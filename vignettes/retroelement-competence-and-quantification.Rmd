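---
title: "Locus-level retroelement expression and competence calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-level retroelement expression and competence calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrolocus)
```

## The problem

Most endogenous retroviruses (ERVs) and LINE-1 elements in the mammalian
genome are transcriptionally silent or defective, but a small number of
discrete loci respond to environmental cues — including colonization of the
skin by commensal bacteria — and a subset of those still encode the protein
machinery needed to reverse-transcribe their own transcripts. Whether an
induced locus can produce cDNA matters biologically, because cytosolic cDNA
is what nucleic-acid sensors such as cGAS/STING detect. Answering that
question computationally requires three things this package provides:

1. **Locus-resolved expression.** Family-level repeat quantification cannot
   say *which* copy is induced. Quantification here counts reads against the
   genomic footprint of individually annotated loci (gEVE-style per-gene
   coordinates), with reads mapping to more than two genomic locations
   discarded outright rather than redistributed.
2. **A sequence-based competence model.** A locus is called
   reverse-transcription/retrotransposition competent or defective from its
   genome sequence via ORF integrity, the gag/pro-pol reading-frame
   relation, and conserved reverse-transcriptase active-site motifs.
3. **Matched statistics.** Locus-level differential expression with the two
   filter profiles used for genes and for retroelements, plus the
   closed-form qPCR ΔCT and flow-cytometry iMFI statistics used to confirm
   expression at the RNA and protein level.

## The competence model

ERVs need a functional protease/polymerase polyprotein (*pro-pol*) to
reverse-transcribe; gammaretrovirus-like elements additionally express Pol
through translation of the *gag* reading frame, so *gag* must be intact and
in frame with *pro-pol*. LINE-1 elements act in *cis* and need both ORF1
(RNA chaperone) and ORF2 (reverse transcriptase/endonuclease) intact. The
model operationalises this as:

* **ERV**: competent iff gag and pol are present and untruncated, gag is in
  frame with pol, and the pol translation contains all four RT active-site
  motifs.
* **LINE-1**: competent iff ORF1 and ORF2 are present and untruncated and
  the ORF2 translation contains the YxDD motif.

Every failed condition contributes one machine-readable reason code
(`MISSING_ORF1`, `TRUNCATED_POL`, `GAG_POL_FRAMESHIFT`,
`MOTIF_ABSENT:YxDD`, ...), and a locus is competent exactly when the reason
list is empty.

### Motifs

Four RVT_1-domain motif patterns are scanned: `YxDD` and `DLKDAF`
(Mg²⁺ coordination and polymerisation site) and `[WY]xxxLPQG` and
`QDLREVNK` (template binding). `x` matches any of the 20 standard residues
and never `X` (ambiguity) or `*` (stop). These motifs are conserved across
active retroviral RTs (HIV-1, MLV, MMTV, HERV-K-class enzymes), while only
YxDD is reliably conserved in LINE-1 ORF2p — hence the asymmetric motif
requirement between the two element classes. The default requires the four
ERV motifs jointly and order-free; `strict_motif_order = TRUE` additionally
requires template-binding → QDLREVNK → YxDD along the protein, the
arrangement seen in RT domain alignments. The weaker reading is the
default because joint presence is the explicit criterion; the ordered
variant is offered as an opt-in because it encodes extra structural
knowledge that partial annotations can violate spuriously.

### Operationalising "truncated" and "in frame"

Neither term has a universal formal definition, so both are explicit,
configurable parameters of `competence_config()`:

* **Truncated** (default): an in-frame stop earlier than the final
  `terminal_stop_window = 5` codons, *or* nucleotide length below
  `min_length_fraction = 0.9` of a canonical length per role. The two
  clauses capture the two ways real annotations are defective: internal
  nonsense mutations, and 5'/3' erosion visible as short annotated
  segments. Canonical lengths default to gag 1600, pol 3600, env 2000,
  ORF1 1000, ORF2 3800 nt — MLV-scale ERV genes and L1-scale ORFs; all are
  configurable because the appropriate reference length depends on the
  element family under study.
* **In frame** (default): (strand-oriented pol CDS start − gag CDS start)
  mod 3 ∈ {0}, the readthrough-style arrangement of gammaretroviruses such
  as MLV — the family of the flagship competent locus. `allowed_offsets =
  c(0, 2)` admits −1 programmed frameshifts (betaretrovirus-style) where
  that is the biology expected.

Start codons are *not* required: the criteria concern truncation and
frame, not initiation, and annotated retroelement ORFs frequently begin
mid-gene. Translation is always frame 0 of the annotated segment (the
annotation delimits the ORF); there is no 6-frame search.

## Quantification contract

* Coordinates in catalogs are 1-based inclusive (matching how annotation
  tables print them); BED export is 0-based half-open; all interval
  arithmetic is encapsulated so the conventions never mix.
* The counting unit is the **locus footprint** — min start to max end over
  the locus's annotated gene segments — because induction is reported per
  locus, not per gene segment.
* A read contributes when any aligned block overlaps a footprint by ≥ 1 bp.
  Under the default best-overlap rule a fragment counts toward the locus
  with the greatest total overlap; exact ties break to the
  lexicographically smallest locus name, a deterministic and
  order-independent rule. `any-overlap` mode counts a fragment once per
  overlapped locus.
* Reads with NH > 2 are removed entirely (all their records), mirroring
  alignment with a multimap cap of 2 where more-multimapped reads are
  treated as unmapped. There is no EM redistribution: exclusion, not
  reassignment, is the contract. Records without an NH tag count as unique,
  the conservative SAM-semantics reading.
* Mates sharing a read id are pooled as one fragment, so paired-end input
  is never double-counted. Counting is unstranded by default (library
  strandedness is an input property, not something the counter should
  guess); `stranded = TRUE` restricts to same-strand overlap.

## The differential-expression substitute

Full shrinkage-based NB GLM machinery is deliberately out of scope; the
package documents and calibrates a simpler test with the same decision
surface:

1. Median-of-ratios size factors (total-count fallback when any sample has
   under 50% nonzero features, which protects tiny synthetic matrices).
2. Per-feature method-of-moments NB dispersion on scaled counts, floored
   at 1e-8.
3. A Wald statistic for `log2((m2 + 0.5)/(m1 + 0.5))` with a delta-method
   variance under the NB mean-variance relation, using a **moderated**
   dispersion: the per-feature estimate shrunk toward the common median
   with prior df 10. At n = 5 per group raw moment estimates are noisy
   enough to visibly inflate the normal-reference test; shrinkage toward
   the common value restores calibration while keeping feature-specific
   signal at larger n.
4. Two-sided p from the normal reference; BH step-up across tested
   features. All-zero features are excluded and reported with p = FDR = 1.

Simulation at the study's scale (1000 features, 5 vs 5, dispersion 0.1,
100 replicate seeds — the sizes used by `analysis/04` and the acceptance
script) gives an aggregate type-I error of ≈ 0.065 at nominal 0.05 and
recall ≈ 1 for planted 4-fold effects at FDR < 0.05. The residual
anticonservatism is a known property of Wald tests with estimated NB
variance at small n; it is documented rather than hidden behind an
empirical reference because the normal reference is part of the stated
contract.

Two filter profiles express the downstream selection rules: **genes** keep
FDR < 0.05 *and* |FC| > 2 (two-sided — both induction and repression
count); **retroelements** keep FDR < 0.05 alone. The retroelement rule
deliberately omits a fold-change floor, following the locus-level
definition exactly.

## Assay formulas

* ΔCT relative expression: `2^(CT_Gapdh − CT_target) × 1e4`. Equal CTs give
  exactly 1e4; the statistic is strictly decreasing in target CT and
  increasing in housekeeping CT. Group fold increase is the ratio of
  unpaired arithmetic group means (no pairing structure is assumed).
  No amplification-efficiency correction and no ΔΔCT variant are applied.
* iMFI = frequency × MFI with frequency on the **percent-of-parent scale
  (0–100)**. The scale is stated prominently because the product is
  100-fold smaller on the fraction scale and the convention is often left
  implicit in reports.

## What the generators emulate — and what they do not

The synthetic-data module is first-class, tested code; every pipeline
stage is validated against its ground truth.

* `build_locus_sequence()` assembles stop-free ORFs from uniformly sampled
  sense codons and splices the RT motifs in at fixed pol positions. Filler
  codons for pol/ORF2 exclude aspartate and glutamine so that no RT motif
  can arise by chance outside the planted sites (every motif pattern
  requires a D or a Q) — this is what makes the planted
  `motif_ablated` truth exact rather than probabilistic.
* Lesions are minimal and surgical: one inserted nucleotide shifts the
  gag→pol frame; one codon becomes TAA; pol truncates to 25% of canonical;
  ORF1 is omitted; the YxDD site is replaced. Each forces exactly one
  reason code, so recovery can be asserted on reasons, not just verdicts.
* `build_genome()` places loci with 1 kb margins and 2 kb gaps (round-robin
  across chromosomes), inserting minus-strand loci as reverse complements.
* `simulate_alignments()` emits perfect-match `<len>M` reads (length 50 nt)
  uniformly within footprints, background reads rejection-sampled outside
  all footprints, NH = 2 read pairs at two paralog sites, and NH = 3
  triplets that the filter must remove. Ground-truth counts follow the
  best-overlap contract analytically (full-length tie at both paralogs →
  lexicographically smaller name).
* `simulate_counts()` draws NB counts (Poisson at dispersion 0) with
  baseline means lognormal(log 100, sd 1) — a realistic bulk RNA-seq spread
  chosen once — and `simulate_ct_table()` inverts the ΔCT formula exactly
  before adding Gaussian CT noise (σ = 0.2 cycles in the noisy analyses).

Passing against these generators shows the *logic* is exact: conventions,
tie-breaks, filters, formulas, calibration. It does not show robustness to
what real data adds — sequencing errors, indels and clipped alignments,
non-uniform coverage, fragment-length effects, annotation errors, ERV
families whose canonical lengths differ from the defaults, or biological
dispersion trends — and the competence model inherits whatever the locus
annotation asserts: it cannot rescue a mis-annotated ORF boundary.

All generators are pure functions of (spec, seed), using R's default
Mersenne-Twister stream via `withr::with_seed()`; identical inputs give
byte-identical FASTA/SAM/TSV outputs on any one platform, and derived
sub-seeds are small fixed offsets of the master seed.

## Numerical and degenerate-input choices

* Zero-width cigar blocks (insertion-only runs between introns) are
  dropped; D runs extend blocks, N splits them.
* A stop codon inside the terminal window does not truncate; a stop at the
  boundary does.
* `bh_adjust()` delegates to the stock step-up implementation and the test
  suite pins it against a from-the-definition oracle; the sorted FDR
  sequence is checked non-decreasing.
* Catalog validation reports issues instead of raising: partial loci
  (pol-only ERVs, LINE-1 without ORF1) are warnings because they occur in
  real annotation tables, while class/role violations and duplicate keys
  are errors that stop the pipeline.
* Empty coordinate cells yield no segment; a missing strand is a parse
  error, never inferred.

## Known limitations

* No HMM search against the actual RVT_1 profile; the motif model is four
  fixed patterns, which is the point — it is auditable — but it will not
  score divergent RTs the way a profile HMM would.
* The NB test handles exactly two groups, no covariates, no outlier
  handling.
* SAM consumption covers the 11 mandatory fields, cigar ops M/=/X/I/D/N/S/H
  and the NH tag; BAM, indexing and random access are out of scope.
* Canonical ORF lengths are global per role; family-specific lengths must
  be supplied by the user via `competence_config()`.
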