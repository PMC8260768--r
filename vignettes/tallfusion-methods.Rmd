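---
title: "Methods and design of the tallfusion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the tallfusion pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tallfusion)
```

# Scope

`tallfusion` re-implements, as reusable and tested functions, the
computational procedures needed to characterise a TCF7-SPI1
fusion-positive T-cell acute lymphoblastic leukemia (T-ALL): paired
tumor/remission somatic-variant filtering, fusion transcript and protein
modelling, cell-barcode demultiplexing of nanopore reads with
fusion-versus-canonical read classification, ETP-ALL gene-signature
derivation and scoring, a pre-ranked enrichment statistic with a
permutation null, and clonal statistics (single-hit limiting dilution,
2x2 co-occurrence). Alignment, variant calling, basecalling, de novo
assembly, batch integration and clustering are deliberately out of scope:
the package consumes the tables and reads those tools produce.

Every stage can be exercised on synthetic data with known ground truth,
so the whole pipeline is testable without access to controlled-access
patient sequencing data.

# Somatic variant filtering

Candidate variants carry tumor and remission ref/alt read counts. The
variant allele fraction (VAF) is `alt / (alt + ref)`; records with zero
depth in either sample are auto-rejected with rule `no_coverage`. A
variant is called somatic when **all** of the following hold:

* tumor VAF >= 5% (inclusive — "at least");
* relative VAF difference `(VAF_T - VAF_R) / VAF_T` >= 20%;
* two-sided Fisher exact p on `[tumor_alt, tumor_ref; remission_alt,
  remission_ref]` below `alpha` (default 0.05, configurable — the rule
  is stated only as "significant");
* remission VAF < 5% (exclusive).

The "minimum 20%" difference admits a relative and an absolute reading;
relative to the tumor VAF is the default and `diff_mode = "absolute"`
provides the alternative. Boundary semantics follow the wording exactly:
inclusive where "at least", strict where "<".

The Fisher p-value is computed in-package by summing hypergeometric
point probabilities no larger than the observed table's (with the
conventional 1e-7 relative tolerance on that comparison). A table with
an all-zero margin is degenerate and returns p = 1 with a logged
message. The test suite checks the implementation against exhaustive
enumeration over all 2x2 tables with total count up to 40, and
cross-checks `stats::fisher.test` on spot tables.

# Fusion transcript and protein model

Gene models are exon lists in transcript order plus a protein length and
named protein domains (amino-acid coordinates, 1-based inclusive, as in
figure annotations). Exon intervals are held in `IRanges` and all
user-facing coordinates are 1-based inclusive.

An intronic breakpoint in each partner defines the fusion transcript:
the 5' partner's exons upstream of its breakpoint followed by the 3'
partner's exons downstream of its breakpoint. Any coordinate inside the
same intron yields the same transcript; exonic breakpoints are refused
(`"exonic breakpoint unsupported"`) because sub-exon fusions are not
modelled. The reading frame is assumed preserved, as it is for the
predicted TCF7-SPI1 product; only exon-level structure is modelled, so
frame checking is not performed.

The fusion protein joins residues `1..a_end` of protein A to residues
`b_start..b_end` of protein B, giving total length
`a_end + (b_end - b_start + 1)`. For the TCF7-SPI1 fusion
(`a_end = 182`, B segment `52..271`) this is 402 aa, and deleting the
55-residue N-terminal beta-catenin binding region leaves 347 aa. A
domain is retained only when it lies entirely inside its retained
segment — a domain straddling the junction is neither intact nor
reported — and retained B domains shift by `a_end - b_start + 1`.

Breakpoint-supporting reads are recognised when they align across the
junction with at least `m = 20` consecutive bases on each side, allowing
2 substitutions per side (tolerant of ~1% sequencing error on a 20-nt
core).

# Long-read demultiplexing and read classification

Demultiplexing follows direct sequence matching of 10x cell barcodes:
the first and last 200 nt of every read strictly longer than 250 nt are
scanned against each whitelist barcode, forward and reverse-complemented,
and a hit is accepted below 2 mismatches (Hamming distance <= 1,
substitutions only — direct matching implies no indel handling; the
`max_mismatches` knob exposes the choice). Decisions taken where the
source procedure is silent:

* two *distinct* barcodes tied at the best distance make the read
  `ambiguous` rather than arbitrarily assigned;
* both 200-nt windows are scanned even when they overlap in short reads
  (each window is clipped to the read);
* non-ACGT characters mismatch every base, including themselves.

`hammingScan` returns the leftmost minimum-distance offset and is tested
against an exhaustive per-offset oracle.

Read classification replaces the original contig-alignment step with
mismatch-tolerant marker search: a read is a *fusion read* when it
contains the TCF7 exon-4 marker, the junction marker and the SPI1 exon-3
marker, and a *canonical read* when it contains the TCF7 exon-4 and
exon-7 markers. Each marker may mismatch at up to 10% of its length (a
documented stand-in for alignment identity), is searched in both
orientations, and a read satisfying both rule sets is returned as
`other` with a conflict flag. `demuxRun` writes per-cell FASTQ files, a
TSV summary and a JSON report, and conserves read counts exactly
(`assigned + ambiguous + unassigned + too_short = total`).

# Expression normalization, QC and signature scoring

* **TPM**: counts over gene length in kb, rescaled per sample to one
  million. Columns of any non-degenerate sample sum to 1e6 exactly.
* **Cell QC**: drop cells with ribosomal fraction > 0.6, mitochondrial
  fraction > 0.1 or fewer than 200 expressed genes — all strict, so a
  cell exactly at a bound is kept.
* **DE stand-in**: Welch t on `log2(CPM + 1)` with Benjamini-Hochberg
  adjustment. This is deliberately simple: it exists so synthetic
  end-to-end runs have a DE table; externally produced tables (e.g. from
  a negative-binomial GLM) plug into `deriveSignature()` and
  `rankGenes()` directly.
* **Signature derivation**: fold change strictly above 2 (log2 above 1)
  with adjusted p strictly below 0.05, up and down separately.
* **Bulk scoring**: each signature gene is z-scored *across samples*,
  per-sample means are taken, and means are z-scored across samples
  again. The source wording ("z-score scaling across signature genes")
  is ambiguous between gene-wise and sample-wise scaling; gene-wise is
  the standard construction and the default, with `gene_wise = FALSE`
  for the alternative. All z-scores use the sample (n-1) SD; the test
  suite pins the two-sample case `(1, 3)` to scores `(-1/sqrt(2),
  +1/sqrt(2))`. Constant and absent genes are dropped with warnings; an
  empty intersection is an error.
* **Per-cell scoring**: module-score construction with
  expression-matched controls — genes are binned by average expression
  into 24 equal-occupancy bins, 100 control genes are drawn per
  signature gene from its bin (with replacement when a bin is too
  small, logged), and the signature-minus-control mean is z-scored
  across cells. The control draw is seeded and reproducible.
* **Ranking statistic**: `-sign(log2FC) * log10(padj)`, zero p-values
  clipped at the smallest positive double with a warning, ties broken
  by gene id.
* **Correlation ranking**: Pearson r of every gene against an anchor
  gene (e.g. SPI1) on a counts-per-10k log1p layer — the original
  "median-scaled log-transformed" layer is not fully specified, so the
  standard CP10K-log1p normalization is used and stated. Constant genes
  are excluded; the anchor never appears in its own top list.

# Pre-ranked enrichment

The enrichment score is the classic weighted running-sum statistic:
hits add `|score|^weight` (normalised over the set), misses subtract
`1/(N - |set|)`, and the ES is the extremum of largest absolute value.
Exact `+x`/`-x` ties are real on symmetric data, so extremum selection
uses a 1e-9 relative tolerance and resolves ties toward the earlier
list position; the brute-force oracle in the tests pins the same
convention. The leading edge is the hits up to the extremum for
positive ES and from the extremum onward for negative ES (the standard
convention; the positive case is forced, the negative case is a
documented choice).

The null is gene-set permutation — the pipeline consumes pre-ranked
lists, so phenotype permutation is unavailable —
with `p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`, and
`NES = ES / mean(|ES_null|)` over null scores of matching sign (sign
conventions differ between implementations; this one is stated and
tested). Null scores are computed by an O(set-size) hit-position
formula whose equality with the full running sum is itself a property
test. Because the observed set in a calibration run is drawn exactly
like the null sets, the p-value is uniform on its grid; the acceptance
suite verifies this with a Kolmogorov-Smirnov check over 1000 runs.

# Limiting dilution and co-occurrence

The single-hit model says a graft of `d` cells fails to initiate
disease with probability `exp(-d f)`, where `f` is the active-cell
frequency. The log-likelihood
`sum(r log(1 - exp(-d f)) - (n - r) d f)` is maximised over `log f` by
bounded search on `[1e-9, 1)` followed by Newton polishing (relative
tolerance well below 1e-10); for a single dose the fit reproduces the
closed form `f = -log(1 - r/n) / d` to machine precision. The 95% CI is
Wald on `log f` (standard LDA practice), with a profile-likelihood
interval behind `ci = "profile"` for small samples. Tables where every
animal responds ("saturated") or none responds carry no finite MLE and
are refused with informative errors; simulation studies exclude them,
as standard tools do.

Two conditions are compared by a likelihood-ratio test: twice the
log-likelihood gain of separate fits over a pooled fit against
chi-squared with 1 df. Calibration simulations use a frequency regime
(1/50,000 on the 2e3..2e6 dose ladder, 5 animals per dose) in which the
dose ladder is informative, i.e. degenerate tables are rare; at the
fusion-condition frequency 1/1243 roughly a third of simulated tables
saturate, which is a property of that design, not of the estimator.

The odds ratio for a 2x2 co-occurrence table is `(a d)/(b c)` with the
Haldane-Anscombe 0.5 correction applied (and flagged) only when a zero
cell exists; the p-value reuses the exact Fisher implementation. The
patient-level fusion/NRAS table behind the published cohort statistics
is controlled-access, and several integer tables are consistent with
the printed OR and p, so the package ships a clearly labelled
*synthetic* stand-in (`inst/extdata/synthetic_cooccurrence_nras.tsv`)
chosen only to be consistent with those two printed statistics; tests
validate the operation against them, not against unpublished counts.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a required
seed.

* `simulatePairedVariants()` — somatic sites draw tumor alt counts from
  `Binomial(depth, VAF)` with remission VAF 0; germline sites use VAF
  0.5 in both samples. Defaults: depth 100 (typical exome depth), tumor
  VAF 0.1-0.4 (clonal to subclonal). Not emulated: mapping artefacts,
  strand bias, contamination, indels.
* `simulateLongReads()` — each read is prefix + 16-nt cell barcode +
  spacer + exon-marker body (+ suffix), reverse-complemented with
  probability 1/2 so barcodes present in both orientations; fusion
  bodies span TCF7 e1-e4 then SPI1 e3-e5, canonical bodies TCF7 e1-e7;
  substitution errors at 0.5% by default (a deliberately clean rate —
  the demultiplexing rule itself tolerates only one mismatch).
  Exon markers are fixed random 40-nt sequences: classification is
  defined by which markers a read spans, not by homology to the real
  genes. Not emulated: nanopore indel-dominated error profiles, UMIs,
  chimeras, doublets.
* `simulateExpression()` — negative-binomial counts, log-normal
  gene means (log-mean log(50), log-SD 1), common dispersion 0.05
  (low, bulk-like biological noise), 10 vs 10 samples, 2000 genes with
  50 up and 50 down planted at log2 effect 2. These defaults are the
  conditions under which recovery and separation are tested. Not
  emulated: library-size imbalance, gene-gene correlation, outlier
  samples.
* `simulateLimitingDilution()` — responders per dose are
  `Binomial(n, 1 - exp(-d f))` at the published dose ladder (2e3, 2e4,
  2e5, 2e6 cells; 5 animals per dose).

Passing tests on these generators show the *procedures* are correct
under their stated statistical models; they do not show robustness to
the real-data artefacts listed above, which upstream tools are expected
to handle.

# Problem sizes and runtime choices

The test and acceptance suites run at sizes chosen to make Monte-Carlo
bands tight while keeping a full run in a few minutes of CPU: exhaustive
Fisher checking over all 135,751 tables with total <= 40; 10,000 random
Hamming-scan instances; 8 cells x 50 reads for demultiplexing truth
recovery; 500 limiting-dilution replicates for recovery and coverage and
2000 for likelihood-ratio calibration; 21,699 exhaustive enrichment
instances (all sets of size <= 5 from a 20-gene list) plus 1000
permutation runs of 199 permutations for uniformity.

# Interface note

The package is used from R: the exported functions, the
`scripts/acceptance.R` entry point and this vignette are the interface.
Stages that produce files (`demuxRun()`, `writeJsonSummary()`) emit
machine-readable JSON summaries alongside TSV/FASTQ outputs, and
filtering stages return per-record decision tables so every kept/dropped
count can be audited.

# Known limitations

* The somatic filter consumes candidate-variant tables; it does not call
  variants, and VCF conversion is left to standard tools.
* Fusion modelling is exon-resolution: sub-exon breakpoints and frame
  validation are not modelled.
* Demultiplexing is substitution-only; an indel in a barcode defeats it
  (as it defeats direct matching generally).
* The DE stand-in is a t-test on transformed counts, not a count model;
  for real cohorts, import DESeq2/edgeR results instead.
* The enrichment module implements one statistic with a gene-set
  permutation null; multi-set FDR beyond BH over per-set p-values is out
  of scope.
* Wald intervals on `log f` can be optimistic for very small designs;
  the profile option is provided for those cases.
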