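---
title: "Nominating cancer-dependency cryptic ORFs on lncRNAs: methods and design"
author: "cryptorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating cancer-dependency cryptic ORFs on lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptorf)
```

## The problem

Long noncoding RNAs (lncRNAs) are annotated as noncoding on sequence
grounds, but ribosome profiling (ribo-seq) shows that some of them carry
short, unannotated ATG→stop open reading frames (ORFs) that are actively
translated into micropeptides. A subset of these cryptic proteins can be a
genuine fitness dependency of a tumor — for example by partnering with a
lineage transcription factor and co-driving its target program. Identifying
them requires integrating several weak, noisy layers of evidence:
translation (ribo-seq), fitness (pooled CRISPR knockout screening), clinical
relevance (tumor-vs-normal expression, survival), physical context (AP-MS
interactors), and direct regulation (ChIP peaks near the targets the
cryptic protein co-regulates, plus cell-line dependency scores for those
targets).

`cryptorf` implements this funnel as composable, individually tested
stages, and ships a synthetic-data module that generates every input with
planted ground truth. The package's validation therefore rests on two legs:
exact oracles (enumeration, closed forms, positional brute force) for the
deterministic machinery, and planted-effect recovery for the statistical
machinery.

## Stage models

### Translation evidence: an exact frame-bias test

A translating ribosome advances in 3-nt steps, so P-sites over a translated
ORF concentrate in one reading frame. For a candidate ORF with `n` pooled
P-sites in `[start, end)` and `x0` of them in frame 0 relative to the
start, we test

> p = P(X ≥ x0), X ~ Binomial(n, 1/3),

one-sided and exact, with Benjamini–Hochberg q-values computed across
*tested* candidates only (those with at least `min_psites` P-sites, default
10 — including untestable ORFs in the BH pass would penalize the testable
ones without adding information). Candidates below the support floor are
reported untested, not accepted or rejected.

This is a deliberate simplification relative to full ORF-calling tools,
which model initiation sites, read-length-specific offsets, and
negative-binomial noise. It preserves the inferential role — periodicity
evidence of translation for ATG ORFs — with a test that is exact,
assumption-light, and conservative for discrete data (its null rejection
rate sits slightly below nominal; the acceptance suite measures it on 2,000
frame-uniform null ORFs). Overlapping candidates are tested independently,
which double-counts shared P-sites across frames; the subsequent
de-duplication step collapses redundant calls.

ORF enumeration follows the longest-isoform convention: per (frame, stop)
group, the most 5' ATG after the previous in-frame stop. De-duplication is
greedy: ORFs sorted by decreasing P-site support (ties by lexicographic
`orf_id`, for determinism) either join the first cluster whose
*representative* they match at global amino-acid identity ≥ 0.9
(matches / gap-inclusive alignment length, BLOSUM62 global alignment) or
found a new cluster. Comparing to representatives only — not cluster
members — makes the procedure order-stable and cheap; chains A~B~C with
A≁C therefore split, which is the intended behavior for a representative
catalog.

### Fitness evidence: empirical depletion against negative controls

The screen library carries targeting guides plus positive controls
(essential genes, expected to deplete) and a large panel of negative
controls. That panel is exactly a null distribution, so per-guide
significance needs no parametric model: with replicate means taken before
the ratio and a pseudocount of 1 guarding `log2(0)`,

> lfc = log2((mean day21 + 1) / (mean day0 + 1)),
> p = (1 + #{negative-control lfc ≤ observed lfc}) / (1 + m),

the add-one-corrected empirical tail (ties count; `p` can never be 0, and a
guide below all `m = 1000` controls gets exactly `1/1001`). Counts are
first normalized so each sample's median negative-control count equals the
across-sample geometric mean of those medians — negative controls should
not change, so they anchor the size factors; the procedure is idempotent.

The hit rule is applied with the printed boundary semantics: a guide is
significantly depleted iff `lfc ≤ −log2(1.5)` (inclusive) **and**
`p < 0.05` (strict); an ORF is a hit iff ≥ 2 guides pass. QC reports
per-class median lfc and a one-sided rank-sum test that positive controls
sit below negative controls (pass at p < 0.01).

### Expression, survival, overlap

Tumor-vs-normal differential expression uses a two-sided Wilcoxon rank-sum
test per gene (robust, assumption-light; a Welch *t* option exists) with BH
FDR across all genes; the *thresholds*, not the test, carry the scientific
content, and they are applied exactly as printed: fold-change bounds
inclusive, FDR bounds strict. Genes constant across all samples get
`p = 1` by convention and a flag. Survival association dichotomizes
samples at the median expression of the prognostic gene (configurable cut)
and applies the standard two-group log-rank test (via `survival::survdiff`;
the test suite checks it against a hand-computed O/E table). Set-overlap
significance is Fisher's exact test on an **explicit** universe — the
right universe (e.g., genes tested in both DE runs) is an analysis
decision, so the function refuses to guess one. The odds ratio is the
sample OR with a Haldane 0.5 correction when a cell is zero.

### Interactome

The AP-MS specificity rule — unique peptides ≥ 2 in the bait purification
and 0 in the tagged-GFP control — is applied after aggregating runs by the
maximum (the most permissive reading of "identified"; sum is available).
Survivors are intersected with the tumor-upregulated gene set
(`lfc ≥ 1`, `FDR < 0.01`) and ranked by descending fold change. An
interactor with no DE record is excluded *with a warning*, never silently
kept.

### Regulatory triage

Common binding sites are the coordinate intersection of the two factors'
peak sets (a position is common iff covered in every set; peak-level
"shared" then means ≥ 1 bp overlap with that common set — the minimal
reading of "overlapped with", with a reciprocal-fraction option left to the
caller via `min_overlap`). Peaks are assigned to a gene iff they overlap
its TSS window by ≥ 1 bp. The window is −30 kb/+10 kb *in transcription
direction*: `[tss−30000, tss+10000)` on the + strand and
`[tss−10000, tss+30000)` on the − strand; the convention is the standard
regulatory one, and a strand-agnostic mode exists because the printed
"−30 kb to +10 kb" does not state strand handling. Peak genomic categories
use the peak midpoint with precedence promoter (≤ 3 kb of a TSS) >
TTS-proximal (≤ 3 kb of a TTS) > exonic > intronic > distal intergenic
(> 3 kb from any TSS/TTS and outside gene bodies); only the > 3 kb distal
rule is prescribed, the precedence order is this package's convention, and
midpoint (vs any-overlap) categorization guarantees exactly one category
per peak.

The final nomination requires all four flags — co-upregulated by both
factors, tumor-upregulated, ≥ 1 common site in the window, and gene-effect
score < −0.2 (strict) in *every* required cell line — and orders targets by
ascending mean gene effect (strongest dependency first). A candidate
without effect scores fails the dependency flag with a warning rather than
erroring the run.

## The synthetic-data generator

Every generator is a pure function of `(config, seed)`: RNG state is
saved/restored around each one, sub-seeds are derived per stage, and
rerunning any stage writes byte-identical outputs.

What it emulates, and the defaults:

* **Transcriptome** — one synthetic chromosome, one gene per 70-kb slot
  (adjacent TSSs are then always > 60 kb apart, so −30/+10-kb windows of
  different genes never overlap and planted peak geometry stays
  gene-specific), two exons around a 2-kb intron; 80 lncRNA and 20 coding
  transcripts. Half of the lncRNAs carry one planted ATG ORF (30–100 aa)
  with an in-frame stop placed immediately upstream of the ATG, so the
  planted start is exactly what the enumerator's most-5'-ATG rule recovers.
* **Ribo-seq** — per-ORF Gamma rates around a mean depth of 80 P-sites,
  independent Poisson replicate draws (3 replicates; negative-binomial
  marginal with size 30). A P-site lands in frame 0 with probability
  `periodicity + (1 − periodicity)/3` (default periodicity 0.8); non-planted
  lncRNAs get frame-uniform background. Read lengths peak at 30 nt.
* **Screen** — default library composition mirrors the emulated study
  (636 positive / 1,064 negative controls; a `n_targeting_sgrnas` override
  reproduces a 3,913-guide targeting section exactly); 5 guides per ORF,
  ~500× day-0 coverage, 3-fold day-21 depletion of essential-ORF and
  positive-control guides, 2 replicates per timepoint (replicate structure
  is not prescribed anywhere, so it is a parameter). The negative-binomial
  size of 30 gives the mild-to-moderate overdispersion typical of
  high-coverage screens — enough to stress the empirical-p machinery
  without drowning a 3-fold effect.
* **Cohort** — log2 expression Gaussian (gene baselines N(5, 1.5²),
  residual sd 1), 50 tumors / 50 normals, planted tumor-up genes shifted by
  2 log2 units; exponential survival for tumors (baseline hazard
  0.02/month) with the hazard multiplied by 2 in the above-median stratum
  of the prognostic gene, administratively censored at 120 months.
* **AP-MS** — true interactors get ≥ 2 unique peptides in every bait run
  and 0 in controls, by construction; background proteins get overlapping
  Poisson counts in both arms and always ≥ 1 control peptide in some run
  (that is what background *means* in this design), so the specificity
  filter separates the classes exactly.
* **Regulatory layer** — each candidate coding gene gets a role: co-bound
  targets receive one peak per factor at a common locus inside their own
  TSS window plus passing (< −0.2) effect scores in both simulated lines;
  each decoy is constructed to fail exactly one triage condition
  (single-factor peak, common peak placed in a gene-free region outside
  every window, failing effect score in one line, or absence from the
  co-up set). This makes end-to-end recovery a sharp test: the pipeline
  must nominate exactly the planted drivers.

What it does **not** emulate: read-level sequencing (FASTQ, errors,
mappability), batch effects, copy-number artifacts in screens, realistic
cohort structure (subtypes, covariates, competing risks), correlated
peptide detection, or peak-calling noise. Passing tests therefore
demonstrate that the *inference machinery* is correct and calibrated under
the stated noise models — not that the pipeline's thresholds are optimal
for any particular real dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED convention); IRanges
  does interval arithmetic per chromosome; FASTA/GTF-style 1-based
  conversion happens at the boundary.
* Boundary semantics follow the printed inequalities everywhere:
  fold-change thresholds inclusive, p/FDR thresholds strict, dependency
  strictly below −0.2.
* Pseudocount 1 in screen lfc; replicate means before ratios.
* Ties: de-duplication order ties broken by lexicographic `orf_id`;
  empirical p is tie-inclusive by definition.
* Degenerate inputs fail loudly and specifically: all-zero screen samples
  and missing negative controls are errors naming the offender; an empty
  survival stratum (all-equal expression) is an error suggesting a
  different split; elements outside the Fisher universe are listed; a
  W > L tumor-diameter pair warns but computes.
* Windows are clipped at position 0 with a warning; peaks on unknown
  chromosomes are categorized `unplaced`.

## Validation problem sizes

The test suite validates calibration on 2,000 frame-uniform null ORFs,
power on 400 planted ORFs (periodicity 0.8, ≥ 50 P-sites), screen recovery
on 500 ORFs (50 planted essential, 5 guides each, 1,000 negative
controls), log-rank operating characteristics over 1,000 null and 200
alternative cohort simulations, interval operations against positional
brute force over 1,000 random cases, and end-to-end driver recovery on the
default fixture. These sizes were chosen to keep every Monte-Carlo
standard error well below the asserted margins while keeping the suite
fast to run.

```{r funnel}
fx <- simulate_study(fixture_config(seed = 1))
run <- run_cryptorf(fx)
run
setequal(run$final_targets, fx$ground_truth$co_bound_target_ids)
```

## Known limitations

* The frame-bias test ignores read-length-specific P-site offsets and
  cannot separate overlapping ORFs sharing a frame; it tests translation of
  a *region*, not initiation at a specific codon.
* The empirical screen p-value is bounded below by `1/(m+1)`; with few
  negative controls it cannot reach small values, and the hit rule then
  leans entirely on the fold-change bound.
* Wilcoxon DE on small groups is conservative; count-model DE (negative
  binomial GLMs) is out of scope by design.
* The triage treats evidence flags as binary; it does not weight or rank
  by strength of the expression or binding evidence beyond the final
  gene-effect ordering.
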