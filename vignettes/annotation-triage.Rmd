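---
title: "Annotation triage for de novo EST assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation triage for de novo EST assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventannot)
```

## The problem

Transcriptome surveys of organisms without a reference genome — here the
deep-sea hydrothermal-vent mussel *Bathymodiolus azoricus*, whose gill
tissue was pyrosequenced to catalog immune and symbiosis-related genes —
produce tens of thousands of assembled contigs that must be triaged into
putative protein-coding transcripts before any functional statement can
be made. `ventannot` implements that triage as a reusable, testable
pipeline: read cleanup, a three-tier reading-frame cascade, ontology
propagation counting, a bacterial-fingerprint screen over ranked
homology hits, a cross-database comparison, and comparative-CT
expression quantification. Because the original reads and 2010-era
databases are not reproducible at desk scale, the package ships a
synthetic-data module that generates every input with ground truth, so
each stage is exercised end to end without downloads.

## Preprocessing

Contigs pass through adapter trimming, poly-A masking, and a length
gate, in that order.

* **Adapter trimming** removes terminal occurrences of user-supplied
  adapter oligos (the SMART adapters of a cDNA normalization protocol
  are not published with the study, so adapters are a required input,
  never a built-in). Matching is Hamming-style with a default tolerance
  of one substitution — in pyrosequencing data, substitutions inside a
  short adapter are far more common than indels — and `max_mismatch = 0`
  gives exact matching. Internal occurrences are only flagged: cutting
  a contig open on an internal match would silently discard sequence
  the assembler joined. Trimming iterates until neither end matches, so
  the pass is idempotent.
* **Poly-A masking** lowercases a 3' run of A (or a 5' run of T, the
  tail of a reverse-complemented transcript) of at least `min_run = 10`
  bases. Masked bases are excluded from the *effective length* because
  a homopolymer tail carries no coding signal; the bases are kept in
  place so that frame coordinates never shift.
* **Length gate**: contigs with effective length strictly below 40 bp
  are discarded ("shorter than 40 bp" is read as strict, so a 40-bp
  contig is kept — 40 bp is the assembler's *minimum* length). Every
  input contig lands in exactly one output partition.

## The three-tier frame cascade

1. **Strict homology** (`tier1_e = 1e-6`): a query is assigned when any
   of its ranked translated-search hits reaches the cutoff; the frame is
   the qualifying hit's frame with the lowest E-value. Ties are broken
   by higher bit score, then lower rank — the search tools' own ordering
   criteria; the best hit decides (not a majority vote), mirroring how
   the hit list is assessed best-first.
2. **Relaxed homology** (`tier2_e = 1e-2`): the same rule re-run over
   the queries the strict tier left unassigned.
3. **Coding scan**: contigs with no usable homology are scored by a
   codon-usage log-odds model *trained on the tiers-1/2 calls* — the
   cascade bootstraps the organism's preferential codon usage from the
   frames homology already fixed. This is an order-0 codon model rather
   than a full HMM with indel states: the upstream tool it stands in for
   is used here purely as a frame detector, and the codon log-odds core
   is the testable essence of that role.

The codon model scores a codon as `log(coding_freq / background)`,
where the background is an independent mononucleotide model fitted on
the full training sequences. Training counts come from the longest
stop-free codon run of each called contig; codons containing `N` are
skipped. A pseudocount (default 1) keeps every entry finite, and
uniform training input against a uniform background yields log-odds of
zero over the sense codons (stop codons cannot occur inside stop-free
training runs, so their log-odds are strongly negative by
construction).

The scan evaluates, in each of the six frames, the best-scoring
stop-free window of at least `min_peptide = 30` codons (a planted floor:
shorter conceptual peptides are rejected outright), via a prefix-sum /
lagged-minimum recursion that is exact and linear per frame. Ambiguous
codons score 0 and do not break windows; stop codons always break them.
The top frame is called only if its score reaches the threshold.

**Threshold calibration.** The default score threshold is the 99th
percentile of the same best-window statistic over sequences simulated
from the model's own mononucleotide background (default 500 draws of
600 nt, seed-controlled). By construction the decision rule then calls
at most 1% of that null population; the test suite re-runs the full
rule (threshold comparison, peptide floor, window breaking) over the
null draws to verify the integrated behaviour, which is the operational
content of the calibration. On an independently drawn null the expected
false-call rate equals 1% exactly, so any fresh-sample check hovers at
the bound by design — a property of percentile thresholds, not of this
implementation.

## Ontology propagation counting

Term assignments are propagated up the `is_a` DAG under the true-path
rule. Reporting categories default to depth 1 — the broad categories
directly under the three namespace roots, which is the granularity of
the study's category charts; the level is configurable because it is
inferred, not stated, and no acceptance value is pinned to those
charts. Each product counts **at most once per category** no matter how
many of its terms fall below that category; a product annotated only to
a root is reported separately as "root-only". Percentages are computed
per namespace over the sum of that namespace's category counts, so a
product spanning *k* categories contributes *k* to the denominator —
this is how category charts can sum to 100% while exceeding a
product-based percentage. Only `is_a` edges are propagated; `part_of`
and other relations are out of scope of the OBO subset handled.

## The bacterial fingerprint

Each hit's subject taxon is verified by walking the taxonomy parent
chain to the rank `superkingdom`; a hit is bacterial only if that walk
reaches the node named Bacteria. The screen then plots `f(r)`, the
number of queries whose *best* (lowest-rank) bacterial hit sits at rank
`<= r`, for ranks 1–20. Reading "position of best hit" cumulatively is
the only reading under which a *convergent* count is well-defined: the
curve is non-decreasing and bounded, and its flattening is the
fingerprint. Because no convergence criterion is published, plateau
detection is explicit and parameterized (earliest rank whose next
`window - 1 = 4` increments are all `<= tol = 0`), and both the plateau
rank and the terminal value `f(20)` are always reported, with a
non-converged flag when the curve is still rising. Hits with taxa
missing from the taxonomy are skipped and logged, never fatal.

## Two-database comparison

The comparison is restricted to domain-annotated sequences on *both*
sides, with `evalue <= 1e-5` and `bitscore >=` a threshold from
{90, 120, 200}; both boundaries are inclusive (the source is silent;
`>=`/`<=` is the convention of the filtering tools). The matched count
is non-increasing in the bit threshold — a structural invariant the
tests enforce in place of the study's absolute counts, which depend on
the original databases. Shared-category percentages are
`100 * shared / total` rounded **half-up** to one decimal, matching the
published table's formatting (half-to-even would round 5.45 to 5.4, not
the printed 5.5). The comparison is one-directional (query set against
subject set), as in the study; reciprocal-best-hit orthology is a
non-goal.

## Comparative-CT quantification

`ddct_fold()` implements the classic comparative threshold-cycle
method at 100% amplification efficiency:
`fold = 2^-((dCT(target) - dCT(calibrator)))` with
`dCT(g) = mean CT(g) - mean CT(reference)` against a housekeeping
reference (role of the 28S rRNA gene in the study). Replicate SDs of
target and reference combine in quadrature; the calibrator's mean
enters as the method's arbitrary constant. The fold interval maps
`ddct ± sd` through the same exponential. Folds are invariant under a
constant CT shift, and a calibrator measured against itself is exactly
1. Replicate count is free (the study states 6 replicates in methods
and N = 3 in its figure; the module accepts any N and records it).

## The synthetic-data module

The generator emulates the *features the pipeline consumes*, not the
sequencing process:

* Coding contigs are `5'UTR + coding stretch + 3'UTR (+ poly-A tail)`,
  the coding stretch drawn codon-by-codon from a configurable usage
  table and closed by a stop codon; half the transcripts are
  reverse-complemented (negative frames, tails becoming 5' poly-T).
  Adapters attach to either end at rate 0.25, and ambiguous `N` bases
  are injected at 0.1% to exercise degenerate-input handling.
* The default codon-usage table is a **joint** 64-entry frequency table
  (summing to 1, stop codons at zero): a typical animal amino-acid
  composition with a geometric 2:1 within-family skew. The joint scale
  is what makes the L1-recovery check (planted table recovered within
  0.05 from ≥ 50k training codons) statistically meaningful.
* The default planted coding length is 120–300 codons with 30–150 bp
  UTRs. Below ~100 codons the longest-ORF frame of a random contig is
  no longer reliably the planted frame (spurious stop-free runs in
  other frames become likely), which would make ground truth itself
  ambiguous; the default floor keeps truth crisp while matching the
  scale of the study's 509-bp average contig.
* The default adapter is a 24-nt SMART-style oligo. Its length is
  divisible by 3 on purpose: full-adapter end trims then never shift
  planted frames, so truth written at generation time remains valid
  after preprocessing.
* Hits: E-values grow exponentially with rank (rate `evalue_decay`)
  from a best E-value log-uniform in (-30, 0) — monotone ranks are the
  only property downstream stages rely on, as no hit-score model is
  published. Hit frames carry 5% noise. Contigs of bacterial origin
  (30% of hit-bearing contigs by default) place their best bacterial
  hit at a geometrically distributed rank within 1–20.
* Defaults `n_contigs = 625`, `coding_fraction = 0.8` yield the 500
  planted coding contigs of the recovery conditions, plus 125
  non-coding contigs for the false-call side.

What the generator does **not** emulate — flowgram noise, assembly
chimerism, homopolymer indels, real protein subjects, biased UTR
composition — bounds what passing tests show: they validate the
pipeline's logic and statistics on data matching its model assumptions,
not robustness to every artifact of real 454 data.

## Numerical choices and problem sizes

* All intervals are 0-based half-open; frames are labelled +1..+3 /
  −1..−3 with negative frames counted from the reverse complement.
* Percentage rounding is half-up (away from zero) to one decimal
  everywhere a table is printed.
* The cascade's degenerate path (no homology calls at all) warns,
  skips the scan, and reports everything unassigned rather than
  erroring.
* Test and acceptance runs use 120–1000 contigs, 500-draw nulls, and
  ≥ 50k-codon training sets — sizes at which every stochastic
  acceptance band (frame recovery ≥ 90%, L1 ≤ 0.05, binomial recovery
  of the bacterial fraction, ≤ 1% null false calls) holds with wide
  margin while a full suite completes in a couple of minutes.
* Determinism is byte-level: one seed reproduces every output file
  identically; the run manifest's only non-reproducible field is its
  timestamp.

## Known limitations

* The coding scan has no indel states, so frameshifted contigs (a real
  feature of pyrosequencing homopolymer errors) are called in at most
  one of their local frames or not at all.
* The published tier counts (18,407 / 3,616 / 17,402 of 39,425
  transcripts) are used as accounting worked examples only; the study
  also prints 42,073 translated sequences, a surplus over the tier sum
  that its text does not explain, and the cascade deliberately emits
  one call per contig rather than modelling it.
* `part_of` propagation, term enrichment, GO-slim mapping, live
  identifier-to-taxon lookups, and the assembly step itself are out of
  scope.
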