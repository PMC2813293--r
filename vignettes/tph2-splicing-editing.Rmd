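---
title: "Clone-based analysis of TPH2 alternative splicing and RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based analysis of TPH2 alternative splicing and RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tph2edit)
```

## The biological problem

Tryptophan hydroxylase 2 (TPH2) is the rate-limiting enzyme of serotonin
biosynthesis in the brain. Its transcripts occur in two splice isoforms that
differ by a 6-nt coding insertion, and each isoform carries a fixed set of
four RNA-editing positions that never co-occur with the other isoform's set —
a mutually exclusive editing scheme. Because edited bases look exactly like
SNPs in cDNA, telling a genuine genomic polymorphism from a
posttranscriptional edit requires sequencing the same individual's genomic
DNA at the same positions. This package implements that entire inferential
chain on cDNA clone libraries, together with the enzyme-kinetics comparison
of the resulting protein variants and the population-genetic tests around the
regulating SNP, driven by a synthetic-data generator with exhaustive truth
tables.

## The reference model

No sequence download is required: `build_reference()` creates a *surrogate*
coding-sequence model whose unconstrained bases are arbitrary (fixed by a
seed) but which satisfies, bit-exactly, every constraint implied by the
variant catalogue:

* a 5'-UTR of 42 nt (so position c.-42 exists) and a 490-codon CDS for the
  short isoform TPH2a;
* TPH2b = TPH2a with the hexamer `GCAAGG` inserted after c.439
  (c.439_440insGCAAGG), adding Gly-Lys to the protein within a Glu-rich
  hinge stretch;
* intron 3 context beginning with the non-canonical `GC` splice donor, with
  the alternative `GT` donor 6 nt downstream (the intervening 6 nt are
  exactly the exonic hexamer);
* codon-level constraints that make every catalogue variant produce its known
  protein consequence by *translation* (e.g. codon 129 is `CAA`, so the
  TPH2b position-1 edit c.385C>T creates a stop; codon 441 is `CGT`, so
  c.1322G>A is an Arg-to-His missense).

Coordinates are HGVS-like c. positions. A subtlety worth stating: the
published protein annotations of the b-pattern edits (synonymous K268 from
c.804, P277L from c.830) only agree with codon arithmetic when those
positions are counted in the TPH2b frame, which gains 6 nt after c.439.
The catalogue therefore stores b-only positions in the b frame and all other
positions in the a frame; `a_to_b_pos()` / `b_to_a_pos()` convert, and
positions 440–445 of the b frame (inside the hexamer) have no a-frame or
genomic counterpart. Protein-level annotation is always derived by codon
substitution and translation, never from stored strings; where a published
protein label disagrees with the coordinate arithmetic (the c.1403 edit), the
arithmetic wins.

## The synthetic-data generator

`generate_clone_library()` emulates the sampling process behind a clone
table: per clone it (i) draws the allele of origin uniformly from the
individual's diploid rs4290270 genotype, (ii) applies the *gating rule*,
(iii) draws the splice isoform, (iv) draws each in-scope editing position
independently (Bernoulli with its per-position probability), and (v) applies
uniform substitution sequencing errors. Key choices:

* **Gating rule.** TPH2b transcripts and editing are only ever produced from
  one rs4290270 allele. The generator follows the observation as stated in
  prose — the A allele suppresses both — so the permissive allele defaults to
  T; since published summary tables label the alleles in the opposite
  convention, `permissive_allele` is a parameter and both conventions are
  reproducible.
* **Independence across editing positions.** Partially edited clones are
  observed in real libraries, but no dependence model is published;
  per-position independence is the minimal assumption and is confined to one
  sampling step should a correlation model become available.
* **Allelic balance.** The allele of origin is drawn 50/50 from the two
  haplotypes; allelic expression imbalance is not modeled.
* **Sequencing error** is uniform random substitution at 10^-3 per base,
  a Sanger-scale rate. It exercises the caller's handling of non-catalogue
  mismatches; chromatogram-level artefacts, PCR bias and RNA secondary
  structure are out of scope.
* Editing probabilities default to 0 and are set per stratum when emulating a
  printed table row (e.g. 0.78/0.96/0.96/0.96 for an amygdala-like TPH2b
  stratum of 27 clones).

Every generated object is accompanied by a truth table (isoform, allele of
origin, edited index set, error count), so the full caller pipeline can be
validated by round trip: with sequencing error 0, isoform calls and pattern
labels must — and do, in the test suite — match truth for 100% of clones.

What passing these tests shows is that the *inference machinery* is correct
under the generative model's assumptions. It does not show that real
libraries satisfy those assumptions (independent editing, uniform errors, no
cloning bias), so quantitative conclusions about real tissue still require
the usual experimental controls.

## Isoform classification and variant calling

Clones are aligned globally (Needleman–Wunsch with affine gaps: match +1,
mismatch −1, gap open −5, gap extension −1 per base; `N` scores 0 and never
yields calls) against both isoform transcripts; the higher-scoring isoform is
called when the score margin reaches a threshold (default 3) *and* the
insertion window reads `GCAAGG`; otherwise the clone is `unclassified`, as
are clones not covering the c.430–c.450 decision window. A
reverse-complement retry handles clones in the opposite cloning orientation.

Two numerical details:

* **Fast path.** A substitution-only clone has exactly the length of one
  transcript. If it carries at most 6 mismatches against the equal-length
  transcript, the ungapped alignment is provably optimal under the scoring
  scheme (any alignment with gaps pays at least 12), so a vectorized ungapped
  scorer replaces the dynamic program; everything else falls back to the full
  affine-gap aligner. The test suite asserts fast-path/DP equivalence and
  checks the aligner itself against an independently written Gotoh dynamic
  program on short instances.
* **Indel canonicalization.** Gaps are shifted to their 3'-most equivalent
  position (the HGVS normalization rule) before naming, so an insertion in a
  repetitive context is always reported at the same coordinate.

Substitution calls are annotated against the catalogue in the called
isoform's frame. QC passes a clone when its non-catalogue mismatch count
(presumed sequencing error) is at most 5.

## Discriminating edits from SNPs

`classify_site()` encodes the core logic: an observed alternative base with a
homozygous-reference genomic genotype is an RNA edit; an observed base
present among the genomic alleles is a genomic allele; anything else is
discordant, and missing genomic data yields `unclassifiable` rather than a
guess. At a heterozygous genomic site the alternative base is deliberately
called `genomic_allele`: without phasing, editing cannot be distinguished
from allelic expression, and this conservative convention is surfaced as a
known limitation. Edit chemistry is reported on the mRNA sense strand with
A>G written A>I and C>T written C>U; the catalogue's eight sites span all
four mammalian chemistries (A>I, C>U, U>C, G>A), which the tests assert.

Pattern labels (`"TPH2a 1234"`, `"TPH2b 234"`, `"TPH2a unedited"`) derive
deterministically from the isoform and the edited index set. An edit verdict
at a site belonging to the *other* isoform's pattern raises an
exclusivity-violation flag instead of silently extending the pattern, and
non-catalogue edit verdicts go to a separate novel-candidate table — the 4+4
scheme is fixed.

## Stratified frequency tables and cohort statistics

`editing_frequency_table()` counts QC-passing clones per stratum × isoform
and reports percent edited per position; a stratum emptied by QC keeps its
row with n = 0 and *undefined* (NA) percentages, never 0%. Group comparisons
use Welch's two-tailed unequal-variance t-test on **per-individual** edited
fractions — the individual, not the clone, is the unit of replication,
because clones from one brain share the editing machinery and a pooled test
would be pseudo-replication. (The source convention "type 3 t-test" is the
spreadsheet label for exactly this two-sample unequal-variance test.) No
multiple-testing correction is applied across the four positions by default,
matching the original analysis; `stats::p.adjust` is one line away for users
who want it.

Hardy–Weinberg equilibrium is tested by Pearson chi-square against
expectations at the estimated allele frequency (df 1, hand-computed since the
HWE expectation is not `chisq.test`'s contract); genotype association by
Pearson chi-square on the collapsed AA-vs-rest 2×2 table or the full 2×3
table, without continuity correction. Both are calibration-tested: under
their nulls at cohort sizes 369/373 they reject at ≈5% over 10^4
replicates.

The in-silico NdeI digest cuts `CA^TATG` and returns 5'→3' fragment lengths
that always sum to the amplicon length. Which rs4290270 allele completes the
palindrome is not derivable from the transcript model (the assay's flanking
genomic sequence is not part of it), so `rflp_amplicon()` builds a synthetic
amplicon in which the T allele completes the site by default — a convention,
exposed as the `completing_allele` parameter.

## Enzyme kinetics

Saturation curves are fitted with two models:

* Michaelis–Menten, v = Vmax·S/(Km + S);
* the Haldane single-site substrate-inhibition form,
  v = Vmax·S/(Km + S + S²/Ki), the standard choice when no specific
  inhibition mechanism is published; its velocity is unimodal with maximum at
  S = √(Km·Ki).

The primary estimator is multi-start Levenberg–Marquardt nonlinear least
squares (≥5 starts: the Lineweaver–Burk estimate plus a grid over the
substrate range; tolerances 10^-10 on ftol/ptol; positivity bounds). The
Lineweaver–Burk double-reciprocal regression is retained side by side because
historical Km values derive from it; on noisy data it is biased relative to
nls (the reciprocal transform inflates low-velocity errors), and a paired
test documents that divergence. Degenerate inputs are flagged rather than
mis-fitted: saturation-only data give a non-identifiability flag, curves
without a descending limb leave Ki unbounded and flagged, velocities
containing zeros are rejected by the reciprocal fit.

Velocities are in arbitrary normalized units (raw rates divided by an
expression signal); only Km (µM) and Vmax *ratios* are interpreted.
Simulation scenarios use substrate-inhibition constants (Ki = 500 µM with
BH4-range Km values) chosen so that within the physiological tryptophan
window of 30–50 µM the SI and MM predictions differ by <10%, i.e.
inhibition only matters at supraphysiological substrate, which the tests
assert. Recovery studies at the published 6MPH4 Km constants
(126/292/124/304 µM; 8-point grid 10–600 µM, 5% multiplicative lognormal
noise, 200 replicates) recover each median Km within 10%, and the
Vmax-ratio scenarios (5% for the fully edited short isoform vs its unedited
form; 2× for TPH2B vs TPH2A) are recovered within the replicate confidence
interval. The odd published BH4 value whose uncertainty exceeds its mean is
not used as a recovery target.

## Problem sizes and runtime choices

The test suite exercises libraries of 12–10,000 clones, recovery studies of
40–200 replicates, and calibration loops of 10^4 replicates — sizes chosen
so the full suite completes in a few minutes while keeping binomial envelopes
(3σ) tight enough to be meaningful. The exact-zero gating check runs at
sequencing error 0: with error > 0, an occasional error at a catalogue
position is — correctly — indistinguishable from an edit at single-clone
resolution, so the exactness claim belongs to the gating rule, not the error
model; the truth-level invariant is additionally asserted under the default
error rate.

## Known limitations

* Heterozygous genomic sites: edits masked by a genomic alternative allele
  are not recoverable without phasing (conservative `genomic_allele` call).
* The editing-dependence structure across positions is assumed independent.
* Base-quality-aware calling, chromatogram deconvolution, and novel splice
  isoforms beyond a/b are out of scope.
* Absolute enzyme activities are not modeled; only ratios and Km are
  comparable across variants.
* The surrogate reference reproduces catalogue behavior exactly but is not
  the biological sequence; analyses depending on non-catalogue sequence
  context (e.g. secondary structure) are outside its contract.
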