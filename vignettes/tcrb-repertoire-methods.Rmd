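---
title: "Methods: TCR-beta repertoire profiling with tcrbrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR-beta repertoire profiling with tcrbrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbrep)
library(dplyr)
```

## Scope and model

`tcrbrep` reconstructs T-cell receptor beta-chain (TRB) repertoires from
amplicon sequencing reads and compares them between tissue groups —
typically tumor versus adjacent normal liver tissue, the setting the
package's defaults emulate. The analysis chain is:

1. **Read QC** — a read is discarded when it contains more than 8
   ambiguous bases (N) or when at least 15% of its positions have Phred
   quality below 30. The 15% bound is *inclusive*; the boundary case
   (exactly 15% low-quality positions) is removed. A read failing both
   rules is tallied under the ambiguous-base counter so the report is
   deterministic. Adaptor trimming is out of scope: the simulator emits
   adaptor-free reads and real inputs are expected pre-trimmed.
2. **V/D/J assignment** — each read is aligned locally against every
   germline V segment and, downstream of the V hit, every J segment. The
   aligner is an in-package Smith–Waterman implementation with fixed
   scoring (match +1, mismatch −1, linear gap −2); alignment is treated
   as a replaceable black box by the method, so a bespoke, unit-testable
   aligner with pinned tie-breaking (smallest read start, then smallest
   segment start; score ties between segments go to the
   lexicographically smaller id) is preferred over an external aligner
   binary. D segments, too short for reliable scored alignment, are
   assigned by the longest exact substring match of at least 5 nt inside
   the junction; ambiguous ties give no call.
3. **CDR3 extraction** — the junction runs from the V segment's second
   conserved cysteine codon through the J segment's conserved
   phenylalanine codon, *both inclusive* (the C...F junction
   convention). The inclusive reading is used because observed mean
   junction lengths of about 14 aa match the anchor-inclusive
   convention; the exclusive reading would shift every length by 2.
   A junction is *productive* when its length is a multiple of 3, its
   translation has no stop codon, and it starts with C and ends with F.
4. **Clonotype assembly** — productive reads are grouped by
   `(CDR3aa, V call, J call)`. Diversity statistics collapse this table
   further to unique CDR3aa, matching the "productive unique CDR3aa"
   counting convention, while usage statistics keep the V/J calls.
5. **Per-sample statistics** — Shannon entropy (natural log), clonality
   `1 − H/ln R`, Simpson dominance `Σ p²`, CF100 (cumulative frequency
   of the 100 most abundant clonotypes), D50 (fraction of clonotypes,
   most-abundant-first, needed to cover half the reads), CDR3 length
   distribution with a discretized-Gaussian fit, clonotype counts per
   frequency decade, the 58 × 14 V–J usage matrix, and the overlap
   coefficient between repertoires. These index formulas are pinned
   explicitly because the literature names them more often than it
   writes them; the chosen forms are the standard repertoire conventions
   under which clonality lies in [0, 1].
6. **Cohort comparison** — Mann–Whitney tests per metric and per
   gene/family/V–J pair, Spearman correlation of diversity with clinical
   covariates (LDH, NLR, ALC) computed separately per group, and
   average-linkage clustering of J-family usage columns.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_ambiguous` | 8 | N bases | removal rule is strict ("more than 8") |
| `phred_min` / `max_low_q_fraction` | 30 / 0.15 | Phred / fraction | the 15% rejection region, inclusive |
| `min_score` | 10 | alignment score | V/J call threshold; see calibration note below |
| frequency-region edges | 0, 1e-5, 1e-4, 1e-3, 1e-2, 1 | clone frequency | decade bins around the 0.01%–0.1% region; bins are half-open `(lo, hi]`, so a frequency exactly on an edge belongs to the lower region |
| length weighting | by clonotype | — | `by_read` available; the source convention is not stated, so the choice is explicit |
| comparison `alpha` | 0.05 | raw p | the "significant set" mirrors raw-p practice; a BH-adjusted column is always reported alongside |

**A note on `min_score = 10`.** For random 100–140 nt reads searched
against 58 V segments with the +1/−1/−2 scoring, the expected best chance
score is about `ln(K·n·m·N)/λ ≈ 10` with `λ = ln 3`, so a minority of
random reads clears the threshold by chance. This is harmless for
clonotype tables: a chance V+J call essentially never yields an in-frame
C...F junction, so spurious calls are never productive and fabricate no
clonotypes (a property the test suite asserts directly). Raising
`min_score` to ~15 removes chance calls entirely at some cost in error
tolerance.

## The synthetic repertoire generator

Because the real tissue data live under controlled access, every pipeline
stage is validated against a generator whose defaults emulate the study's
statistical structure:

* 13 tumor and 9 normal samples; per-sample clone numbers drawn around
  8,900 (tumor) and 7,200 (normal) with SD 1,500 — the unique-CDR3aa
  scale of the tissues.
* log-normal clone sizes (σ = 1.5 by default), giving realistically
  skewed CF100/D50 values; σ is an exposed parameter, not a claim about
  any particular dataset.
* junction lengths `round(Normal(14, 1.5))` clipped to [8, 24] aa;
  junction nucleotides are built as the V anchor codon + a uniformly
  back-translated random interior + the J anchor codon, with a
  codon-aligned 6- or 9-nt D-segment substring embedded with probability
  0.7 (codon alignment keeps embedded stretches stop-free without
  rejection sampling).
* per-sample V/J usage drawn from a Dirichlet (concentration 100) around
  a group centre; the default tumor centre shifts TRBV16 and TRBV7-6 up
  by +0.05 before renormalization.
* clinical covariates generated through a Gaussian copula on ranks
  against the latent diversity driver, so target Spearman couplings are
  built in directly (LDH −0.8 in tumor / −0.2 in normal; NLR +0.6 /
  +0.2; ALC −0.5 / +0.3 — signs follow the reported tumor/normal
  correlation pattern; magnitudes beyond the stated LDH pair are this
  package's choice). The per-sample log-normal σ is a monotone function
  of the latent driver, which makes realized entropy track it tightly.
* reads: 5 × 10⁴ per sample, single-end, forward strand, substitution
  errors at rate 0.002, Phred qualities centred at 38 with a degraded
  tail, and 1% junk reads (a third planted with 9 Ns, a third
  low-quality, a third clean random) so that both QC rules and the
  no-call path are exercised.

What the generator does *not* emulate: PCR amplification bias, chimeras,
paired-end structure, strand mixtures, indel sequencing errors, allele
(\*01/\*02) variation, and biological sharing of public clones between
samples. Passing the closure tests therefore demonstrates that the
pipeline inverts the generator's read model exactly and recovers built-in
statistical structure at realistic sizes — not that it is robust to every
artefact of real amplicon chemistry.

## The bundled germline reference

The package ships a synthetic reference whose *structure* matches the
analysis gene space: 58 V segments in 28 families (TRBV7 holding 8
subfamilies), 2 D segments, and 14 J segments including the
pseudogene-style `TRBJ2-2p` (family truncation treats the trailing `p` as
part of the subfamily token). Sequences are short random segments with
correct conserved anchors (Cys codon near the V 3' end, Phe codon near
the J 5' end) — real IMGT alleles are deliberately not redistributed, and
allele-level resolution is a non-goal. Anchor coordinates are 0-based;
all intervals in the package are half-open `[start, end)`.

## Statistical choices

* **Mann–Whitney U**: exact two-sided p by full enumeration of group
  labelings when the combined sample size is ≤ 12 without ties, else the
  normal approximation with tie correction and 0.5 continuity
  correction. The study-sized design (13 vs 9) always takes the
  approximation path; its true type-I error at α = 0.05 is 0.0434
  (slightly conservative), which the calibration test brackets in
  [0.04, 0.06].
* **Spearman**: Pearson correlation of midranks with the t
  approximation for p. "TCR diversity" in correlation analyses means
  Shannon entropy.
* **Multiplicity**: gene-level comparisons report raw p (used for the
  significant set, mirroring common practice in this literature) *and*
  Benjamini–Hochberg adjusted p side by side — 58 subfamily tests at
  α = 0.05 expect ~3 false positives under the null, so the BH column is
  the honest companion.
* **J clustering**: Euclidean distance on the J columns of the
  group-mean V–J matrix, average linkage, cut at k = 2; the
  dendrogram is exported as Newick. Distance and linkage are this
  package's choice; heatmap tools rarely state theirs.
* **Overlap**: the overlap coefficient (min denominator) rather than
  Jaccard, so nested repertoires score 1.
* **Paired structure** (patients contributing both tissues) is *not*
  exploited; comparisons are unpaired by design, and a signed-rank
  paired mode is a documented non-goal.

## Numerical and degenerate-input conventions

* Diversity functions require strictly positive frequencies summing to 1
  (tolerance 1e-6); clonality is undefined for a single clonotype and
  errors rather than returning a sentinel.
* Empty repertoires (no productive reads) propagate as zero-count
  profiles with `NA` indices; `run_sample()` finishes with a `"warning"`
  status instead of failing.
* `d50` uses a strict cumulative threshold (`>= 0.5`); `cf100` sums the
  100 largest frequencies, which makes it invariant to how ties at rank
  100 are ordered.
* The Gaussian length fit reports `R²` between observed proportions and
  the `Normal(mean, sd)` mass integrated over half-integer edges and
  renormalized on the observed support; `sd = 0` yields `NA`.
* All randomness flows through R's RNG; simulator functions accept a
  `seed` and identical seed + parameters give byte-identical FASTQ and
  tables.

## Problem sizes used in the test suite

The suite validates exactness at small sizes and statistical behaviour at
reduced-but-representative sizes, chosen so the whole suite stays quick on
one CPU: aligner-vs-oracle on all substring pairs up to 8 nt (seeded
subsample), pipeline closure at 2,000 clones × 10⁴ error-free reads,
mean-length recovery at 5,000 clones × 2 × 10⁴ reads, rank-test
calibration at 10⁴ null replicates, usage-shift power over 100 simulated
cohorts, and copula recovery over 50 cohorts at 4,000 clones per sample.

## Known limitations

* Only exact unique CDR3aa sequences are counted; no clustering of
  near-identical junctions, no rarefaction or Hill-number extrapolation.
* Reverse-complement search is off by default (`search_revcomp = TRUE`
  enables it) because the simulator and typical pre-processed amplicon
  data are forward-stranded.
* The D-call rule is deterministic but conservative: ties and short
  overlaps return `NA`, so `n_vdj_combos` counts an explicit "no D"
  class.
* The bundled reference supports structure-faithful simulation and
  pipeline validation, not annotation of real biological reads; point
  `load_reference()` at a real germline set for that.
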