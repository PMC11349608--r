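# tcrbrep

End-to-end T-cell receptor beta-chain (TRB) immune-repertoire analysis
from amplicon sequencing reads, written for studies that compare the
CDR3 repertoire of tumor and adjacent normal tissue (the motivating
setting is HBV-associated hepatocellular carcinoma, where the two
tissues turn out to be surprisingly similar).

The package covers the whole chain as composable, pipe-friendly
functions returning tibbles:

* **Read QC** — remove reads with more than 8 ambiguous bases (N) or
  with ≥ 15% of positions below Phred 30.
* **V/D/J annotation** — Smith–Waterman local alignment (match +1,
  mismatch −1, gap −2; Rcpp) against a bundled 58 V / 2 D / 14 J
  germline reference; D genes by longest exact substring match (≥ 5 nt).
* **CDR3 extraction** — the junction from the V segment's second
  conserved cysteine through the J segment's conserved phenylalanine,
  both anchors included, with productivity calling (in-frame, stop-free,
  C...F).
* **Clonotype assembly** — productive reads grouped by
  (CDR3aa, V, J), written/read as AIRR-style Rearrangement TSV.
* **Per-sample statistics** — Shannon entropy `H = −Σ pᵢ ln pᵢ`,
  clonality `1 − H/ln R`, Simpson `Σ pᵢ²`, CF100, D50, CDR3 length
  distribution with Gaussian fit, clonotype counts per frequency decade,
  the 58 × 14 = 812-cell V–J usage matrix, repertoire overlap.
* **Cohort comparison** — Mann–Whitney tests (exact enumeration for
  small samples, tie/continuity-corrected normal approximation
  otherwise) per metric and per gene/family/V–J pair with raw and BH
  p-values, Spearman correlation of diversity with clinical covariates
  (LDH, NLR, ALC) per tissue group, and average-linkage clustering of
  J-family usage with Newick export.
* **A ground-truthed simulator** — generates cohorts (default 13 tumor
  vs 9 normal) with known clone tables, usage shifts (TRBV16 / TRBV7-6
  up in tumor), Gaussian-copula couplings between entropy and clinical
  covariates, sequencing errors, quality models and junk reads, so every
  pipeline stage is testable without controlled-access patient data.

## Worked example

Simulate one sample, run the full pipeline, and look at its diversity
profile:

```r
library(tcrbrep)

ref <- trb_reference()
p <- sim_params(n_clones = 2000L, read_depth = 10000L, seed = 42L)
truth <- sample_clones(p, ref)

dir <- tempfile(); dir.create(dir)
fq <- file.path(dir, "T01.fastq")
emit_reads(truth, p, ref, fastq_path = fq)

cfg <- run_config(ref = ref, out_dir = file.path(dir, "out"))
res <- run_sample(cfg, fq, "T01", "tumor", clinical = list(LDH = 230))

res$repertoire
#> TRB repertoire 'T01' (tumor): 1854 clonotypes, 9732 productive reads
#> # A tibble: 1,854 x 7
#>   cdr3_aa           v_call  j_call  d_call cdr3_nt    count frequency
#> 1 CNISAQTMDFNDEKSYF TRBV5-6 TRBJ2-7 TRBD2  TGCAATA...   259    0.0266
#> 2 CDPDIGWYGLAIKWF   TRBV5-4 TRBJ2-5 TRBD2  TGCGACC...   185    0.0190
#> ...

dplyr::glimpse(res$profile)
#> $ shannon_entropy        <dbl> 6.590879
#> $ clonality              <dbl> 0.1241474
#> $ simpson                <dbl> 0.003372694
#> $ cf100                  <dbl> 0.4235512
#> $ d50                    <dbl> 0.07928803
#> $ n_clonotypes           <int> 1854
#> $ mean_cdr3_len          <dbl> 14.10194
```

Reading the numbers: of 10,000 simulated reads, 9,897 passed QC (31
removed for ambiguous bases, 72 for quality) and 9,732 were productive,
collapsing to 1,854 unique clonotypes. The entropy of 6.59 nats against
`ln(1854) = 7.53` gives a clonality of 0.124 — a moderately skewed
repertoire in which the top 100 clonotypes hold 42% of reads (CF100) and
7.9% of clonotypes cover half the reads (D50). The mean CDR3 length of
14.1 aa matches the junction length model.

Cohort-level analysis takes a metadata table (sample id, group, clinical
covariates, per-sample AIRR paths) and writes the full report set —
diversity comparisons, usage comparisons at family/subfamily/J/pair
level, group-mean V–J matrices with J-family clustering, clinical
correlations, and frequency-region comparisons:

```r
reports <- run_cohort(cfg, metadata)
```

See the methods vignette (`vignettes/tcrb-repertoire-methods.Rmd`) for
the statistical conventions, the simulator's design, and its limits.

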