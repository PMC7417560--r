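---
title: "Designing and verifying junction-spanning shRNAs for circRNA knockdown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying junction-spanning shRNAs for circRNA knockdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circshrna)
```

## The model

An exonic circRNA and the linear mRNA of its host gene are built from the
same exons; the only circle-specific sequence is the back-splice junction
(BSJ), where the 3' end of the circle's last exon is covalently joined to
the 5' start of its first. `circshrna` models the circle as a genomic span
(BED, 0-based half-open) from back-splice acceptor to donor with optional
exon blocks; the mature circle sequence is the strand-aware concatenation
of those exons, read 5'→3' starting at the acceptor, so the junction sits
between the last and first characters of the string.

A knockdown guide is the exact reverse complement of a window of the
circle crossing that junction. Because the window must bridge the
junction, the full window cannot occur contiguously in any linear isoform
of the host gene — that, and nothing else, is the source of specificity.
The residual risks are (i) slicing of other mRNAs through long contiguous
complementarity and (ii) miRNA-like repression through seed matches in 3'
UTRs; the package quantifies both and screens differential-expression
(DE) tables for their footprints.

All sequences are stored as uppercase DNA (U→T at input boundaries);
"complementary" always means contiguous Watson–Crick pairing with no G:U
wobble and no gaps, so a k-base complementary stretch between guide and
transcript is exactly a shared k-substring between the guide's reverse
complement (the target-sense sequence) and the transcript.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `guide_length` | 21 | nt | the junction-spanning hairpin length used with miR-1-scaffold shRNA vectors |
| `min_overhang` | 5 | nt | no published minimum junction overlap exists; 5 nt on each side keeps every emitted guide anchored across the BSJ while still permitting the ±-shifted alternates. Configurable. |
| `context_width` | 30 | nt | circle sequence taken per side of the junction; only needs to exceed `guide_length` |
| `shift` | +3 | nt | the published alternate design steps the window 3 nt toward the target 3' side |
| `min_len` (scan) | 12 | nt | shortest contiguous complementarity reported to suffice for slicing (12–13 nt) |
| seed window | 2–8 | nt | canonical miRNA seed; the source protocol does not define its window, so the canonical 7-mer is used |
| `bin_step` | 50 | genes | leading-bin increment of the enrichment landscape; not stated in the source protocol, chosen at typical landscape resolution. Configurable. |
| `alpha` | 0.05 | — | enrichment verdict level, Bonferroni-corrected |
| `fc_threshold`, `p_threshold` | 1.5, 0.05 | — | transcriptome characterisation: linear fold change > 1.5 (as magnitude) and **raw** p < 0.05 |
| `ot_log2fc_threshold`, `ot_padj_threshold` | 1, 0.05 | — | off-target calls: \|log2FC\| > 1 and **adjusted** p < 0.05 |

Two deliberately distinct threshold sets coexist because the protocol this
package operationalises applies them in different roles and never
reconciles them; unifying them would silently change one screen or the
other. Inequalities are strict (`>`/`<`) exactly as printed.

## Design choices where the design was open

* **Centring tie-break.** A 21-nt window cannot be centred exactly on the
  junction; the extra base goes to the 5' (upstream-of-junction) side,
  giving the 11|10 primary split. The choice is arbitrary but fixed, so
  default designs are reproducible.
* **Passenger strand.** The passenger ("star") strand is modelled as the
  exact reverse complement of the guide (a blunt duplex). Real
  miR-scaffold processing imposes 2-nt overhangs, but the scaffold
  sequence is not available to this package; the star seed used in
  enrichment scans derives from this modelled passenger and is therefore
  an approximation.
* **Host-linear safety.** A design is flagged `host_linear_risk` when its
  longer side alone reaches the slicing threshold (default 12 nt), since
  that side is a contiguous match to the linear host mRNA. The flag is a
  warning, not a rejection: the published +3-shifted design (8|13) itself
  triggers it.
* **Enrichment statistic.** Published ranked-list word-enrichment tools
  correct for word composition via Markov background models. This package
  uses gene-level *presence* of the seed site in the 3' UTR and a plain
  hypergeometric tail: exactly testable against enumeration, at the price
  of composition-bias blindness (see limitations). The deviation is
  deliberate and this is the prominent notice.
* **Verdict restriction.** Only leading bins lying entirely within the
  downregulated part of the ranking (bin edge ≤ number of genes with
  log2FC < 0) are tested, because guide-mediated off-targeting represses:
  enrichment among upregulated genes is the wrong tail. The Bonferroni
  factor counts tested bins × seeds; bins never tested are not corrected
  for.
* **Gene-level UTR.** When a gene has several transcripts, the longest 3'
  UTR represents it in seed scans (ties by transcript id). Transcripts
  with no annotated CDS contribute their full sequence, flagged and
  counted, rather than being silently dropped — fly-style annotations
  vary and dropping them would blind the scan.
* **`not_testable` is a status, not a removal.** Genes with padj = NA
  (as DESeq2 emits for low counts or Cook's-distance outliers) appear in
  verdict tables and report counts, keeping the off-target audit complete.
* **No efficacy modelling.** GC content, thermodynamic asymmetry and
  hairpin folding are out of scope: the screen ranks nothing beyond
  off-target evidence.

## Numerical notes

* Hypergeometric tails are computed in log space via `stats::phyper`; the
  test suite verifies agreement with exhaustive subset enumeration for all
  N ≤ 12 to better than 10 significant digits, and the worked example
  P[X ≥ 3] = 66/252 for (N, K, n) = (10, 4, 5) to 1e-12.
* The landscape at bin size N is identically 0 (the draw is the whole
  universe), as is any landscape for a word no gene carries (K = 0); both
  fall out of the tail definitions rather than being special-cased.
* The off-target scanner is a k-mer (k = `min_len`) seed-and-extend over
  each transcript with bidirectional maximal extension and deduplication;
  every maximal shared substring of length ≥ k contains a k-seed, so the
  scan is exact. The quadratic DP longest-common-substring routine is kept
  in the package as the independent oracle and the tests hold the two
  routes equal on hundreds of random pairs.
* Degenerate inputs fail loudly with the offending item named: FASTA
  parse errors carry line numbers, BED spans with end ≤ start and missing
  strands are rejected, circles shorter than 2 × `context_width` get an
  error suggesting the largest feasible width, and infeasible shifts get
  the feasible shift range.

## What the synthetic data emulates — and what it does not

The fixture generators are pure functions of a `fixture_spec` (single
integer seed; byte-identical outputs; global RNG untouched). They emulate:

* a circRNA locus whose host transcript has flanking exons beyond the
  circularised ones, on either strand, with the junction-spanning windows
  verified absent from the linear mRNA (rejection-sampled);
* transcriptomes with planted complementarity stretches of exact lengths
  (flanks rejection-sampled so the planted length is also the DP-maximal
  length) over i.i.d. uniform-composition background;
* DE tables with exact planted (log2FC, padj) and Normal(0, 0.2)/Uniform
  nulls — null genes essentially never cross the |log2FC| > 1 call line;
* rankings with seed sites planted at a top rate (default 0.6 in the top
  100 of 2000) versus background (0.05), all other UTRs rejection-sampled
  site-free so presence equals the planted truth exactly.

They do **not** emulate: realistic codon/UTR composition or repeat
structure (so k-mer abundance biases that motivate composition-corrected
enrichment statistics are absent), count-level noise or dispersion (DE
tables are consumed, never fitted), isoform diversity, or read-level
artefacts. A green suite therefore establishes algorithmic correctness on
a stated world — exact thresholds, exact statistics, exact bookkeeping —
not robustness to the composition biases of a real transcriptome.

## Known limitations

* No G:U wobble or gapped/bulged duplexes in the complementarity scan; if
  slicing tolerates such imperfections, the scan undercounts.
* The presence-based hypergeometric is less powerful than
  composition-corrected landscape statistics when UTR base composition
  correlates with expression change.
* The passenger-strand seed is approximate (blunt-duplex model, above).
* Cloning adapters for hairpin oligos are reduced to configurable strings;
  no vector sequence is bundled.
* The DE model itself (dispersion estimation, shrinkage, outlier
  handling) is upstream of this package: verdicts inherit whatever the DE
  tool decided, including its padj = NA policy.
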