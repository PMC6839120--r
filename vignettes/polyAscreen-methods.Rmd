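---
title: "Screening long-read poly(A) sites for template-switching artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening long-read poly(A) sites for template-switching artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAscreen)
```

## The problem

Long-read cDNA sequencing reads through a transcript into its poly(A)
tail, so the genomic position where the aligned part of a polyadenylated
read ends is a direct estimate of the cleavage/polyadenylation site.
Two reverse-transcription artifacts corrupt this signal:

* **Internal priming** — the oligo-d(T) primer anneals to an A-rich
  stretch inside the transcript, creating a false 3' end with a
  primer-length tail. Classical filters look for at least 6 consecutive
  As, or at least 12 As in the 20 nt upstream of a called site.
* **Template switching (TS)** — the polymerase dislocates from its
  template and reinitiates on a homologous sequence. Because the
  poly(A) tail is the most abundant template in the library, TS
  produces spurious polyadenylated ends wherever the genome offers even
  a short A stretch — including loci with only 3–5 As, far below the
  classical internal-priming thresholds. These artifacts carry
  full-length tails and pile up at a single nucleotide, so neither tail
  length nor window A content separates them well.

`polyAscreen` calls candidate poly(A) sites from cDNA alignments and
classifies each as a genuine transcript end site (TES) or a TS
artifact, with the classical filters and a direct-RNA (dRNA)
confirmation framework alongside for comparison.

## Site detection

All coordinates are 1-based inclusive internally, the native convention
of the R/Bioconductor stack the package builds on (BED output is
0-based half-open). A read's 3' end is its rightmost aligned base on
the forward strand and its leftmost on the reverse strand; its poly(A)
evidence is a dense A start in the 3' soft clip (at least 10 As in the
first 11 clip bases, configurable — long-read basecalls are noisy
enough that demanding a perfect run would discard genuine tails).

A genomic position becomes a candidate site when at least **2**
poly(A)+ reads end exactly there and those ends are at least **0.1%**
of the same-strand reads overlapping the position. Within any 21-nt
window only the position with the most poly(A)+ ends survives; ties
break toward the transcript-3'-most position (cleavage heterogeneity
makes the most-downstream position the conventional site summary). A
site is *high-confidence* when more than 10 poly(A)+ reads end in its
21-nt window.

## The A-count

The upstream A-richness measure is a halting counter rather than a
plain window count. Walking the 20 nt upstream of the site (strand
aware, site excluded, proximal base first), the counter starts at 0,
gains 1 per A and loses 1 per non-A (N counts as non-A, a conservative
choice); iteration halts when the counter reaches −1. The A-count *n*
is the maximum counter value observed, so `CCCC…` scores 0 (immediate
halt) and `AACAACCGTAAA…` scores 3 (the trailing As are never
reached). This weights As adjacent to the site — the ones a tail can
anneal or switch to — while still seeing the broader window.

## The classifier

A site with *n* < 3 is accepted as a TES outright — the same 3-A
threshold that marks an individual read end as "A-rich" when a run of
at least 3 As begins within 3 nt upstream of the read's end. A site at
an A-rich locus (*n* ≥ 3) is accepted as a TES when **either**

1. more of the poly(A)+ reads ending in its 21-nt window end at
   non-A-rich genomic positions than at A-rich ones (genuine cleavage
   is dispersed, so some of its reads end clear of the A patch), **or**
2. the fraction of overlapping reads ending in the window exceeds

$$\frac{0.8}{1 + 2^{-100\left(\frac{1}{20 - n} - 0.08\right)}},$$

a logistic threshold that rises steeply with *n* and saturates at 0.8;
at *n* = 20 the singular point is defined by its limit, 0.8. Genuine
minor isoform ends are used by a modest but consistent fraction of the
local transcripts, whereas TS ends are rare events relative to
coverage, so demanding a higher proportion at more A-rich loci trades
the two errors explicitly.

Sites failing both criteria are TS artifacts. Two post-passes follow:
a site whose 21-nt window holds at least **100-fold** more
opposite-strand 5' ends than same-strand poly(A)+ 3' ends is forced to
artifact (antisense TS mirrors a true end onto the other strand), and
artifacts within **50 nt** of a TES (same strand, inclusive) are
relabeled `EXCLUDED` so TES-derived features — its PAS, nearby dRNA
ends — cannot contaminate the artifact class in downstream
comparisons. When several experiments cover the same locus, discordant
calls resolve to TES: a site genuinely used in any experiment is an
end site. The merged record takes its position from the experiment
with the greatest window support, ties again 3'-most.

## Validation against dRNA and the baseline filters

Native RNA sequencing cannot read through the terminal tail, so every
dRNA read end is counted without any poly(A) requirement. A site is
dRNA-confirmed when at least **0.5%** (inclusive) of the same-strand
dRNA reads overlapping it end within its 21-nt window; zero overlap
never confirms. Filters are compared by PPV (confirmed fraction of
kept sites) and NPV (unconfirmed fraction of discarded sites), overall,
for high-confidence sites only, and stratified by A-count (bins 0–9
and a merged "≥10"). Empty denominators report `NA`, not 0.

The baselines: internal priming discards on a ≥6-A run or ≥12/20 As
upstream; the SQANTI-style rule discards above 80% upstream A content,
i.e. at ≥17/20 (the smallest integer count strictly above 80%), so its
kept set always contains the internal-priming kept set; the database
rule keeps only sites with a same-strand database entry within 10 nt
(strandedness is required — poly(A) sites are stranded, even though
some database dumps omit it).

## Sequence features

**PAS detection.** The 12 most common human polyadenylation-signal
hexamers (AATAAA first) are searched, exact-match only, in the 40 nt
upstream of each site. Among hits the most common motif wins; among
equal-rank hits the one whose 3'-end-to-site distance is closest to
the canonical 25 nt wins (the package's own tie-break; a further tie
takes the smaller distance).

**Tail length.** Per read, the last 30 aligned bases plus the first
150 soft-clip bases are aligned locally (Smith–Waterman) against a
stretch of 180 As with match +2, mismatch −3 and gap −3. Against a
homopolymer target no optimal alignment contains a gap — skipping a
target A costs 3 for no gain, and deleting a query base costs the same
as mismatching it — so a linear −3 per-base gap cost is score-identical
to affine opening/extension of −3, and the package scores gaps
linearly. The tail length is the number of A characters of the query
inside the best alignment: mismatched bases are tolerated inside the
alignment (robust to read errors) but not counted. Where the mapped 3'
terminus is itself A-rich the measure can absorb genomic As and
overestimate; this is inherent to the definition and documented rather
than corrected.

**Profiles.** Nucleotide composition is tabulated over ±50 nt around
each site (Ns excluded from the denominator) and the distribution of
read-end offsets over ±10 nt around high-confidence sites is averaged
per class — genuine cleavage shows dispersion, TS a point mass.

## The synthetic study

The simulator generates the conditions the classifier is built for, on
a 60 kb random genome (G+C 0.5): **40 TES**, **30 TS-artifact loci**
with exact upstream A-counts of 3–5, and **10 internal-priming loci**
(13 proximal As), alternating strands, ≥200 nt apart so the 50-nt
exclusion stays controllable. cDNA coverage is ~**100×** per locus and
dRNA ~**50×**.

Choices the simulator makes, and why:

* Poly(A)+ support per locus averages **12 reads** (floor 2) over the
  ~100× background — site usage around 10% of local coverage, the
  low-proportion regime in which TS filtering is actually hard; at
  high usage fractions criterion 2 makes the call trivially.
* Genuine cleavage positions get Normal(0, **2 nt**) dispersion;
  artifact reads end at a single position. The cleavage base itself is
  non-A (cleavage canonically occurs at a CA-style dinucleotide),
  which also keeps the planted upstream window stable under that
  dispersion.
* TES and TS reads draw tails from one Normal(**50**, **15**) nt
  distribution (truncated at 5) — TS artifacts copy genuine tails, so
  tail length carries no signal; IP tails are primer-length
  (Normal(20, 2)). Typical nanopore cDNA tail estimates sit near
  50 nt.
* A fifth of the TESs (`tes_arich_frac = 0.2`) sit in windows that are
  classically A-rich (a ≥12/20, ≥6-run window behind a 3-base non-A
  shield, A-count 0). These are the genuine sites the window-count
  filters wrongly discard; without them the qualitative PPV/NPV
  contrast between the TS filter and the internal-priming baseline
  cannot manifest in a clean fixture.
* Every TES gets AATAAA planted with its 3' end 25 nt upstream;
  artifact loci get none, so their PAS rate is the random-hexamer
  background.
* dRNA reads terminate (±2 nt) only at genuine TESs; all loci receive
  read-through dRNA coverage whose 3' ends fall 40–150 nt downstream,
  outside every confirmation window, so the confirmation denominator
  is exercised at artifact loci too.
* Reads are error-free: the classifier consumes alignments, not
  signal, and error-free reads keep every planted property sharp.
  Real data add basecall noise in the clip (softened only by the
  poly(A)-evidence rule), alignment wobble around A stretches, and
  expression heterogeneity — so passing tests demonstrate the logic,
  not performance on any particular real library.

Test sizes: the end-to-end suite runs this 80-locus fixture once
(~9,000 cDNA and ~7,000 dRNA reads, a few seconds to simulate and
under half a minute to screen). The tail-median comparison between the
TES and TS classes is made on a variant with ~2,000 measured reads per
class, the sampling size at which an integer median resolves well
inside the 2-nt comparison band; at ~450 reads per class the median's
sampling error alone (~1 nt) would dominate the comparison.

## Numerical and boundary conventions

* All stated thresholds are inclusive exactly as written: ≥2 reads,
  ≥0.1%, ≥0.5%, ≥100-fold, ≤50 nt; high confidence is strictly >10.
* The logistic threshold at *n* = 20 is the limit 0.8; *n* outside
  [0, 20] is an error.
* Window-maximum and merge tie-breaks: highest support, then
  transcript-3'-most.
* A site with zero overlapping reads cannot be classified (it cannot
  have been detected); classifying one is an error, not a default.
* Upstream windows truncate at contig boundaries; composition windows
  pad with N, which drops out of the denominators.

## Limitations

* The classifier inherits the resolution of the aligner's soft-clip
  placement; systematic clip misplacement around genomic A runs shifts
  both site positions and A-counts.
* The opposite-strand rule needs antisense coverage to fire; on
  strand-specific sparse data it is inert.
* Tail length is overestimated where the mapped 3' terminus is A-rich
  (see above).
* PPV/NPV against dRNA are estimates, not truth: low dRNA/cDNA
  coverage ratios depress PPV and inflate NPV estimates for every
  filter, which is why filter comparisons should be read as orderings
  rather than absolute accuracies.

## A worked run

```{r example, eval = FALSE}
bundle <- simulate_polya_run(sim_config(seed = 7), dir = "fixture")
screen <- screen_polya_sites(c(run1 = bundle$paths[["cdna"]]),
                             bundle$paths[["genome"]],
                             drna_bam = bundle$paths[["drna"]])
print(screen)
features <- run_features(screen, load_genome(bundle$paths[["genome"]]))
features$tail_distribution$summary
```
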