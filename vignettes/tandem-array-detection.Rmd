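---
title: "Detecting tandem gene arrays by vicinity translated-similarity search"
author: "TandemArrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem gene arrays by vicinity translated-similarity search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the idea

Tandem gene arrays (TGAs) are runs of contiguous paralogous gene copies
on a chromosome. Most catalogs of tandem duplicates are built from
all-against-all protein comparisons of *annotated* genes, which by
construction cannot see copies that have degenerated past annotation:
gene relics riddled with premature stops, frameshifts and truncations.
This package takes the opposite route: instead of comparing proteins to
proteins, it asks, for every annotated CDS, *does the DNA next to this
gene still resemble the gene itself?* Translated similarity between a
CDS protein and its own chromosomal vicinity reveals neighbouring
copies whether or not they are annotated, intact, or even open reading
frames.

The package is aimed at compact genomes — prokaryotes and unicellular
eukaryotes with ~1.4 kb genes at ~one gene per 2 kb, few and short
introns, and no alternative splicing. In large intron-rich genomes the
flanking windows would mostly contain intergenic and intronic DNA and
the statistics below would need re-tuning.

## The score

For a CDS of spliced length $L$, two flanking windows of length
$\max(3L,\; 1500\,\mathrm{bp})$ are taken immediately upstream and
downstream of its outermost genomic coordinates. The CDS protein is
aligned locally against all six reading frames of each window
(Waterman–Eggert multi-HSP search, BLOSUM62, affine gaps 11/1). Raw
scores become bit scores through the Karlin–Altschul transform
$S' = (\lambda S - \ln K)/\ln 2$ with the published gapped BLOSUM62
statistics $\lambda = 0.267$, $K = 0.041$; HSPs with
$E = mn\,2^{-S'} > 1$ are discarded, where $m$ is the protein length in
residues and $n$ the window length in bp.

Per window and strand, the **TB score** is the sum of bit scores of all
HSPs that do not overlap by more than 20% (greedy selection in
decreasing bit-score order; overlap is measured on the protein axis as
a fraction of the shorter span — the subject axis would double-count
tandem copies, which legitimately hit the same query region twice).
Four TB scores per CDS (upstream/downstream × plus/minus) are divided
by the **TB self-score** — the same aggregate of the protein against
its own coding sequence — and expressed as percent of self. The two
strands of one window are then differenced, $F_+ = X - Y$ and
$F_- = Y - X$, cancelling compositional signal (low-complexity DNA
scores on both strands; a real gene copy scores on one). These are the
four **FTB scores**; per side one is $\ge 0$ and the other is its
negative.

Small proteins have small self-scores and therefore noisy
percent-of-self values, so when the self-score is below 250 bits, any
FTB score strictly between 0 and 50 is reduced by
$(250 - \text{self})/4$. The filter acts per score, never increases a
value, and never touches scores $\le 0$ or $\ge 50$.

Stop codons translate to `*` and score $-4$ against every residue, so
an alignment can run straight across the premature stops of a relic —
this is what makes relic detection work at all.

## Array assembly and relic tags

CDSs are walked in coordinate order. Two CDSs are *adjacent in tandem*
when the earlier one's downstream side and the later one's upstream
side are both significant (FTB $\ge$ threshold, default 10; the useful
range is 10–15). Arrays are maximal runs of adjacency: a CDS adjacent
to its successor and not to its predecessor opens a TGA, adjacency
extends it, and it closes at the last adjacent CDS. One heterologous
spacer gene is allowed between two homologous members (adjacency is
probed at rank gaps 1 and 2; the direct link is preferred).

A CDS with a significant score but no adjacency receives a *relic tag*:
the similarity points into DNA that carries no annotated partner. Array
edge members with an additional outward significant score are tagged
too (their S1/S4 flank scores exceed the threshold — candidate arrays
that begin or end with a relic). Per TGA, S1 is the outward upstream
FTB score of the first member, S4 the outward downstream score of the
last, and each homologous pair carries its facing S2/S3 scores.

Orientation classes come from annotated strands, pairwise in coordinate
order: `(+,+)` direct sense, `(-,-)` direct antisense, `(+,-)` opposite
convergent, `(-,+)` opposite divergent; an array mixing direct and
opposite pairs is `mixed`. For a relic partner the strand is inferred
from the window strand the similarity was found on.

## Curation

Three mechanised screens replace what would otherwise be manual review:

1. **Tag merging.** Isolated tagged CDSs whose significant scores face
   each other across at most one spacer become a new TGA (this matters
   mostly when the spacer allowance is disabled during extraction).
2. **Relic confirmation.** Each remaining tag is checked by DNA
   dotplot: the CDS's genomic sequence against the flanking window its
   score points at, both window orientations, sliding window 23 with
   stringency 15. A diagonal run of at least 30 dots lying at least
   50% outside annotated CDSs confirms a relic (a 1CDS-relic TGA, or a
   relic member appended to an array edge, class nCDSs-relic);
   otherwise the tag is rejected. The run length of 30 is this
   package's own default for what counts as a sustained diagonal
   rather than background speckle.
3. **Pair verification.** Every adjacent CDS pair of every TGA must
   show a diagonal run of $\ge 30$ dots in a *protein* dot matrix
   (window 23, stringency 5 — the classic protein dot-matrix settings).
   The full-sensitivity aligner used here reports every HSP with
   $E \le 1$, and three or four coincidental 20-bit HSPs summed over a
   window can push a mid-sized protein past FTB 10; when two such
   noise scores happen to face each other, a false array appears.
   Genuinely paralogous pairs pass this screen down to very low
   identity (at 23/5 even 30% identical proteins dot densely), while
   noise pairs have no sustained diagonal. Failing bonds are cut and
   fragments with fewer than two homologous members are dropped.

Finally every member CDS is scanned for **minisatellites**
(intragenic tandem repeats, confirmed unit 10–300 bp): a quick
autocorrelation pass (lags up to 600, best match-run $\ge 20$)
proposes unit sizes and a consensus scorer (matches minus mismatches
against the column-majority consensus, whole copies, no gaps)
confirms the best block. An array with internal repeats is flagged;
it is *rejected* only if, after masking the repeat spans with N, the
re-scored facing FTB scores of every pair fall below the threshold —
i.e. the shared repeat was the only thing holding it together. The
masked re-score keeps the original self-score as normaliser so that
masking can only lower a score. Gapped repeat units are not modelled;
the consensus scorer is a definition of its own and does not claim
equivalence with the EMBOSS tools it replaces.

## The synthetic test bed

`generateGenome()` plants known structure in an otherwise random
compact genome and records the truth: background genes drawn by codon
sampling from a yeast-like amino-acid composition (mean length 1.38 kb,
gamma-distributed, truncated to 0.3–3 kb; single exon by default, an
optional mode inserts one short intron); intergenic gaps gamma with
mean 620 bp (one gene per ~2 kb). Planted families are copies of one
founder diverged by codon-level substitutions to a target protein
identity (nonsynonymous swaps to the target, plus synonymous-biased
extra substitutions so DNA identity drops below protein identity);
relics are diverged copies degraded with premature stops, frameshift
deletions and optional 3'-truncation until no stop-free stretch reaches
half the original length, then planted *without annotation* next to
their host.

Two generator choices matter for interpreting the tests:

* **Array-internal spacing.** Gaps between members of one planted
  array are drawn from 150–600 bp, tighter than the background
  distribution. Tandem duplication copies lie closer together than
  average gene spacing, and the method by definition cannot link
  copies separated by more than its window length — with Lmin = 1500
  bp, a 500 bp gene cannot see across a 1.6 kb gap. Heavy-tailed
  internal gaps would therefore plant arrays the score is defined not
  to see — copies farther apart than the window reach are the
  vicinity search's intrinsic false-negative mode.
* **Orientation.** Member strands are drawn per array — 2-CDS arrays
  from the four orientation classes (direct ~80%), larger arrays on
  one common strand. A middle copy flanked by homologs on *both*
  strands of one window has $X \approx Y$ and its FTB scores cancel:
  alternating-strand arrays are a structural blind spot of the
  strand-differenced score itself, and real arrays are overwhelmingly
  direct.

What passing tests show, and what they do not: recovery, orientation
and relic-confirmation rates on these genomes exercise every step of
the pipeline under realistic sizes, densities and divergences, but the
background is homology-free by construction. Real genomes add
dispersed paralogs in flanking windows, transposons, segmental
duplications and compositional biases that the codon sampler does not
emulate; on real data a much larger fraction of relic tags are
false positives and curation does correspondingly more work.

## Numerical and procedural choices

* Coordinates are 1-based inclusive GRanges/IRanges everywhere;
  external GFF3/TSV use the same convention, so nothing shifts.
* Window length uses the *spliced* CDS length; the excluded span uses
  the outermost genomic coordinates (introns excluded from length,
  included in the span). Flagged as a sensitivity point for
  intron-rich genes.
* Upstream/downstream are chromosomal directions, not gene-orientation
  directions; since both window strands are searched, the two readings
  are observationally equivalent.
* $\lambda$ and $K$ are fixed at the published gapped BLOSUM62/11/1
  values, not re-estimated per genome; the E-value uses plain
  $m \times n$ with no finite-size correction. Gap costs and the
  statistical parameters are assumptions surfaced in
  `alignParams()`.
* The filter applies per score, only to values in $(0, 50)$, exactly
  as the condition reads; negative scores are never filtered.
* Greedy HSP selection processes HSPs in decreasing bit-score order
  with deterministic tie-breaks (query start, then subject start);
  for configurations where no pair overlaps more than 20% it equals
  the exhaustive optimum, and it never exceeds it.
* The genetic code is configurable per genome (NCBI table 12 for
  CUG-Ser clade species); translation renders ambiguous codons as X,
  which scores like BLAST's X and cannot create spurious positives in
  all-N windows.
* Arrays are never auto-merged across more than one spacer; the
  automaton is a single deterministic left-to-right pass, and a CDS
  adjacent on both sides takes a middle position rather than splitting.
* Whether the in-pass spacer allowance and the post-hoc tag merging
  are one mechanism or two is ambiguous in the source description;
  both are implemented and individually switchable
  (`allowSpacer`, `mergePairs`).

## Problem sizes

The bundled validation (`scripts/acceptance.R` and the acceptance test
file) runs twenty 100-gene genomes of ~200 kb each — planted arrays of
sizes 2–5 at 80–100% identity, a one-spacer case and an intergenic
relic per genome — plus the formula, oracle-equivalence and
repeat-scoring checks. One genome takes roughly 20 s end to end on one
CPU; the full study runs in under ten minutes.

## Known limitations

* Heuristic-free alignment is more sensitive than seeded TBLASTN:
  marginal HSP sums make isolated tags common (curation removes them,
  but pre-curation tag counts are not comparable between engines).
* Alternating-strand arrays self-cancel (see above).
* Copies separated by more than one spacer, or by more DNA than the
  window length, are invisible by design; a disrupted large array
  appears as several smaller ones.
* The consensus repeat scorer has no gaps, so minisatellites with
  indel-diverged units may be under-scored.
* Identity targets below ~30% are outside the generator's contract,
  and the score itself degrades smoothly there (BLOSUM62 local
  alignments of <30% identical proteins often fragment).
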