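# TandemArrays

Genome-wide prediction of **tandem gene arrays (TGAs)** — runs of
contiguous paralogous gene copies — in compact genomes (prokaryotes,
unicellular eukaryotes), including arrays whose members have
degenerated into unannotated **gene relics**.

## Who it is for and what it does

Catalogs of tandem duplicates are usually built by all-against-all
protein comparison of annotated genes, which cannot see copies that
have decayed past annotation (premature stops, frameshifts,
truncations). TandemArrays instead searches, for every annotated CDS,
for *translated similarity in the DNA flanking that CDS*: a
neighbouring copy shows up whether it is an intact gene, a pseudogene,
or a relic that no longer forms an open reading frame.

The decision statistic is the **FTB score**. For a CDS of spliced
length *L*, two windows of length max(3 *L*, 1500 bp) immediately
upstream and downstream are searched with the CDS protein
(Waterman–Eggert multi-HSP local alignment, six frames, BLOSUM62,
gaps 11/1, Karlin–Altschul bits with λ = 0.267, K = 0.041, E ≤ 1).
Per window and strand, bit scores of HSPs that do not overlap by more
than 20 % are summed into a **TB score**; dividing by the protein's
**TB self-score** and differencing the two strands of one window
(X − Y and Y − X, cancelling low-complexity noise) gives four FTB
scores per CDS, in percent-of-self units. Small proteins
(self-score < 250 bits) have FTB scores in (0, 50) reduced by
(250 − self)/4.

CDSs whose FTB profiles face each other (one's downstream and the
next one's upstream side ≥ 10) are assembled into arrays by a single
left-to-right pass, allowing one heterologous spacer gene. Isolated
significant scores tag candidate relics, confirmed or rejected by DNA
dotplot (window 23, stringency 15, diagonal ≥ 30 dots, ≥ 50 % outside
annotated CDSs); every array pair is verified on a protein dot matrix
(23/5); members are screened for minisatellites (equicktandem- and
etandem-style scanning, reimplemented) and arrays held together only
by a shared repeat are rejected after masked re-scoring.

A synthetic-genome generator with a machine-readable truth ledger
(planted families at controlled divergence, spacers, relics,
minisatellites, all four pair orientations) is part of the package
and drives its validation.

## Worked example

```r
library(TandemArrays)

## a 100-gene synthetic genome with planted arrays (sizes 2-5),
## a spacer case, and an intergenic gene relic
sim <- generateGenome(defaultSynthConfig(seed = 7))
res <- predictTgas(sim$genome)
res$tgas
#> TgaSet: 6 TGA(s), 17 member CDS, 1 relic(s), 1 tagged CDS, threshold 10
#>   size classes: 1CDS-relic=1 2CDS=2 3CDS=1 4CDS=1 5CDS=1
#>   orientations: direct_antisense=3 direct_sense=2 opposite_convergent=1
```

All six planted structures are recovered: the four plain arrays, the
spacer-containing pair, and the relic — reported as a `1CDS-relic`
TGA whose relic member carries the intergenic interval where the
dotplot diagonal was found. The summary and the per-pair facing
scores (S2/S3, in percent of self-score; ~80–100 here because the
planted copies are 80–100 % identical):

```r
res$summary
#> CDS: 100, in TGAs: 17 (17.0%), TGAs: 6, with relic: 1
head(as.data.frame(flankScores(res$tgas)$pairs), 4)
#>   tga_id    a_id    b_id       s2       s3
#> 1 TGA001 CDS0011 CDS0012 80.48723 83.13766
#> 2 TGA002 CDS0022 CDS0023 82.48180 80.83048
#> 3 TGA002 CDS0023 CDS0024 65.51488 79.68090
#> 4 TGA003 CDS0038 CDS0039 92.86150 99.23466
```

Real genomes go in as FASTA plus GFF3 (or a simple 4-column TSV):

```r
g  <- readAnnotatedGenome("genome.fasta", "annotation.gff3",
                          geneticCode = "12")   # CUG-Ser clade
res <- predictTgas(g)
writeTgaTables(res$tgas, "out/")
```

A thin command-line driver wraps the same functions:

```sh
Rscript inst/scripts/tandemscan.R extract \
    --fasta genome.fasta --annotation annotation.gff3 --out out/
Rscript inst/scripts/tandemscan.R simulate --seed 7 --out sim/
Rscript inst/scripts/tandemscan.R sweep \
    --fasta genome.fasta --annotation annotation.gff3   # factors x thresholds
```

The methods vignette (`vignettes/tandem-array-detection.Rmd`)
describes the score, the extraction automaton, the curation screens,
what the generator does and does not emulate, and every numerical
default.

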