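test_that("translated search recovers the hand-scored BLOSUM62 example on both strands", {
  p <- alignParams()
  h <- searchWindow("MKL", "ATGAAACTG", p)
  top <- h[1, ]
  expect_equal(top$raw, 14)  # M/M 5 + K/K 5 + L/L 4
  expect_equal(top$strand, "plus")
  expect_equal(c(top$s_start, top$s_end), c(1, 9))

  hrc <- searchWindow("MKL", "CAGTTTCAT", p)
  expect_equal(hrc$raw[1], 14)
  expect_equal(hrc$strand[1], "minus")
})

test_that("reverse-complementing the window swaps strands with identical scores", {
  set.seed(21)
  gene <- toyGene(60)
  prot <- substr(TandemArrays:::fastTranslateChr(gene, "1"), 1, 58)
  win <- paste0(toyDna(200), gene, toyDna(200))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  h1 <- searchWindow(prot, win)
  h2 <- searchWindow(prot, rc)
  expect_equal(sort(h1$raw), sort(h2$raw))
  swap <- c(plus = "minus", minus = "plus")
  expect_equal(table(unname(swap[h1$strand])), table(h2$strand))
})

test_that("every reported HSP respects the E-value threshold", {
  set.seed(22)
  prot <- substr(TandemArrays:::fastTranslateChr(toyGene(120), "1"), 1, 100)
  for (rep in 1:5) {
    h <- searchWindow(prot, toyDna(1500))
    if (nrow(h)) expect_true(all(h$evalue <= 1.0))
  }
  # degenerate all-N window: nothing to report
  expect_equal(nrow(searchWindow(prot, strrep("N", 600))), 0)
})

test_that("an exact in-frame copy is recovered nearly full length", {
  set.seed(23)
  gene <- toyGene(150)
  prot <- TandemArrays:::fastTranslateChr(gene, "1")
  prot <- sub("\\*$", "", prot)
  win <- paste0(toyDna(400), gene, toyDna(400))
  h <- searchWindow(prot, win)
  cover <- h$q_end[1] - h$q_start[1] + 1
  expect_gte(cover / nchar(prot), 0.95)
})

test_that("bit scores follow the Karlin-Altschul transform and are monotone", {
  p <- alignParams()
  expect_equal(bitScore(0, p), -log(0.041) / log(2), tolerance = 1e-10)
  expect_equal(round(bitScore(0, p), 2), 4.61)
  expect_equal(round(bitScore(14, p), 2), 10.00)
  expect_gt(bitScore(20, p), bitScore(14, p))
  # E-value decreases as bit score grows at fixed lengths
  ev <- TandemArrays:::hspEvalue(c(14, 20, 30), 100, 1000, p)
  expect_true(all(diff(ev) < 0))
})

test_that("TB aggregation follows the 20%-overlap rule", {
  mk <- function(qs, qe, bits)
    data.frame(q_start = qs, q_end = qe, s_start = 1, s_end = 3,
               strand = "plus", frame = 0, raw = 0, bits = bits,
               evalue = 0.1)
  # disjoint: plain sum
  expect_equal(aggregateTb(rbind(mk(1, 50, 30), mk(60, 100, 20))), 50)
  # 50% of the shorter span overlapping: the weaker one is culled
  expect_equal(aggregateTb(rbind(mk(1, 50, 30), mk(41, 60, 20))), 30)
  # exactly 20% overlap: both kept ("more than 20%" is the cutoff)
  expect_equal(aggregateTb(rbind(mk(1, 50, 30), mk(46, 70, 20))), 50)
  expect_equal(aggregateTb(mk(1, 10, 5)[0, ]), 0)
})

test_that("single-HSP raw scores agree with pairwiseAlignment as oracle", {
  set.seed(24)
  p <- alignParams()
  mat <- TandemArrays:::scoringMatrix(p)
  for (rep in 1:5) {
    gene <- toyGene(80)
    div <- mutateCopy(Biostrings::DNAString(gene), 75)
    prot <- sub("\\*$", "", TandemArrays:::fastTranslateChr(gene, "1"))
    subj <- sub("\\*$", "",
                TandemArrays:::fastTranslateChr(as.character(div$dna), "1"))
    h <- searchWindow(prot, as.character(div$dna), p)
    ora <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot), Biostrings::AAString(subj),
      type = "local", substitutionMatrix = mat,
      gapOpening = p@gapOpen, gapExtension = p@gapExtend)
    expect_equal(h$raw[1], BiocGenerics::score(ora))
  }
})
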