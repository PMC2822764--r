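test_that("FTB scores are the strand-differenced percent-of-self values", {
  f <- computeFtb(100, 40, 10, 0, 0)
  expect_equal(f$f_up_plus, 30)
  expect_equal(f$f_up_minus, -30)
  f2 <- computeFtb(100, 25, 25, 25, 25)
  expect_equal(f2$f_up_plus, 0)
  expect_equal(f2$f_down_minus, 0)
  # antisymmetry for arbitrary inputs
  set.seed(31)
  for (rep in 1:50) {
    tb <- runif(4, 0, 500)
    f <- computeFtb(runif(1, 1, 1000), tb[1], tb[2], tb[3], tb[4])
    expect_equal(f$f_up_plus, -f$f_up_minus)
    expect_equal(f$f_down_plus, -f$f_down_minus)
  }
})

test_that("the small-protein filter follows its defining arithmetic and boundaries", {
  expect_equal(as.numeric(applyScoreFilter(30, 150)), 30 - (250 - 150) / 4)
  expect_equal(as.numeric(applyScoreFilter(30, 250)), 30)  # self not < 250
  expect_equal(as.numeric(applyScoreFilter(50, 150)), 50)  # score not < 50
  expect_equal(as.numeric(applyScoreFilter(0, 150)), 0)    # score not > 0
  # never increases, never touches scores >= 50 or <= 0
  set.seed(32)
  f <- runif(200, -60, 120)
  s <- runif(200, 10, 400)
  out <- as.numeric(applyScoreFilter(f, s))
  expect_true(all(out <= f))
  keep <- f >= 50 | f <= 0
  expect_equal(out[keep], f[keep])
})

test_that("self-score equals the protein-vs-own-CDS aggregate and grows with length", {
  g <- toyGenome(list(list(seq = "ATGAAACTGTAA")))
  expect_equal(round(selfScore(g, "G1"), 2), 10.00)  # raw 14
  set.seed(33)
  gene <- toyGene(100)
  doubled <- paste0(substr(gene, 1, nchar(gene) - 3),
                    substr(gene, 4, nchar(gene)))
  g2 <- toyGenome(list(list(seq = gene), list(seq = doubled)),
                  gap = 4000)
  expect_gt(selfScore(g2, "G2"), selfScore(g2, "G1"))
})

test_that("score table flags a planted identical pair and leaves unique genes quiet", {
  set.seed(34)
  gene <- toyGene(330)  # ~1 kb, a realistic yeast-sized CDS
  others <- replicate(3, toyGene(330))
  g <- toyGenome(list(list(seq = others[1]), list(seq = gene),
                      list(seq = gene), list(seq = others[2]),
                      list(seq = others[3])),
                 gap = 400, lead = 3200)
  sc <- scoreGenome(g)
  tab <- scoreTable(sc)
  # the identical adjacent pair faces each other near 100% of self
  expect_gte(tab$f_down_plus[2], 95)
  expect_lte(tab$f_down_plus[2], 105)
  expect_gte(tab$f_up_plus[3], 95)
  # unique neighbours: all scores stay below the threshold
  expect_lt(max(tab$f_up_plus[1], tab$f_down_plus[4],
                tab$f_down_plus[5]), 10)
})

test_that("FTB of a planted copy decreases with divergence over a seed ensemble", {
  set.seed(35)
  meanFtb <- function(identity) {
    vals <- numeric(3)
    for (r in 1:3) {
      gene <- toyGene(150)
      cp <- mutateCopy(Biostrings::DNAString(gene), identity)
      g <- toyGenome(list(list(seq = gene),
                          list(seq = as.character(cp$dna))),
                     gap = 400, lead = 1800)
      sc <- scoreTable(scoreGenome(g))
      vals[r] <- sc$f_down_plus[1]
    }
    mean(vals)
  }
  f100 <- meanFtb(100); f70 <- meanFtb(70); f40 <- meanFtb(40)
  expect_gte(f100, f70)
  expect_gte(f70, f40)
})

test_that("score tables persist deterministically", {
  set.seed(36)
  g <- toyGenome(list(list(seq = toyGene(120)), list(seq = toyGene(110))),
                 gap = 2000)
  sc <- scoreGenome(g)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeScoreTable(sc, f1)
  writeScoreTable(scoreGenome(g), f2)
  expect_identical(readLines(f1), readLines(f2))
})
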