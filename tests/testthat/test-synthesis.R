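test_that("the truth ledger books planted arrays and members", {
  cfg <- synthConfig(nGenes = 20,
                     arrays = list(arraySpec(2, identity = 95),
                                   arraySpec(3, identity = 90)),
                     seed = 61)
  sim <- generateGenome(cfg)
  tr <- sim$truth$arrays
  expect_equal(length(unique(tr$family)), 2)
  expect_equal(sum(tr$kind == "cds"), 5)
  expect_equal(length(cdsFeatures(sim$genome)), 20)
})

test_that("generation is deterministic in the seed", {
  cfg <- defaultSynthConfig(seed = 62)
  s1 <- generateGenome(cfg)
  s2 <- generateGenome(cfg)
  expect_identical(as.character(chromosomes(s1$genome)[[1]]),
                   as.character(chromosomes(s2$genome)[[1]]))
  expect_identical(as.data.frame(s1$truth$arrays),
                   as.data.frame(s2$truth$arrays))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSyntheticGenome(s1, d1)
  writeSyntheticGenome(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("relics are planted outside the annotation but inside the truth", {
  cfg <- synthConfig(nGenes = 15,
                     arrays = list(arraySpec(1, relic = "downstream")),
                     seed = 63)
  sim <- generateGenome(cfg)
  tr <- sim$truth$arrays
  rel <- tr[tr$kind == "relic", ]
  expect_equal(nrow(rel), 1)
  expect_true(is.na(rel$cds_id))
  cds <- cdsFeatures(sim$genome)
  expect_false(any(start(cds) <= rel$end & end(cds) >= rel$start))
})

test_that("mutateCopy hits its protein identity target and keeps the frame", {
  set.seed(64)
  gene <- toyGene(200)
  same <- mutateCopy(Biostrings::DNAString(gene), 100)
  expect_identical(as.character(same$dna), gene)
  for (target in c(80, 60)) {
    mc <- mutateCopy(Biostrings::DNAString(gene), target)
    expect_lte(abs(mc$identity - target), 2)
    pa <- TandemArrays:::fastTranslateChr(gene, "1")
    pb <- TandemArrays:::fastTranslateChr(as.character(mc$dna), "1")
    direct <- 100 * mean(strsplit(pa, "")[[1]] == strsplit(pb, "")[[1]])
    expect_lte(abs(direct - target), 2)
    # alignment-based identity agrees with the recorded truth
    pid <- pairIdentity(sub("\\*$", "", pa), sub("\\*$", "", pb))
    expect_lte(abs(pid - mc$identity), 3)
  }
})

test_that("relic degradation destroys every long open reading frame", {
  set.seed(65)
  gene <- toyGene(300)
  expect_error(degradeToRelic(Biostrings::DNAString(gene), 0),
               "disruption")
  rel <- degradeToRelic(Biostrings::DNAString(gene), 2,
                        truncateFrac = 0.2)
  orf <- TandemArrays:::longestStopFree(as.character(rel), "1")
  expect_lt(orf$len, 0.5 * nchar(gene))
  # still detectable by dotplot against its source
  runs <- dotplot(gene, as.character(rel))
  expect_gte(max(runs$length), 30)
})

test_that("background genes are mutually dissimilar", {
  set.seed(66)
  sim <- generateGenome(synthConfig(nGenes = 8, arrays = list(),
                                    seed = 5))
  ids <- cdsFeatures(sim$genome)$cds_id
  prots <- lapply(ids, function(i)
    as.character(translateCds(sim$genome, i)))
  mat <- TandemArrays:::scoringMatrix(alignParams())
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prots[[i]]),
      Biostrings::AAString(prots[[j]]), type = "global",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    expect_lt(Biostrings::pid(aln, type = "PID1"), 30)
  }
})

test_that("the optional intron mode produces translatable spliced genes", {
  sim <- generateGenome(synthConfig(nGenes = 10, arrays = list(),
                                    intronProb = 1, seed = 67))
  ex <- cdsExons(sim$genome)
  expect_true(any(lengths(ex) == 2))
  two <- names(ex)[lengths(ex) == 2][1]
  aa <- as.character(translateCds(sim$genome, two))
  expect_false(grepl("\\*", aa))
  expect_equal(substr(aa, 1, 1), "M")
})
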