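test_that("features are rank-ordered by coordinate regardless of input order", {
  dir <- withr::local_tempdir()
  set.seed(7)
  chrom <- toyDna(3000)
  writeLines(c(">chrA", chrom), file.path(dir, "g.fasta"))
  ann <- data.frame(
    id = c("b", "a", "c"), chrom = "chrA", strand = c("+", "-", "+"),
    exons = c("1001-1300", "101-400", "2001-2300"))
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- readAnnotatedGenome(file.path(dir, "g.fasta"),
                           file.path(dir, "a.tsv"))
  cds <- cdsFeatures(g)
  expect_identical(cds$cds_id, c("a", "b", "c"))
  expect_identical(cds$rank, 0:2)
})

test_that("multi-exon spliced length sums exon lengths", {
  dir <- withr::local_tempdir()
  set.seed(8)
  writeLines(c(">chrA", toyDna(2000)), file.path(dir, "g.fasta"))
  ann <- data.frame(id = "x", chrom = "chrA", strand = "+",
                    exons = "101-220,301-405")
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- readAnnotatedGenome(file.path(dir, "g.fasta"),
                           file.path(dir, "a.tsv"))
  expect_identical(cdsFeatures(g)$spliced_len, 120L + 105L)
})

test_that("unknown chromosome in annotation names the offending feature", {
  dir <- withr::local_tempdir()
  writeLines(c(">chrA", toyDna(500, seed = 1)), file.path(dir, "g.fasta"))
  ann <- data.frame(id = "lost", chrom = "chrB", strand = "+",
                    exons = "1-300")
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readAnnotatedGenome(file.path(dir, "g.fasta"),
                                   file.path(dir, "a.tsv")),
               "lost")
})

test_that("translation handles strand, internal stops and the CUG-Ser code", {
  g <- toyGenome(list(list(seq = "ATGAAACTGTAA"),
                      list(seq = "ATGAAACTGTAA", strand = "-")))
  expect_identical(as.character(translateCds(g, "G1")), "MKL")
  expect_identical(as.character(translateCds(g, "G2")), "MKL")
  g12 <- toyGenome(list(list(seq = "ATGAAACTGTAA")), geneticCode = "12")
  expect_identical(as.character(translateCds(g12, "G1")), "MKS")
  # internal stop rendered as '*'
  gs <- toyGenome(list(list(seq = "ATGTAACTGTAA")))
  expect_identical(as.character(translateCds(gs, "G1")), "M*L")
})

test_that("flanking windows follow the max(factor x L, minLen) rule", {
  gene600 <- toyGene(200, seed = 2)   # 600 bp
  gene402 <- toyGene(134, seed = 3)   # 402 bp
  g <- toyGenome(list(list(seq = gene600), list(seq = gene402)),
                 gap = 2500, lead = 2500)
  expect_equal(width(flankingWindow(g, "G1", "upstream")), 1800)
  expect_equal(width(flankingWindow(g, "G1", "downstream")), 1800)
  expect_equal(width(flankingWindow(g, "G2", "upstream")), 1500)

  # chromosome-edge truncation
  gEdge <- toyGenome(list(list(seq = gene600)), lead = 200)
  expect_equal(width(flankingWindow(gEdge, "G1", "upstream")), 200)
})

test_that("window length matches the rule for random CDS lengths and never overlaps the CDS", {
  set.seed(11)
  for (rep in 1:20) {
    L <- 3 * sample(50:3000, 1)
    g <- toyGenome(list(list(seq = toyGene(L / 3))),
                   lead = 3 * L + 2000)
    cds <- cdsFeatures(g)
    up <- flankingWindow(g, "G1", "upstream")
    down <- flankingWindow(g, "G1", "downstream")
    expect_equal(width(up), max(3 * L, 1500))
    expect_lt(end(up), start(cds))
    expect_gt(start(down), end(cds))
  }
})

test_that("write -> read round-trips features exactly (TSV and GFF3)", {
  set.seed(12)
  sim <- generateGenome(synthConfig(nGenes = 8, arrays = list(),
                                    seed = 3))
  for (fmt in c("tsv", "gff3")) {
    dir <- withr::local_tempdir()
    fa <- file.path(dir, "g.fasta")
    ann <- file.path(dir, paste0("a.", if (fmt == "tsv") "tsv" else "gff3"))
    writeAnnotatedGenome(sim$genome, fa, ann, format = fmt)
    g2 <- readAnnotatedGenome(fa, ann)
    c1 <- cdsFeatures(sim$genome); c2 <- cdsFeatures(g2)
    expect_identical(c1$cds_id, c2$cds_id)
    expect_identical(start(c1), start(c2))
    expect_identical(end(c1), end(c2))
    expect_identical(as.character(strand(c1)), as.character(strand(c2)))
    expect_identical(as.character(chromosomes(sim$genome)[[1]]),
                     as.character(chromosomes(g2)[[1]]))
  }
})

test_that("trailing incomplete codons are trimmed with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c(">chrA", paste0(toyDna(100, seed = 5), "ATGAAACTGTAAG",
                               toyDna(100))),
             file.path(dir, "g.fasta"))
  ann <- data.frame(id = "x", chrom = "chrA", strand = "+",
                    exons = "101-113")  # 13 bp: one dangling base
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_warning(g <- readAnnotatedGenome(file.path(dir, "g.fasta"),
                                          file.path(dir, "a.tsv")),
                 "trimmed")
  expect_identical(as.character(translateCds(g, "x")), "MKL")
})
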