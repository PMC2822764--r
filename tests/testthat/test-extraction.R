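mkToy <- function(n, gap = 400) {
  set.seed(41)
  toyGenome(lapply(seq_len(n), function(i) list(seq = toyGene(110))),
            gap = gap)
}

test_that("side significance returns the strand reaching the threshold", {
  expect_equal(isSignificant(35, -35), "plus")
  expect_equal(isSignificant(9.9, -9.9, threshold = 10), NA_character_)
  expect_equal(isSignificant(-12, 12), "minus")
  expect_equal(isSignificant(10, -10), "plus")  # boundary: >= threshold
})

test_that("pair and TGA orientation classes follow the strand definitions", {
  expect_equal(unname(pairOrientation("+", "+")), "direct_sense")
  expect_equal(unname(pairOrientation("-", "-")), "direct_antisense")
  expect_equal(unname(pairOrientation("+", "-")), "opposite_convergent")
  expect_equal(unname(pairOrientation("-", "+")), "opposite_divergent")
  expect_equal(classifyTgaOrientation(c("direct_sense", "direct_sense")),
               "direct_sense")
  expect_equal(classifyTgaOrientation(c("direct_sense",
                                        "opposite_convergent")), "mixed")
  expect_equal(classifyTgaOrientation("opposite_divergent"),
               "opposite_divergent")
})

test_that("the automaton assembles maximal arrays from facing profiles", {
  g <- mkToy(12)
  prof <- rbind(
    ftbRow(),              # 1 background
    ftbRow(down = 60),     # 2 opens array A
    ftbRow(up = 55),       # 3 closes array A
    ftbRow(),              # 4
    ftbRow(down = 40),     # 5 opens array B
    ftbRow(up = 42, down = 41),  # 6 middle of B
    ftbRow(up = 39),       # 7 closes B
    ftbRow(),              # 8
    ftbRow(down = 30),     # 9 opens C
    ftbRow(up = 33),       # 10 closes C
    ftbRow(),              # 11
    ftbRow())              # 12
  ts <- extractTgas(toyScores(g, prof), g)
  tg <- tgaTable(ts)
  expect_equal(nrow(tg), 3)
  expect_equal(tg$n_cds, c(2L, 3L, 2L))
  mem <- tgaMembers(ts)
  expect_equal(mem$cds_id[mem$tga_id == tg$tga_id[2]],
               c("G5", "G6", "G7"))
  # no CDS in two TGAs; members + untagged cover everything
  expect_equal(anyDuplicated(mem$cds_id), 0L)
  # arrays without spacers are unchanged when the allowance is removed
  ts0 <- extractTgas(toyScores(g, prof), g, allowSpacer = FALSE)
  expect_identical(as.data.frame(tgaMembers(ts0)),
                   as.data.frame(mem))
})

test_that("one spacer gene is allowed inside a TGA and the allowance can be disabled", {
  g <- mkToy(6)
  prof <- rbind(
    ftbRow(),
    ftbRow(down = 50),   # 2: facing across the spacer
    ftbRow(),            # 3: spacer, no signal
    ftbRow(up = 45),     # 4
    ftbRow(), ftbRow())
  sc <- toyScores(g, prof)
  ts <- extractTgas(sc, g)
  mem <- tgaMembers(ts)
  expect_equal(nrow(tgaTable(ts)), 1)
  expect_equal(mem$kind, c("cds", "spacer", "cds"))
  expect_equal(mem$cds_id, c("G2", "G3", "G4"))

  ts0 <- extractTgas(sc, g, allowSpacer = FALSE)
  expect_equal(nrow(tgaTable(ts0)), 0)
  # without the allowance both signals become isolated relic tags
  expect_setequal(taggedCds(ts0)$cds_id, c("G2", "G4"))
})

test_that("isolated significant CDSs are relic-tagged, not arrayed", {
  g <- mkToy(5)
  prof <- rbind(
    ftbRow(),
    ftbRow(down = -25),  # minus-strand signal, no partner
    ftbRow(), ftbRow(), ftbRow())
  ts <- extractTgas(toyScores(g, prof), g)
  expect_equal(nrow(tgaTable(ts)), 0)
  tags <- taggedCds(ts)
  expect_equal(tags$cds_id, "G2")
  expect_equal(tags$reason, "isolated_with_signal")
  expect_equal(tags$match_strand, "minus")
  expect_equal(tags$side, "downstream")
})

test_that("edge CDSs with outward signals are flagged as relic candidates via S1/S4", {
  g <- mkToy(6)
  prof <- rbind(
    ftbRow(),
    ftbRow(up = 20, down = 60),  # 2: outward upstream signal
    ftbRow(up = 55),             # 3
    ftbRow(), ftbRow(), ftbRow())
  ts <- extractTgas(toyScores(g, prof), g)
  tg <- tgaTable(ts)
  expect_equal(tg$s1, 20)
  expect_equal(tg$s4, 0)
  expect_true(tg$relic_candidate)
  tags <- taggedCds(ts)
  edge <- tags[tags$reason == "tga_edge_outward_signal", ]
  expect_equal(edge$cds_id, "G2")
  expect_equal(edge$tga_id, tg$tga_id)
})

test_that("flank and pair scores land in S1..S4 as defined", {
  g <- mkToy(5)
  prof <- rbind(
    ftbRow(),
    ftbRow(down = 61),
    ftbRow(up = 58, down = 44),
    ftbRow(up = 47),
    ftbRow())
  ts <- extractTgas(toyScores(g, prof), g)
  fs <- flankScores(ts)
  expect_equal(fs$flanks$s1, 0)
  expect_equal(fs$flanks$s4, 0)
  expect_equal(fs$pairs$s2, c(61, 44))
  expect_equal(fs$pairs$s3, c(58, 47))
})

test_that("raising the threshold never creates tags or arrays", {
  g <- mkToy(8)
  set.seed(42)
  prof <- do.call(rbind, lapply(1:8, function(i)
    ftbRow(up = runif(1, -20, 20), down = runif(1, -20, 20))))
  sc <- toyScores(g, prof)
  t10 <- extractTgas(sc, g, threshold = 10)
  t15 <- extractTgas(sc, g, threshold = 15)
  expect_lte(nrow(tgaTable(t15)), nrow(tgaTable(t10)))
  expect_lte(sum(taggedCds(t15)$reason == "isolated_with_signal"),
             sum(taggedCds(t10)$reason == "isolated_with_signal"))
})
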