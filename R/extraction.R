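#' Which strand of one flank is significant?
#'
#' A side (upstream or downstream) of a CDS is significant when one of
#' its two filtered FTB scores reaches the threshold (default 10; the
#' useful range is 10-15). By antisymmetry at most one strand per side
#' can be positive.
#'
#' @param fPlus,fMinus filtered FTB scores of the side's two strands.
#' @param threshold significance threshold (default 10).
#' @return \code{"plus"}, \code{"minus"} or \code{NA_character_}
#'   (vectorised over inputs).
#' @export
isSignificant <- function(fPlus, fMinus, threshold = 10) {
  out <- rep(NA_character_, length(fPlus))
  p <- !is.na(fPlus) & fPlus >= threshold
  m <- !is.na(fMinus) & fMinus >= threshold
  both <- p & m
  out[p] <- "plus"
  out[m & !p] <- "minus"
  out[both] <- ifelse(fPlus[both] >= fMinus[both], "plus", "minus")
  out
}

sigSide <- function(tab, i, side, threshold) {
  fp <- tab[[paste0("f_", side, "_plus")]][i]
  fm <- tab[[paste0("f_", side, "_minus")]][i]
  s <- isSignificant(fp, fm, threshold)
  list(strand = s,
       value = if (is.na(s)) 0 else if (s == "plus") fp else fm)
}

#' Are two CDSs in tandem according to their FTB profiles?
#'
#' CDS \code{a} (lower rank) and CDS \code{b} form a tandem pair when
#' \code{a}'s downstream side and \code{b}'s upstream side are both
#' significant -- their similarity signals face each other across the
#' intervening DNA.
#'
#' @param tab a score table (\code{scoreTable} of an \code{FtbScores}).
#' @param i,j row indices of the two CDSs (same chromosome, \code{i}
#'   preceding \code{j} by 1 or 2 ranks; a gap of 2 is a spacer
#'   candidate).
#' @param threshold FTB significance threshold.
#' @return a list: \code{ok} (logical), \code{strand_a}, \code{strand_b}
#'   (matched window strands, NA when not significant).
#' @export
adjacency <- function(tab, i, j, threshold = 10) {
  a <- sigSide(tab, i, "down", threshold)
  b <- sigSide(tab, j, "up", threshold)
  list(ok = !is.na(a$strand) && !is.na(b$strand),
       strand_a = a$strand, strand_b = b$strand,
       s2 = a$value, s3 = b$value)
}

#' Orientation class of a CDS pair
#'
#' From annotated strands, in coordinate order: \code{(+,+)} direct
#' sense, \code{(-,-)} direct antisense, \code{(+,-)} opposite
#' convergent, \code{(-,+)} opposite divergent.
#'
#' @param strandA,strandB strands (\code{"+"}/\code{"-"}), vectorised.
#' @return character vector of orientation classes.
#' @export
pairOrientation <- function(strandA, strandB) {
  key <- paste0(strandA, strandB)
  c("++" = "direct_sense", "--" = "direct_antisense",
    "+-" = "opposite_convergent", "-+" = "opposite_divergent")[key]
}

#' Orientation class of a whole TGA
#'
#' All pairs in one class give that class; any mixture of direct and
#' opposite pairs (or of the two opposite classes) is \code{mixed}.
#'
#' @param pairClasses character vector of pair orientation classes.
#' @return a single orientation class.
#' @export
classifyTgaOrientation <- function(pairClasses) {
  u <- unique(pairClasses[!is.na(pairClasses)])
  if (length(u) == 0L) return(NA_character_)
  if (length(u) == 1L) u else "mixed"
}

# strand of a relic inferred from the window strand its similarity was
# found on: a plus-strand match means the relic reads in chromosome
# plus orientation.
relicStrand <- function(matchStrand) ifelse(matchStrand == "plus", "+", "-")

#' Extract tandem gene arrays from a score table
#'
#' Walks the rank-ordered CDSs of each chromosome once, left to right. A
#' TGA opens at a CDS adjacent (facing significant FTB scores) to its
#' successor -- directly or across one spacer gene -- and not to its
#' predecessor, extends while adjacency continues, and closes at the
#' last adjacent CDS. CDSs with a significant score but no adjacency at
#' rank gaps 1 or 2 receive an \code{isolated_with_signal} relic tag;
#' TGA edge CDSs with an additional outward significant score receive a
#' \code{tga_edge_outward_signal} tag (candidate arrays starting or
#' ending with a gene relic). Flank scores S1 (upstream of the first
#' member) and S4 (downstream of the last) are stored per TGA; TGAs with
#' S1 or S4 above the threshold are flagged as nCDSs-relic candidates.
#'
#' @param scores an \code{\link[=FtbScores-class]{FtbScores}} object.
#' @param genome the \code{AnnotatedGenome} the scores came from.
#' @param threshold FTB significance threshold (default 10).
#' @param allowSpacer allow one heterologous spacer gene inside a TGA.
#' @return a \code{\link[=TgaSet-class]{TgaSet}}.
#' @export
extractTgas <- function(scores, genome, threshold = 10,
                        allowSpacer = TRUE) {
  tab <- scoreTable(scores)
  cds <- cdsFeatures(genome)
  stopifnot(identical(tab$cds_id, cds$cds_id))

  memRows <- list(); tgaRows <- list(); tagRows <- list()
  tgaN <- 0L

  for (chr in unique(tab$chrom)) {
    idx <- which(tab$chrom == chr)
    idx <- idx[order(tab$rank[idx])]
    k <- length(idx)
    inArray <- rep(FALSE, k)

    linkFrom <- function(p) {
      if (p + 1L <= k) {
        a <- adjacency(tab, idx[p], idx[p + 1L], threshold)
        if (a$ok) return(list(j = p + 1L, spacer = NA_integer_, adj = a))
      }
      if (allowSpacer && p + 2L <= k) {
        a <- adjacency(tab, idx[p], idx[p + 2L], threshold)
        if (a$ok) return(list(j = p + 2L, spacer = p + 1L, adj = a))
      }
      NULL
    }

    p <- 1L
    while (p <= k) {
      l <- linkFrom(p)
      if (is.null(l)) { p <- p + 1L; next }
      tgaN <- tgaN + 1L
      tid <- sprintf("TGA%03d", tgaN)
      mem <- data.frame(tga_id = tid, pos = 1L, kind = "cds",
                        row = idx[p], s2 = NA_real_, s3 = NA_real_)
      cur <- p
      repeat {
        l <- linkFrom(cur)
        if (is.null(l)) break
        np <- nrow(mem)
        mem$s2[np] <- l$adj$s2  # facing score of the pair just closed
        if (!is.na(l$spacer))
          mem <- rbind(mem, data.frame(tga_id = tid, pos = np + 1L,
                                       kind = "spacer",
                                       row = idx[l$spacer],
                                       s2 = NA_real_, s3 = NA_real_))
        mem <- rbind(mem, data.frame(tga_id = tid, pos = nrow(mem) + 1L,
                                     kind = "cds", row = idx[l$j],
                                     s2 = NA_real_, s3 = l$adj$s3))
        cur <- l$j
      }
      inArray[match(mem$row, idx)] <- TRUE
      memRows[[tid]] <- mem
      tgaRows[[tid]] <- data.frame(tga_id = tid, chrom = chr,
                                   first = idx[p], last = idx[cur])
      p <- cur + 1L
    }

    # relic tags: significant CDSs outside every array with no adjacency
    for (p in seq_len(k)) {
      if (inArray[p]) next
      i <- idx[p]
      up <- sigSide(tab, i, "up", threshold)
      dn <- sigSide(tab, i, "down", threshold)
      if (is.na(up$strand) && is.na(dn$strand)) next
      hasAdj <- FALSE
      for (g in seq_len(1L + as.integer(allowSpacer))) {
        if (p + g <= k && adjacency(tab, i, idx[p + g], threshold)$ok)
          hasAdj <- TRUE
        if (p - g >= 1L && adjacency(tab, idx[p - g], i, threshold)$ok)
          hasAdj <- TRUE
      }
      if (hasAdj) next  # partner consumed by an array; not isolated
      for (side in c("up", "down")) {
        s <- if (side == "up") up else dn
        if (is.na(s$strand)) next
        tagRows[[length(tagRows) + 1L]] <- data.frame(
          cds_id = tab$cds_id[i], chrom = chr,
          reason = "isolated_with_signal",
          side = ifelse(side == "up", "upstream", "downstream"),
          match_strand = s$strand, score = s$value, tga_id = NA_character_)
      }
    }
  }

  # assemble TGA-level rows: orientation, flank scores, size class
  tgas <- DataFrame(tga_id = character(), chrom = character(),
                    n_members = integer(), n_cds = integer(),
                    n_relic = integer(), size_class = character(),
                    orientation_class = character(),
                    s1 = numeric(), s4 = numeric(),
                    relic_candidate = logical())
  members <- NULL
  for (tid in names(memRows)) {
    mem <- memRows[[tid]]
    info <- tgaRows[[tid]]
    cdsMem <- mem[mem$kind == "cds", ]
    strands <- tab$strand[cdsMem$row]
    pcls <- pairOrientation(strands[-length(strands)], strands[-1L])
    s1 <- sigSide(tab, info$first, "up", threshold)
    s4 <- sigSide(tab, info$last, "down", threshold)
    s1v <- max(0, s1$value); s4v <- max(0, s4$value)
    relicCand <- s1v > threshold || s4v > threshold
    tgas <- rbind(tgas, DataFrame(
      tga_id = tid, chrom = info$chrom,
      n_members = nrow(mem), n_cds = nrow(cdsMem), n_relic = 0L,
      size_class = paste0(nrow(cdsMem), "CDS"),
      orientation_class = classifyTgaOrientation(pcls),
      s1 = s1v, s4 = s4v, relic_candidate = relicCand))
    rows <- mem$row
    md <- DataFrame(tga_id = tid, pos = mem$pos, kind = mem$kind,
                    cds_id = tab$cds_id[rows],
                    chrom = tab$chrom[rows],
                    start = tab$start[rows], end = tab$end[rows],
                    strand = tab$strand[rows],
                    s2 = mem$s2, s3 = mem$s3)
    members <- if (is.null(members)) md else rbind(members, md)
    # outward-signal tags on the edges
    if (s1v >= threshold)
      tagRows[[length(tagRows) + 1L]] <- data.frame(
        cds_id = tab$cds_id[info$first], chrom = info$chrom,
        reason = "tga_edge_outward_signal", side = "upstream",
        match_strand = s1$strand, score = s1v, tga_id = tid)
    if (s4v >= threshold)
      tagRows[[length(tagRows) + 1L]] <- data.frame(
        cds_id = tab$cds_id[info$last], chrom = info$chrom,
        reason = "tga_edge_outward_signal", side = "downstream",
        match_strand = s4$strand, score = s4v, tga_id = tid)
  }
  if (is.null(members))
    members <- DataFrame(tga_id = character(), pos = integer(),
                         kind = character(), cds_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         s2 = numeric(), s3 = numeric())
  tagged <- if (length(tagRows)) DataFrame(do.call(rbind, tagRows))
    else DataFrame(cds_id = character(), chrom = character(),
                   reason = character(), side = character(),
                   match_strand = character(), score = numeric(),
                   tga_id = character())
  tagged$status <- rep("pending", nrow(tagged))
  new("TgaSet", tgas = tgas, members = members, tagged = tagged,
      threshold = threshold)
}

#' Flank and pair scores of extracted TGAs
#'
#' S1 is the outward (upstream-side) significant-strand FTB score of the
#' first member CDS, S4 the outward score of the last (both floored at
#' 0); S2/S3 are the facing scores of each adjacent homologous pair.
#'
#' @param tgaSet a \code{TgaSet}.
#' @return a list: \code{flanks} (one row per TGA: \code{s1}, \code{s4},
#'   \code{relic_candidate}) and \code{pairs} (one row per adjacent
#'   homologous pair: \code{s2}, \code{s3}).
#' @export
flankScores <- function(tgaSet) {
  tg <- tgaTable(tgaSet)
  mem <- tgaMembers(tgaSet)
  pairs <- NULL
  for (tid in tg$tga_id) {
    m <- mem[mem$tga_id == tid & mem$kind == "cds", , drop = FALSE]
    if (nrow(m) < 2L) next
    for (q in seq_len(nrow(m) - 1L)) {
      pairs <- rbind(pairs, data.frame(
        tga_id = tid, a_id = m$cds_id[q], b_id = m$cds_id[q + 1L],
        s2 = m$s2[q], s3 = m$s3[q + 1L]))
    }
  }
  list(flanks = tg[, c("tga_id", "s1", "s4", "relic_candidate")],
       pairs = if (is.null(pairs)) data.frame(
         tga_id = character(), a_id = character(), b_id = character(),
         s2 = numeric(), s3 = numeric()) else DataFrame(pairs))
}
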