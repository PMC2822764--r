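bestRelicDiagonal <- function(genome, cdsId, side, scores, threshold,
                              dotWindow, dotStringency, minDiagonal) {
  cds <- cdsFeatures(genome)
  i <- match(cdsId, cds$cds_id)
  win <- flankingWindow(genome, cdsId, side, factor = scores@factor,
                        minLen = scores@minLen)
  if (width(win) < dotWindow) return(NULL)
  wseq <- windowSequence(genome, win)
  cseq <- windowSequence(genome, GRanges(seqnames(cds[i]),
                                         IRanges(start(cds[i]),
                                                 end(cds[i])),
                                         seqlengths = seqlengths(cds)))
  best <- NULL
  for (rc in c(FALSE, TRUE)) {
    sub <- if (rc) reverseComplement(DNAString(wseq)) else wseq
    runs <- dotplot(cseq, sub, window = dotWindow,
                    stringency = dotStringency)
    runs <- runs[runs$length >= minDiagonal, , drop = FALSE]
    if (!nrow(runs)) next
    # window centre coords -> chromosome coords of the subject span,
    # padded out to full-window extent
    half <- dotWindow %/% 2L
    bs <- runs$b_start - half; be <- runs$b_end + half
    if (rc) {
      tmp <- width(win) - be + 1L
      be <- width(win) - bs + 1L
      bs <- tmp
    }
    gs <- start(win) + bs - 1L
    ge <- start(win) + be - 1L
    for (r in seq_len(nrow(runs))) {
      cand <- GRanges(seqnames(win), IRanges(gs[r], ge[r]))
      inCds <- sum(width(GenomicRanges::intersect(
        cand, GenomicRanges::reduce(cds[, NULL]),
        ignore.strand = TRUE)))
      if (inCds > 0.5 * width(cand)) next  # mostly inside annotated CDS
      if (is.null(best) || runs$length[r] > best$length)
        best <- list(length = runs$length[r], start = gs[r], end = ge[r],
                     strand = if (rc) "-" else "+")
    }
  }
  best
}

#' Curate relic-tagged CDSs
#'
#' Mechanised curation of the relic tags produced by
#' \code{\link{extractTgas}}, in two stages. (i) Pairs of isolated
#' tagged CDSs whose significant scores face each other across at most
#' one spacer are merged into new TGAs. (ii) Each remaining tag is
#' screened by dotplot: the CDS's genomic sequence is compared with the
#' flanking window its significant score points at (both window
#' orientations), and a diagonal run of at least \code{minDiagonal}
#' dots (window/stringency defaults 23/15) lying at least 50\% outside
#' annotated CDSs confirms a gene relic. A confirmed isolated tag
#' becomes a 1CDS-relic TGA; a confirmed edge tag appends a relic
#' member to its TGA (nCDSs-relic class); anything else is rejected as
#' a false positive.
#'
#' @param tgaSet the \code{TgaSet} from \code{\link{extractTgas}}.
#' @param scores the \code{FtbScores} used for extraction.
#' @param genome the \code{AnnotatedGenome}.
#' @param mergePairs,confirmRelics switch the two stages individually.
#' @param dotWindow,dotStringency dotplot settings (default 23/15).
#' @param minDiagonal minimal diagonal run, in dots (default 30).
#' @return an updated \code{TgaSet}: new/extended TGAs, relic members
#'   with their intervals, and a \code{status} per tag
#'   (\code{merged}, \code{confirmed_relic}, \code{rejected}).
#' @export
curateTagged <- function(tgaSet, scores, genome, mergePairs = TRUE,
                         confirmRelics = TRUE, dotWindow = 23,
                         dotStringency = 15, minDiagonal = 30) {
  tagged <- tgaSet@tagged
  tgas <- tgaSet@tgas
  members <- tgaSet@members
  threshold <- tgaSet@threshold
  tab <- scoreTable(scores)
  nextId <- nrow(tgas)

  iso <- which(tagged$reason == "isolated_with_signal")
  done <- rep(FALSE, nrow(tagged))

  if (mergePairs && length(iso) > 1L) {
    ranks <- tab$rank[match(tagged$cds_id, tab$cds_id)]
    for (ai in iso) {
      if (done[ai] || tagged$side[ai] != "downstream") next
      for (bi in iso) {
        if (done[bi] || bi == ai) next
        if (tagged$side[bi] != "upstream") next
        if (tagged$chrom[ai] != tagged$chrom[bi]) next
        gap <- ranks[bi] - ranks[ai]
        if (!(gap %in% c(1L, 2L))) next
        # merge into a new TGA (with spacer when gap == 2)
        nextId <- nextId + 1L
        tid <- sprintf("TGA%03d", nextId)
        ia <- match(tagged$cds_id[ai], tab$cds_id)
        ib <- match(tagged$cds_id[bi], tab$cds_id)
        rows <- c(ia, if (gap == 2L)
          which(tab$chrom == tagged$chrom[ai] &
                  tab$rank == ranks[ai] + 1L), ib)
        kinds <- if (gap == 2L) c("cds", "spacer", "cds") else
          c("cds", "cds")
        members <- rbind(members, DataFrame(
          tga_id = tid, pos = seq_along(rows), kind = kinds,
          cds_id = tab$cds_id[rows], chrom = tab$chrom[rows],
          start = tab$start[rows], end = tab$end[rows],
          strand = tab$strand[rows],
          s2 = c(tagged$score[ai], rep(NA_real_, length(rows) - 1L)),
          s3 = c(rep(NA_real_, length(rows) - 1L), tagged$score[bi])))
        ori <- pairOrientation(tab$strand[ia], tab$strand[ib])
        tgas <- rbind(tgas, DataFrame(
          tga_id = tid, chrom = tagged$chrom[ai],
          n_members = length(rows), n_cds = 2L, n_relic = 0L,
          size_class = "2CDS", orientation_class = ori,
          s1 = 0, s4 = 0, relic_candidate = FALSE))
        done[ai] <- TRUE; done[bi] <- TRUE
        tagged$status[c(ai, bi)] <- "merged"
        tagged$tga_id[c(ai, bi)] <- tid
        break
      }
    }
  }

  if (confirmRelics) {
    for (ti in seq_len(nrow(tagged))) {
      if (done[ti]) next
      d <- bestRelicDiagonal(genome, tagged$cds_id[ti],
                             tagged$side[ti], scores, threshold,
                             dotWindow, dotStringency, minDiagonal)
      if (is.null(d)) {
        tagged$status[ti] <- "rejected"
        next
      }
      i <- match(tagged$cds_id[ti], tab$cds_id)
      if (tagged$reason[ti] == "isolated_with_signal") {
        nextId <- nextId + 1L
        tid <- sprintf("TGA%03d", nextId)
        relFirst <- tagged$side[ti] == "upstream"
        mk <- function(pos, kind, id, st, en, strd, s2, s3)
          DataFrame(tga_id = tid, pos = pos, kind = kind, cds_id = id,
                    chrom = tagged$chrom[ti], start = st, end = en,
                    strand = strd, s2 = s2, s3 = s3)
        relStrand <- relicStrand(tagged$match_strand[ti])
        cdsRow <- mk(ifelse(relFirst, 2L, 1L), "cds", tab$cds_id[i],
                     tab$start[i], tab$end[i], tab$strand[i],
                     ifelse(relFirst, NA_real_, tagged$score[ti]),
                     ifelse(relFirst, tagged$score[ti], NA_real_))
        relRow <- mk(ifelse(relFirst, 1L, 2L), "relic", NA_character_,
                     d$start, d$end,
                     if (tagged$match_strand[ti] == "plus")
                       tab$strand[i] else
                         ifelse(tab$strand[i] == "+", "-", "+"),
                     NA_real_, NA_real_)
        members <- rbind(members,
                         if (relFirst) rbind(relRow, cdsRow)
                         else rbind(cdsRow, relRow))
        pr <- if (relFirst)
          pairOrientation(relRow$strand, cdsRow$strand) else
            pairOrientation(cdsRow$strand, relRow$strand)
        tgas <- rbind(tgas, DataFrame(
          tga_id = tid, chrom = tagged$chrom[ti], n_members = 2L,
          n_cds = 1L, n_relic = 1L, size_class = "1CDS-relic",
          orientation_class = pr, s1 = 0, s4 = 0,
          relic_candidate = FALSE))
        tagged$status[ti] <- "confirmed_relic"
        tagged$tga_id[ti] <- tid
      } else {  # edge of an existing TGA
        tid <- tagged$tga_id[ti]
        r <- which(tgas$tga_id == tid)
        msel <- which(members$tga_id == tid)
        pos <- if (tagged$side[ti] == "upstream") 0L else
          max(members$pos[msel]) + 1L
        members <- rbind(members, DataFrame(
          tga_id = tid, pos = pos, kind = "relic",
          cds_id = NA_character_, chrom = tagged$chrom[ti],
          start = d$start, end = d$end,
          strand = if (tagged$match_strand[ti] == "plus")
            tab$strand[i] else ifelse(tab$strand[i] == "+", "-", "+"),
          s2 = NA_real_, s3 = NA_real_))
        tgas$n_relic[r] <- tgas$n_relic[r] + 1L
        tgas$n_members[r] <- tgas$n_members[r] + 1L
        tgas$size_class[r] <- "nCDSs-relic"
        tagged$status[ti] <- "confirmed_relic"
      }
    }
  }

  # keep members of each TGA in coordinate order
  ord <- order(members$tga_id, members$start)
  members <- members[ord, , drop = FALSE]
  for (tid in unique(members$tga_id)) {
    sel <- which(members$tga_id == tid)
    members$pos[sel] <- seq_along(sel)
  }
  new("TgaSet", tgas = tgas, members = members, tagged = tagged,
      threshold = threshold)
}

#' Verify TGA pairs by protein dotplot
#'
#' Mechanises the final false-positive screen: every adjacent CDS pair
#' of every TGA must show sustained similarity in a protein
#' protein-against-protein dot matrix (window 23, stringency 5) -- a
#' diagonal run of at least \code{minRun} dots in either relative
#' orientation. Pairs held together only by coincidental weak HSP sums
#' fail; genuinely paralogous pairs pass down to low identity. Failing
#' bonds are cut: arrays split into the surviving segments, and
#' segments left with fewer than two homologous members are dropped
#' (their CDSs are released). Pairs involving a relic member are not
#' re-checked here (relics were confirmed on the DNA dotplot).
#'
#' @param tgaSet a \code{TgaSet}.
#' @param genome the \code{AnnotatedGenome}.
#' @param window,stringency protein dot-matrix settings (default 23/5).
#' @param minRun minimal diagonal run in dots (default 30).
#' @return the screened \code{TgaSet}; cut bonds are recorded in its
#'   \code{metadata}-like attribute \code{"rejected_pairs"}.
#' @export
verifyTgaPairs <- function(tgaSet, genome, window = 23, stringency = 5,
                           minRun = 30) {
  tg <- tgaTable(tgaSet)
  mem <- tgaMembers(tgaSet)
  rejected <- NULL
  keepTga <- DataFrame()
  keepMem <- NULL
  nextId <- 0L

  pairOk <- function(idA, idB) {
    pa <- translateCds(genome, idA)
    pb <- translateCds(genome, idB)
    if (length(pa) < window || length(pb) < window) return(TRUE)
    for (revB in c(FALSE, TRUE)) {
      sb <- if (revB) paste(rev(strsplit(as.character(pb), "")[[1]]),
                            collapse = "") else as.character(pb)
      runs <- dotplot(pa, sb, window = window, stringency = stringency,
                      alphabet = "protein")
      if (nrow(runs) && max(runs$length) >= minRun) return(TRUE)
    }
    FALSE
  }

  for (tid in tg$tga_id) {
    m <- mem[mem$tga_id == tid, , drop = FALSE]
    m <- m[order(m$pos), , drop = FALSE]
    hom <- which(m$kind != "spacer")
    bondOk <- rep(TRUE, max(0L, length(hom) - 1L))
    for (q in seq_along(bondOk)) {
      a <- hom[q]; b <- hom[q + 1L]
      if (m$kind[a] == "relic" || m$kind[b] == "relic") next
      if (!pairOk(m$cds_id[a], m$cds_id[b])) {
        bondOk[q] <- FALSE
        rejected <- rbind(rejected, data.frame(
          tga_id = tid, a_id = m$cds_id[a], b_id = m$cds_id[b]))
      }
    }
    # split into maximal runs of intact bonds
    seg <- cumsum(c(0L, !bondOk))
    for (sg in unique(seg)) {
      hs <- hom[seg == sg]
      if (length(hs) < 2L) next
      lo <- min(hs); hi <- max(hs)
      rows <- lo:hi  # homologous members plus interior spacers
      nextId <- nextId + 1L
      newTid <- sprintf("TGA%03d", nextId)
      sm <- m[rows, , drop = FALSE]
      sm$tga_id <- newTid
      sm$pos <- seq_len(nrow(sm))
      keepMem <- if (is.null(keepMem)) sm else rbind(keepMem, sm)
      r <- which(tg$tga_id == tid)
      nCds <- sum(sm$kind == "cds"); nRel <- sum(sm$kind == "relic")
      cls <- if (nRel == 0L) paste0(nCds, "CDS") else
        if (nCds == 1L) "1CDS-relic" else "nCDSs-relic"
      strands <- sm$strand[sm$kind != "spacer"]
      pcls <- pairOrientation(strands[-length(strands)], strands[-1L])
      intact <- identical(rows, seq_len(nrow(m)))
      keepTga <- rbind(keepTga, DataFrame(
        tga_id = newTid, chrom = tg$chrom[r],
        n_members = nrow(sm), n_cds = nCds, n_relic = nRel,
        size_class = cls,
        orientation_class = classifyTgaOrientation(pcls),
        s1 = if (intact) tg$s1[r] else 0,
        s4 = if (intact) tg$s4[r] else 0,
        relic_candidate = if (intact) tg$relic_candidate[r] else FALSE))
    }
  }
  if (is.null(keepMem))
    keepMem <- tgaSet@members[0, , drop = FALSE]
  if (nrow(keepTga) == 0L)
    keepTga <- tgaSet@tgas[0, , drop = FALSE]
  out <- new("TgaSet", tgas = keepTga, members = keepMem,
             tagged = tgaSet@tagged, threshold = tgaSet@threshold)
  attr(out, "rejected_pairs") <- if (is.null(rejected))
    data.frame(tga_id = character(), a_id = character(),
               b_id = character()) else rejected
  out
}
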