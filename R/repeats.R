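dnaCodes <- function(x, sentinel = -1L) {
  lut <- rep.int(sentinel, 127L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[as.integer(charToRaw(toupper(as.character(x))))]
}

#' Quick scan for candidate tandem-repeat unit sizes
#'
#' For every lag \code{u} up to \code{maxUnit}, the sequence is compared
#' with itself shifted by \code{u}; the score of a unit is the length of
#' its longest run of consecutive matching positions. Units scoring at
#' least \code{threshold} are reported best-first; a unit that is an
#' exact multiple of an already-reported unit is dropped as redundant.
#'
#' @param dna a \code{DNAString} or string.
#' @param maxUnit largest unit size considered (default 600).
#' @param threshold minimal run score (default 20).
#' @return a data.frame (\code{unit}, \code{score}, \code{start},
#'   \code{end}), ordered by decreasing score; zero rows when nothing
#'   reaches the threshold.
#' @export
quickTandemScan <- function(dna, maxUnit = 600, threshold = 20) {
  s <- dnaCodes(dna)
  hits <- cpp_quick_tandem(s, as.integer(maxUnit))
  out <- data.frame(unit = hits[, 1], score = hits[, 2],
                    start = hits[, 3], end = hits[, 4])
  out <- out[out$score >= threshold, , drop = FALSE]
  out <- out[order(-out$score, out$unit), , drop = FALSE]
  keep <- logical(nrow(out))
  kept <- integer()
  for (i in seq_len(nrow(out))) {
    u <- out$unit[i]
    if (!any(kept < u & u %% kept == 0L)) { keep[i] <- TRUE
      kept <- c(kept, u) }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best tandem repeat under consensus scoring
#'
#' A repeat block is two or more consecutive whole copies of a unit; its
#' consensus takes the majority base per unit column, and its score is
#' (matches to consensus) - (mismatches). The maximal-scoring block over
#' all unit sizes, phases and spans is returned, ties broken toward the
#' smaller unit, then the leftmost span. By default only unit sizes
#' proposed by \code{\link{quickTandemScan}} are examined (the fast
#' two-stage design); pass \code{candidates = NULL} explicitly via
#' \code{exhaustive = TRUE} to scan every unit in range.
#'
#' @param dna a \code{DNAString} or string.
#' @param minUnit,maxUnit unit-size range for a confirmed call
#'   (defaults 10 and 300).
#' @param candidates integer vector of unit sizes to examine, or
#'   \code{NULL} to derive them from a quick scan.
#' @param exhaustive scan all units in \code{minUnit:maxUnit} instead.
#' @param quickThreshold threshold for the candidate quick scan.
#' @return a one-row data.frame (\code{unit}, \code{copies},
#'   \code{start}, \code{end}, \code{score}, \code{consensus}) or
#'   \code{NULL} when no block scores > 0.
#' @export
exactTandem <- function(dna, minUnit = 10, maxUnit = 300,
                        candidates = NULL, exhaustive = FALSE,
                        quickThreshold = 20) {
  s <- dnaCodes(dna)
  units <- if (exhaustive) {
    seq.int(minUnit, min(maxUnit, length(s) %/% 2L))
  } else if (!is.null(candidates)) {
    sort(unique(candidates))
  } else {
    q <- quickTandemScan(dna, maxUnit = max(maxUnit, 600),
                         threshold = quickThreshold)
    sort(unique(q$unit))
  }
  units <- units[units >= minUnit & units <= maxUnit]
  if (!length(units)) return(NULL)
  best <- cpp_exact_tandem(s, as.integer(units))
  if (best[4] <= 0L) return(NULL)
  u <- best[1]; st <- best[2]; cp <- best[3]
  block <- matrix(s[st:(st + cp * u - 1L)], nrow = u)
  cons <- apply(block, 1L, function(col) {
    tb <- tabulate(col + 1L, nbins = 4L)
    c("A", "C", "G", "T")[which.max(tb)]
  })
  data.frame(unit = u, copies = cp, start = st, end = st + cp * u - 1L,
             score = best[4], consensus = paste(cons, collapse = ""))
}

#' Sliding-window dotplot with merged diagonal runs
#'
#' A dot sits at \code{(i, j)} when the \code{window}-long windows
#' centred there share at least \code{stringency} identical letters
#' (defaults 23/15, the DNA settings used for relic curation; use 23/5
#' for protein self-matrices). Consecutive dots on one diagonal are
#' merged into runs.
#'
#' @param seqA,seqB sequences (strings, \code{DNAString} or
#'   \code{AAString}).
#' @param window odd window length (default 23).
#' @param stringency minimal identities per window (default 15).
#' @param alphabet \code{"dna"} (N never matches) or \code{"protein"}.
#' @return a data.frame of diagonal runs (\code{a_start}, \code{a_end},
#'   \code{b_start}, \code{b_end}, \code{length}) sorted by decreasing
#'   length; coordinates are window centres, 1-based.
#' @export
dotplot <- function(seqA, seqB, window = 23, stringency = 15,
                    alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(window %% 2 == 1)
  if (alphabet == "dna") {
    a <- dnaCodes(seqA, sentinel = -1L)
    b <- dnaCodes(seqB, sentinel = -2L)  # N on either side never matches
  } else {
    a <- as.integer(charToRaw(toupper(as.character(seqA))))
    b <- as.integer(charToRaw(toupper(as.character(seqB))))
  }
  runs <- cpp_dotplot(a, b, as.integer(window), as.integer(stringency))
  out <- data.frame(a_start = runs[, 1], a_end = runs[, 2],
                    b_start = runs[, 3], b_end = runs[, 4],
                    length = runs[, 5])
  out[order(-out$length, out$a_start), , drop = FALSE]
}

# spliced CDS coordinate -> genomic coordinate lookup (coding order)
splicedToGenomic <- function(genome, cdsId) {
  ex <- genome@exons[[cdsId]]
  pos <- unlist(lapply(seq_along(ex),
                       function(k) seq.int(start(ex)[k], end(ex)[k])))
  if (as.character(strand(ex))[1] == "-") pos <- rev(pos)
  pos
}

maskChromosome <- function(genome, chrom, spans) {
  s <- genome@seqs
  ch <- as.character(s[[chrom]])
  for (r in seq_len(nrow(spans)))
    substr(ch, spans$start[r], spans$end[r]) <-
      strrep("N", spans$end[r] - spans$start[r] + 1L)
  s[[chrom]] <- DNAString(ch)
  out <- genome
  out@seqs <- s
  out
}

# facing FTB scores of one adjacent CDS pair, recomputed on a genome
# copy where the given genomic spans are masked to N. The original
# (unmasked) self-scores stay as normalisers, so masking can only
# lower an FTB score.
rescorePair <- function(genome, idA, idB, maskSpans, params, factor,
                        minLen, selfA, selfB) {
  g <- genome
  if (nrow(maskSpans)) {
    for (chrom in unique(maskSpans$chrom))
      g <- maskChromosome(g, chrom,
                          maskSpans[maskSpans$chrom == chrom, ,
                                    drop = FALSE])
  }
  one <- function(id, side, tbSelf) {
    protein <- translateCds(g, id)
    win <- flankingWindow(g, id, side, factor = factor, minLen = minLen)
    hs <- searchWindow(protein, windowSequence(g, win), params)
    fp <- 100 * (aggregateTb(hs, "plus") - aggregateTb(hs, "minus")) /
      tbSelf
    max(as.numeric(applyScoreFilter(fp, tbSelf)),
        as.numeric(applyScoreFilter(-fp, tbSelf)))
  }
  c(a_down = one(idA, "downstream", selfA),
    b_up = one(idB, "upstream", selfB))
}

#' Screen TGA members for minisatellites and re-score suspicious arrays
#'
#' Every member CDS of every TGA is scanned
#' (\code{\link{quickTandemScan}} then \code{\link{exactTandem}}); a TGA
#' with any confirmed internal tandem repeat is flagged suspicious. A
#' flagged TGA is auto-rejected only when, after masking all repeat
#' spans in the genome, the re-scored facing FTB scores of every
#' adjacent CDS pair fall below the threshold -- i.e. the similarity
#' holding the array together was due to the shared repeat alone.
#'
#' @param tgaSet a \code{TgaSet}.
#' @param genome the \code{AnnotatedGenome}.
#' @param scores the \code{FtbScores} the TGAs came from (supplies the
#'   window rule and alignment parameters).
#' @param minUnit,maxUnit confirmed unit-size range (defaults 10, 300).
#' @param quickMaxUnit,quickThreshold quick-scan settings (600, 20).
#' @param threshold FTB threshold for the masked re-score (defaults to
#'   the set's extraction threshold).
#' @return a list: \code{flags} (one row per TGA: \code{flagged},
#'   \code{rejected}) and \code{repeats} (one row per confirmed repeat:
#'   host CDS, unit, copies, span, score, consensus).
#' @export
flagMinisatelliteTgas <- function(tgaSet, genome, scores,
                                  minUnit = 10, maxUnit = 300,
                                  quickMaxUnit = 600, quickThreshold = 20,
                                  threshold = NULL) {
  if (is.null(threshold)) threshold <- tgaSet@threshold
  params <- alignmentParams(scores)
  mem <- tgaMembers(tgaSet)
  tg <- tgaTable(tgaSet)
  reps <- NULL
  for (tid in tg$tga_id) {
    m <- mem[mem$tga_id == tid & mem$kind == "cds", , drop = FALSE]
    for (q in seq_len(nrow(m))) {
      id <- m$cds_id[q]
      dna <- cdsSequence(genome, id)
      cand <- quickTandemScan(dna, maxUnit = quickMaxUnit,
                              threshold = quickThreshold)
      if (!nrow(cand)) next
      et <- exactTandem(dna, minUnit = minUnit, maxUnit = maxUnit,
                        candidates = cand$unit)
      if (is.null(et)) next
      reps <- rbind(reps, cbind(data.frame(tga_id = tid, cds_id = id),
                                et))
    }
  }
  flags <- data.frame(tga_id = tg$tga_id, flagged = FALSE,
                      rejected = FALSE)
  if (!is.null(reps)) {
    for (tid in unique(reps$tga_id)) {
      r <- which(flags$tga_id == tid)
      flags$flagged[r] <- TRUE
      # genomic spans of every repeat in this TGA's members
      rr <- reps[reps$tga_id == tid, , drop = FALSE]
      spans <- do.call(rbind, lapply(seq_len(nrow(rr)), function(i) {
        map <- splicedToGenomic(genome, rr$cds_id[i])
        gpos <- map[rr$start[i]:rr$end[i]]
        data.frame(chrom = as.character(
          seqnames(genome@exons[[rr$cds_id[i]]]))[1],
          start = min(gpos), end = max(gpos))
      }))
      m <- mem[mem$tga_id == tid & mem$kind == "cds", , drop = FALSE]
      tab <- scoreTable(scores)
      selfOf <- stats::setNames(tab$tb_self, tab$cds_id)
      allBelow <- TRUE
      for (q in seq_len(nrow(m) - 1L)) {
        v <- rescorePair(genome, m$cds_id[q], m$cds_id[q + 1L], spans,
                         params, scores@factor, scores@minLen,
                         selfOf[[m$cds_id[q]]],
                         selfOf[[m$cds_id[q + 1L]]])
        if (any(v >= threshold)) { allBelow <- FALSE; break }
      }
      flags$rejected[r] <- allBelow
    }
  }
  list(flags = flags,
       repeats = if (is.null(reps)) data.frame(
         tga_id = character(), cds_id = character(), unit = integer(),
         copies = integer(), start = integer(), end = integer(),
         score = integer(), consensus = character()) else reps)
}
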