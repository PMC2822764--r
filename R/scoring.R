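#' TB self-score of a CDS
#'
#' The protein of the CDS aligned against its own spliced coding
#' sequence, aggregated with the same HSP-compatibility rule as any
#' window search. This is the normaliser that turns TB scores into
#' percent-of-self FTB scores.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param cdsId a CDS id.
#' @param params an \code{\link{alignParams}} object.
#' @return the self-score in bits (> 0 for any translatable CDS).
#' @export
selfScore <- function(genome, cdsId, params = alignParams()) {
  protein <- translateCds(genome, cdsId)
  dna <- cdsSequence(genome, cdsId)
  tb <- aggregateTb(searchWindow(protein, dna, params), "plus")
  if (tb <= 0)
    stop("degenerate annotation: self-score of ", cdsId, " is not > 0")
  tb
}

#' Strand-differenced FTB scores from four TB scores
#'
#' Each TB score is expressed as a percentage of the self-score
#' (X = plus strand, Y = minus strand, per side) and the two strands of
#' one side are differenced to cancel compositional background:
#' \code{f_plus = X - Y}, \code{f_minus = Y - X}. Per side, one score is
#' >= 0 and the other is its negative.
#'
#' @param tbSelf self-score in bits (> 0).
#' @param tbUpPlus,tbUpMinus,tbDownPlus,tbDownMinus TB scores in bits.
#' @return a list with \code{f_up_plus}, \code{f_up_minus},
#'   \code{f_down_plus}, \code{f_down_minus} in percent-of-self units.
#' @export
computeFtb <- function(tbSelf, tbUpPlus, tbUpMinus, tbDownPlus,
                       tbDownMinus) {
  stopifnot(all(tbSelf > 0))
  xu <- 100 * tbUpPlus / tbSelf
  yu <- 100 * tbUpMinus / tbSelf
  xd <- 100 * tbDownPlus / tbSelf
  yd <- 100 * tbDownMinus / tbSelf
  list(f_up_plus = xu - yu, f_up_minus = yu - xu,
       f_down_plus = xd - yd, f_down_minus = yd - xd)
}

#' Small-protein / low-complexity background filter
#'
#' Short or low-complexity proteins have small self-scores and therefore
#' inflated percent-of-self FTB scores. When the self-score is below 250
#' bits and an FTB score lies strictly between 0 and 50, the score is
#' reduced by \code{(250 - selfScore) / 4}. The filter is applied per
#' score, never increases a score, and leaves scores <= 0 or >= 50
#' untouched.
#'
#' @param ftb numeric vector of FTB scores.
#' @param tbSelf self-score(s) in bits (recycled).
#' @return numeric vector of filtered scores, with attribute
#'   \code{"filtered"}: a logical vector marking the scores touched.
#' @export
applyScoreFilter <- function(ftb, tbSelf) {
  hit <- tbSelf < 250 & ftb > 0 & ftb < 50
  out <- ifelse(hit, ftb - (250 - tbSelf) / 4, ftb)
  attr(out, "filtered") <- hit
  out
}

#' Score every CDS of a genome
#'
#' For each CDS: translate it, compute the TB self-score against its own
#' coding sequence, search both strands of its upstream and downstream
#' flanking windows, aggregate HSPs into the four TB scores, normalise
#' and strand-difference into FTB scores, and apply the small-protein
#' filter. Untranslatable CDSs (or CDSs whose self-score degenerates to
#' 0) get \code{NA} scores and are reported in a message.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param params an \code{\link{alignParams}} object.
#' @param factor,minLen flanking-window rule, see
#'   \code{\link{flankingWindow}}.
#' @param verbose print a progress line per chromosome.
#' @return an \code{\link[=FtbScores-class]{FtbScores}} object.
#' @export
scoreGenome <- function(genome, params = alignParams(), factor = 3,
                        minLen = 1500, verbose = FALSE) {
  cds <- cdsFeatures(genome)
  k <- length(cds)
  chrChar <- stats::setNames(as.character(genome@seqs),
                             names(genome@seqs))
  chrLen <- stats::setNames(nchar(chrChar), names(chrChar))
  st <- start(cds); en <- end(cds)
  chr <- as.character(seqnames(cds)); spl <- cds$spliced_len
  tbSelfV <- rep(NA_real_, k)
  rawM <- matrix(NA_real_, k, 4)  # up+, up-, down+, down-
  filtM <- matrix(NA_real_, k, 4)
  filtFlags <- character(k)
  cols <- c("f_up_plus", "f_up_minus", "f_down_plus", "f_down_minus")
  skipped <- character()
  for (i in seq_len(k)) {
    id <- cds$cds_id[i]
    if (!cds$translatable[i]) { skipped <- c(skipped, id); next }
    protein <- as.character(translateCds(genome, id))
    tbSelf <- aggregateTb(
      searchWindow(protein, as.character(cdsSequence(genome, id)),
                   params), "plus")
    if (tbSelf <= 0) { skipped <- c(skipped, id); next }
    wlen <- as.integer(max(factor * spl[i], minLen))
    seqc <- chrChar[[chr[i]]]
    tb <- numeric(4)
    for (s in 1:2) {
      wseq <- if (s == 1L) {
        if (st[i] > 1L) substr(seqc, max(1L, st[i] - wlen), st[i] - 1L)
        else ""
      } else {
        if (en[i] < chrLen[[chr[i]]])
          substr(seqc, en[i] + 1L, min(chrLen[[chr[i]]], en[i] + wlen))
        else ""
      }
      if (nchar(wseq) >= 3L) {
        hs <- searchWindow(protein, wseq, params)
        tb[2 * s - 1] <- aggregateTb(hs, "plus")
        tb[2 * s] <- aggregateTb(hs, "minus")
      }
    }
    f <- computeFtb(tbSelf, tb[1], tb[2], tb[3], tb[4])
    tbSelfV[i] <- tbSelf
    raw <- c(f$f_up_plus, f$f_up_minus, f$f_down_plus, f$f_down_minus)
    filt <- applyScoreFilter(raw, tbSelf)
    rawM[i, ] <- raw
    filtM[i, ] <- as.numeric(filt)
    filtFlags[i] <- paste(cols[attr(filt, "filtered")], collapse = ",")
    if (verbose && (i %% 25 == 0 || i == k))
      message("scored ", i, "/", k, " CDS")
  }
  if (length(skipped))
    message("CDS with null scores (untranslatable/degenerate): ",
            paste(skipped, collapse = ", "))
  tab <- DataFrame(
    cds_id = cds$cds_id, chrom = chr, rank = cds$rank,
    start = st, end = en, strand = as.character(strand(cds)),
    spliced_len = spl, tb_self = tbSelfV,
    f_up_plus = filtM[, 1], f_up_minus = filtM[, 2],
    f_down_plus = filtM[, 3], f_down_minus = filtM[, 4],
    raw_f_up_plus = rawM[, 1], raw_f_up_minus = rawM[, 2],
    raw_f_down_plus = rawM[, 3], raw_f_down_minus = rawM[, 4],
    filtered = filtFlags)
  new("FtbScores", table = tab, params = params, factor = factor,
      minLen = minLen)
}

#' Write a score table as TSV
#'
#' Floating scores are fixed at 2 decimals and rows keep their stable
#' (chromosome, rank) order, so identical runs give byte-identical
#' files.
#'
#' @param scores an \code{FtbScores} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeScoreTable <- function(scores, path) {
  tab <- as.data.frame(scoreTable(scores))
  num <- vapply(tab, is.numeric, logical(1)) &
    !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.2f", x))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
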