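.taCache <- new.env(parent = emptyenv())

# Substitution matrix with the stop-codon convention applied: '*' scores
# params@stopScore against everything (itself included), so alignments
# can run across the premature stops of degenerated gene copies.
scoringMatrix <- function(params) {
  key <- paste0(params@matrixName, "|", params@stopScore)
  if (!is.null(.taCache[[key]])) return(.taCache[[key]])
  e <- new.env()
  utils::data(list = params@matrixName, package = "Biostrings", envir = e)
  mat <- e[[params@matrixName]]
  if ("*" %in% rownames(mat)) {
    mat["*", ] <- params@stopScore
    mat[, "*"] <- params@stopScore
  }
  storage.mode(mat) <- "integer"
  .taCache[[key]] <- mat
  mat
}

# 0-based codes into the matrix alphabet; unknown letters map to X.
aaCodes <- function(aa, mat) {
  alph <- rownames(mat)
  lut <- rep.int(match("X", alph) - 1L, 127L)
  lut[utf8ToInt(paste(alph, collapse = ""))] <- seq_along(alph) - 1L
  lut[as.integer(charToRaw(as.character(aa)))]
}

# codon index (16 b1 + 4 b2 + b3, ACGT = 0..3) -> matrix-alphabet code
codonAaCodes <- function(params) {
  key <- paste0("codon|", params@matrixName, "|", params@stopScore,
                "|", params@geneticCode)
  if (!is.null(.taCache[[key]])) return(.taCache[[key]])
  mat <- scoringMatrix(params)
  gc <- getGeneticCode(params@geneticCode)
  b <- c("A", "C", "G", "T")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4),
                   rep(b, 16))
  aa <- unname(gc[codons])
  code <- match(aa, rownames(mat)) - 1L
  code[is.na(code)] <- match("X", rownames(mat)) - 1L
  .taCache[[key]] <- code
  code
}

#' Bit score of a raw alignment score
#'
#' The standard Karlin-Altschul transform
#' \code{(lambda * raw - ln K) / ln 2}.
#'
#' @param raw raw score(s) in substitution-matrix units.
#' @param params an \code{\link{alignParams}} object.
#' @return bit score(s).
#' @examples
#' bitScore(0, alignParams())   # -ln(0.041)/ln 2 = 4.61 bits
#' bitScore(14, alignParams())  # ~10 bits
#' @export
bitScore <- function(raw, params = alignParams()) {
  (params@lambda * raw - log(params@K)) / log(2)
}

hspEvalue <- function(raw, m, n, params) {
  params@K * m * n * exp(-params@lambda * raw)
}

#' Translated local alignment of a protein against a DNA window
#'
#' All six reading frames (three per strand) of the window are translated
#' and aligned locally against the protein with affine gaps
#' (Waterman-Eggert: within one frame, successive non-overlapping-in-
#' subject alignments are reported until the score drops below the
#' E-value cutoff). Coordinates are reported in window space (1-based,
#' plus-strand orientation); E-values use m x n = protein length x
#' window length in bp.
#'
#' @param protein an \code{AAString} (or string).
#' @param dna a \code{DNAString} (or string); may be empty.
#' @param params an \code{\link{alignParams}} object.
#' @param maxHsps cap on HSPs per frame.
#' @return a data.frame of HSPs sorted by decreasing bit score:
#'   \code{q_start}, \code{q_end} (protein aa), \code{s_start},
#'   \code{s_end} (window bp, plus strand), \code{strand}, \code{frame},
#'   \code{raw}, \code{bits}, \code{evalue}.
#' @export
searchWindow <- function(protein, dna, params = alignParams(),
                         maxHsps = 30L) {
  empty <- data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), frame = integer(),
                      raw = integer(), bits = numeric(),
                      evalue = numeric())
  prot <- as.character(protein)
  dnaChr <- as.character(dna)
  m <- nchar(prot); n <- nchar(dnaChr)
  if (m == 0L || n < 3L) return(empty)
  mat <- scoringMatrix(params)
  q <- aaCodes(prot, mat)
  s <- dnaCodes(dnaChr)
  minRaw <- max(1L, as.integer(ceiling(
    log(params@K * m * n / params@evalueMax) / params@lambda)))
  hits <- cpp_search_frames(q, s, codonAaCodes(params),
                            match("X", rownames(mat)) - 1L, mat,
                            as.integer(params@gapOpen),
                            as.integer(params@gapExtend), minRaw,
                            as.integer(maxHsps))
  if (nrow(hits) == 0L) return(empty)
  f <- hits[, 2L]
  nt1 <- f + 3L * (hits[, 5L] - 1L) + 1L
  nt2 <- f + 3L * hits[, 6L]
  minus <- hits[, 1L] == 1L
  tmp <- ifelse(minus, n - nt2 + 1L, nt1)
  nt2 <- ifelse(minus, n - nt1 + 1L, nt2)
  nt1 <- tmp
  res <- data.frame(
    q_start = hits[, 3L], q_end = hits[, 4L],
    s_start = nt1, s_end = nt2,
    strand = ifelse(minus, "minus", "plus"), frame = f,
    raw = hits[, 7L], bits = bitScore(hits[, 7L], params),
    evalue = hspEvalue(hits[, 7L], m, n, params))
  res <- res[res$evalue <= params@evalueMax, , drop = FALSE]
  res <- res[order(-res$bits, res$q_start, res$s_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aggregate compatible HSPs into a TB score
#'
#' The TB score of one window strand is the sum of bit scores of all
#' HSPs on that strand that do not overlap by more than 20\%. Selection
#' is greedy in decreasing bit-score order; a candidate is kept iff its
#' overlap with every already-kept HSP is at most 20\% of the shorter of
#' the two spans. Overlap is measured on the protein (query) axis, the
#' axis the self-score normalisation is relative to. An overlap of
#' exactly 20\% is allowed.
#'
#' @param hsps a data.frame from \code{\link{searchWindow}}.
#' @param strand \code{"plus"} or \code{"minus"}.
#' @param maxOverlap overlap tolerance as a fraction of the shorter
#'   query span (default 0.2).
#' @return the TB score in bits (0 for no HSPs).
#' @export
aggregateTb <- function(hsps, strand = c("plus", "minus"),
                        maxOverlap = 0.2) {
  strand <- match.arg(strand)
  h <- hsps[hsps$strand == strand, , drop = FALSE]
  if (nrow(h) == 0L) return(0)
  h <- h[order(-h$bits, h$q_start, h$s_start), , drop = FALSE]
  keptS <- integer(); keptE <- integer()
  tb <- 0
  for (i in seq_len(nrow(h))) {
    s <- h$q_start[i]; e <- h$q_end[i]; len <- e - s + 1L
    ok <- TRUE
    for (k in seq_along(keptS)) {
      ov <- min(e, keptE[k]) - max(s, keptS[k]) + 1L
      if (ov > 0L) {
        shorter <- min(len, keptE[k] - keptS[k] + 1L)
        if (ov > maxOverlap * shorter) { ok <- FALSE; break }
      }
    }
    if (ok) {
      keptS <- c(keptS, s); keptE <- c(keptE, e)
      tb <- tb + h$bits[i]
    }
  }
  tb
}
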