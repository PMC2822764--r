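#' AlignParams: translated-search scoring context
#'
#' Holds the substitution matrix and Karlin-Altschul statistics used for
#' every translated local alignment. Defaults follow the published gapped
#' BLOSUM62/11/1 statistics (lambda = 0.267, K = 0.041); the E-value
#' cutoff of 1.0 is the method's search threshold. Stop codons translate
#' to \code{*} and score \code{stopScore} against every residue, so
#' alignments can extend across the premature stops of gene relics.
#'
#' @slot matrixName name of a substitution matrix shipped with Biostrings.
#' @slot gapOpen,gapExtend affine gap penalties (positive).
#' @slot lambda,K gapped Karlin-Altschul parameters.
#' @slot evalueMax maximum E-value for a reported HSP.
#' @slot stopScore score of \code{*} against everything.
#' @slot geneticCode NCBI genetic-code table id (\code{"1"} standard,
#'   \code{"12"} alternative yeast nuclear, CUG = Ser).
#' @exportClass AlignParams
setClass("AlignParams", representation(
  matrixName = "character",
  gapOpen = "numeric",
  gapExtend = "numeric",
  lambda = "numeric",
  K = "numeric",
  evalueMax = "numeric",
  stopScore = "numeric",
  geneticCode = "character"
))

setValidity("AlignParams", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@K <= 0 || object@K >= 1) msg <- c(msg, "K must be in (0, 1)")
  if (object@gapOpen <= 0 || object@gapExtend <= 0)
    msg <- c(msg, "gap penalties must be > 0")
  if (object@evalueMax <= 0) msg <- c(msg, "evalueMax must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct alignment parameters
#'
#' @param matrixName substitution matrix name (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend affine gap penalties, default 11 and 1.
#' @param lambda,K gapped Karlin-Altschul parameters for the matrix and
#'   gap costs; defaults are the published BLOSUM62/11/1 values.
#' @param evalueMax E-value threshold for reported HSPs (default 1.0).
#' @param stopScore score of a stop codon against any residue (default -4).
#' @param geneticCode NCBI translation table id (default \code{"1"}).
#' @return an \code{AlignParams} object.
#' @examples
#' alignParams()
#' alignParams(geneticCode = "12")  # CUG-Ser clade genomes
#' @export
alignParams <- function(matrixName = "BLOSUM62", gapOpen = 11,
                        gapExtend = 1, lambda = 0.267, K = 0.041,
                        evalueMax = 1.0, stopScore = -4,
                        geneticCode = "1") {
  new("AlignParams", matrixName = matrixName, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, K = K,
      evalueMax = evalueMax, stopScore = stopScore,
      geneticCode = geneticCode)
}

setMethod("show", "AlignParams", function(object) {
  cat("AlignParams:", object@matrixName,
      sprintf("gap %g/%g, lambda %g, K %g, E<=%g, code %s\n",
              object@gapOpen, object@gapExtend, object@lambda, object@K,
              object@evalueMax, object@geneticCode))
})

#' AnnotatedGenome: chromosome sequences plus ordered CDS annotation
#'
#' The container every step of the method works from: chromosome DNA as a
#' \code{DNAStringSet}, per-CDS exon structure as a named
#' \code{GRangesList}, and a rank-ordered CDS summary \code{GRanges}
#' (one range per CDS spanning its outermost coordinates). Ranks are
#' 0-based, contiguous per chromosome, ascending with start coordinate --
#' the position index the extraction automaton walks.
#'
#' @slot seqs chromosome sequences (\code{DNAStringSet}).
#' @slot exons exon ranges per CDS (\code{GRangesList}, names = CDS ids).
#' @slot cds one range per CDS with mcols \code{cds_id}, \code{rank},
#'   \code{spliced_len}, \code{translatable}.
#' @slot geneticCode NCBI translation table id for this genome.
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome", representation(
  seqs = "DNAStringSet",
  exons = "GRangesList",
  cds = "GRanges",
  geneticCode = "character"
))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  ids <- object@cds$cds_id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated CDS ids")
  if (!all(ids %in% names(object@exons)))
    msg <- c(msg, "every CDS needs an exon entry")
  sl <- seqlengths(object@cds)
  if (any(is.na(sl))) msg <- c(msg, "missing chromosome lengths")
  bad <- end(object@cds) > sl[as.character(seqnames(object@cds))] |
    start(object@cds) < 1L
  if (any(bad))
    msg <- c(msg, paste("CDS outside chromosome bounds:",
                        paste(ids[bad], collapse = ", ")))
  for (chr in unique(as.character(seqnames(object@cds)))) {
    sel <- as.character(seqnames(object@cds)) == chr
    r <- sort(object@cds$rank[sel])
    if (!identical(r, seq_len(sum(sel)) - 1L))
      msg <- c(msg, sprintf("ranks on %s not contiguous 0..k-1", chr))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome:", length(object@seqs), "chromosome(s),",
      length(object@cds), "CDS, genetic code", object@geneticCode, "\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%d bp)", names(object@seqs),
                    BiocGenerics::width(object@seqs)), collapse = ", "),
      "\n")
})

#' FtbScores: the per-CDS TB/FTB score table of one genome
#'
#' One row per CDS with the TB self-score (bits) and the four filtered
#' FTB scores (percent-of-self units): upstream/downstream x plus/minus
#' strand. Raw (pre-filter) FTB values and filter flags are kept
#' alongside. FTB scores are antisymmetric per side before filtering:
#' \code{f_up_plus == -f_up_minus}.
#'
#' @slot table a \code{DataFrame}, one row per CDS.
#' @slot params the \code{AlignParams} used.
#' @slot factor,minLen the flanking-window rule used (length =
#'   \code{max(factor * L_CDS, minLen)}).
#' @exportClass FtbScores
setClass("FtbScores", representation(
  table = "DataFrame",
  params = "AlignParams",
  factor = "numeric",
  minLen = "numeric"
))

setValidity("FtbScores", function(object) {
  need <- c("cds_id", "chrom", "rank", "strand", "tb_self",
            "f_up_plus", "f_up_minus", "f_down_plus", "f_down_minus")
  if (!all(need %in% colnames(object@table)))
    return(paste("score table must have columns:",
                 paste(need, collapse = ", ")))
  TRUE
})

setMethod("show", "FtbScores", function(object) {
  tab <- object@table
  nsig <- sum(pmax(tab$f_up_plus, tab$f_up_minus, tab$f_down_plus,
                   tab$f_down_minus, na.rm = TRUE) >= 10, na.rm = TRUE)
  cat("FtbScores:", nrow(tab), "CDS scored, window = max(",
      object@factor, "x L,", object@minLen, "bp );",
      nsig, "CDS with an FTB score >= 10\n")
})

#' TgaSet: extracted tandem gene arrays, members and tagged CDSs
#'
#' Result of the extraction automaton (and, after curation, of relic
#' confirmation). \code{tgas} has one row per array with its size class
#' (\code{2CDS}, \code{3CDS}, ..., \code{1CDS-relic}, \code{nCDSs-relic}),
#' orientation class and flank scores S1/S4; \code{members} one row per
#' member (kind \code{cds}, \code{spacer} or \code{relic}) in coordinate
#' order with the facing pair scores; \code{tagged} one row per relic-tag
#' (isolated CDS with a significant score, or array edge with an outward
#' significant score) with its curation status.
#'
#' @slot tgas,members,tagged \code{DataFrame}s, see above.
#' @slot threshold the FTB significance threshold used.
#' @exportClass TgaSet
setClass("TgaSet", representation(
  tgas = "DataFrame",
  members = "DataFrame",
  tagged = "DataFrame",
  threshold = "numeric"
))

setValidity("TgaSet", function(object) {
  msg <- character()
  if (nrow(object@members)) {
    cdsm <- object@members[object@members$kind == "cds", , drop = FALSE]
    if (anyDuplicated(cdsm$cds_id))
      msg <- c(msg, "a CDS belongs to more than one TGA")
    ncds <- table(factor(cdsm$tga_id, levels = object@tgas$tga_id))
    nrel <- table(factor(
      object@members$tga_id[object@members$kind == "relic"],
      levels = object@tgas$tga_id))
    if (any(ncds + nrel < 2))
      msg <- c(msg, "every TGA needs >= 2 homologous members")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TgaSet", function(object) {
  cat("TgaSet:", nrow(object@tgas), "TGA(s),",
      sum(object@members$kind == "cds"), "member CDS,",
      sum(object@members$kind == "relic"), "relic(s),",
      nrow(object@tagged), "tagged CDS, threshold",
      object@threshold, "\n")
  if (nrow(object@tgas)) {
    cat("  size classes:",
        paste(names(table(object@tgas$size_class)),
              table(object@tgas$size_class), sep = "=", collapse = " "),
        "\n")
    cat("  orientations:",
        paste(names(table(object@tgas$orientation_class)),
              table(object@tgas$orientation_class), sep = "=",
              collapse = " "), "\n")
  }
})
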