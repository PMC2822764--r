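#' Full TGA prediction pipeline
#'
#' Runs the complete method on one genome: per-CDS FTB scoring, the
#' extraction automaton, tagged-CDS curation (pair merging and dotplot
#' relic confirmation), protein-dotplot pair verification, and the
#' minisatellite screen (suspicious arrays whose masked re-score falls
#' below the threshold are removed).
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param params an \code{\link{alignParams}}.
#' @param threshold FTB significance threshold (default 10).
#' @param factor,minLen flanking-window rule (defaults 3 and 1500 bp).
#' @param allowSpacer allow one spacer gene inside a TGA.
#' @param scores optionally, a precomputed \code{FtbScores} for this
#'   genome (skips the expensive scoring step).
#' @param verbose progress messages.
#' @return a list: \code{scores} (\code{FtbScores}), \code{tgas} (the
#'   final \code{TgaSet}), \code{raw_tgas} (before curation),
#'   \code{minisat} (screen output of
#'   \code{\link{flagMinisatelliteTgas}}), \code{summary}
#'   (\code{\link{summarizeTgas}}).
#' @export
predictTgas <- function(genome, params = alignParams(), threshold = 10,
                        factor = 3, minLen = 1500, allowSpacer = TRUE,
                        scores = NULL, verbose = FALSE) {
  if (is.null(scores))
    scores <- scoreGenome(genome, params = params, factor = factor,
                          minLen = minLen, verbose = verbose)
  raw <- extractTgas(scores, genome, threshold = threshold,
                     allowSpacer = allowSpacer)
  cur <- curateTagged(raw, scores, genome)
  ver <- verifyTgaPairs(cur, genome)
  ms <- flagMinisatelliteTgas(ver, genome, scores,
                              threshold = threshold)
  drop <- ms$flags$tga_id[ms$flags$rejected]
  final <- ver
  if (length(drop)) {
    final@tgas <- final@tgas[!(final@tgas$tga_id %in% drop), ,
                             drop = FALSE]
    final@members <- final@members[!(final@members$tga_id %in% drop), ,
                                   drop = FALSE]
  }
  list(scores = scores, tgas = final, raw_tgas = raw, minisat = ms,
       summary = summarizeTgas(final, genome))
}
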