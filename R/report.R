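#' Summary statistics of a TGA catalog
#'
#' @param tgaSet a \code{TgaSet} (typically after curation).
#' @param genome the \code{AnnotatedGenome}.
#' @return a list: total and in-TGA CDS counts, the percentage of CDSs
#'   in TGAs (1 decimal), TGA count, counts per size class and per
#'   orientation class, and the count/fraction of relic-containing
#'   TGAs.
#' @export
summarizeTgas <- function(tgaSet, genome) {
  tg <- tgaTable(tgaSet)
  mem <- tgaMembers(tgaSet)
  nTotal <- length(cdsFeatures(genome))
  nIn <- sum(mem$kind == "cds")
  withRelic <- tg$size_class %in% c("1CDS-relic", "nCDSs-relic") |
    tg$n_relic > 0
  list(
    n_cds_total = nTotal,
    n_cds_in_tgas = nIn,
    pct_cds_in_tgas = round(100 * nIn / max(1L, nTotal), 1),
    n_tgas = nrow(tg),
    size_classes = table(tg$size_class),
    orientation_classes = table(tg$orientation_class),
    n_tgas_with_relic = sum(withRelic),
    frac_tgas_with_relic = if (nrow(tg)) round(sum(withRelic) /
                                                 nrow(tg), 3) else 0)
}

#' Expected frequency of mixed TGAs among large ones
#'
#' Under independence, the expected frequency of arrays that are both
#' large (>= 3 CDSs) and contain an opposite-oriented pair is the
#' product of the two marginal frequencies, reported to 3 decimals.
#'
#' @param pOpposite frequency of opposite-oriented pairs, in [0, 1].
#' @param pGe3 frequency of arrays with >= 3 CDSs, in [0, 1].
#' @return the product, rounded to 3 decimals.
#' @examples
#' expectedOppositeInLarge(0.190, 0.139)  # 0.026
#' @export
expectedOppositeInLarge <- function(pOpposite, pGe3) {
  stopifnot(pOpposite >= 0, pOpposite <= 1, pGe3 >= 0, pGe3 <= 1)
  round(pOpposite * pGe3, 3)
}

#' Percent identity of two proteins from a local alignment
#'
#' Identity = 100 x identities / alignment length of the best local
#' alignment (substitution matrix and gap costs from \code{params}), no
#' low-complexity masking. Pairs whose alignment is not significant at
#' the E-value cutoff are reported as \code{NA}.
#'
#' @param proteinA,proteinB \code{AAString}s or strings.
#' @param params an \code{\link{alignParams}} object.
#' @return percent identity, or \code{NA} for no significant alignment.
#' @export
pairIdentity <- function(proteinA, proteinB, params = alignParams()) {
  a <- AAString(proteinA); b <- AAString(proteinB)
  mat <- scoringMatrix(params)
  aln <- pairwiseAlignment(a, b, type = "local",
                           substitutionMatrix = mat,
                           gapOpening = params@gapOpen,
                           gapExtension = params@gapExtend)
  raw <- BiocGenerics::score(aln)
  ev <- hspEvalue(raw, length(a), length(b), params)
  if (!is.finite(raw) || raw <= 0 || ev > params@evalueMax)
    return(NA_real_)
  pid(aln, type = "PID1")
}

#' Sweep the two method parameters
#'
#' Re-runs the full score + extraction pipeline for every combination
#' of window factor and FTB threshold and reports TGA and tagged-CDS
#' counts. Scoring is done once per factor; thresholds only re-run the
#' (cheap) extraction.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param factors window factors (default \code{c(2, 3)}).
#' @param thresholds FTB thresholds (default \code{c(10, 15)}).
#' @param params an \code{\link{alignParams}}.
#' @param minLen minimal window length (default 1500).
#' @param allowSpacer passed to \code{\link{extractTgas}}.
#' @return a data.frame with one row per (factor, threshold) cell:
#'   \code{n_tgas}, \code{n_tagged} (isolated relic tags),
#'   \code{n_tagged_edge}.
#' @export
sweepParameters <- function(genome, factors = c(2, 3),
                            thresholds = c(10, 15),
                            params = alignParams(), minLen = 1500,
                            allowSpacer = TRUE) {
  out <- NULL
  for (f in factors) {
    sc <- scoreGenome(genome, params = params, factor = f,
                      minLen = minLen)
    for (th in sort(thresholds)) {
      ts <- extractTgas(sc, genome, threshold = th,
                        allowSpacer = allowSpacer)
      tags <- taggedCds(ts)
      out <- rbind(out, data.frame(
        factor = f, threshold = th,
        n_tgas = nrow(tgaTable(ts)),
        n_tagged = sum(tags$reason == "isolated_with_signal"),
        n_tagged_edge = sum(tags$reason == "tga_edge_outward_signal")))
    }
  }
  out
}

#' Write a TGA catalog as TSV (plus a BED of relic intervals)
#'
#' @param tgaSet a \code{TgaSet}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeTgaTables <- function(tgaSet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "tgas.tsv")
  p2 <- file.path(dir, "tga_members.tsv")
  p3 <- file.path(dir, "tagged_cds.tsv")
  p4 <- file.path(dir, "relics.bed")
  write.table(as.data.frame(tgaTable(tgaSet)), p1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(tgaMembers(tgaSet)), p2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(taggedCds(tgaSet)), p3, sep = "\t",
              quote = FALSE, row.names = FALSE)
  rel <- as.data.frame(tgaMembers(tgaSet))
  rel <- rel[rel$kind == "relic", , drop = FALSE]
  if (nrow(rel)) {
    bed <- data.frame(chrom = rel$chrom, start = rel$start - 1L,
                      end = rel$end,
                      name = paste0(rel$tga_id, "_relic"),
                      score = 0L, strand = rel$strand)
    write.table(bed, p4, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else file.create(p4)
  invisible(c(p1, p2, p3, p4))
}
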