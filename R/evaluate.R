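truthArrayClass <- function(strands) {
  classifyTgaOrientation(pairOrientation(strands[-length(strands)],
                                         strands[-1L]))
}

#' Score a prediction against planted synthetic truth
#'
#' Compares a pipeline result with the truth ledger of
#' \code{\link{generateGenome}}. An all-CDS planted array counts as
#' recovered only when some predicted TGA has exactly its member set
#' (spacers excluded on both sides); its orientation is correct when
#' the predicted class equals the class computed from the planted
#' strands. A planted relic is confirmed when a relic-class TGA pairs
#' the host CDS with a relic interval overlapping the planted locus. A
#' predicted TGA is a false positive when it involves any background
#' CDS or mixes families.
#'
#' @param sim output of \code{\link{generateGenome}}.
#' @param tgaSet the final \code{TgaSet} of \code{\link{predictTgas}}.
#' @return a list of counts and rates; see field names.
#' @export
evaluateRecovery <- function(sim, tgaSet) {
  truth <- sim$truth$arrays
  tg <- tgaTable(tgaSet)
  mem <- tgaMembers(tgaSet)
  fam2id <- split(truth$cds_id[truth$kind == "cds"],
                  truth$family[truth$kind == "cds"])
  id2fam <- stats::setNames(truth$family[truth$kind == "cds"],
                            truth$cds_id[truth$kind == "cds"])
  predSets <- lapply(tg$tga_id, function(tid)
    sort(mem$cds_id[mem$tga_id == tid & mem$kind == "cds"]))
  names(predSets) <- tg$tga_id

  relFams <- unique(truth$family[truth$kind == "relic"])
  arrFams <- setdiff(names(fam2id)[lengths(fam2id) >= 2L], relFams)

  nRec <- 0L; oriOk <- 0L
  for (fam in arrFams) {
    ids <- sort(fam2id[[fam]])
    hit <- which(vapply(predSets, identical, logical(1), ids))
    if (length(hit)) {
      nRec <- nRec + 1L
      tstr <- truth[truth$family == fam & truth$kind == "cds", ,
                    drop = FALSE]
      tstr <- tstr[order(tstr$start), , drop = FALSE]
      if (identical(tg$orientation_class[hit[1]],
                    truthArrayClass(tstr$strand)))
        oriOk <- oriOk + 1L
    }
  }

  nRelConf <- 0L
  for (fam in relFams) {
    host <- fam2id[[fam]]
    rel <- truth[truth$family == fam & truth$kind == "relic", ,
                 drop = FALSE]
    ok <- FALSE
    for (tid in tg$tga_id[tg$n_relic > 0]) {
      mm <- mem[mem$tga_id == tid, , drop = FALSE]
      if (!all(host %in% mm$cds_id)) next
      rm <- mm[mm$kind == "relic", , drop = FALSE]
      if (any(rm$start <= rel$end[1] & rm$end >= rel$start[1]))
        ok <- TRUE
    }
    if (ok) nRelConf <- nRelConf + 1L
  }

  nFp <- 0L
  for (tid in tg$tga_id) {
    ids <- mem$cds_id[mem$tga_id == tid & mem$kind == "cds"]
    fams <- unname(id2fam[ids])
    if (any(is.na(fams)) || length(unique(fams)) > 1L)
      nFp <- nFp + 1L
  }

  list(n_arrays = length(arrFams), n_recovered = nRec,
       n_orientation_ok = oriOk,
       n_relics = length(relFams), n_relics_confirmed = nRelConf,
       n_false_positive = nFp, n_tgas = nrow(tg))
}
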