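#' Accessors for TandemArrays classes
#'
#' @param x an \code{AnnotatedGenome}, \code{FtbScores} or \code{TgaSet}.
#' @return \code{chromosomes}: the \code{DNAStringSet} of chromosome
#'   sequences; \code{cdsFeatures}: the rank-ordered CDS summary
#'   \code{GRanges}; \code{cdsExons}: the per-CDS exon
#'   \code{GRangesList}; \code{geneticCode}: the NCBI table id;
#'   \code{scoreTable}, \code{tgaTable}, \code{tgaMembers},
#'   \code{taggedCds}: the corresponding \code{DataFrame}s;
#'   \code{alignmentParams}: the \code{AlignParams} used for scoring.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setMethod("chromosomes", "AnnotatedGenome", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("cdsFeatures", function(x) standardGeneric("cdsFeatures"))
#' @rdname accessors
#' @export
setMethod("cdsFeatures", "AnnotatedGenome", function(x) x@cds)

#' @rdname accessors
#' @export
setGeneric("cdsExons", function(x) standardGeneric("cdsExons"))
#' @rdname accessors
#' @export
setMethod("cdsExons", "AnnotatedGenome", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("geneticCode", function(x) standardGeneric("geneticCode"))
#' @rdname accessors
#' @export
setMethod("geneticCode", "AnnotatedGenome", function(x) x@geneticCode)

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname accessors
#' @export
setMethod("scoreTable", "FtbScores", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("alignmentParams", function(x) standardGeneric("alignmentParams"))
#' @rdname accessors
#' @export
setMethod("alignmentParams", "FtbScores", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("tgaTable", function(x) standardGeneric("tgaTable"))
#' @rdname accessors
#' @export
setMethod("tgaTable", "TgaSet", function(x) x@tgas)

#' @rdname accessors
#' @export
setGeneric("tgaMembers", function(x) standardGeneric("tgaMembers"))
#' @rdname accessors
#' @export
setMethod("tgaMembers", "TgaSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("taggedCds", function(x) standardGeneric("taggedCds"))
#' @rdname accessors
#' @export
setMethod("taggedCds", "TgaSet", function(x) x@tagged)
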