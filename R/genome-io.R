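#' Assemble an AnnotatedGenome from sequences and exon ranges
#'
#' Internal constructor shared by the file readers and the synthetic
#' generator. Sorts CDSs by start coordinate, assigns contiguous 0-based
#' ranks per chromosome, and flags untranslatable features. A spliced
#' length that is not a multiple of 3 triggers a warning; the trailing
#' incomplete codon is trimmed at sequence-extraction time.
#'
#' @param seqs a \code{DNAStringSet} of chromosomes (upper-cased here).
#' @param exons a named \code{GRangesList}, one element per CDS, each with
#'   sorted, non-overlapping exon ranges and one strand.
#' @param geneticCode NCBI table id.
#' @return an \code{AnnotatedGenome}.
#' @keywords internal
makeAnnotatedGenome <- function(seqs, exons, geneticCode = "1") {
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  sl <- stats::setNames(BiocGenerics::width(seqs), names(seqs))
  ids <- names(exons)
  if (is.null(ids) || anyDuplicated(ids))
    stop("exon list must be uniquely named by CDS id")
  chr1 <- vapply(seq_along(exons),
                 function(i) as.character(seqnames(exons[[i]]))[1],
                 character(1))
  unknown <- !(chr1 %in% names(seqs))
  if (any(unknown))
    stop("annotation references chromosome(s) absent from FASTA for ",
         "feature(s): ", paste(ids[unknown], collapse = ", "))
  spl <- vapply(seq_along(exons), function(i) sum(width(exons[[i]])),
                integer(1))
  if (any(spl %% 3L != 0L))
    warning("spliced length not a multiple of 3 for ",
            paste(ids[spl %% 3L != 0L], collapse = ", "),
            "; trailing incomplete codon will be trimmed")
  st <- vapply(seq_along(exons), function(i) min(start(exons[[i]])),
               integer(1))
  en <- vapply(seq_along(exons), function(i) max(end(exons[[i]])),
               integer(1))
  strd <- vapply(seq_along(exons),
                 function(i) as.character(strand(exons[[i]]))[1],
                 character(1))
  ord <- order(chr1, st, en, ids)
  cds <- GRanges(chr1[ord], IRanges(st[ord], en[ord]), strand = strd[ord],
                 seqlengths = sl)
  mcols(cds)$cds_id <- ids[ord]
  mcols(cds)$spliced_len <- spl[ord]
  mcols(cds)$translatable <- (spl[ord] %/% 3L) >= 2L
  rank <- integer(length(cds))
  for (chr in names(seqs)) {
    sel <- as.character(seqnames(cds)) == chr
    rank[sel] <- seq_len(sum(sel)) - 1L
  }
  mcols(cds)$rank <- rank
  exons <- exons[ids[ord]]
  new("AnnotatedGenome", seqs = seqs, exons = exons, cds = cds,
      geneticCode = geneticCode)
}

parseExonSpec <- function(spec) {
  parts <- strsplit(strsplit(spec, ",")[[1]], "-")
  st <- as.integer(vapply(parts, `[`, character(1), 1))
  en <- as.integer(vapply(parts, `[`, character(1), 2))
  list(start = st, end = en)
}

#' Read a genome with its CDS annotation
#'
#' Loads chromosome sequences from a (multi-record) FASTA file and CDS
#' features from either a GFF3 file (rows of type \code{CDS}, grouped by
#' their \code{Parent}, or \code{ID} when no parent is given) or a simple
#' 4-column TSV: \code{id}, \code{chrom}, \code{strand}, \code{exons}
#' with exons written \code{start-end,start-end} (1-based inclusive).
#' Features are sorted by start coordinate and given contiguous 0-based
#' ranks per chromosome. When a GFF3 locus carries several isoforms only
#' the first is kept (with a message).
#'
#' @param fastaPath path to the genome FASTA.
#' @param annotationPath path to the GFF3 or TSV annotation.
#' @param geneticCode NCBI translation table id; \code{"12"} selects the
#'   alternative yeast nuclear code (CUG = Ser).
#' @param format \code{"auto"} (by extension), \code{"gff3"} or
#'   \code{"tsv"}.
#' @return an \code{\link[=AnnotatedGenome-class]{AnnotatedGenome}}.
#' @export
readAnnotatedGenome <- function(fastaPath, annotationPath,
                                geneticCode = "1",
                                format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", annotationPath, ignore.case = TRUE))
      "gff3" else "tsv"
  seqs <- readDNAStringSet(fastaPath)
  if (format == "tsv") {
    tab <- read.delim(annotationPath, stringsAsFactors = FALSE)
    need <- c("id", "chrom", "strand", "exons")
    if (!all(need %in% colnames(tab)))
      stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
    grl <- lapply(seq_len(nrow(tab)), function(i) {
      ex <- parseExonSpec(tab$exons[i])
      o <- order(ex$start)
      GRanges(tab$chrom[i], IRanges(ex$start[o], ex$end[o]),
              strand = tab$strand[i])
    })
    names(grl) <- tab$id
  } else {
    gff <- rtracklayer::import(annotationPath)
    gff <- gff[gff$type == "CDS"]
    if (!length(gff)) stop("no CDS features in ", annotationPath)
    parent <- if (!is.null(gff$Parent) && any(lengths(gff$Parent) > 0)) {
      vapply(seq_along(gff), function(i) {
        p <- gff$Parent[[i]]
        if (length(p)) as.character(p[1]) else as.character(gff$ID[i])
      }, character(1))
    } else as.character(gff$ID)
    grl <- split(gff, parent)
    grl <- lapply(grl, function(g) sort(g[, NULL]))
    # first isoform per gene locus: isoforms of one gene share a span
    names(grl) <- names(split(gff, parent))
  }
  grl <- GRangesList(grl)
  makeAnnotatedGenome(seqs, grl, geneticCode = geneticCode)
}

#' Write a genome and its annotation back to files
#'
#' Inverse of \code{\link{readAnnotatedGenome}}; a read-write-read cycle
#' reproduces ids, coordinates and strands exactly.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param fastaPath,annotationPath output paths.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @return invisibly, the paths written.
#' @export
writeAnnotatedGenome <- function(genome, fastaPath, annotationPath,
                                 format = c("tsv", "gff3")) {
  format <- match.arg(format)
  writeXStringSet(chromosomes(genome), fastaPath)
  ex <- cdsExons(genome)
  ids <- names(ex)
  if (format == "tsv") {
    rows <- vapply(seq_along(ex), function(i) {
      g <- ex[[i]]
      paste(sprintf("%d-%d", start(g), end(g)), collapse = ",")
    }, character(1))
    tab <- data.frame(
      id = ids,
      chrom = vapply(seq_along(ex), function(i)
        as.character(seqnames(ex[[i]]))[1], character(1)),
      strand = vapply(seq_along(ex), function(i)
        as.character(strand(ex[[i]]))[1], character(1)),
      exons = rows, stringsAsFactors = FALSE)
    write.table(tab, annotationPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    g <- unlist(ex, use.names = FALSE)
    g$type <- "CDS"
    g$ID <- paste0(rep(ids, lengths(ex)), ".cds")
    g$Parent <- rep(ids, lengths(ex))
    g$source <- "TandemArrays"
    g$phase <- unlist(lapply(seq_along(ex), function(i) {
      w <- width(ex[[i]])
      if (as.character(strand(ex[[i]]))[1] == "-") w <- rev(w)
      ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
      if (as.character(strand(ex[[i]]))[1] == "-") rev(ph) else ph
    }), use.names = FALSE)
    rtracklayer::export(g, annotationPath, format = "gff3")
  }
  invisible(c(fastaPath, annotationPath))
}

cdsIndex <- function(genome, cdsId) {
  i <- match(cdsId, genome@cds$cds_id)
  if (is.na(i)) stop("unknown CDS id: ", cdsId)
  i
}

#' Spliced coding sequence of a CDS
#'
#' Exons are concatenated in genomic order, reverse-complemented for
#' minus-strand CDSs, and any trailing incomplete codon is trimmed.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param cdsId a CDS id.
#' @return a \code{DNAString} in coding (5'->3') orientation.
#' @export
cdsSequence <- function(genome, cdsId) {
  i <- cdsIndex(genome, cdsId)
  ex <- genome@exons[[cdsId]]
  chr <- genome@seqs[[as.character(seqnames(ex))[1]]]
  parts <- lapply(seq_along(ex),
                  function(k) subseq(chr, start(ex)[k], end(ex)[k]))
  s <- do.call(Biostrings::xscat, parts)
  if (as.character(strand(ex))[1] == "-") s <- reverseComplement(s)
  keep <- (length(s) %/% 3L) * 3L
  subseq(s, 1L, keep)
}

# cached codon (16 b1 + 4 b2 + b3 + 1) -> amino-acid letter table
geneticCodeTable <- function(geneticCode) {
  key <- paste0("gc64|", geneticCode)
  if (!is.null(.taCache[[key]])) return(.taCache[[key]])
  gc <- getGeneticCode(geneticCode)
  b <- c("A", "C", "G", "T")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4),
                   rep(b, 16))
  tab <- unname(gc[codons])
  .taCache[[key]] <- tab
  tab
}

# vectorised translation of a plain character sequence; codons with
# ambiguous bases give X
fastTranslateChr <- function(dnaChr, geneticCode) {
  s <- dnaCodes(dnaChr)
  n <- length(s) %/% 3L
  if (n < 1L) return("")
  i1 <- s[seq.int(1L, 3L * n, 3L)]
  i2 <- s[seq.int(2L, 3L * n, 3L)]
  i3 <- s[seq.int(3L, 3L * n, 3L)]
  bad <- i1 < 0L | i2 < 0L | i3 < 0L
  idx <- 16L * pmax(i1, 0L) + 4L * pmax(i2, 0L) + pmax(i3, 0L) + 1L
  aa <- geneticCodeTable(geneticCode)[idx]
  aa[bad] <- "X"
  paste(aa, collapse = "")
}

#' Translate a CDS to protein
#'
#' Minus-strand CDSs are reverse-complemented before translation;
#' internal stop codons are rendered as \code{*} and a terminal stop is
#' dropped. Codons containing ambiguous bases translate to \code{X}.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param cdsId a CDS id.
#' @return an \code{AAString}.
#' @export
translateCds <- function(genome, cdsId) {
  i <- cdsIndex(genome, cdsId)
  if (!genome@cds$translatable[i])
    stop("CDS ", cdsId, " is not translatable")
  aa <- fastTranslateChr(as.character(cdsSequence(genome, cdsId)),
                         genome@geneticCode)
  aa <- sub("\\*$", "", aa)
  AAString(aa)
}

#' Flanking search window of a CDS
#'
#' The DNA interval in which the method looks for similarity to a CDS:
#' length \code{max(factor * spliced CDS length, minLen)}, immediately
#' adjacent to the CDS's outermost genomic coordinate on the given side
#' (the CDS span itself, introns included, is excluded), truncated at
#' chromosome ends. \code{"upstream"}/\code{"downstream"} are
#' chromosomal-coordinate directions, not gene-orientation directions;
#' both strands of each window are searched later, which makes the two
#' conventions observationally equivalent.
#'
#' @param genome an \code{AnnotatedGenome}.
#' @param cdsId a CDS id.
#' @param side \code{"upstream"} (lower coordinates) or
#'   \code{"downstream"}.
#' @param factor window length as a multiple of the spliced CDS length
#'   (default 3).
#' @param minLen minimal window length in bp (default 1500).
#' @return a length-1 \code{GRanges}; possibly zero-width at a
#'   chromosome edge.
#' @examples
#' ## a 600 bp CDS gets a 1800 bp window; a 400 bp CDS gets 1500 bp
#' @export
flankingWindow <- function(genome, cdsId, side = c("upstream", "downstream"),
                           factor = 3, minLen = 1500) {
  side <- match.arg(side)
  i <- cdsIndex(genome, cdsId)
  cds <- genome@cds[i]
  wlen <- max(factor * cds$spliced_len, minLen)
  chrLen <- seqlengths(cds)[[as.character(seqnames(cds))]]
  if (side == "upstream") {
    en <- start(cds) - 1L
    st <- max(1L, start(cds) - as.integer(wlen))
    if (en < st) { st <- 1L; en <- 0L }  # zero-width at chromosome start
  } else {
    st <- end(cds) + 1L
    en <- min(chrLen, end(cds) + as.integer(wlen))
    if (en < st) { st <- chrLen; en <- chrLen - 1L }  # zero-width at end
  }
  gr <- GRanges(seqnames(cds), IRanges(st, en),
                seqlengths = seqlengths(cds))
  gr$cds_id <- cds$cds_id
  gr$side <- side
  gr
}

windowSequence <- function(genome, window) {
  if (width(window) == 0L) return(DNAString(""))
  chr <- genome@seqs[[as.character(seqnames(window))]]
  subseq(chr, start(window), end(window))
}
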