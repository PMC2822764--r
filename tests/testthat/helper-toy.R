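# In-code fixtures: toy genomes assembled from explicit gene sequences.

# random coding gene via the package's own generator machinery
toyGene <- function(nCodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG",
         paste(TandemArrays:::randomCodons(nCodons - 2L), collapse = ""),
         "TAA")
}

toyDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  TandemArrays:::randomDna(n)
}

# Build an AnnotatedGenome from plus-strand gene sequences placed left
# to right with the given gaps. genes: list of list(seq=, strand=)
# (strand defaults "+"; minus-strand genes are reverse-complemented at
# placement). Returns the genome; CDS ids are G1, G2, ...
toyGenome <- function(genes, gap = 300, lead = 500, geneticCode = "1",
                      chrom = "chr1") {
  gaps <- rep_len(gap, length(genes))
  parts <- character(); cursor <- 0L
  exons <- list()
  parts <- c(parts, toyDna(lead)); cursor <- lead
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    strand <- if (is.null(g$strand)) "+" else g$strand
    s <- g$seq
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    if (i > 1L) { parts <- c(parts, toyDna(gaps[i])); cursor <- cursor + gaps[i] }
    st <- cursor + 1L; en <- cursor + nchar(s)
    parts <- c(parts, s); cursor <- en
    exons[[paste0("G", i)]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(st, en), strand = strand)
  }
  parts <- c(parts, toyDna(400))
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(paste(parts, collapse = ""), chrom))
  TandemArrays:::makeAnnotatedGenome(
    seqs, GenomicRanges::GRangesList(exons), geneticCode = geneticCode)
}

# Hand-crafted FtbScores for automaton tests: scores is a data.frame
# with columns f_up_plus ... f_down_minus (one row per CDS of genome,
# in rank order); everything else is filled consistently.
toyScores <- function(genome, scores, threshold = 10) {
  cds <- cdsFeatures(genome)
  tab <- S4Vectors::DataFrame(
    cds_id = cds$cds_id,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    rank = cds$rank,
    start = BiocGenerics::start(cds), end = BiocGenerics::end(cds),
    strand = as.character(BiocGenerics::strand(cds)),
    spliced_len = cds$spliced_len,
    tb_self = 500,
    f_up_plus = scores$f_up_plus, f_up_minus = scores$f_up_minus,
    f_down_plus = scores$f_down_plus,
    f_down_minus = scores$f_down_minus,
    raw_f_up_plus = scores$f_up_plus,
    raw_f_up_minus = scores$f_up_minus,
    raw_f_down_plus = scores$f_down_plus,
    raw_f_down_minus = scores$f_down_minus,
    filtered = "")
  methods::new("FtbScores", table = tab, params = alignParams(),
               factor = 3, minLen = 1500)
}

# antisymmetric FTB profile row: positive value = plus-strand signal,
# negative = minus-strand signal of that magnitude
ftbRow <- function(up = 0, down = 0) {
  data.frame(f_up_plus = up, f_up_minus = -up,
             f_down_plus = down, f_down_minus = -down)
}
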