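# yeast-like average amino-acid composition; synonymous codons drawn
# uniformly within an amino acid
.aaFreq <- c(A = 0.055, R = 0.045, N = 0.061, D = 0.058, C = 0.013,
             Q = 0.039, E = 0.065, G = 0.050, H = 0.022, I = 0.066,
             L = 0.096, K = 0.073, M = 0.021, F = 0.045, P = 0.044,
             S = 0.090, T = 0.059, W = 0.010, Y = 0.034, V = 0.056)

codonsByAa <- function(geneticCode = "1") {
  gc <- getGeneticCode(geneticCode)
  split(names(gc), unname(gc))
}

randomCodons <- function(n, geneticCode = "1") {
  byAa <- codonsByAa(geneticCode)
  byAa <- byAa[names(byAa) %in% names(.aaFreq)]
  fr <- .aaFreq[names(byAa)] / sum(.aaFreq[names(byAa)])
  aas <- sample(names(byAa), n, replace = TRUE, prob = fr)
  vapply(aas, function(a) {
    cs <- byAa[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

randomGene <- function(lenBp, geneticCode = "1") {
  nCod <- lenBp %/% 3L
  stopifnot(nCod >= 4L)
  paste0("ATG", paste(randomCodons(nCod - 2L, geneticCode),
                      collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

randomDna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.305, 0.195, 0.195, 0.305)), collapse = "")
}

#' Diverge a coding sequence to a target protein identity
#'
#' Codon-level substitutions: the requested fraction of protein
#' positions gets a nonsynonymous codon swap (to a random different
#' amino acid), and a synonymous-biased set of additional positions gets
#' silent codon swaps, so DNA identity drops below protein identity as
#' in real paralogs. The reading frame, start codon and terminal stop
#' are preserved.
#'
#' @param dna a coding \code{DNAString} (length a multiple of 3).
#' @param targetIdentity target protein identity in percent, in
#'   \eqn{[30, 100]}.
#' @param geneticCode NCBI table id.
#' @param seed optional RNG seed for a reproducible copy.
#' @return a list: \code{dna} (the diverged copy) and \code{identity}
#'   (the realised protein identity, within 2 points of the target).
#' @export
mutateCopy <- function(dna, targetIdentity, geneticCode = "1",
                       seed = NULL) {
  stopifnot(targetIdentity >= 30, targetIdentity <= 100)
  if (!is.null(seed)) set.seed(seed)
  s <- as.character(dna)
  L <- nchar(s)
  stopifnot(L %% 3L == 0L)
  cod <- substring(s, seq(1L, L, 3L), seq(3L, L, 3L))
  gc <- getGeneticCode(geneticCode)
  n <- length(cod)
  P <- n - as.integer(gc[[cod[n]]] == "*")   # protein length
  mutable <- seq(2L, P)
  nChange <- min(round((1 - targetIdentity / 100) * P), length(mutable))
  byAa <- codonsByAa(geneticCode)
  byAa <- byAa[names(byAa) != "*"]
  chg <- if (nChange > 0L) sample(mutable, nChange) else integer()
  for (p in chg) {
    aa <- gc[[cod[p]]]
    newAa <- sample(setdiff(names(byAa), aa), 1L)
    cs <- byAa[[newAa]]
    cod[p] <- cs[sample.int(length(cs), 1L)]
  }
  syn <- setdiff(mutable, chg)
  nSyn <- if (nChange == 0L) 0L else  # target 100: exact copy
    min(length(syn), round(0.7 * nChange + 0.03 * P))
  for (p in if (nSyn > 0L) sample(syn, nSyn) else integer()) {
    aa <- gc[[cod[p]]]
    alts <- setdiff(byAa[[aa]], cod[p])
    if (length(alts)) cod[p] <- alts[sample.int(length(alts), 1L)]
  }
  list(dna = DNAString(paste(cod, collapse = "")),
       identity = 100 * (P - nChange) / P)
}

longestStopFree <- function(s, geneticCode = "1") {
  gc <- getGeneticCode(geneticCode)
  bestLen <- 0L; bestStart <- 1L
  for (f in 0:2) {
    n <- (nchar(s) - f) %/% 3L
    if (n < 1L) next
    aa <- suppressWarnings(as.character(translate(
      subseq(DNAString(s), f + 1L, f + 3L * n),
      genetic.code = gc, if.fuzzy.codon = "X")))
    stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"), n + 1L)
    for (k in seq_len(length(stops) - 1L)) {
      len <- (stops[k + 1L] - stops[k] - 1L) * 3L
      if (len > bestLen) {
        bestLen <- len
        bestStart <- f + 3L * stops[k] + 1L
      }
    }
  }
  list(len = bestLen, start = bestStart)
}

#' Degrade a coding sequence into a gene relic
#'
#' Introduces premature stop codons and/or single-nucleotide frameshift
#' deletions (the first disruption is always a stop), optionally
#' truncates the 3' end, and guarantees that no stop-free stretch in any
#' plus-strand frame reaches 50\% of the original length -- the
#' defining property of a gene relic as opposed to a pseudogene.
#'
#' @param dna a coding \code{DNAString}.
#' @param nDisruptions number of disruptions (>= 1).
#' @param truncateFrac fraction of the 3' end to delete (default 0).
#' @param geneticCode NCBI table id.
#' @param seed optional RNG seed.
#' @return the relic \code{DNAString}.
#' @export
degradeToRelic <- function(dna, nDisruptions = 2, truncateFrac = 0,
                           geneticCode = "1", seed = NULL) {
  if (nDisruptions < 1) stop("a relic needs at least one disruption")
  if (!is.null(seed)) set.seed(seed)
  s <- as.character(dna)
  L0 <- nchar(s)
  if (truncateFrac > 0)
    s <- substr(s, 1L, max(30L, round((1 - truncateFrac) * L0)))
  n <- nchar(s) %/% 3L
  pos <- round(n * seq_len(nDisruptions) / (nDisruptions + 1) +
                 stats::runif(nDisruptions, -0.03, 0.03) * n)
  pos <- sort(unique(pmin(pmax(pos, 2L), n - 1L)), decreasing = TRUE)
  types <- c(sample(c("stop", "frameshift"),
                    max(0L, length(pos) - 1L), replace = TRUE), "stop")
  for (k in seq_along(pos)) {
    off <- (pos[k] - 1L) * 3L
    if (types[k] == "stop") {
      substr(s, off + 1L, off + 3L) <- "TAA"
    } else {
      s <- paste0(substr(s, 1L, off), substr(s, off + 2L, nchar(s)))
    }
  }
  repeat {
    orf <- longestStopFree(s, geneticCode)
    if (orf$len < 0.5 * L0) break
    mid <- orf$start + ((orf$len %/% 2L) %/% 3L) * 3L
    if (mid + 2L > nchar(s)) mid <- nchar(s) - 2L
    substr(s, mid, mid + 2L) <- "TAA"
  }
  DNAString(s)
}

#' Specify one planted tandem array
#'
#' @param size number of functional CDS copies (1 only together with a
#'   relic).
#' @param identity per-copy target protein identity (percent) against
#'   the family founder; \code{NA} samples uniformly in \eqn{[80, 100]}
#'   at generation time.
#' @param strands explicit strand vector, or \code{NULL} to sample.
#' @param spacerAfter index of the member after which one heterologous
#'   spacer gene is inserted (\code{NA}: none).
#' @param relic \code{"none"}, \code{"upstream"} or \code{"downstream"}:
#'   attach a degenerated copy at that edge of the array.
#' @param relicIdentity protein identity target of the relic source
#'   copy before degradation.
#' @param relicDisruptions,relicTruncate degradation settings, see
#'   \code{\link{degradeToRelic}}.
#' @param minGeneLen lower bound on the founder (and spacer partner)
#'   length for this array; arrays with spacers need founders long
#'   enough that the flanking window (3 x L) spans the spacer.
#' @return a list describing the array, for \code{\link{synthConfig}}.
#' @export
arraySpec <- function(size, identity = NA, strands = NULL,
                      spacerAfter = NA, relic = c("none", "upstream",
                                                 "downstream"),
                      relicIdentity = 80, relicDisruptions = 2,
                      relicTruncate = 0.1, minGeneLen = NA) {
  relic <- match.arg(relic)
  if (size + (relic != "none") < 2)
    stop("an array needs >= 2 members counting relics")
  if (!is.na(identity) && (identity < 30 || identity > 100))
    stop("identity must be in [30, 100]")
  list(size = size, identity = identity, strands = strands,
       spacerAfter = spacerAfter, relic = relic,
       relicIdentity = relicIdentity,
       relicDisruptions = relicDisruptions,
       relicTruncate = relicTruncate, minGeneLen = minGeneLen)
}

#' Synthetic genome configuration
#'
#' Defaults emulate a compact hemiascomycete-like genome: mean coding
#' gene 1.38 kb, one gene per ~2 kb (mean intergenic 620 bp),
#' single-exon genes. \code{nGenes} counts all annotated CDSs including
#' array members and spacers.
#'
#' @param nGenes total annotated CDS count.
#' @param geneLenMean,geneLenShape,geneLenMin,geneLenMax gamma law (bp)
#'   for coding gene lengths, truncated and rounded to codons.
#' @param intergenicMean,intergenicShape,intergenicMin gamma law (bp)
#'   for intergenic spacers.
#' @param arrays list of \code{\link{arraySpec}} entries.
#' @param minisatellites list of entries
#'   \code{list(array=, member=, unit=, copies=)} (or
#'   \code{background=} instead of array/member): an in-frame tandem
#'   repeat inserted into the host CDS; entries with several hosts reuse
#'   the same unit sequence.
#' @param intronProb probability that a background gene carries one
#'   short intron.
#' @param geneticCode NCBI table id.
#' @param chromName chromosome name.
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @return a \code{SynthConfig} list.
#' @export
synthConfig <- function(nGenes = 100, geneLenMean = 1380,
                        geneLenShape = 4, geneLenMin = 300,
                        geneLenMax = 3000, intergenicMean = 620,
                        intergenicShape = 2, intergenicMin = 150,
                        arrays = list(), minisatellites = list(),
                        intronProb = 0, geneticCode = "1",
                        chromName = "chrI", seed = 1L) {
  cfg <- list(nGenes = nGenes, geneLenMean = geneLenMean,
              geneLenShape = geneLenShape, geneLenMin = geneLenMin,
              geneLenMax = geneLenMax, intergenicMean = intergenicMean,
              intergenicShape = intergenicShape,
              intergenicMin = intergenicMin, arrays = arrays,
              minisatellites = minisatellites, intronProb = intronProb,
              geneticCode = geneticCode, chromName = chromName,
              seed = as.integer(seed))
  class(cfg) <- "SynthConfig"
  cfg
}

#' Default study configuration
#'
#' One chromosome, 100 genes: planted all-CDS arrays of sizes 2, 3, 4
#' and 5 (per-copy identity sampled in \eqn{[80, 100]}), one 2-CDS array
#' with a spacer gene, one isolated CDS with a downstream gene relic,
#' and one minisatellite inside an array member.
#'
#' @param seed RNG seed.
#' @return a \code{SynthConfig}.
#' @export
defaultSynthConfig <- function(seed = 1L) {
  synthConfig(
    nGenes = 100,
    arrays = list(
      arraySpec(2), arraySpec(3), arraySpec(4), arraySpec(5),
      arraySpec(2, spacerAfter = 1, minGeneLen = 1200),
      arraySpec(1, relic = "downstream")),
    minisatellites = list(list(array = 1, member = 1, unit = 24,
                               copies = 6)),
    seed = seed)
}

sampleLen <- function(n, mean, shape, lo, hi, codon = TRUE) {
  x <- round(stats::rgamma(n, shape = shape, rate = shape / mean))
  x <- pmin(pmax(x, lo), hi)
  if (codon) x <- x - x %% 3L
  as.integer(x)
}

dnaIdentityPct <- function(a, b) {
  a <- strsplit(as.character(a), "")[[1]]
  b <- strsplit(as.character(b), "")[[1]]
  n <- min(length(a), length(b))
  100 * sum(a[seq_len(n)] == b[seq_len(n)]) / n
}

#' Generate a synthetic annotated genome with planted truth
#'
#' Background genes are drawn by codon sampling from a fixed yeast-like
#' composition, so they are mutually dissimilar; planted families are
#' copies of one founder diverged to their target identities; relics
#' are diverged copies degraded with stops/frameshifts and left out of
#' the annotation; minisatellites are inserted in frame. Deterministic
#' given the seed.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return a list: \code{genome} (an \code{AnnotatedGenome}),
#'   \code{truth} (list of \code{DataFrame}s \code{arrays} and
#'   \code{minisatellites}).
#' @export
generateGenome <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  nArr <- length(config$arrays)
  sizes <- vapply(config$arrays, `[[`, numeric(1), "size")
  nSpacer <- sum(!is.na(vapply(config$arrays, `[[`, numeric(1),
                               "spacerAfter")))
  nBack <- config$nGenes - sum(sizes) - nSpacer
  if (nBack < 2L * (nArr + 1L))
    stop("infeasible plan: not enough background genes to separate ",
         "the planted arrays")

  geneLen <- function(lo = config$geneLenMin)
    sampleLen(1L, config$geneLenMean, config$geneLenShape,
              max(lo, config$geneLenMin), config$geneLenMax)
  interLen <- function()
    sampleLen(1L, config$intergenicMean, config$intergenicShape,
              config$intergenicMin, 10L * config$intergenicMean,
              codon = FALSE)

  # one element: list(type, dna(plus-strand coding), strand, family,
  #   member, kind, identity, dna_identity, gapBefore)
  mkElement <- function(type, dna, strand, family = NA, member = NA,
                        kind = type, identity = NA, dnaId = NA,
                        gapBefore = NA)
    list(type = type, dna = dna, strand = strand, family = family,
         member = member, kind = kind, identity = identity,
         dna_identity = dnaId, gapBefore = gapBefore)

  blocks <- list()
  for (k in seq_len(nArr)) {
    a <- config$arrays[[k]]
    fam <- sprintf("FAM%02d", k)
    lo <- if (is.na(a$minGeneLen)) config$geneLenMin else a$minGeneLen
    founder <- randomGene(geneLen(lo), config$geneticCode)
    ident <- if (is.na(a$identity)) stats::runif(1, 80, 100) else
      a$identity
    # orientations are drawn per array, not per member: tandem
    # duplication overwhelmingly preserves orientation (direct arrays),
    # and opposite orientations occur as 2-CDS arrays; a copy whose
    # window holds homologs on both strands would self-cancel in the
    # X - Y differencing, which is a limitation of the score itself
    strands <- if (!is.null(a$strands)) a$strands else if (a$size == 2) {
      switch(sample(c("ds", "da", "oc", "od"), 1L,
                    prob = c(0.4, 0.4, 0.1, 0.1)),
             ds = c("+", "+"), da = c("-", "-"),
             oc = c("+", "-"), od = c("-", "+"))
    } else rep(sample(c("+", "-"), 1L), a$size)
    els <- list()
    mi <- 0L
    for (i in seq_len(a$size)) {
      mi <- mi + 1L
      if (i == 1L) {
        els[[mi]] <- mkElement("gene", founder, strands[i], fam, i,
                               "cds", identity = 100)
      } else {
        mc <- mutateCopy(DNAString(founder), ident,
                         config$geneticCode)
        els[[mi]] <- mkElement("gene", as.character(mc$dna),
                               strands[i], fam, i, "cds",
                               identity = mc$identity)
      }
      if (!is.na(a$spacerAfter) && a$spacerAfter == i) {
        mi <- mi + 1L
        spLen <- sampleLen(1L, min(1100, config$geneLenMean),
                           config$geneLenShape, config$geneLenMin,
                           1200L)
        els[[mi]] <- mkElement("gene",
                               randomGene(spLen, config$geneticCode),
                               sample(c("+", "-"), 1L), fam, i + 0.5,
                               "spacer")
      }
    }
    if (a$relic != "none") {
      src <- mutateCopy(DNAString(founder), a$relicIdentity,
                        config$geneticCode)
      relic <- degradeToRelic(src$dna, a$relicDisruptions,
                              a$relicTruncate, config$geneticCode)
      host <- if (a$relic == "upstream") els[[1L]] else
        els[[length(els)]]
      relStrand <- if (stats::runif(1) < 0.7) host$strand else
        setdiff(c("+", "-"), host$strand)
      rel <- mkElement("relic", as.character(relic), relStrand, fam,
                       if (a$relic == "upstream") 0L else
                         a$size + 1L, "relic",
                       identity = src$identity,
                       dnaId = dnaIdentityPct(founder, src$dna),
                       gapBefore = sample(150:250, 1L))
      if (a$relic == "upstream") {
        els[[1L]]$gapBefore <- NA  # relic precedes, host keeps default
        els <- c(list(rel), els)
        els[[2L]]$gapBefore <- sample(150:250, 1L)
      } else {
        els <- c(els, list(rel))
      }
    }
    # tandem-duplicated copies lie closer together than the average
    # gene spacing (the duplicated unit carries only part of the
    # flanking DNA); array-internal gaps are drawn short so adjacency
    # stays within the method's own window rule
    for (j in seq_along(els)[-1L])
      if (is.na(els[[j]]$gapBefore))
        els[[j]]$gapBefore <- sample(150:600, 1L)
    blocks[[k]] <- els
  }

  backs <- lapply(seq_len(max(nBack, 0L)), function(i)
    mkElement("gene", randomGene(geneLen(), config$geneticCode),
              sample(c("+", "-"), 1L)))

  # minisatellites: same in-frame unit inserted into each host
  msTruth <- list()
  if (length(config$minisatellites)) {
    for (e in seq_along(config$minisatellites)) {
      ms <- config$minisatellites[[e]]
      stopifnot(ms$unit %% 3L == 0L)
      unit <- paste(randomCodons(ms$unit %/% 3L, config$geneticCode),
                    collapse = "")
      block <- strrep(unit, ms$copies)
      hosts <- if (!is.null(ms$array))
        lapply(seq_along(ms$array), function(h)
          list(array = ms$array[h], member = ms$member[h]))
      else lapply(ms$background, function(b) list(background = b))
      for (h in hosts) {
        if (!is.null(h$array)) {
          el <- blocks[[h$array]]
          # member index among cds elements of the block
          cdsIdx <- which(vapply(el, function(x) x$kind == "cds",
                                 logical(1)))
          tgt <- cdsIdx[h$member]
          dna <- el[[tgt]]$dna
        } else {
          tgt <- h$background
          dna <- backs[[tgt]]$dna
        }
        nCod <- nchar(dna) %/% 3L
        at <- 3L * (nCod %/% 2L)   # codon boundary near the middle
        dna2 <- paste0(substr(dna, 1L, at), block,
                       substr(dna, at + 1L, nchar(dna)))
        if (!is.null(h$array)) blocks[[h$array]][[tgt]]$dna <- dna2
        else backs[[tgt]]$dna <- dna2
        msTruth[[length(msTruth) + 1L]] <- data.frame(
          entry = e, array = if (!is.null(h$array)) h$array else NA,
          member = if (!is.null(h$array)) h$member else NA,
          background = if (is.null(h$array)) h$background else NA,
          unit = ms$unit, copies = ms$copies, at = at,
          seq = unit)
      }
    }
  }

  # interleave: background runs separate the planted blocks
  gapSizes <- rep(2L, nArr + 1L)
  if (nArr > 0L) { gapSizes[1L] <- 1L; gapSizes[nArr + 1L] <- 1L }
  extra <- nBack - sum(gapSizes)
  if (nArr == 0L) gapSizes <- nBack
  else if (extra > 0L) {
    add <- as.integer(stats::rmultinom(1L, extra,
                                       rep(1, nArr + 1L)))
    gapSizes <- gapSizes + add
  }
  order <- list()
  bi <- 0L
  for (g in seq_len(nArr + 1L)) {
    ng <- gapSizes[g]
    if (ng > 0L) {
      order <- c(order, backs[bi + seq_len(ng)])
      bi <- bi + ng
    }
    if (g <= nArr) order <- c(order, blocks[[g]])
  }

  # assemble the chromosome
  parts <- character(); cursor <- 0L
  ann <- list(); truthRows <- list()
  cdsN <- 0L
  lead <- interLen()
  parts <- c(parts, randomDna(lead)); cursor <- lead
  for (el in order) {
    gap <- if (!is.na(el$gapBefore)) el$gapBefore else interLen()
    if (length(ann) || length(truthRows)) {  # no double leading gap
      parts <- c(parts, randomDna(gap)); cursor <- cursor + gap
    }
    dna <- el$dna
    placed <- if (el$strand == "-")
      as.character(reverseComplement(DNAString(dna))) else dna
    st <- cursor + 1L; en <- cursor + nchar(placed)
    intron <- NULL
    if (el$kind == "gene" && is.na(el$family) &&
        config$intronProb > 0 && stats::runif(1) < config$intronProb) {
      ilen <- sample(50:80, 1L)
      cut <- 3L * ((nchar(placed) %/% 3L) %/% 2L)
      intron <- paste0("GT", randomDna(ilen - 4L), "AG")
      placed <- paste0(substr(placed, 1L, cut), intron,
                       substr(placed, cut + 1L, nchar(placed)))
      en <- cursor + nchar(placed)
    }
    parts <- c(parts, placed); cursor <- en
    if (el$type == "gene") {
      cdsN <- cdsN + 1L
      id <- sprintf("CDS%04d", cdsN)
      exons <- if (is.null(intron))
        data.frame(start = st, end = en) else {
          cut <- st + 3L * (((en - st + 1L - nchar(intron)) %/% 3L)
                            %/% 2L) - 1L
          data.frame(start = c(st, cut + nchar(intron) + 1L),
                     end = c(cut, en))
        }
      ann[[id]] <- list(exons = exons, strand = el$strand)
      if (!is.na(el$family))
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          family = el$family, member = el$member, kind = el$kind,
          cds_id = id, start = st, end = en, strand = el$strand,
          protein_identity = el$identity,
          dna_identity = el$dna_identity)
    } else {  # relic: unannotated
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        family = el$family, member = el$member, kind = "relic",
        cds_id = NA_character_, start = st, end = en,
        strand = el$strand, protein_identity = el$identity,
        dna_identity = el$dna_identity)
    }
  }
  tail <- interLen()
  parts <- c(parts, randomDna(tail))
  chrom <- paste(parts, collapse = "")

  seqs <- DNAStringSet(stats::setNames(chrom, config$chromName))
  grl <- GRangesList(lapply(ann, function(a)
    GRanges(config$chromName,
            IRanges(a$exons$start, a$exons$end), strand = a$strand)))
  names(grl) <- names(ann)
  genome <- makeAnnotatedGenome(seqs, grl,
                                geneticCode = config$geneticCode)

  arrT <- if (length(truthRows)) DataFrame(do.call(rbind, truthRows))
    else DataFrame(family = character(), member = numeric(),
                   kind = character(), cds_id = character(),
                   start = integer(), end = integer(),
                   strand = character(), protein_identity = numeric(),
                   dna_identity = numeric())
  # resolve minisatellite hosts to CDS ids
  msT <- if (length(msTruth)) {
    m <- do.call(rbind, msTruth)
    m$cds_id <- vapply(seq_len(nrow(m)), function(i) {
      if (!is.na(m$array[i])) {
        fam <- sprintf("FAM%02d", m$array[i])
        sel <- arrT$family == fam & arrT$kind == "cds" &
          arrT$member == m$member[i]
        arrT$cds_id[sel][1]
      } else NA_character_   # background hosts matched by position below
    }, character(1))
    DataFrame(m)
  } else DataFrame(entry = integer(), array = integer(),
                   member = integer(), background = integer(),
                   unit = integer(), copies = integer(), at = integer(),
                   seq = character(), cds_id = character())

  list(genome = genome,
       truth = list(arrays = arrT, minisatellites = msT),
       config = config)
}

#' Write a synthetic genome, annotation and truth ledger to disk
#'
#' Emits the same FASTA/TSV dialects \code{\link{readAnnotatedGenome}}
#' reads, plus the truth tables.
#'
#' @param sim result of \code{\link{generateGenome}}.
#' @param dir output directory (created if needed).
#' @param format annotation format, \code{"tsv"} or \code{"gff3"}.
#' @return invisibly, the paths written.
#' @export
writeSyntheticGenome <- function(sim, dir, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  annExt <- if (format == "tsv") "tsv" else "gff3"
  ann <- file.path(dir, paste0("annotation.", annExt))
  writeAnnotatedGenome(sim$genome, fa, ann, format = format)
  ta <- file.path(dir, "truth_arrays.tsv")
  write.table(as.data.frame(sim$truth$arrays), ta, sep = "\t",
              quote = FALSE, row.names = FALSE)
  tm <- file.path(dir, "truth_minisatellites.tsv")
  write.table(as.data.frame(sim$truth$minisatellites), tm, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fa, ann, ta, tm))
}
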