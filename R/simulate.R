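## Deterministic synthetic-fixture generation: truth sets, per-caller
## dialect VCFs with configurable detection profiles, exon BED panels and
## repeat-spanning reads. A single integer seed drives an explicit
## hierarchical stream (one child seed per generator), so adding a
## generator never perturbs the output of an existing one.

.childSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer(((seed %% 1000003) * 1009 + h) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a simulation configuration
#'
#' The defaults emulate the validation conditions of a clinical long-read
#' cohort: a roster of 80 SNVs, 26 indels (1--36 bp), 32 SVs
#' (DEL/DUP/INS/INV/BND, 50 bp -- 100 kb) and 29 repeat-expansion loci,
#' all placed in exons of a phenotype gene panel, with 2% read-length
#' noise on repeat-spanning reads.
#'
#' @param seed Master seed; identical config + seed gives byte-identical
#'   outputs.
#' @param genome Named contig-length vector (defaults to hg19 primary
#'   contigs without chrM).
#' @param roster Named counts of planted variants per class:
#'   \code{snv}, \code{indel}, \code{sv}, \code{cnv}, \code{repeats}.
#' @param nGenes Panel size; \code{nDecoyGenes} additional genes flagged
#'   not phenotype-associated.
#' @param nDecoyGenes See above.
#' @param fracExonic Fraction of planted sequence/SV variants placed in
#'   panel exons (the rest go to intergenic space).
#' @param depth Spanning-read depth per repeat allele.
#' @param noiseCV Coefficient of variation of repeat-read copy counts.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1,
                             genome = genomeContigs()[setdiff(
                               names(genomeContigs()), "chrM")],
                             roster = c(snv = 80, indel = 26, sv = 32,
                                        cnv = 0, repeats = 29),
                             nGenes = 60, nDecoyGenes = 0,
                             fracExonic = 1, depth = 15,
                             noiseCV = 0.02) {
  stopifnot(all(roster >= 0), fracExonic >= 0, fracExonic <= 1)
  structure(list(seed = seed, genome = genome, roster = roster,
                 nGenes = nGenes, nDecoyGenes = nDecoyGenes,
                 fracExonic = fracExonic, depth = depth,
                 noiseCV = noiseCV),
            class = "SimulationConfig")
}

.simulatePanel <- function(config) {
  genome <- config$genome
  nAll <- config$nGenes + config$nDecoyGenes
  .withSeed(.childSeed(config$seed, "panel"), {
    exList <- vector("list", nAll)
    for (g in seq_len(nAll)) {
      contig <- sample(names(genome), 1L)
      gstart <- sample.int(as.integer(genome[contig] - 4e6), 1L) + 2e6
      nEx <- sample(4:12, 1L)
      widths <- sample(100:300, nEx, replace = TRUE)
      gaps <- sample(500:5000, nEx - 1L, replace = TRUE)
      starts <- gstart + cumsum(c(0L, widths[-nEx] + gaps))
      exList[[g]] <- GenomicRanges::GRanges(contig,
        IRanges::IRanges(starts, width = widths),
        symbol = sprintf("GENE%04d", g),
        phenotype_associated = g <= config$nGenes)
    }
    GenePanel(.bindGRanges(exList))
  })
}

## Candidate planting slots with >= 1 kb separation, split into exonic
## (one slot per exon, greedily thinned per contig) and intergenic.
.plantingSlots <- function(config, panel) {
  ex <- exons(panel)
  ex <- ex[S4Vectors::mcols(ex)$phenotype_associated]
  exonic <- data.frame(
    contig = as.character(GenomeInfoDb::seqnames(ex)),
    pos = BiocGenerics::start(ex) +
      BiocGenerics::width(ex) %/% 2L,
    symbol = S4Vectors::mcols(ex)$symbol,
    exon_start = BiocGenerics::start(ex),
    exon_end = BiocGenerics::end(ex))
  keep <- logical(nrow(exonic))
  for (ct in unique(exonic$contig)) {
    idx <- which(exonic$contig == ct)
    idx <- idx[order(exonic$pos[idx])]
    last <- -Inf
    for (i in idx) {
      if (exonic$pos[i] - last >= 1000) { keep[i] <- TRUE
                                          last <- exonic$pos[i] }
    }
  }
  exonic <- exonic[keep, , drop = FALSE]
  genome <- config$genome
  inter <- do.call(rbind, lapply(names(genome), function(ct) {
    grid <- seq(2e6, genome[ct] - 2e6, by = 20000)
    data.frame(contig = ct, pos = grid)
  }))
  ## drop intergenic slots within 1 Mb of any panel gene
  spans <- geneSpans(panel)
  ig <- GenomicRanges::GRanges(inter$contig,
                               IRanges::IRanges(inter$pos, width = 1L))
  near <- suppressWarnings(GenomicRanges::countOverlaps(
    ig, spans + 1e6, ignore.strand = TRUE)) > 0
  inter <- inter[!near, , drop = FALSE]
  list(exonic = exonic, intergenic = inter)
}

.randBase <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    pool <- setdiff(bases, exclude[i])
    sample(pool, 1L)
  }, character(1))
}

.randSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

#' Simulate a truth set and gene panel
#'
#' Plants non-colliding variants of each roster class (at least 1 kb
#' apart) inside panel-gene exons (or in intergenic space for the
#' \code{1 - fracExonic} remainder), defines repeat loci with known
#' diploid genotypes, and optionally writes the truth VCF, exon BED and
#' an echo of the configuration.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param dir Output directory; when non-NULL writes \code{truth.vcf},
#'   \code{genes.bed}, \code{repeat_loci.tsv} and \code{config.yaml}.
#' @return List of class \code{"TruthSet"}: \code{calls} (mixed
#'   \code{\linkS4class{CallSet}}, caller \code{"truth"}), \code{panel},
#'   \code{repeatLoci} (list of \code{\linkS4class{RepeatLocus}}),
#'   \code{repeatGenotypes} (data.frame with per-locus planted allele
#'   copies/motifs), \code{paths} (written files, if any).
#' @export
simulateTruthSet <- function(config = simulationConfig(), dir = NULL) {
  panel <- .simulatePanel(config)
  slots <- .plantingSlots(config, panel)
  roster <- config$roster
  nSeqVar <- sum(roster[c("snv", "indel", "sv", "cnv")])
  nExonic <- round(config$fracExonic * nSeqVar)

  rows <- .withSeed(.childSeed(config$seed, "variants"), {
    exAvail <- slots$exonic[sample.int(nrow(slots$exonic)), , drop = FALSE]
    igAvail <- slots$intergenic[sample.int(nrow(slots$intergenic)), ,
                                drop = FALSE]
    if (nExonic > nrow(exAvail) ||
        (nSeqVar - nExonic) > nrow(igAvail))
      stop("roster exceeds available placement space")
    exonicFlag <- rep(FALSE, nSeqVar)
    if (nExonic > 0) exonicFlag[seq_len(nExonic)] <- TRUE
    exonicFlag <- sample(exonicFlag)
    ei <- 0L; ii <- 0L
    takeSlot <- function(exonic) {
      if (exonic) { ei <<- ei + 1L; exAvail[ei, ] }
      else { ii <<- ii + 1L; igAvail[ii, ] }
    }
    out <- list(); vi <- 0L
    addRow <- function(df) { vi <<- vi + 1L; out[[vi]] <<- df }
    classes <- rep(c("snv", "indel", "sv", "cnv"),
                   times = roster[c("snv", "indel", "sv", "cnv")])
    svCycle <- c("DEL", "DUP", "INS", "INV", "BND")
    svI <- 0L
    for (j in seq_along(classes)) {
      slot <- takeSlot(exonicFlag[j])
      cls <- classes[j]
      if (cls == "snv") {
        refb <- .randBase(1L)
        altb <- .randBase(1L, exclude = refb)
        addRow(data.frame(class = "smallvariant", contig = slot$contig,
          start = slot$pos, end = slot$pos, ref = refb, alt = altb,
          vtype = "SNV", genotype = sample(c("het", "hom"), 1L,
                                           prob = c(0.7, 0.3)),
          vaf = NA_real_, quality = round(runif(1, 20, 60), 1),
          size_change = 0L, svtype = NA, svlen = NA, generic_flag = NA,
          mate_contig = NA, mate_pos = NA, copy_state = NA, q0 = NA,
          p_n = NA, p_value = NA, bin_size = NA))
      } else if (cls == "indel") {
        size <- sample(1:36, 1L)
        kind <- sample(c("INS", "DEL", "DELINS"), 1L,
                       prob = c(0.4, 0.4, 0.2))
        if (kind == "INS") {
          refs <- .randSeq(1L); alts <- paste0(refs, .randSeq(size))
        } else if (kind == "DEL") {
          refs <- .randSeq(size + 1L); alts <- substr(refs, 1L, 1L)
        } else {
          refs <- .randSeq(size + 2L); alts <- .randSeq(size %/% 2L + 1L)
          while (alts == refs) alts <- .randSeq(size %/% 2L + 1L)
        }
        addRow(data.frame(class = "smallvariant", contig = slot$contig,
          start = slot$pos, end = slot$pos + nchar(refs) - 1L,
          ref = refs, alt = alts, vtype = .classifySmall(refs, alts),
          genotype = sample(c("het", "hom"), 1L, prob = c(0.7, 0.3)),
          vaf = NA_real_, quality = round(runif(1, 20, 60), 1),
          size_change = nchar(alts) - nchar(refs), svtype = NA,
          svlen = NA, generic_flag = NA, mate_contig = NA, mate_pos = NA,
          copy_state = NA, q0 = NA, p_n = NA, p_value = NA,
          bin_size = NA))
      } else if (cls == "sv") {
        svI <- svI + 1L
        st <- svCycle[(svI - 1L) %% length(svCycle) + 1L]
        if (st == "BND") {
          mateSlot <- takeSlot(FALSE)
          addRow(data.frame(class = "sv", contig = slot$contig,
            start = slot$pos, end = slot$pos, ref = NA, alt = NA,
            vtype = NA, genotype = NA, vaf = NA_real_,
            quality = round(runif(1, 20, 60), 1), size_change = NA,
            svtype = "BND", svlen = NA_integer_, generic_flag = FALSE,
            mate_contig = mateSlot$contig, mate_pos = mateSlot$pos,
            copy_state = NA, q0 = NA, p_n = NA, p_value = NA,
            bin_size = NA))
        } else {
          len <- if (st == "INS") sample(50:500, 1L) else
            round(exp(runif(1, log(50), log(1e5))))
          w <- if (st == "INS") 1L else len
          addRow(data.frame(class = "sv", contig = slot$contig,
            start = slot$pos, end = slot$pos + w - 1L, ref = NA,
            alt = NA, vtype = NA, genotype = NA, vaf = NA_real_,
            quality = round(runif(1, 20, 60), 1), size_change = NA,
            svtype = st, svlen = as.integer(len), generic_flag = FALSE,
            mate_contig = NA, mate_pos = NA, copy_state = NA, q0 = NA,
            p_n = NA, p_value = NA, bin_size = NA))
        }
      } else { # cnv
        nbins <- sample(10:500, 1L)
        start <- (slot$pos %/% 1000L) * 1000L + 1L
        addRow(data.frame(class = "cnv", contig = slot$contig,
          start = start, end = start + nbins * 1000L - 1L, ref = NA,
          alt = NA, vtype = NA, genotype = NA, vaf = NA_real_,
          quality = round(runif(1, 20, 60), 1), size_change = NA,
          svtype = NA, svlen = NA, generic_flag = NA, mate_contig = NA,
          mate_pos = NA, copy_state = sample(c("loss", "gain"), 1L),
          q0 = runif(1, 0, 0.3), p_n = runif(1, 0, 0.3),
          p_value = runif(1, 1e-6, 5e-4), bin_size = 1000L))
      }
    }
    if (vi) do.call(rbind, out[seq_len(vi)]) else NULL
  })

  if (!is.null(rows)) {
    gr <- GenomicRanges::GRanges(rows$contig,
      IRanges::IRanges(rows$start, rows$end))
    mc <- rows[setdiff(colnames(rows), c("contig", "start", "end"))]
    mc$typelab <- ifelse(rows$class == "smallvariant", rows$vtype,
                         ifelse(rows$class == "cnv", rows$copy_state,
                                rows$svtype))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  } else {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(class = character(),
                                                 typelab = character())
  }
  truthCalls <- CallSet(gr, "truth", "mixed",
                        list(config_seed = config$seed))

  ## repeat loci with planted diploid genotypes
  nRep <- roster[["repeats"]]
  repeatDefs <- list(
    list(motif = "CAG", pathogenic = "CAG", interruption = "CAT",
         normal = c(6, 35), threshold = 39),
    list(motif = "GAA", pathogenic = "GAA", interruption = character(),
         normal = c(5, 33), threshold = 66),
    list(motif = "AAAAG", pathogenic = "AAGGG",
         interruption = character(), normal = c(11, 200),
         threshold = 400),
    list(motif = "CTG", pathogenic = "CTG", interruption = character(),
         normal = c(5, 34), threshold = 50),
    list(motif = "CGG", pathogenic = "CGG", interruption = "AGG",
         normal = c(6, 44), threshold = 200)
  )
  rp <- .withSeed(.childSeed(config$seed, "repeats"), {
    loci <- list(); geno <- list()
    genome <- config$genome
    for (r in seq_len(nRep)) {
      def <- repeatDefs[[(r - 1L) %% length(repeatDefs) + 1L]]
      contig <- sample(names(genome), 1L)
      start <- sample.int(as.integer(genome[contig] - 4e6), 1L) + 2e6
      normCopies <- sample(def$normal[1]:def$normal[2], 1L)
      expCopies <- sample(
        (def$threshold + 10):(def$threshold * 2 + 50), 1L)
      loc <- repeatLocus(sprintf("RPT%03d", r), contig, start,
        start + normCopies * nchar(def$motif) - 1L, def$motif,
        pathogenicMotifs = def$pathogenic,
        interruptionMotifs = def$interruption,
        normalRange = def$normal, pathogenicThreshold = def$threshold)
      loci[[r]] <- loc
      geno[[r]] <- data.frame(locus = loc@name, motif = def$motif,
        pathogenic_motif = def$pathogenic, copies1 = normCopies,
        motif1 = def$motif, copies2 = expCopies,
        motif2 = def$pathogenic)
    }
    list(loci = loci,
         genotypes = if (length(geno)) do.call(rbind, geno) else
           data.frame())
  })

  paths <- list()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths$truth_vcf <- file.path(dir, "truth.vcf")
    writeCallVcf(truthCalls, paths$truth_vcf, genome = config$genome)
    paths$gene_bed <- file.path(dir, "genes.bed")
    ex <- exons(panel)
    ex <- ex[S4Vectors::mcols(ex)$phenotype_associated]
    writeLines(paste(as.character(GenomeInfoDb::seqnames(ex)),
                     BiocGenerics::start(ex) - 1L, BiocGenerics::end(ex),
                     S4Vectors::mcols(ex)$symbol, sep = "\t"),
               paths$gene_bed)
    paths$repeat_loci <- file.path(dir, "repeat_loci.tsv")
    utils::write.table(rp$genotypes, paths$repeat_loci, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$config <- file.path(dir, "config.yaml")
    cfg <- unclass(config)
    cfg$genome <- as.list(cfg$genome)
    cfg$roster <- as.list(cfg$roster)
    yaml::write_yaml(cfg, paths$config)
  }
  structure(list(calls = truthCalls, panel = panel,
                 repeatLoci = rp$loci, repeatGenotypes = rp$genotypes,
                 config = config, paths = paths),
            class = "TruthSet")
}

#' Define a caller detection profile
#'
#' @param caller Registered caller id (decides the dialect and record
#'   class emitted).
#' @param detection Detection sensitivity as a fraction in \code{[0,1]}
#'   (per-record seeded Bernoulli draws); ignored when
#'   \code{detectCounts} is given.
#' @param detectCounts Exact detected count \code{k} out of the eligible
#'   planted records (the \code{k} are chosen by seeded shuffle) — use
#'   this to reproduce printed k-of-n detection rates exactly.
#' @param falsePerMb False-call rate per megabase of genome.
#' @param sizeRange Eligible planted-record size range \code{c(min,max)}.
#' @param dialect Dialect override.
#' @return List of class \code{"CallerProfile"}.
#' @examples
#' callerProfile("nanovar", detectCounts = 27)  # 27-of-n breakpoints
#' @export
callerProfile <- function(caller, detection = 1.0, detectCounts = NULL,
                          falsePerMb = 0, sizeRange = c(0, Inf),
                          dialect = callerDialect(caller)) {
  stopifnot(detection >= 0, detection <= 1, falsePerMb >= 0)
  structure(list(caller = caller, detection = detection,
                 detectCounts = detectCounts, falsePerMb = falsePerMb,
                 sizeRange = sizeRange, dialect = dialect),
            class = "CallerProfile")
}

#' Emulate a caller over a planted truth set
#'
#' Selects the detected subset of the eligible truth records (exact
#' \code{k}-of-\code{n} by seeded shuffle when \code{detectCounts} is
#' given, otherwise per-record seeded Bernoulli draws at the profile
#' sensitivity), adds false calls at the configured per-megabase rate,
#' leaves detected records' coordinates untouched, and returns (and
#' optionally writes) the result in the caller's dialect.
#'
#' @param truth A \code{"TruthSet"} or a \code{\linkS4class{CallSet}}.
#' @param profile A \code{\link{callerProfile}}.
#' @param seed Integer seed (combined with the caller id into a child
#'   stream).
#' @param path Optional output VCF path (written in the caller dialect).
#' @param genome Contig-length vector for false-call placement/writing.
#' @return A \code{\linkS4class{CallSet}} in the caller's record class.
#' @export
emulateCaller <- function(truth, profile, seed = 1, path = NULL,
                          genome = genomeContigs()) {
  truthCalls <- if (inherits(truth, "TruthSet")) truth$calls else truth
  if (inherits(truth, "TruthSet")) genome <- truth$config$genome
  cls <- profile$dialect$class
  gr <- calls(truthCalls)
  mc <- S4Vectors::mcols(gr)
  recClass <- if (callClass(truthCalls) == "mixed") as.character(mc$class)
    else rep(callClass(truthCalls), length(gr))
  eligible <- which(recClass == cls)
  sizes <- .callSizes(truthCalls)[eligible]
  inRange <- is.na(sizes) |
    (sizes >= profile$sizeRange[1] & sizes <= profile$sizeRange[2])
  eligible <- eligible[inRange]
  n <- length(eligible)

  .withSeed(.childSeed(seed, paste0("caller_", profile$caller)), {
    detected <- if (!is.null(profile$detectCounts)) {
      k <- profile$detectCounts
      if (k > n) stop("detectCounts (", k, ") exceeds eligible planted ",
                      "records (", n, ")")
      sort(eligible[sample.int(n)[seq_len(k)]])
    } else {
      eligible[stats::rbinom(n, 1L, profile$detection) == 1L]
    }
    out <- gr[detected]
    mcOut <- S4Vectors::mcols(out)
    ## false calls
    nFalse <- stats::rpois(1L, profile$falsePerMb * sum(genome) / 1e6)
    if (nFalse > 0) {
      fcontig <- sample(names(genome), nFalse, replace = TRUE,
                        prob = genome / sum(genome))
      fpos <- vapply(fcontig, function(ct)
        sample.int(as.integer(genome[ct] - 2e6), 1L) + 1e6, numeric(1))
      if (cls == "smallvariant") {
        refb <- .randBase(nFalse)
        altb <- .randBase(nFalse, exclude = refb)
        fgr <- GenomicRanges::GRanges(fcontig,
          IRanges::IRanges(fpos, fpos))
        S4Vectors::mcols(fgr) <- S4Vectors::DataFrame(
          class = "smallvariant", typelab = "SNV", ref = refb,
          alt = altb, vtype = "SNV",
          genotype = sample(c("het", "hom"), nFalse, replace = TRUE),
          vaf = round(runif(nFalse, 0.3, 0.6), 3),
          quality = round(runif(nFalse, 3, 20), 1),
          size_change = 0L)
      } else if (cls == "sv") {
        lens <- round(exp(runif(nFalse, log(max(50,
          profile$sizeRange[1])), log(min(1e5,
          max(profile$sizeRange[2], 100))))))
        fgr <- GenomicRanges::GRanges(fcontig,
          IRanges::IRanges(fpos, fpos + lens - 1L))
        S4Vectors::mcols(fgr) <- S4Vectors::DataFrame(class = "sv",
          typelab = "DEL", svtype = "DEL", svlen = as.integer(lens),
          quality = round(runif(nFalse, 1, 15), 1),
          generic_flag = FALSE, mate_contig = NA_character_,
          mate_pos = NA_integer_)
      } else {
        nbins <- sample(5:100, nFalse, replace = TRUE)
        fstart <- (fpos %/% 1000L) * 1000L + 1L
        fgr <- GenomicRanges::GRanges(fcontig,
          IRanges::IRanges(fstart, fstart + nbins * 1000L - 1L))
        S4Vectors::mcols(fgr) <- S4Vectors::DataFrame(class = "cnv",
          typelab = sample(c("loss", "gain"), nFalse, replace = TRUE),
          copy_state = sample(c("loss", "gain"), nFalse, replace = TRUE),
          q0 = runif(nFalse, 0, 1), p_n = runif(nFalse, 0, 1),
          p_value = runif(nFalse, 0, 1), bin_size = 1000L,
          quality = round(runif(nFalse, 1, 15), 1))
      }
      out <- .bindGRanges(list(out, fgr))
    }
    ## strip to the dialect's record class columns
    keepCols <- switch(cls,
      smallvariant = c("ref", "alt", "vtype", "genotype", "vaf",
                       "quality", "size_change"),
      sv = c("svtype", "svlen", "quality", "generic_flag", "mate_contig",
             "mate_pos"),
      cnv = c("copy_state", "q0", "p_n", "p_value", "bin_size",
              "quality"))
    mcAll <- S4Vectors::mcols(out)
    for (col in setdiff(keepCols, colnames(mcAll)))
      mcAll[[col]] <- rep(NA, length(out))
    S4Vectors::mcols(out) <- mcAll[keepCols]
    if (cls == "smallvariant" && any(is.na(mcAll$vaf))) {
      ## fill unset truth VAFs consistently with the planted genotype
      gt <- S4Vectors::mcols(out)$genotype
      navaf <- is.na(S4Vectors::mcols(out)$vaf)
      S4Vectors::mcols(out)$vaf[navaf] <-
        round(ifelse(gt[navaf] == "hom", runif(sum(navaf), 0.95, 1),
                     runif(sum(navaf), 0.4, 0.6)), 3)
    }
    res <- CallSet(out, profile$caller, cls,
                   list(profile = profile$caller, seed = seed))
    if (!is.null(path))
      writeCallVcf(res, path, dialect = profile$dialect, genome = genome)
    res
  })
}

#' Simulate repeat-spanning reads for a locus
#'
#' Emits \code{depth} tract sequences per allele; each read's copy count
#' is the allele count perturbed by a seeded normal draw with the given
#' coefficient of variation (rounded, floored at 1). Interruption units
#' are substituted at the specified positions.
#'
#' @param locus A \code{\linkS4class{RepeatLocus}}.
#' @param genotype Either \code{c(copies1, copies2)} (both alleles use
#'   the reference motif) or a list of two allele specs
#'   \code{list(copies =, motif =, interruptions = list(list(after =,
#'   motif =, copies = 1)))}.
#' @param depth Reads per allele.
#' @param noiseCV Coefficient of variation of the per-read copy count
#'   (0 = noise-free).
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return A \code{Biostrings::DNAStringSet} named
#'   \code{<locus>_a<allele>_r<read>}.
#' @examples
#' loc <- repeatLocus("ATXN1", "chr6", 16327636, 16327722, "CAG",
#'                    pathogenicMotifs = "CAG", normalRange = c(6, 35),
#'                    pathogenicThreshold = 38)
#' reads <- simulateRepeatReads(loc, c(30, 45), depth = 5, noiseCV = 0,
#'                              seed = 7)
#' @export
simulateRepeatReads <- function(locus, genotype, depth = 15,
                                noiseCV = 0.02, seed = 1, path = NULL) {
  alleles <- if (is.numeric(genotype))
    list(list(copies = genotype[1], motif = locus@refMotif),
         list(copies = genotype[2], motif = locus@refMotif))
  else genotype
  stopifnot(length(alleles) == 2L, depth >= 1)
  .withSeed(.childSeed(seed, paste0("repeat_", locus@name)), {
    seqs <- character(0); nms <- character(0)
    for (ai in 1:2) {
      al <- alleles[[ai]]
      stopifnot(al$copies >= 1)
      for (ri in seq_len(depth)) {
        nCopies <- if (noiseCV > 0)
          max(1L, as.integer(round(al$copies *
                                     (1 + stats::rnorm(1, 0, noiseCV)))))
        else as.integer(al$copies)
        units <- rep(al$motif, nCopies)
        if (!is.null(al$interruptions)) {
          for (intr in al$interruptions) {
            nI <- intr$copies %||% 1L
            at <- intr$after + seq_len(nI)
            at <- at[at <= length(units)]
            units[at] <- intr$motif
          }
        }
        seqs <- c(seqs, paste(units, collapse = ""))
        nms <- c(nms, sprintf("%s_a%d_r%d", locus@name, ai, ri))
      }
    }
    reads <- Biostrings::DNAStringSet(stats::setNames(seqs, nms))
    if (!is.null(path)) Biostrings::writeXStringSet(reads, path)
    reads
  })
}
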