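## Tandem-repeat tract analysis from spanning-read sequences: motif-run
## decomposition, per-read copy numbers, biallelic genotyping by
## deterministic 1-D two-means, interruption detection and locus-specific
## pathogenicity classification. Pathogenicity can require both a size
## and a motif-content change (RFC1/CANVAS: AAAAG -> AAGGG conversion AND
## > 400 copies).

#' Construct a RepeatLocus
#'
#' @param name Locus name (conventionally the gene symbol).
#' @param contig,start,end Tract coordinates (1-based closed).
#' @param refMotif Reference repeat unit.
#' @param pathogenicMotifs Character vector of motifs that confer
#'   pathogenicity when expanded (empty if expansion of the reference
#'   motif itself is pathogenic, as for CAG loci — then pass
#'   \code{refMotif} here too).
#' @param interruptionMotifs Interruption units (e.g. \code{"CAT"} inside
#'   a CAG tract).
#' @param normalRange Inclusive copy range of normal alleles, default
#'   \code{c(11, 200)}.
#' @param pathogenicThreshold Copies strictly above this count as
#'   expanded, default 400.
#' @return A \code{\linkS4class{RepeatLocus}}.
#' @examples
#' rfc1 <- repeatLocus("RFC1", "chr4", 39350045, 39350103, "AAAAG",
#'                     pathogenicMotifs = "AAGGG")
#' @export
repeatLocus <- function(name, contig, start, end, refMotif,
                        pathogenicMotifs = character(),
                        interruptionMotifs = character(),
                        normalRange = c(11, 200),
                        pathogenicThreshold = 400) {
  methods::new("RepeatLocus", name = name,
               region = GenomicRanges::GRanges(contig,
                 IRanges::IRanges(start, end)),
               refMotif = toupper(refMotif),
               pathogenicMotifs = toupper(pathogenicMotifs),
               interruptionMotifs = toupper(interruptionMotifs),
               normalRange = normalRange,
               pathogenicThreshold = pathogenicThreshold)
}

setMethod("show", "RepeatLocus", function(object) {
  cat("RepeatLocus ", object@name, " [",
      as.character(GenomeInfoDb::seqnames(object@region)), ":",
      BiocGenerics::start(object@region), "-",
      BiocGenerics::end(object@region), "] unit ", object@refMotif,
      "; normal ", object@normalRange[1], "-", object@normalRange[2],
      ", pathogenic > ", object@pathogenicThreshold, sep = "")
  if (length(object@pathogenicMotifs))
    cat(" with motif(s) ", paste(object@pathogenicMotifs, collapse = "/"),
        sep = "")
  cat("\n")
  invisible(NULL)
})

## Motif priority order used for decomposition at a locus: reference
## first, then pathogenic, then interruption motifs.
.locusMotifs <- function(locus) {
  unique(c(locus@refMotif, locus@pathogenicMotifs,
           locus@interruptionMotifs))
}

#' Decompose a tract sequence into motif runs
#'
#' Greedy left-to-right scan: at each offset, if the window of motif
#' length matches one of the motifs (first match in the given priority
#' order), the run of that motif is opened or extended and the scan
#' advances by one unit; otherwise one non-motif base is emitted and the
#' scan advances by one base. Consecutive non-motif bases are coalesced
#' into segments. The output tiles the input exactly.
#'
#' @param seq Tract sequence (character or \code{DNAString}).
#' @param motifs Motifs in priority order; all must share one unit
#'   length.
#' @return \code{data.frame} with columns \code{kind} (\code{"run"} or
#'   \code{"nonmotif"}), \code{motif} (\code{NA} for non-motif
#'   segments), \code{copies}, \code{start} (1-based offset in the
#'   tract), \code{width}, \code{seq}.
#' @examples
#' decomposeTract("CAGCAGCAGCATCAGCAG", c("CAG", "CAT"))
#' @export
decomposeTract <- function(seq, motifs) {
  seq <- toupper(as.character(seq))
  if (!length(motifs)) stop("configuration error: empty motif list")
  motifs <- toupper(motifs)
  if (length(unique(nchar(motifs))) != 1L)
    stop("configuration error: motifs of unequal length")
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over {A,C,G,T,N}")
  k <- nchar(motifs[1L])
  n <- nchar(seq)
  empty <- data.frame(kind = character(), motif = character(),
                      copies = integer(), start = integer(),
                      width = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  nm <- n - k + 1L
  m <- if (nm >= 1L) match(substring(seq, 1:nm, k:n), motifs) else
    integer(0)
  rows <- vector("list", 16L); nr <- 0L
  push <- function(row) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * nr
    rows[[nr]] <<- row
  }
  pos <- 1L
  while (pos <= n) {
    if (pos <= nm && !is.na(m[pos])) {
      j <- m[pos]; copies <- 1L; p2 <- pos + k
      while (p2 <= nm && !is.na(m[p2]) && m[p2] == j) {
        copies <- copies + 1L; p2 <- p2 + k
      }
      push(list(kind = "run", motif = motifs[j], copies = copies,
                start = pos, width = copies * k))
      pos <- pos + copies * k
    } else {
      s0 <- pos
      pos <- pos + 1L
      while (pos <= n && (pos > nm || is.na(m[pos]))) pos <- pos + 1L
      push(list(kind = "nonmotif", motif = NA_character_,
                copies = NA_integer_, start = s0, width = pos - s0))
    }
  }
  rows <- rows[seq_len(nr)]
  out <- data.frame(
    kind = vapply(rows, `[[`, character(1), "kind"),
    motif = vapply(rows, function(r) r$motif %||% NA_character_,
                   character(1)),
    copies = vapply(rows, function(r) as.integer(r$copies %||% NA),
                    integer(1)),
    start = vapply(rows, `[[`, integer(1), "start"),
    width = vapply(rows, `[[`, integer(1), "width"),
    stringsAsFactors = FALSE)
  out$seq <- substring(seq, out$start, out$start + out$width - 1L)
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a)))
  b else a

#' Construct a RepeatRead (decomposed tract sequence)
#'
#' @param seq Tract sequence spanning the repeat.
#' @param motifs Motif priority list, or a
#'   \code{\linkS4class{RepeatLocus}} (reference, then pathogenic, then
#'   interruption motifs).
#' @param id Read identifier.
#' @return A \code{RepeatRead} with the run decomposition in
#'   \code{repeatRuns(x)}.
#' @export
repeatRead <- function(seq, motifs, id = "read") {
  if (methods::is(motifs, "RepeatLocus")) motifs <- .locusMotifs(motifs)
  methods::new("RepeatRead", id = id, seq = toupper(as.character(seq)),
               runs = decomposeTract(seq, motifs))
}

#' @exportClass RepeatRead
#' @rdname repeatRead
setClass("RepeatRead", representation(id = "character", seq = "character",
                                      runs = "data.frame"))

setValidity("RepeatRead", function(object) {
  if (sum(object@runs$width) != nchar(object@seq))
    return("runs plus non-motif segments must tile the tract")
  TRUE
})

#' @rdname repeatRead
#' @param x A \code{RepeatRead}.
#' @export
repeatRuns <- function(x) x@runs

setMethod("show", "RepeatRead", function(object) {
  runs <- object@runs[object@runs$kind == "run", , drop = FALSE]
  cat("RepeatRead '", object@id, "' (", nchar(object@seq), " bp): ",
      if (nrow(runs)) paste0(runs$motif, "x", runs$copies,
                             collapse = " ") else "no motif runs",
      "\n", sep = "")
  invisible(NULL)
})

#' Total motif copies carried by a read
#'
#' @param read A \code{RepeatRead}.
#' @param motifClass \code{"any"} (all runs), \code{"reference"} or
#'   \code{"pathogenic"} (runs whose motif is in the corresponding locus
#'   set).
#' @param locus Required for \code{"reference"}/\code{"pathogenic"}.
#' @return Non-negative integer copy count.
#' @examples
#' rd <- repeatRead("AAAAGAAAAGAAAAGAAGGGAAGGGAAGGGAAGGG",
#'                  c("AAAAG", "AAGGG"))
#' readCopyNumber(rd)  # 7
#' @export
readCopyNumber <- function(read, motifClass = c("any", "reference",
                                                "pathogenic"),
                           locus = NULL) {
  motifClass <- match.arg(motifClass)
  runs <- read@runs[read@runs$kind == "run", , drop = FALSE]
  if (!nrow(runs)) return(0L)
  keep <- switch(motifClass,
    any = rep(TRUE, nrow(runs)),
    reference = {
      if (is.null(locus)) stop("locus required for motifClass 'reference'")
      runs$motif %in% locus@refMotif
    },
    pathogenic = {
      if (is.null(locus)) stop("locus required for motifClass 'pathogenic'")
      runs$motif %in% locus@pathogenicMotifs
    })
  sum(runs$copies[keep])
}

#' Interruption runs in a decomposed read
#'
#' Returns the runs whose motif belongs to the locus's interruption set
#' (e.g. CAT units inside a CAG tract; their presence is protective at
#' some loci).
#'
#' @param read A \code{RepeatRead} decomposed with the locus's
#'   interruption motifs included.
#' @param locus A \code{\linkS4class{RepeatLocus}}.
#' @return \code{data.frame} of interruption runs (\code{motif},
#'   \code{copies}, \code{start}); zero rows when uninterrupted.
#' @export
detectInterruptions <- function(read, locus) {
  runs <- read@runs[read@runs$kind == "run", , drop = FALSE]
  runs <- runs[runs$motif %in% locus@interruptionMotifs, , drop = FALSE]
  rownames(runs) <- NULL
  runs[, c("motif", "copies", "start")]
}

#' Classify a repeat allele at a locus
#'
#' Both size and motif content decide pathogenicity:
#' \itemize{
#'   \item \code{pathogenic}: dominant motif in the pathogenic set AND
#'     copies strictly above the pathogenic threshold;
#'   \item \code{expanded_nonpathogenic_motif}: copies above the
#'     threshold with a non-pathogenic dominant motif;
#'   \item \code{normal}: copies inside the normal range with the
#'     reference motif;
#'   \item \code{intermediate}: everything else (e.g. motif converted but
#'     not yet expanded).
#' }
#' Every (motif, copy number) pair maps to exactly one class.
#'
#' @param allele A \code{\linkS4class{RepeatAllele}} (or a numeric copy
#'   count, with \code{dominantMotif} supplied).
#' @param locus A \code{\linkS4class{RepeatLocus}}.
#' @param dominantMotif Used when \code{allele} is a bare copy count.
#' @return Classification string.
#' @examples
#' rfc1 <- repeatLocus("RFC1", "chr4", 39350045, 39350103, "AAAAG",
#'                     pathogenicMotifs = "AAGGG")
#' classifyAllele(450, rfc1, dominantMotif = "AAGGG")  # pathogenic
#' classifyAllele(100, rfc1, dominantMotif = "AAGGG")  # intermediate
#' @export
classifyAllele <- function(allele, locus, dominantMotif = NULL) {
  if (methods::is(allele, "RepeatAllele")) {
    copies <- allele@copies
    motif <- allele@dominantMotif
  } else {
    copies <- allele
    motif <- dominantMotif
    if (is.null(motif)) stop("dominantMotif required")
  }
  if (copies > locus@pathogenicThreshold) {
    if (motif %in% locus@pathogenicMotifs) return("pathogenic")
    return("expanded_nonpathogenic_motif")
  }
  if (copies >= locus@normalRange[1] && copies <= locus@normalRange[2] &&
      motif == locus@refMotif) return("normal")
  "intermediate"
}

setMethod("show", "RepeatAllele", function(object) {
  cat("RepeatAllele: ", object@copies, " copies of ",
      object@dominantMotif, " (", object@supportingReads, " reads",
      if (!is.na(object@classification))
        paste0("; ", object@classification), ")\n", sep = "")
  invisible(NULL)
})

#' Genotype a repeat locus from spanning reads
#'
#' Per-read total copy numbers are split into two clusters by 1-D
#' two-means with deterministic initialization at the minimum and maximum
#' values; clusters whose centers end up within \code{mergeDistance}
#' copies are merged into a homozygous call (the same allele reported
#' twice). Each allele's copy number is the median of its member reads;
#' its dominant motif is the motif with the plurality of copies across
#' member reads. Alleles are classified with
#' \code{\link{classifyAllele}}.
#'
#' @param reads List of \code{RepeatRead}, or character/\code{DNAStringSet}
#'   of tract sequences (decomposed against the locus motifs).
#' @param locus A \code{\linkS4class{RepeatLocus}}.
#' @param minReads Minimum spanning-read count (default 4); fewer is an
#'   error naming the locus.
#' @param mergeDistance Homozygote merge distance in copies (default 3).
#' @return List of two \code{\linkS4class{RepeatAllele}}s,
#'   \code{allele1} (smaller) and \code{allele2}.
#' @examples
#' loc <- repeatLocus("ATXN1", "chr6", 16327636, 16327722, "CAG",
#'                    pathogenicMotifs = "CAG",
#'                    interruptionMotifs = "CAT",
#'                    normalRange = c(6, 35), pathogenicThreshold = 38)
#' reads <- c(strrep("CAG", 30), strrep("CAG", 29), strrep("CAG", 45),
#'            strrep("CAG", 46))
#' genotypeLocus(reads, loc)
#' @export
genotypeLocus <- function(reads, locus, minReads = 4, mergeDistance = 3) {
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.character(reads)) {
    ids <- if (!is.null(names(reads))) names(reads) else
      paste0("read", seq_along(reads))
    reads <- mapply(repeatRead, reads, id = ids,
                    MoreArgs = list(motifs = locus), SIMPLIFY = FALSE)
  }
  if (length(reads) < minReads)
    stop("locus ", locus@name, ": only ", length(reads),
         " spanning read(s), need >= ", minReads)
  v <- vapply(reads, readCopyNumber, numeric(1))
  ## deterministic 1-D two-means
  c1 <- min(v); c2 <- max(v)
  assign <- NULL
  for (it in seq_len(100L)) {
    a <- ifelse(abs(v - c1) <= abs(v - c2), 1L, 2L)
    if (identical(a, assign)) break
    assign <- a
    if (any(a == 1L)) c1 <- mean(v[a == 1L])
    if (any(a == 2L)) c2 <- mean(v[a == 2L])
  }
  homozygous <- abs(c1 - c2) <= mergeDistance
  mkAllele <- function(members) {
    copies <- stats::median(v[members])
    motifTotals <- list()
    for (rd in reads[members]) {
      runs <- rd@runs[rd@runs$kind == "run", , drop = FALSE]
      for (r in seq_len(nrow(runs))) {
        mt <- runs$motif[r]
        motifTotals[[mt]] <- (motifTotals[[mt]] %||% 0L) + runs$copies[r]
      }
    }
    dominant <- if (length(motifTotals)) {
      tot <- unlist(motifTotals)
      prio <- .locusMotifs(locus)
      cand <- names(tot)[tot == max(tot)]
      cand[order(match(cand, prio))][1L]
    } else locus@refMotif
    al <- methods::new("RepeatAllele", copies = copies,
                       dominantMotif = dominant,
                       supportingReads = length(members),
                       classification = NA_character_)
    al@classification <- classifyAllele(al, locus)
    al
  }
  if (homozygous) {
    al <- mkAllele(seq_along(reads))
    return(list(allele1 = al, allele2 = al))
  }
  a1 <- mkAllele(which(assign == 1L))
  a2 <- mkAllele(which(assign == 2L))
  if (a1@copies <= a2@copies) list(allele1 = a1, allele2 = a2)
  else list(allele1 = a2, allele2 = a1)
}

#' Write per-read decomposition and per-locus genotype tables
#'
#' The decomposition table has one row per motif run or non-motif
#' segment per read — the data behind a stacked-read "waterfall" plot of
#' a repeat tract.
#'
#' @param reads List of \code{RepeatRead}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRepeatTable <- function(reads, path) {
  rows <- lapply(reads, function(rd)
    cbind(read = rd@id, rd@runs[, c("kind", "motif", "copies", "start",
                                    "width")]))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
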