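## Central S4 classes. Calls of every class live in a GRanges (1-based,
## closed intervals, the native Bioconductor convention); VCF positions and
## BED half-open coordinates are converted at the I/O boundary.

.CALL_CLASSES <- c("smallvariant", "sv", "cnv", "mixed")
.SMALL_VTYPES <- c("SNV", "INS", "DEL", "DELINS")
.SV_TYPES <- c("DEL", "DUP", "INS", "INV", "BND")
.CNV_STATES <- c("loss", "gain")
.GENOTYPES <- c("het", "hom", "hemi", "unknown")
.IMPACT_LEVELS <- c("exonic_disrupting", "partial_coding_disruption",
                    "intronic_near_splice", "intronic_deep",
                    "whole_gene_contained", "breakpoint_in_gene",
                    "intergenic")
.ALLELE_CLASSES <- c("normal", "intermediate",
                     "expanded_nonpathogenic_motif", "pathogenic")

#' CallSet: calls from one caller (or one merge) as an annotated GRanges
#'
#' A \code{CallSet} holds the records of a single source caller — small
#' variants, structural variants or read-depth CNV segments — as a
#' \code{GRanges} with class-specific metadata columns, plus provenance.
#'
#' Metadata columns by call class:
#' \describe{
#'   \item{smallvariant}{\code{ref}, \code{alt}, \code{vtype} (SNV/INS/DEL/
#'     DELINS), \code{genotype}, \code{vaf}, \code{quality},
#'     \code{size_change} (\code{nchar(alt) - nchar(ref)}).}
#'   \item{sv}{\code{svtype} (DEL/DUP/INS/INV/BND), \code{svlen} (NA only
#'     for BND), \code{quality}, \code{generic_flag} (breakpoint reported
#'     without a determined rearrangement class), \code{mate_contig},
#'     \code{mate_pos} (BND only).}
#'   \item{cnv}{\code{copy_state} (loss/gain), \code{q0}, \code{p_n},
#'     \code{p_value}, \code{bin_size}, \code{quality}.}
#' }
#' Merged sets additionally carry \code{callers} (comma-joined provenance)
#' and \code{support} (number of distinct supporting callers); annotated
#' sets carry \code{genes} (comma-joined gene symbols).
#'
#' @slot calls \code{GRanges} of call coordinates with the columns above.
#' @slot caller Single caller identifier (or \code{"merged"}/\code{"truth"}).
#' @slot callClass One of \code{"smallvariant"}, \code{"sv"}, \code{"cnv"},
#'   \code{"mixed"} (merged/truth sets only).
#' @slot provenance List of ingest metadata (path, dialect, timestamp,
#'   quarantined record report).
#' @exportClass CallSet
setClass("CallSet", representation(
  calls = "GRanges",
  caller = "character",
  callClass = "character",
  provenance = "list"
))

setValidity("CallSet", function(object) {
  msgs <- character()
  if (length(object@caller) != 1L || is.na(object@caller))
    msgs <- c(msgs, "caller must be a single non-NA string")
  if (!(object@callClass %in% .CALL_CLASSES))
    msgs <- c(msgs, paste0("callClass must be one of: ",
                           paste(.CALL_CLASSES, collapse = ", ")))
  mc <- S4Vectors::mcols(object@calls)
  need <- switch(object@callClass,
    smallvariant = c("ref", "alt", "vtype", "genotype", "vaf", "quality",
                     "size_change"),
    sv = c("svtype", "svlen", "quality", "generic_flag"),
    cnv = c("copy_state", "q0", "p_n", "p_value", "bin_size"),
    mixed = "class")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    msgs <- c(msgs, paste0("missing metadata column(s): ",
                           paste(miss, collapse = ", ")))
  if (object@callClass == "smallvariant" && !length(miss)) {
    bad <- !(mc$vtype %in% .SMALL_VTYPES)
    if (any(bad)) msgs <- c(msgs, "invalid vtype value(s)")
    if (length(object@calls)) {
      refs <- as.character(mc$ref); alts <- as.character(mc$alt)
      if (any(!nzchar(refs)) || any(!nzchar(alts)))
        msgs <- c(msgs, "ref and alt must be nonempty")
      else {
        if (any(refs == alts)) msgs <- c(msgs, "ref must differ from alt")
        if (any(grepl("[^ACGTN]", refs)) || any(grepl("[^ACGTN]", alts)))
          msgs <- c(msgs, "ref/alt must be over {A,C,G,T,N}")
        snv <- mc$vtype == "SNV"
        if (any(snv & (nchar(refs) != 1L | nchar(alts) != 1L)))
          msgs <- c(msgs, "SNV requires single-base ref and alt")
      }
      if (!all(mc$genotype %in% .GENOTYPES))
        msgs <- c(msgs, "invalid genotype value(s)")
      v <- mc$vaf[!is.na(mc$vaf)]
      if (length(v) && (any(v < 0) || any(v > 1)))
        msgs <- c(msgs, "vaf must lie in [0,1]")
    }
  }
  if (object@callClass == "sv" && !length(miss) && length(object@calls)) {
    if (!all(mc$svtype %in% .SV_TYPES))
      msgs <- c(msgs, "invalid svtype value(s)")
    nolen <- is.na(mc$svlen)
    if (any(nolen & mc$svtype != "BND"))
      msgs <- c(msgs, "svlen may be absent only for BND")
    span <- (mc$svtype %in% c("DEL", "DUP", "INV")) & !nolen
    if (any(mc$svlen[span] != BiocGenerics::width(object@calls)[span]))
      msgs <- c(msgs, "DEL/DUP/INV interval width must equal svlen")
    bnd <- mc$svtype == "BND"
    if (any(bnd)) {
      if (!all(c("mate_contig", "mate_pos") %in% colnames(mc)) ||
          any(is.na(mc$mate_contig[bnd])) || any(is.na(mc$mate_pos[bnd])))
        msgs <- c(msgs, "BND calls must carry a mate breakend")
    }
  }
  if (object@callClass == "cnv" && !length(miss) && length(object@calls)) {
    if (!all(mc$copy_state %in% .CNV_STATES))
      msgs <- c(msgs, "copy_state must be loss or gain")
    for (f in c("q0", "p_n")) {
      v <- mc[[f]][!is.na(mc[[f]])]
      if (length(v) && (any(v < 0) || any(v > 1)))
        msgs <- c(msgs, paste0(f, " must lie in [0,1]"))
    }
    pv <- mc$p_value[!is.na(mc$p_value)]
    if (length(pv) && (any(pv <= 0) || any(pv > 1)))
      msgs <- c(msgs, "p_value must lie in (0,1]")
    w <- BiocGenerics::width(object@calls)
    if (any(w %% mc$bin_size != 0))
      msgs <- c(msgs, "segment width must be a positive multiple of bin_size")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenePanel: exon coordinates for a set of (phenotype) genes
#'
#' @slot exons \code{GRanges} of exons with metadata column \code{symbol};
#'   per gene the exons are sorted and pairwise disjoint, on one contig.
#' @slot genes \code{data.frame} with one row per gene: \code{symbol},
#'   \code{contig}, \code{strand}, \code{phenotype_associated},
#'   \code{gene_start}, \code{gene_end} (1-based closed span),
#'   \code{n_exons}.
#' @exportClass GenePanel
setClass("GenePanel", representation(
  exons = "GRanges",
  genes = "data.frame"
))

setValidity("GenePanel", function(object) {
  mc <- S4Vectors::mcols(object@exons)
  if (!("symbol" %in% colnames(mc)))
    return("exons must carry a 'symbol' metadata column")
  need <- c("symbol", "contig", "strand", "phenotype_associated",
            "gene_start", "gene_end", "n_exons")
  if (!all(need %in% colnames(object@genes)))
    return("gene table is missing required columns")
  for (sym in object@genes$symbol) {
    ex <- object@exons[mc$symbol == sym]
    if (length(unique(as.character(GenomeInfoDb::seqnames(ex)))) > 1L)
      return(paste0("gene ", sym, " has exons on multiple contigs"))
    s <- BiocGenerics::start(ex)
    if (is.unsorted(s)) return(paste0("exons of ", sym, " are unsorted"))
    if (length(ex) > 1L &&
        any(BiocGenerics::start(ex)[-1L] <=
            BiocGenerics::end(ex)[-length(ex)]))
      return(paste0("exons of ", sym, " overlap"))
  }
  TRUE
})

#' RoutingPolicy: per-caller size windows, chromosome partition and
#' depth-segment thresholds
#'
#' The policy encodes how raw caller output is restricted before filtering:
#' the small-variant caller is trusted below \code{smallMaxSize} (exclusive),
#' the bridging SV caller inside \code{[bridgeMin, bridgeMax)}, the primary
#' SV caller at \code{>= svMinSize}; the two read-depth callers split the
#' genome into autosomes and sex chromosomes; sex-chromosome depth segments
#' must additionally pass \code{q0 < q0Max}, \code{p_n < pNMax} and
#' \code{p_value < pMax} (all strict).
#'
#' @slot smallMaxSize,bridgeMin,bridgeMax,svMinSize Size windows in bp.
#' @slot q0Max,pNMax,pMax Depth-segment thresholds.
#' @slot callerRoles Named character: caller id -> role, roles drawn from
#'   \code{small}, \code{bridge}, \code{primary_sv}, \code{depth_autosome},
#'   \code{depth_sexchrom}, \code{repeat}, \code{haplotype}.
#' @slot callerOrder Caller ids in tie-breaking priority order for merging.
#' @exportClass RoutingPolicy
setClass("RoutingPolicy", representation(
  smallMaxSize = "numeric",
  bridgeMin = "numeric",
  bridgeMax = "numeric",
  svMinSize = "numeric",
  q0Max = "numeric",
  pNMax = "numeric",
  pMax = "numeric",
  callerRoles = "character",
  callerOrder = "character"
))

setValidity("RoutingPolicy", function(object) {
  msgs <- character()
  if (object@bridgeMin != object@smallMaxSize)
    msgs <- c(msgs, "bridging window must start at the small-variant max size")
  if (object@bridgeMax != object@svMinSize)
    msgs <- c(msgs, "bridging window must end at the primary SV caller floor")
  roles <- c("small", "bridge", "primary_sv", "depth_autosome",
             "depth_sexchrom", "repeat", "haplotype")
  if (!all(object@callerRoles %in% roles))
    msgs <- c(msgs, "unknown caller role")
  if (is.null(names(object@callerRoles)) ||
      anyDuplicated(names(object@callerRoles)))
    msgs <- c(msgs, "callerRoles must be uniquely named by caller id")
  if (length(msgs)) msgs else TRUE
})

#' MatchResult: outcome of exact truth-set matching
#'
#' @slot matched \code{data.frame} of matched pairs (one row per matched
#'   truth record): \code{contig}, \code{pos}, \code{ref}, \code{alt},
#'   \code{query_idx}, \code{truth_idx}.
#' @slot missed \code{data.frame} of truth-only records.
#' @slot extra \code{data.frame} of query-only records.
#' @slot nQuery,nTruth Record counts of the compared sets.
#' @exportClass MatchResult
setClass("MatchResult", representation(
  matched = "data.frame",
  missed = "data.frame",
  extra = "data.frame",
  nQuery = "integer",
  nTruth = "integer"
))

setValidity("MatchResult", function(object) {
  if (nrow(object@matched) + nrow(object@missed) != object@nTruth)
    return("|matched| + |missed| must equal the truth count")
  if (nrow(object@matched) + nrow(object@extra) != object@nQuery)
    return("|matched| + |extra| must equal the query count")
  TRUE
})

#' ConcordanceReport: stratified detection proportions with Wilson intervals
#'
#' @slot table \code{data.frame} with one row per stratum plus an
#'   \code{"Overall"} row: \code{stratum}, \code{k}, \code{n},
#'   \code{proportion}, \code{ci_low}, \code{ci_high}.
#' @slot confidence Confidence level of the intervals.
#' @exportClass ConcordanceReport
setClass("ConcordanceReport", representation(
  table = "data.frame",
  confidence = "numeric"
))

setValidity("ConcordanceReport", function(object) {
  tb <- object@table
  if (!all(c("stratum", "k", "n", "proportion", "ci_low", "ci_high") %in%
           colnames(tb)))
    return("report table is missing required columns")
  ok <- tb$ci_low >= 0 & tb$ci_low <= tb$proportion &
        tb$proportion <= tb$ci_high & tb$ci_high <= 1
  if (!all(ok)) return("each row must satisfy 0 <= low <= p <= high <= 1")
  ov <- tb$stratum == "Overall"
  if (sum(ov) == 1L && sum(!ov) > 0L) {
    if (tb$k[ov] != sum(tb$k[!ov]) || tb$n[ov] != sum(tb$n[!ov]))
      return("overall counts must equal the stratum sums")
  }
  TRUE
})

#' FunnelReport: per-stage input/output counts of the triage cascade
#'
#' @slot stages \code{data.frame}: \code{stage}, \code{n_in}, \code{n_out}.
#' @exportClass FunnelReport
setClass("FunnelReport", representation(stages = "data.frame"))

setValidity("FunnelReport", function(object) {
  st <- object@stages
  if (!all(c("stage", "n_in", "n_out") %in% colnames(st)))
    return("stages must have columns stage, n_in, n_out")
  if (any(st$n_out > st$n_in))
    return("every stage must satisfy n_out <= n_in")
  if (nrow(st) > 1L && any(st$n_in[-1L] != st$n_out[-nrow(st)]))
    return("stage outputs must chain to the next stage's inputs")
  TRUE
})

#' RepeatLocus: a tandem-repeat tract and its clinical thresholds
#'
#' @slot name Locus name (e.g. the gene symbol).
#' @slot region \code{GRanges} of the tract (length 1).
#' @slot refMotif Reference (wild-type) repeat unit, e.g. "AAAAG" or "CAG".
#' @slot pathogenicMotifs Motifs that confer pathogenicity when expanded
#'   (e.g. "AAGGG"); may be empty when size alone is disqualifying.
#' @slot interruptionMotifs Interruption units (e.g. "CAT" in a CAG tract).
#' @slot normalRange Inclusive copy-number range of normal alleles.
#' @slot pathogenicThreshold Copies strictly above this are expanded.
#' @exportClass RepeatLocus
setClass("RepeatLocus", representation(
  name = "character",
  region = "GRanges",
  refMotif = "character",
  pathogenicMotifs = "character",
  interruptionMotifs = "character",
  normalRange = "numeric",
  pathogenicThreshold = "numeric"
))

setValidity("RepeatLocus", function(object) {
  motifs <- c(object@refMotif, object@pathogenicMotifs,
              object@interruptionMotifs)
  if (length(unique(nchar(motifs))) > 1L)
    return("all motifs at one locus must share a common unit length")
  if (grepl("[^ACGT]", paste(motifs, collapse = "")))
    return("motifs must be over {A,C,G,T}")
  if (length(object@normalRange) != 2L ||
      object@normalRange[1] > object@normalRange[2])
    return("normalRange must be c(low, high) with low <= high")
  if (object@normalRange[2] >= object@pathogenicThreshold)
    return("normal range upper bound must be below the pathogenic threshold")
  TRUE
})

#' RepeatAllele: a clustered allele estimate at a repeat locus
#'
#' @slot copies Copy-number estimate (median of member reads).
#' @slot dominantMotif Motif with the plurality of copies among member reads.
#' @slot supportingReads Number of member reads.
#' @slot classification One of \code{normal}, \code{intermediate},
#'   \code{expanded_nonpathogenic_motif}, \code{pathogenic} (or \code{NA}
#'   before classification).
#' @exportClass RepeatAllele
setClass("RepeatAllele", representation(
  copies = "numeric",
  dominantMotif = "character",
  supportingReads = "integer",
  classification = "character"
))

setValidity("RepeatAllele", function(object) {
  if (object@supportingReads < 1L)
    return("supporting read count must be >= 1")
  if (!is.na(object@classification) &&
      !(object@classification %in% .ALLELE_CLASSES))
    return("invalid classification")
  TRUE
})
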