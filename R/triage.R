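## The structured SV filtering cascade: per-caller restriction, chromosome
## partition of the depth callers, cross-caller merging, mechanistic
## gene-impact classification, phenotype-gene intersection and declarative
## logic rules, with a per-stage funnel report.

#' Restrict a caller's output to its trusted size band
#'
#' Each caller is only trusted inside its declared size range: the
#' small-variant genotyper below \code{smallMaxSize}, the bridging SV
#' caller inside \code{[bridgeMin, bridgeMax)}, the primary SV caller at
#' \code{>= svMinSize}. Breakend (BND) records carry no length and pass
#' the breakpoint callers' restriction unconditionally; depth, repeat and
#' haplotype callers are not size-restricted here.
#'
#' @param x A \code{\linkS4class{CallSet}} from a single registered caller.
#' @param policy A \code{\linkS4class{RoutingPolicy}}.
#' @return The restricted \code{CallSet}.
#' @export
restrictByCaller <- function(x, policy = routingPolicy()) {
  role <- policy@callerRoles[callerId(x)]
  if (is.na(role))
    stop("caller '", callerId(x), "' is not registered in the policy")
  sizes <- .callSizes(x)
  types <- .callTypes(x)
  keep <- switch(unname(role),
    small = abs(sizes) < policy@smallMaxSize,
    bridge = types == "BND" |
      (!is.na(sizes) & sizes >= policy@bridgeMin &
         sizes < policy@bridgeMax),
    primary_sv = types == "BND" | (!is.na(sizes) & sizes >= policy@svMinSize),
    rep(TRUE, length(x)))
  x[which(keep)]
}

#' Filter read-depth CNV segments by chromosome partition and quality
#'
#' The sex-chromosome depth caller keeps only chrX/chrY segments that pass
#' all three quality thresholds (\code{q0 < q0Max}, \code{p_n < pNMax},
#' \code{p_value < pMax}, strict); the autosomal depth caller keeps only
#' autosomal segments. Sex-chromosome segments missing any required
#' annotation are quarantined into the ingest report.
#'
#' @param x A \code{\linkS4class{CallSet}} of class \code{"cnv"}.
#' @param policy A \code{\linkS4class{RoutingPolicy}}.
#' @return The filtered \code{CallSet}; quarantined records are appended
#'   to \code{provenance(x)$quarantined}.
#' @export
filterDepthSegments <- function(x, policy = routingPolicy()) {
  if (callClass(x) != "cnv")
    stop("filterDepthSegments expects a CNV CallSet")
  role <- policy@callerRoles[callerId(x)]
  if (is.na(role) || !(role %in% c("depth_autosome", "depth_sexchrom")))
    stop("caller '", callerId(x), "' is not a registered depth caller")
  contigs <- as.character(GenomeInfoDb::seqnames(calls(x)))
  mc <- S4Vectors::mcols(calls(x))
  if (role == "depth_autosome") return(x[which(.isAutosome(contigs))])
  onSex <- .isSexChrom(contigs)
  missing_ann <- is.na(mc$q0) | is.na(mc$p_n) | is.na(mc$p_value)
  keep <- onSex & !missing_ann &
    mc$q0 < policy@q0Max & mc$p_n < policy@pNMax & mc$p_value < policy@pMax
  out <- x[which(keep)]
  quar <- which(onSex & missing_ann)
  if (length(quar)) {
    rep0 <- out@provenance$quarantined
    if (is.null(rep0))
      rep0 <- data.frame(record = integer(), reason = character())
    out@provenance$quarantined <- rbind(rep0,
      data.frame(record = quar,
                 reason = "depth segment missing q0/p_n/p_value"))
  }
  out
}

#' Classify the mechanistic impact of one call on one gene
#'
#' Assigns exactly one impact class to a (call, gene) pair:
#' \describe{
#'   \item{breakpoint_in_gene}{BND with a breakend (either end) inside the
#'     gene span.}
#'   \item{whole_gene_contained}{the call contains every exon and both call
#'     endpoints lie outside the gene span — e.g. a complete gene inversion
#'     with intergenic breakpoints.}
#'   \item{exonic_disrupting}{overlaps at least one exon without containing
#'     the gene.}
#'   \item{partial_coding_disruption}{an inversion overlapping a proper
#'     subset of the exons.}
#'   \item{intronic_near_splice}{no exon overlap, inside the gene, within
#'     \code{nearSpliceBp} of an exon boundary.}
#'   \item{intronic_deep}{inside the gene but far from any exon.}
#'   \item{intergenic}{anything else.}
#' }
#'
#' @param call Length-1 \code{GRanges}; for SVs the metadata column
#'   \code{svtype} (or \code{typelab}) gives the rearrangement class, with
#'   \code{mate_contig}/\code{mate_pos} for BND.
#' @param gene Exon \code{GRanges} of a single gene (e.g.
#'   \code{exons(panel, "PKD1")}); must be nonempty.
#' @param nearSpliceBp Distance in bp from an exon boundary inside which
#'   an intronic call is still considered splice-relevant (default 100,
#'   chosen so that a clinically decisive insertion 49 bp from a splice
#'   boundary survives the default filter).
#' @return Single impact class string.
#' @examples
#' ex <- GenomicRanges::GRanges("chr11",
#'   IRanges::IRanges(c(1000, 2000), c(1100, 2100)))
#' ins <- GenomicRanges::GRanges("chr11", IRanges::IRanges(1149, 1149),
#'                               svtype = "INS")
#' classifyGeneImpact(ins, ex)  # intronic_near_splice (49 bp from exon 1)
#' @export
classifyGeneImpact <- function(call, gene, nearSpliceBp = 100) {
  if (!length(gene)) stop("gene has zero exons")
  stopifnot(length(call) == 1L)
  mc <- S4Vectors::mcols(call)
  st <- if ("typelab" %in% colnames(mc)) as.character(mc$typelab[1L])
        else if ("svtype" %in% colnames(mc)) as.character(mc$svtype[1L])
        else if ("vtype" %in% colnames(mc)) as.character(mc$vtype[1L])
        else "DEL"
  gcontig <- as.character(GenomeInfoDb::seqnames(gene))[1L]
  gs <- min(BiocGenerics::start(gene)); ge <- max(BiocGenerics::end(gene))
  ccontig <- as.character(GenomeInfoDb::seqnames(call))
  cs <- BiocGenerics::start(call); ce <- BiocGenerics::end(call)
  if (identical(st, "BND")) {
    inSpan <- ccontig == gcontig && cs >= gs && cs <= ge
    mateIn <- FALSE
    if (all(c("mate_contig", "mate_pos") %in% colnames(mc)) &&
        !is.na(mc$mate_contig[1L]))
      mateIn <- mc$mate_contig[1L] == gcontig &&
        mc$mate_pos[1L] >= gs && mc$mate_pos[1L] <= ge
    return(if (inSpan || mateIn) "breakpoint_in_gene" else "intergenic")
  }
  if (ccontig != gcontig) return("intergenic")
  if (cs < gs && ce > ge) return("whole_gene_contained")
  novl <- sum(BiocGenerics::start(gene) <= ce & BiocGenerics::end(gene) >= cs)
  if (novl > 0L) {
    if (identical(st, "INV") && novl < length(gene))
      return("partial_coding_disruption")
    return("exonic_disrupting")
  }
  if (ce >= gs && cs <= ge) {
    gaps <- pmax(BiocGenerics::start(gene) - ce, cs - BiocGenerics::end(gene))
    if (min(gaps) <= nearSpliceBp) return("intronic_near_splice")
    return("intronic_deep")
  }
  "intergenic"
}

## All (call, gene) impact assignments for a CallSet against a panel.
## Only pairs where the call touches the gene span (or a BND breakend /
## mate falls inside it) are returned; absent pairs are intergenic.
.impactTable <- function(x, panel, nearSpliceBp = 100) {
  gr <- calls(x)
  spans <- geneSpans(panel)
  out <- data.frame(call = integer(), symbol = character(),
                    impact = character())
  if (!length(gr) || !length(spans)) return(out)
  types <- .callTypes(x)
  mc <- S4Vectors::mcols(gr)
  isBnd <- types == "BND"
  ## span overlap for non-BND calls
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, spans, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keepPair <- !isBnd[qh]
  pairs <- data.frame(call = qh[keepPair], gene = sh[keepPair])
  ## BND: breakend position or mate inside a span
  if (any(isBnd)) {
    bidx <- which(isBnd)
    bgr <- gr[bidx]
    h1 <- suppressWarnings(
      GenomicRanges::findOverlaps(bgr, spans, ignore.strand = TRUE))
    p1 <- data.frame(call = bidx[S4Vectors::queryHits(h1)],
                     gene = S4Vectors::subjectHits(h1))
    p2 <- NULL
    if (all(c("mate_contig", "mate_pos") %in% colnames(mc))) {
      hasMate <- !is.na(mc$mate_contig[bidx])
      if (any(hasMate)) {
        mgr <- GenomicRanges::GRanges(mc$mate_contig[bidx][hasMate],
          IRanges::IRanges(mc$mate_pos[bidx][hasMate], width = 1L))
        h2 <- suppressWarnings(
          GenomicRanges::findOverlaps(mgr, spans, ignore.strand = TRUE))
        p2 <- data.frame(
          call = bidx[hasMate][S4Vectors::queryHits(h2)],
          gene = S4Vectors::subjectHits(h2))
      }
    }
    pairs <- unique(rbind(pairs, p1, p2))
  }
  if (!nrow(pairs)) return(out)
  symbols <- S4Vectors::mcols(spans)$symbol
  imp <- character(nrow(pairs))
  exCache <- list()
  for (r in seq_len(nrow(pairs))) {
    sym <- symbols[pairs$gene[r]]
    ex <- exCache[[sym]]
    if (is.null(ex)) { ex <- exons(panel, sym); exCache[[sym]] <- ex }
    imp[r] <- classifyGeneImpact(gr[pairs$call[r]], ex, nearSpliceBp)
  }
  data.frame(call = pairs$call, symbol = symbols[pairs$gene],
             impact = imp)
}

#' Default mechanistic keep/drop matrix
#'
#' Rows are call types (small-variant and SV classes plus CNV copy
#' states), columns impact classes; \code{TRUE} means a (call, gene)
#' assignment in that cell lets the call advance. The default keeps
#' exonic-disrupting, partial coding disruption, near-splice intronic and
#' in-gene breakpoint assignments for every type; whole-gene containment
#' is kept for copy-changing types (DEL/DUP/loss/gain — whole-gene dosage
#' change is mechanistically disease-causing) but dropped for inversions
#' (a complete gene inversion with intergenic breakpoints leaves the gene
#' intact); deep-intronic and intergenic assignments are dropped.
#'
#' @return Logical matrix with complete (type, impact) coverage.
#' @examples defaultImpactRules()["INV", "whole_gene_contained"]
#' @export
defaultImpactRules <- function() {
  types <- c("SNV", "DELINS", "DEL", "DUP", "INS", "INV", "BND",
             "loss", "gain")
  m <- matrix(FALSE, nrow = length(types), ncol = length(.IMPACT_LEVELS),
              dimnames = list(types, .IMPACT_LEVELS))
  m[, "exonic_disrupting"] <- TRUE
  m[, "partial_coding_disruption"] <- TRUE
  m[, "intronic_near_splice"] <- TRUE
  m[, "breakpoint_in_gene"] <- TRUE
  m[c("DEL", "DUP", "loss", "gain"), "whole_gene_contained"] <- TRUE
  m
}

#' Keep calls whose gene impact could mechanistically cause disease
#'
#' Every call is classified against every gene it touches
#' (\code{\link{classifyGeneImpact}}); a call survives iff at least one of
#' its (type, impact) assignments is marked keep in the rules matrix.
#' Surviving calls are annotated with their keep-triggering gene symbols
#' in the \code{genes} metadata column.
#'
#' @param x A \code{\linkS4class{CallSet}}.
#' @param panel A \code{\linkS4class{GenePanel}}.
#' @param rules Logical keep/drop matrix as from
#'   \code{\link{defaultImpactRules}}; must cover every call type present
#'   and every impact class (an incomplete matrix is a configuration
#'   error).
#' @param nearSpliceBp See \code{\link{classifyGeneImpact}}.
#' @return The filtered, gene-annotated \code{CallSet}.
#' @export
mechanisticFilter <- function(x, panel, rules = defaultImpactRules(),
                              nearSpliceBp = 100) {
  types <- unique(.callTypes(x))
  missT <- setdiff(types, rownames(rules))
  missI <- setdiff(.IMPACT_LEVELS, colnames(rules))
  if (length(missT) || length(missI))
    stop("configuration error: rules matrix does not cover ",
         paste(c(missT, missI), collapse = ", "))
  if (!length(x)) return(x)
  tab <- .impactTable(x, panel, nearSpliceBp)
  keepRow <- logical(0)
  if (nrow(tab))
    keepRow <- rules[cbind(.callTypes(x)[tab$call], tab$impact)]
  keepIdx <- sort(unique(tab$call[keepRow]))
  genes <- vapply(keepIdx, function(i)
    paste(sort(unique(tab$symbol[keepRow & tab$call == i])),
          collapse = ","), character(1))
  out <- x[keepIdx]
  S4Vectors::mcols(out@calls)$genes <- genes
  out
}

#' Restrict calls to phenotype-associated genes
#'
#' Keeps calls that touch (overlap, or for BND have a breakend inside) the
#' span of at least one phenotype-associated gene in the panel.
#'
#' @param x A \code{\linkS4class{CallSet}}.
#' @param panel A \code{\linkS4class{GenePanel}} carrying
#'   \code{phenotype_associated} flags.
#' @return The restricted \code{CallSet}.
#' @export
intersectPhenotypeGenes <- function(x, panel) {
  if (!length(x)) return(x)
  ptab <- geneTable(panel)
  if (!any(ptab$phenotype_associated)) return(x[integer(0)])
  sub <- methods::new("GenePanel",
    exons = exons(panel)[S4Vectors::mcols(exons(panel))$symbol %in%
                           ptab$symbol[ptab$phenotype_associated]],
    genes = ptab[ptab$phenotype_associated, , drop = FALSE])
  ## any (call, gene) pair at all counts as an annotation to the gene
  tab <- .impactTable(x, sub, nearSpliceBp = 0)
  x[sort(unique(tab$call))]
}

#' Validate an ordered logic-rule list
#'
#' Rules are declarative predicates applied in order as the last filtering
#' step. Each rule is a list with \code{name}, \code{type} and parameters:
#' \describe{
#'   \item{max_size / min_size}{\code{value} in bp, optional \code{svtype}
#'     to restrict the rule to one call type; records without a defined
#'     size (BND) are unaffected.}
#'   \item{min_support}{\code{value}: minimum number of distinct callers.}
#'   \item{min_quality}{\code{value}: quality floor (records without a
#'     quality are unaffected).}
#'   \item{exclude_region / require_region}{\code{region}: a \code{GRanges}
#'     or a BED path; drop (resp. keep only) calls overlapping it.}
#' }
#'
#' @param rules List of rule lists.
#' @return The validated rules, with regions materialised as GRanges.
#' @export
validateLogicRules <- function(rules) {
  known <- c("max_size", "min_size", "min_support", "min_quality",
             "exclude_region", "require_region")
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (is.null(r$type) || !(r$type %in% known))
      stop("configuration error: unknown logic-rule type '", r$type, "'")
    if (is.null(r$name)) rules[[k]]$name <- paste0("rule", k)
    if (r$type %in% c("exclude_region", "require_region") &&
        is.character(r$region))
      rules[[k]]$region <- rtracklayer::import(r$region, format = "BED")
    if (r$type %in% c("max_size", "min_size", "min_support",
                      "min_quality") && is.null(r$value))
      stop("configuration error: rule '", rules[[k]]$name,
           "' needs a value")
  }
  rules
}

#' Apply ordered logic rules
#'
#' Applies the validated rules in order; the per-rule input/output counts
#' are recorded in \code{provenance(x)$rule_log} for the funnel report.
#' An empty rule list is the identity.
#'
#' @param x A \code{\linkS4class{CallSet}}.
#' @param rules Rule list (see \code{\link{validateLogicRules}}).
#' @return The filtered \code{CallSet}.
#' @export
applyLogicRules <- function(x, rules = list()) {
  rules <- validateLogicRules(rules)
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer())
  for (r in rules) {
    nin <- length(x)
    sizes <- .callSizes(x)
    types <- .callTypes(x)
    mc <- S4Vectors::mcols(calls(x))
    inScope <- if (is.null(r$svtype)) rep(TRUE, length(x)) else
      types == r$svtype
    keep <- switch(r$type,
      max_size = !(inScope & !is.na(sizes) & sizes > r$value),
      min_size = !(inScope & !is.na(sizes) & sizes < r$value),
      min_support = {
        supp <- if ("support" %in% colnames(mc)) mc$support else
          rep(1L, length(x))
        supp[is.na(supp)] <- 1L
        !(inScope & supp < r$value)
      },
      min_quality = {
        q <- if ("quality" %in% colnames(mc)) mc$quality else
          rep(NA_real_, length(x))
        !(inScope & !is.na(q) & q < r$value)
      },
      exclude_region = {
        ov <- suppressWarnings(GenomicRanges::countOverlaps(
          calls(x), r$region, ignore.strand = TRUE)) > 0
        !(inScope & ov)
      },
      require_region = {
        ov <- suppressWarnings(GenomicRanges::countOverlaps(
          calls(x), r$region, ignore.strand = TRUE)) > 0
        !inScope | ov
      })
    x <- x[which(keep)]
    log <- rbind(log, data.frame(stage = paste0("rule:", r$name),
                                 n_in = nin, n_out = length(x)))
  }
  x@provenance$rule_log <- log
  x
}

#' Merge concordant calls across callers
#'
#' Structural and CNV calls of the same type from \emph{different} callers
#' whose reciprocal overlap is at least \code{minReciprocal} are merged
#' (single linkage) into one call carrying the union of caller provenance;
#' the merged interval is that of the highest-quality member (ties broken
#' by caller priority order, then by leftmost start). Small variants merge
#' only on exact contig/position/REF/ALT identity. Merging the merged
#' output again changes nothing (idempotence).
#'
#' @param callsets A list of \code{\linkS4class{CallSet}}s (or a single
#'   one).
#' @param minReciprocal Reciprocal-overlap threshold, default 0.5.
#' @param callerOrder Caller ids in tie-breaking priority order; defaults
#'   to the order the callsets are given in.
#' @return A merged \code{CallSet} (class \code{"mixed"}, caller
#'   \code{"merged"}) with \code{callers} and \code{support} metadata.
#' @export
mergeConcordantCalls <- function(callsets, minReciprocal = 0.5,
                                 callerOrder = NULL) {
  if (methods::is(callsets, "CallSet")) callsets <- list(callsets)
  if (!length(callsets)) stop("need at least one CallSet")
  if (is.null(callerOrder))
    callerOrder <- unique(vapply(callsets, callerId, character(1)))
  parts <- lapply(callsets, function(cs) {
    gr <- calls(cs)
    mc <- S4Vectors::mcols(gr)
    if (callClass(cs) != "mixed") {
      mc$class <- rep(callClass(cs), length(gr))
      mc$typelab <- .callTypes(cs)
    }
    if (!("callers" %in% colnames(mc)) || all(is.na(mc$callers)))
      mc$callers <- rep(callerId(cs), length(gr))
    if (!("quality" %in% colnames(mc)))
      mc$quality <- rep(NA_real_, length(gr))
    S4Vectors::mcols(gr) <- mc
    gr
  })
  gr <- .bindGRanges(parts)
  n <- length(gr)
  if (n == 0L)
    return(CallSet(gr, "merged", "mixed"))
  mc <- S4Vectors::mcols(gr)
  ## union-find over merge edges
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]
                             i <- parent[i] }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[rb] <<- ra
  }
  isSmall <- mc$class == "smallvariant"
  if (any(isSmall)) {
    idx <- which(isSmall)
    key <- paste(as.character(GenomeInfoDb::seqnames(gr))[idx],
                 BiocGenerics::start(gr)[idx], mc$ref[idx], mc$alt[idx])
    for (grp in split(idx, key))
      if (length(grp) > 1L)
        for (j in grp[-1L]) unite(grp[1L], j)
  }
  isBnd <- !isSmall & mc$typelab == "BND"
  if (any(isBnd)) {
    idx <- which(isBnd)
    key <- paste(as.character(GenomeInfoDb::seqnames(gr))[idx],
                 BiocGenerics::start(gr)[idx], mc$mate_contig[idx],
                 mc$mate_pos[idx])
    for (grp in split(idx, key))
      if (length(grp) > 1L)
        for (j in grp[-1L]) unite(grp[1L], j)
  }
  spanIdx <- which(!isSmall & mc$typelab != "BND")
  if (length(spanIdx)) {
    for (grp in split(spanIdx,
                      paste(mc$class[spanIdx], mc$typelab[spanIdx]))) {
      if (length(grp) < 2L) next
      sub <- gr[grp]
      hits <- GenomicRanges::findOverlaps(sub, sub, ignore.strand = TRUE)
      hits <- hits[S4Vectors::queryHits(hits) <
                     S4Vectors::subjectHits(hits)]
      if (!length(hits)) next
      ro <- .reciprocalOverlapHits(sub, hits)
      qh <- grp[S4Vectors::queryHits(hits)]
      sh <- grp[S4Vectors::subjectHits(hits)]
      ok <- ro >= minReciprocal &
        .firstCaller(mc$callers[qh]) != .firstCaller(mc$callers[sh])
      for (e in which(ok)) unite(qh[e], sh[e])
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  reps <- integer(0); callersOut <- character(0)
  for (grp in split(seq_len(n), roots)) {
    allCallers <- sort(unique(unlist(strsplit(mc$callers[grp], ","))))
    q <- mc$quality[grp]; q[is.na(q)] <- -Inf
    pri <- match(.firstCaller(mc$callers[grp]), callerOrder)
    pri[is.na(pri)] <- length(callerOrder) + 1L
    ord <- order(-q, pri, BiocGenerics::start(gr)[grp])
    reps <- c(reps, grp[ord[1L]])
    callersOut <- c(callersOut, paste(allCallers, collapse = ","))
  }
  ord <- order(reps)
  out <- gr[reps[ord]]
  S4Vectors::mcols(out)$callers <- callersOut[ord]
  S4Vectors::mcols(out)$support <- vapply(
    strsplit(callersOut[ord], ","), length, integer(1))
  CallSet(out, "merged", "mixed",
          list(merged_from = callerOrder,
               min_reciprocal = minReciprocal))
}

.firstCaller <- function(x) vapply(strsplit(x, ","), `[`, character(1), 1L)

#' Run the full triage cascade
#'
#' Executes restriction by caller, depth-segment filtering, cross-caller
#' merging, the mechanistic gene-impact filter, phenotype-gene
#' intersection and the ordered logic rules, recording every stage in a
#' \code{\linkS4class{FunnelReport}}.
#'
#' @param callsets List of per-caller \code{\linkS4class{CallSet}}s.
#' @param panel A \code{\linkS4class{GenePanel}}.
#' @param policy A \code{\linkS4class{RoutingPolicy}}.
#' @param logicRules Ordered rule list (see
#'   \code{\link{validateLogicRules}}).
#' @param impactRules Keep/drop matrix (see
#'   \code{\link{defaultImpactRules}}).
#' @param nearSpliceBp See \code{\link{classifyGeneImpact}}.
#' @param minReciprocal Cross-caller merge threshold.
#' @return \code{list(calls = CallSet, funnel = FunnelReport)}.
#' @export
runTriage <- function(callsets, panel, policy = routingPolicy(),
                      logicRules = list(),
                      impactRules = defaultImpactRules(),
                      nearSpliceBp = 100, minReciprocal = 0.5) {
  logicRules <- validateLogicRules(logicRules)
  stages <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer())
  total <- function(sets) sum(vapply(sets, length, integer(1)))

  nin <- total(callsets)
  callsets <- lapply(callsets, restrictByCaller, policy = policy)
  stages <- rbind(stages, data.frame(stage = "restrict_by_caller",
                                     n_in = nin, n_out = total(callsets)))

  nin <- total(callsets)
  callsets <- lapply(callsets, function(cs) {
    role <- policy@callerRoles[callerId(cs)]
    if (callClass(cs) == "cnv" &&
        role %in% c("depth_autosome", "depth_sexchrom"))
      filterDepthSegments(cs, policy) else cs
  })
  stages <- rbind(stages, data.frame(stage = "filter_depth_segments",
                                     n_in = nin, n_out = total(callsets)))

  nin <- total(callsets)
  merged <- mergeConcordantCalls(callsets, minReciprocal = minReciprocal,
                                 callerOrder = policy@callerOrder)
  stages <- rbind(stages, data.frame(stage = "merge_concordant_calls",
                                     n_in = nin, n_out = length(merged)))

  nin <- length(merged)
  merged <- mechanisticFilter(merged, panel, rules = impactRules,
                              nearSpliceBp = nearSpliceBp)
  stages <- rbind(stages, data.frame(stage = "mechanistic_filter",
                                     n_in = nin, n_out = length(merged)))

  nin <- length(merged)
  merged <- intersectPhenotypeGenes(merged, panel)
  stages <- rbind(stages, data.frame(stage = "intersect_phenotype_genes",
                                     n_in = nin, n_out = length(merged)))

  merged <- applyLogicRules(merged, logicRules)
  rl <- merged@provenance$rule_log
  if (!is.null(rl) && nrow(rl)) stages <- rbind(stages, rl)

  list(calls = merged, funnel = methods::new("FunnelReport",
                                             stages = stages))
}

#' @rdname FunnelReport-class
#' @param x A \code{\linkS4class{FunnelReport}}.
#' @export
setMethod("funnelStages", "FunnelReport", function(x) x@stages)

#' FunnelReport accessors
#'
#' @name FunnelReport-class
#' @aliases funnelStages
NULL

setMethod("show", "FunnelReport", function(object) {
  cat("Triage funnel:\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-28s %8d -> %8d\n", st$stage[i], st$n_in[i],
                st$n_out[i]))
  if (nrow(st)) cat("  reviewed calls:", st$n_out[nrow(st)], "\n")
  invisible(NULL)
})

#' Write a funnel report as TSV
#' @param x A \code{\linkS4class{FunnelReport}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFunnelReport <- function(x, path) {
  utils::write.table(funnelStages(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
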