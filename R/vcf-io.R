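## VCF ingest and emission through the caller-dialect registry.
##
## Reading is done with VariantAnnotation (multiallelic rows are split with
## expand()); the dialect map then decides how INFO/FORMAT fields become
## CallSet metadata. Writing emits the requested dialect directly — the
## package must be able to produce *foreign* caller dialects for fixture
## generation, and the unified output dialect is just one more registry
## entry. Span convention for symbolic records: POS = first affected base,
## INFO END = POS + length, so the internal interval is [POS, END - 1].

.parseError <- function(path, msg, line = NA_integer_) {
  stop(structure(class = c("lrtriage_parse_error", "error", "condition"),
                 list(message = paste0("VCF parse error in ", path,
                                       if (!is.na(line))
                                         paste0(" at line ", line),
                                       ": ", msg),
                      call = NULL, path = path, line = line)))
}

## Cheap structural pre-scan so malformed records are reported with their
## line number (readVcf's own messages often lack one).
.scanVcfStructure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    .parseError(path, "missing ##fileformat header", 1L)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      .parseError(path, paste0("record has ", length(f),
                               " field(s), expected >= 8"), i)
    if (is.na(suppressWarnings(as.integer(f[2L]))))
      .parseError(path, paste0("non-numeric POS '", f[2L], "'"), i)
  }
  invisible(length(body))
}

.gtToGenotype <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("unknown", length(gt))
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt == "1/1"] <- "hom"
  out[gt == "1"] <- "hemi"
  out
}

.genotypeToGT <- function(g) {
  unname(c(het = "0/1", hom = "1/1", hemi = "1", unknown = "./.")[g])
}

.classifySmall <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
    ifelse(nchar(ref) < nchar(alt) & substr(alt, 1L, nchar(ref)) == ref,
           "INS",
      ifelse(nchar(alt) < nchar(ref) & substr(ref, 1L, nchar(alt)) == alt,
             "DEL", "DELINS")))
}

.infoScalar <- function(info, key, i, default = NA) {
  if (is.null(key) || !(key %in% colnames(info))) return(default)
  v <- info[[key]][i]
  if (methods::is(v, "List") || is.list(v)) {
    v <- v[[1L]]
    if (!length(v)) return(default)
    v <- v[1L]
  }
  if (is.na(v)) default else v
}

.parseBndMate <- function(alt) {
  m <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                               alt, perl = TRUE))[[1L]]
  if (length(m) != 3L) return(NULL)
  list(contig = m[2L], pos = as.integer(m[3L]))
}

#' Read a caller VCF into a CallSet
#'
#' Parses a VCF (v4.x) in the given caller's dialect. Multiallelic rows
#' are split into one record per ALT allele; symbolic ALTs become SV or
#' CNV records with lengths taken from the dialect's SVLEN/END keys;
#' breakend ALT notation becomes BND records with the mate parsed.
#' Records the dialect cannot interpret (unknown symbolic ALT, missing
#' required annotations) are quarantined into the ingest report
#' (\code{provenance(x)$quarantined}) rather than aborting the run.
#'
#' @param path Path to a VCF file.
#' @param caller Registered caller id; decides the default dialect.
#' @param dialect Dialect list, by default \code{callerDialect(caller)}.
#' @param genome Named contig-length vector for name normalization.
#' @return A \code{\linkS4class{CallSet}}.
#' @seealso \code{\link{writeCallVcf}}, \code{\link{callerDialect}}
#' @export
readCallerVcf <- function(path, caller = "unified",
                          dialect = callerDialect(caller),
                          genome = genomeContigs()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  .scanVcfStructure(path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) .parseError(path, conditionMessage(e)))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  quarantined <- data.frame(record = integer(), reason = character())
  quarantine <- function(i, reason) {
    quarantined <<- rbind(quarantined,
                          data.frame(record = i, reason = reason))
  }
  emptySet <- function(cls) {
    gr <- GenomicRanges::GRanges()
    mc <- switch(cls,
      smallvariant = S4Vectors::DataFrame(ref = character(),
        alt = character(), vtype = character(), genotype = character(),
        vaf = numeric(), quality = numeric(), size_change = integer()),
      sv = S4Vectors::DataFrame(svtype = character(), svlen = integer(),
        quality = numeric(), generic_flag = logical(),
        mate_contig = character(), mate_pos = integer(),
        support_reads = integer()),
      cnv = S4Vectors::DataFrame(copy_state = character(), q0 = numeric(),
        p_n = numeric(), p_value = numeric(), bin_size = integer(),
        quality = numeric()),
      mixed = S4Vectors::DataFrame(class = character(),
        typelab = character()))
    S4Vectors::mcols(gr) <- mc
    gr
  }
  mkProv <- function() list(path = path, dialect = dialect$caller,
                            ingested = format(Sys.time(), tz = "UTC"),
                            quarantined = quarantined)
  if (n == 0L)
    return(CallSet(emptySet(dialect$class), dialect$caller, dialect$class,
                   mkProv()))

  contig <- normalizeContig(as.character(GenomeInfoDb::seqnames(rr)),
                            genome)
  pos <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- as.character(VariantAnnotation::alt(vcf))
  qual <- S4Vectors::mcols(rr)$QUAL
  inf <- VariantAnnotation::info(vcf)
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT[, 1L],
                 error = function(e) rep(NA_character_, n))
  symbolic <- grepl("^<.+>$", alts)
  breakend <- grepl("[][]", alts)

  recClass <- function(i) {
    if (dialect$class != "mixed") return(dialect$class)
    cl <- .infoScalar(inf, "CLASS", i, NA_character_)
    if (!is.na(cl)) return(cl)
    if (symbolic[i] || breakend[i]) "sv" else "smallvariant"
  }

  small <- list(); svs <- list(); cnvs <- list()
  for (i in seq_len(n)) {
    cls <- recClass(i)
    if (identical(cls, "smallvariant")) {
      if (symbolic[i] || breakend[i]) {
        quarantine(i, paste0("symbolic/breakend ALT '", alts[i],
                             "' in a small-variant dialect"))
        next
      }
      if (grepl("[^ACGTN]", refs[i]) || grepl("[^ACGTN]", alts[i])) {
        quarantine(i, "non-ACGTN allele"); next
      }
      vaf <- NA_real_
      if (!is.null(dialect$vaf_key))
        vaf <- as.numeric(.infoScalar(inf, dialect$vaf_key, i))
      if (is.na(vaf) && !is.null(dialect$ad_format)) {
        ad <- tryCatch(VariantAnnotation::geno(vcf)[[dialect$ad_format]],
                       error = function(e) NULL)
        if (!is.null(ad)) {
          depths <- ad[i, 1L, ]
          tot <- sum(depths, na.rm = TRUE)
          if (tot > 0) vaf <- depths[length(depths)] / tot
        }
      }
      small[[length(small) + 1L]] <- data.frame(
        contig = contig[i], start = pos[i],
        end = pos[i] + nchar(refs[i]) - 1L,
        ref = refs[i], alt = alts[i],
        vtype = .classifySmall(refs[i], alts[i]),
        genotype = .gtToGenotype(gt[i]), vaf = vaf,
        quality = ifelse(is.na(qual[i]), NA_real_, qual[i]),
        size_change = nchar(alts[i]) - nchar(refs[i]))
    } else if (identical(cls, "sv")) {
      if (breakend[i]) {
        mate <- .parseBndMate(alts[i])
        if (is.null(mate)) { quarantine(i, "unparseable breakend ALT"); next }
        stype <- .infoScalar(inf, dialect$svtype_key, i, "BND")
        svs[[length(svs) + 1L]] <- data.frame(
          contig = contig[i], start = pos[i], end = pos[i],
          svtype = "BND", svlen = NA_integer_,
          quality = ifelse(is.na(qual[i]), NA_real_, qual[i]),
          generic_flag = isTRUE(dialect$generic_bnd) &&
            stype %in% c("BND", "BP", "breakpoint"),
          mate_contig = normalizeContig(mate$contig, genome),
          mate_pos = mate$pos,
          support_reads = as.integer(.infoScalar(inf, dialect$support_key,
                                                 i)))
        next
      }
      stype <- .infoScalar(inf, dialect$svtype_key, i, NA_character_)
      if (is.na(stype) && symbolic[i]) stype <- gsub("[<>]", "", alts[i])
      if (!(stype %in% c("DEL", "DUP", "INS", "INV"))) {
        quarantine(i, paste0("unknown symbolic ALT/SVTYPE '",
                             if (is.na(stype)) alts[i] else stype, "'"))
        next
      }
      svlen <- abs(as.numeric(.infoScalar(inf, dialect$svlen_key, i)))
      if (is.na(svlen)) {
        endv <- as.numeric(.infoScalar(inf, dialect$end_key, i))
        if (!is.na(endv) && stype != "INS") svlen <- endv - pos[i]
      }
      if (is.na(svlen) || svlen < 1) {
        quarantine(i, "SV record without a usable SVLEN/END"); next
      }
      w <- if (stype == "INS") 1L else as.integer(svlen)
      svs[[length(svs) + 1L]] <- data.frame(
        contig = contig[i], start = pos[i], end = pos[i] + w - 1L,
        svtype = stype, svlen = as.integer(svlen),
        quality = ifelse(is.na(qual[i]), NA_real_, qual[i]),
        generic_flag = FALSE, mate_contig = NA_character_,
        mate_pos = NA_integer_,
        support_reads = as.integer(.infoScalar(inf, dialect$support_key,
                                               i)))
    } else if (identical(cls, "cnv")) {
      stype <- .infoScalar(inf, dialect$svtype_key, i, NA_character_)
      if (is.na(stype) && symbolic[i]) stype <- gsub("[<>]", "", alts[i])
      state <- switch(as.character(stype), DEL = "loss", DUP = "gain",
                      deletion = "loss", duplication = "gain", NA)
      if (is.na(state)) { quarantine(i, "CNV record without DEL/DUP type")
                          next }
      endv <- as.numeric(.infoScalar(inf, dialect$end_key, i))
      if (is.na(endv)) { quarantine(i, "CNV record without END"); next }
      bin <- as.integer(.infoScalar(inf, dialect$binsize_key, i, 1000L))
      cnvs[[length(cnvs) + 1L]] <- data.frame(
        contig = contig[i], start = pos[i], end = as.integer(endv) - 1L,
        copy_state = state,
        q0 = as.numeric(.infoScalar(inf, dialect$q0_key, i)),
        p_n = as.numeric(.infoScalar(inf, dialect$pn_key, i)),
        p_value = as.numeric(.infoScalar(inf, dialect$pval_key, i)),
        bin_size = bin,
        quality = ifelse(is.na(qual[i]), NA_real_, qual[i]))
    } else quarantine(i, paste0("unknown record class '", cls, "'"))
  }

  toGr <- function(rows, cols) {
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$contig,
      IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[cols])
    gr
  }
  smallCols <- c("ref", "alt", "vtype", "genotype", "vaf", "quality",
                 "size_change")
  svCols <- c("svtype", "svlen", "quality", "generic_flag", "mate_contig",
              "mate_pos", "support_reads")
  cnvCols <- c("copy_state", "q0", "p_n", "p_value", "bin_size", "quality")

  if (dialect$class == "mixed") {
    parts <- list()
    if (length(small)) {
      gr <- toGr(small, smallCols); S4Vectors::mcols(gr)$class <-
        "smallvariant"
      S4Vectors::mcols(gr)$typelab <- S4Vectors::mcols(gr)$vtype
      parts <- c(parts, list(gr))
    }
    if (length(svs)) {
      gr <- toGr(svs, svCols); S4Vectors::mcols(gr)$class <- "sv"
      S4Vectors::mcols(gr)$typelab <- S4Vectors::mcols(gr)$svtype
      parts <- c(parts, list(gr))
    }
    if (length(cnvs)) {
      gr <- toGr(cnvs, cnvCols); S4Vectors::mcols(gr)$class <- "cnv"
      S4Vectors::mcols(gr)$typelab <- S4Vectors::mcols(gr)$copy_state
      parts <- c(parts, list(gr))
    }
    gr <- if (length(parts)) .bindGRanges(parts) else emptySet("mixed")
    return(CallSet(gr, dialect$caller, "mixed", mkProv()))
  }
  gr <- switch(dialect$class,
    smallvariant = if (length(small)) toGr(small, smallCols) else
      emptySet("smallvariant"),
    sv = if (length(svs)) toGr(svs, svCols) else emptySet("sv"),
    cnv = if (length(cnvs)) toGr(cnvs, cnvCols) else emptySet("cnv"))
  CallSet(gr, dialect$caller, dialect$class, mkProv())
}

## rbind GRanges with differing mcols by filling missing columns with NA.
.bindGRanges <- function(parts) {
  allCols <- unique(unlist(lapply(parts, function(g)
    colnames(S4Vectors::mcols(g)))))
  levels <- unique(unlist(lapply(parts, GenomeInfoDb::seqlevels)))
  parts <- lapply(parts, function(g) {
    mc <- S4Vectors::mcols(g)
    for (col in setdiff(allCols, colnames(mc)))
      mc[[col]] <- rep(NA, length(g))
    S4Vectors::mcols(g) <- mc[allCols]
    GenomeInfoDb::seqlevels(g) <- levels
    g
  })
  suppressWarnings(do.call(c, parts))
}

.fmtInfoNum <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, digits = 15, scientific = FALSE,
                                         trim = TRUE))
}

#' Write a CallSet as VCF in a registered dialect
#'
#' Emits a sorted, header-complete VCF. Reading the file back with the
#' same dialect reproduces the records (round-trip property). Span records
#' are written with \code{INFO END = POS + length}.
#'
#' @param x A \code{\linkS4class{CallSet}}.
#' @param path Output path.
#' @param dialect Dialect list; defaults to the unified output dialect,
#'   which carries \code{CLASS}, \code{CALLER}, \code{SUPPORT} and
#'   \code{GENES} provenance keys.
#' @param genome Named contig-length vector; records on contigs outside it
#'   are an error (they cannot be sorted).
#' @param sample Sample name for the genotype column.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readCallerVcf}}
#' @export
writeCallVcf <- function(x, path, dialect = callerDialect("unified"),
                         genome = genomeContigs(), sample = "SAMPLE") {
  gr <- calls(x)
  contigs <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- setdiff(unique(contigs), names(genome))
  if (length(bad))
    stop("cannot sort records on unknown contig(s): ",
         paste(bad, collapse = ", "))
  mc <- S4Vectors::mcols(gr)
  cls <- if (x@callClass == "mixed") as.character(mc$class) else
    rep(x@callClass, length(gr))

  ord <- order(match(contigs, names(genome)), BiocGenerics::start(gr))
  gr <- gr[ord]; mc <- mc[ord, , drop = FALSE]; cls <- cls[ord]
  contigs <- contigs[ord]

  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=lrtriage-", dialect$caller),
           paste0("##contig=<ID=", names(genome), ",length=",
                  format(genome, scientific = FALSE, trim = TRUE), ">"))
  infoDef <- function(id, num, type, desc)
    paste0("##INFO=<ID=", id, ",Number=", num, ",Type=", type,
           ",Description=\"", desc, "\">")
  for (key in c("svtype_key", "svlen_key", "end_key", "support_key",
                "vaf_key", "q0_key", "pn_key", "pval_key", "binsize_key")) {
    k <- dialect[[key]]
    if (is.null(k)) next
    hdr <- c(hdr, switch(key,
      svtype_key = infoDef(k, 1, "String", "SV type"),
      svlen_key = infoDef(k, 1, "Integer", "SV length"),
      end_key = infoDef(k, 1, "Integer", "End position (POS + length)"),
      support_key = infoDef(k, 1, "Integer", "Supporting reads"),
      vaf_key = infoDef(k, 1, "Float", "Variant allele fraction"),
      q0_key = infoDef(k, 1, "Float", "Low mapping-quality read fraction"),
      pn_key = infoDef(k, 1, "Float", "Reference N fraction"),
      pval_key = infoDef(k, 1, "Float", "Depth deviation p-value"),
      binsize_key = infoDef(k, 1, "Integer", "Depth bin size")))
  }
  if (dialect$class == "mixed")
    hdr <- c(hdr, infoDef("CLASS", 1, "String", "Record class"),
             infoDef("CALLER", ".", "String", "Source caller(s)"),
             infoDef("GENES", ".", "String", "Annotated gene symbols"))
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))

  lines <- character(length(gr))
  for (i in seq_along(gr)) {
    ci <- cls[i]
    posi <- BiocGenerics::start(gr)[i]
    info <- character()
    if (dialect$class == "mixed") info <- c(info, paste0("CLASS=", ci))
    qv <- if ("quality" %in% colnames(mc) && !is.na(mc$quality[i]))
      format(mc$quality[i], digits = 10, scientific = FALSE, trim = TRUE)
      else "."
    if (ci == "smallvariant") {
      refi <- as.character(mc$ref[i]); alti <- as.character(mc$alt[i])
      gti <- .genotypeToGT(as.character(mc$genotype[i]))
      if (!is.null(dialect$vaf_key) && !is.na(mc$vaf[i]))
        info <- c(info, paste0(dialect$vaf_key, "=",
                               .fmtInfoNum(mc$vaf[i])))
    } else if (ci == "sv") {
      stype <- as.character(mc$svtype[i])
      refi <- "N"
      if (stype == "BND") {
        alti <- paste0("N[", mc$mate_contig[i], ":", mc$mate_pos[i], "[")
        info <- c(info, paste0(dialect$svtype_key, "=BND"))
      } else {
        alti <- paste0("<", stype, ">")
        len <- as.integer(mc$svlen[i])
        slen <- if (stype == "DEL") -len else len
        info <- c(info, paste0(dialect$svtype_key, "=", stype))
        if (!is.null(dialect$svlen_key))
          info <- c(info, paste0(dialect$svlen_key, "=", slen))
        if (!is.null(dialect$end_key))
          info <- c(info, paste0(dialect$end_key, "=", posi + len))
      }
      if (!is.null(dialect$support_key) &&
          "support_reads" %in% colnames(mc) &&
          !is.na(mc$support_reads[i]))
        info <- c(info, paste0(dialect$support_key, "=",
                               mc$support_reads[i]))
      gti <- "0/1"
    } else if (ci == "cnv") {
      state <- as.character(mc$copy_state[i])
      refi <- "N"
      alti <- if (state == "loss") "<DEL>" else "<DUP>"
      w <- BiocGenerics::width(gr)[i]
      info <- c(info,
        paste0(dialect$svtype_key, "=", if (state == "loss") "DEL" else
          "DUP"),
        paste0(dialect$end_key, "=", posi + w))
      for (pair in list(c("q0_key", "q0"), c("pn_key", "p_n"),
                        c("pval_key", "p_value"))) {
        k <- dialect[[pair[1L]]]
        if (!is.null(k) && pair[2L] %in% colnames(mc) &&
            !is.na(mc[[pair[2L]]][i]))
          info <- c(info, paste0(k, "=", .fmtInfoNum(mc[[pair[2L]]][i])))
      }
      if (!is.null(dialect$binsize_key))
        info <- c(info, paste0(dialect$binsize_key, "=", mc$bin_size[i]))
      gti <- "0/1"
    } else stop("cannot write record of class ", ci)
    if (dialect$class == "mixed") {
      srcs <- if ("callers" %in% colnames(mc) && !is.na(mc$callers[i]))
        mc$callers[i] else x@caller
      info <- c(info, paste0("CALLER=", srcs))
      if ("genes" %in% colnames(mc) && !is.na(mc$genes[i]))
        info <- c(info, paste0("GENES=", mc$genes[i]))
    }
    lines[i] <- paste(contigs[i], posi, ".", refi, alti, qv, "PASS",
                      if (length(info)) paste(info, collapse = ";") else
                        ".",
                      "GT", gti, sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
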