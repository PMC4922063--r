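#' @import methods
#' @importFrom stats pchisq fisher.test rnbinom rpois rbinom runif median
#'   setNames quantile cor
#' @importFrom utils read.table write.table head combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData assayNames
#' @importFrom S4Vectors DataFrame
NULL

GENO_CODES <- c(0L, 1L, 2L)

#' GenotypeMatrix: samples x markers allele-count codes with a marker map
#'
#' Genotype calls are integer copies of alleleB (0, 1, 2); missing calls are
#' `NA`. Rows are samples, columns markers. The marker map records id,
#' chromosome, 1-based position and the two alleles; positions must be
#' strictly increasing within a chromosome.
#'
#' @slot calls integer matrix, samples x markers, values 0/1/2/NA.
#' @slot markers data.frame with columns id, chrom, pos, alleleA, alleleB.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", markers = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@markers
  need <- c("id", "chrom", "pos", "alleleA", "alleleB")
  if (!all(need %in% names(m)))
    return(paste("marker map must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@calls) != nrow(m))
    return("ncol(calls) must equal nrow(markers)")
  v <- object@calls
  if (!all(v[!is.na(v)] %in% GENO_CODES))
    return("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (any(diff(p) <= 0))
      return(sprintf("marker positions not strictly increasing on chromosome %s", ch))
  }
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (samples x markers) of 0/1/2/NA alleleB counts.
#' @param markers data.frame with columns id, chrom, pos, alleleA, alleleB.
#' @param sample_ids optional character vector of row names.
#' @return A [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(calls, markers, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  rownames(calls) <- sample_ids
  colnames(calls) <- markers$id
  markers$chrom <- as.character(markers$chrom)
  new("GenotypeMatrix", calls = calls, markers = markers)
}

#' @describeIn genotypeMatrix sample identifiers
#' @param x a GenotypeMatrix
#' @export
sampleIDs <- function(x) rownames(x@calls)

#' @describeIn genotypeMatrix the marker map data.frame
#' @export
markerInfo <- function(x) x@markers

#' @describeIn genotypeMatrix the integer call matrix (samples x markers)
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn genotypeMatrix number of markers
#' @export
nMarkers <- function(x) ncol(x@calls)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers on chromosome(s) %s\n",
    nrow(object@calls), ncol(object@calls),
    paste(unique(object@markers$chrom), collapse = ", ")))
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
})

## ---------------------------------------------------------------------------

#' VariantSet: biallelic variants with per-sample genotype codes
#'
#' Each row of `info` is one biallelic variant (chrom, 1-based pos, ref, alt,
#' derived class SNP/INS/DEL, optional id). `calls` holds alt-allele count
#' codes (0/1/2, NA = missing), one row per variant, one column per sample.
#' An optional `groups` factor assigns samples to case/control/panel strata.
#'
#' @slot info data.frame: chrom, pos, id, ref, alt, vclass.
#' @slot calls integer matrix, variants x samples.
#' @slot samples character vector of sample names.
#' @slot groups factor over levels case/control/panel (or length 0).
#' @export
setClass("VariantSet",
  representation(info = "data.frame", calls = "matrix",
                 samples = "character", groups = "factor"))

#' Derive the variant class from its alleles
#'
#' @param ref,alt allele strings (uppercase A/C/G/T, anchored-base indels).
#' @return "SNP", "INS" or "DEL".
#' @export
variantClass <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- character(length(lr))
  out[lr == 1L & la == 1L] <- "SNP"
  out[la > lr] <- "INS"
  out[lr > la] <- "DEL"
  bad <- out == ""
  if (any(bad))
    stop("unsupported allele pair (equal-length multi-base substitution): ",
         ref[bad][1], ">", alt[bad][1])
  out
}

setValidity("VariantSet", function(object) {
  info <- object@info
  need <- c("chrom", "pos", "id", "ref", "alt", "vclass")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(info) == 0) return(TRUE)
  if (any(info$pos < 1)) return("positions must be >= 1")
  if (any(info$ref == info$alt)) return("ref must differ from alt")
  if (!all(grepl("^[ACGT]+$", info$ref)) || !all(grepl("^[ACGT]+$", info$alt)))
    return("alleles must be non-empty uppercase A/C/G/T")
  expect <- variantClass(info$ref, info$alt)
  if (!all(info$vclass == expect)) return("vclass inconsistent with alleles")
  if (nrow(object@calls) != nrow(info)) return("nrow(calls) != nrow(info)")
  if (ncol(object@calls) != length(object@samples))
    return("ncol(calls) != number of samples")
  v <- object@calls
  if (!all(v[!is.na(v)] %in% GENO_CODES)) return("codes must be 0/1/2/NA")
  if (length(object@groups) &&
      length(object@groups) != length(object@samples))
    return("groups must match samples in length")
  TRUE
})

#' Construct a VariantSet
#'
#' @param info data.frame with chrom, pos, ref, alt and optional id;
#'   vclass is derived.
#' @param calls integer matrix of alt-allele counts, variants x samples.
#' @param samples character sample names.
#' @param groups optional factor ("case", "control", "panel") per sample.
#' @return A [VariantSet-class].
#' @export
variantSet <- function(info, calls, samples = colnames(calls), groups = factor()) {
  info <- as.data.frame(info)
  if (is.null(info$id)) info$id <- paste0(info$chrom, ":", info$pos)
  info$chrom <- as.character(info$chrom)
  info$ref <- toupper(info$ref); info$alt <- toupper(info$alt)
  info$vclass <- variantClass(info$ref, info$alt)
  info <- info[c("chrom", "pos", "id", "ref", "alt", "vclass")]
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  colnames(calls) <- samples
  if (length(groups)) groups <- factor(as.character(groups),
    levels = c("case", "control", "panel"))
  new("VariantSet", info = info, calls = calls,
      samples = samples, groups = groups)
}

#' @describeIn variantSet variant table (chrom, pos, id, ref, alt, vclass)
#' @param x a VariantSet
#' @export
variantInfo <- function(x) x@info

#' @describeIn variantSet integer call matrix (variants x samples)
#' @export
variantCalls <- function(x) x@calls

#' @describeIn variantSet sample grouping factor
#' @export
variantGroups <- function(x) x@groups

#' @describeIn variantSet calls restricted to one group
#' @param group one of "case", "control", "panel"
#' @export
groupCalls <- function(x, group) {
  stopifnot(length(x@groups) > 0)
  x@calls[, x@groups == group, drop = FALSE]
}

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet: %d variants x %d samples\n",
    nrow(object@info), length(object@samples)))
  if (nrow(object@info))
    print(table(object@info$vclass))
  if (length(object@groups)) print(table(object@groups))
})

## ---------------------------------------------------------------------------

#' CandidateInterval: a recombinant-bounded candidate region
#'
#' 1-based inclusive interval; `lengthKb` is floor((end - start)/1000),
#' the convention under which boundaries 56,170,062 and 56,933,573 give a
#' 763 kb interval. `open` flags an interval truncated by a chromosome end
#' rather than bounded by an informative recombinant on that side.
#'
#' @slot chrom character chromosome name.
#' @slot start,end 1-based inclusive boundary positions (bp).
#' @slot open logical: TRUE when a boundary is a terminal marker, not a
#'   recombinant.
#' @export
setClass("CandidateInterval",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 open = "logical"))

setValidity("CandidateInterval", function(object) {
  if (object@start >= object@end) return("start must be < end")
  if (object@start < 1) return("start must be >= 1")
  TRUE
})

#' Construct a CandidateInterval
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive boundaries, start < end.
#' @param open logical, interval not closed by recombinants.
#' @return A [CandidateInterval-class].
#' @export
candidateInterval <- function(chrom, start, end, open = FALSE) {
  new("CandidateInterval", chrom = as.character(chrom),
      start = as.numeric(start), end = as.numeric(end), open = open)
}

#' @describeIn candidateInterval interval length in whole kb (truncated)
#' @param x a CandidateInterval
#' @export
lengthKb <- function(x) floor((x@end - x@start) / 1000)

#' @describeIn candidateInterval start position (1-based)
#' @export
intervalStart <- function(x) x@start

#' @describeIn candidateInterval end position (1-based)
#' @export
intervalEnd <- function(x) x@end

#' @describeIn candidateInterval chromosome name
#' @export
intervalChrom <- function(x) x@chrom

#' @describeIn candidateInterval TRUE when a boundary is a terminal marker
#' @export
isOpenInterval <- function(x) x@open

setMethod("show", "CandidateInterval", function(object) {
  cat(sprintf("CandidateInterval %s:%s-%s (%d kb)%s\n", object@chrom,
    format(object@start, big.mark = ","), format(object@end, big.mark = ","),
    lengthKb(object), if (object@open) " [open]" else ""))
})

## ---------------------------------------------------------------------------

#' GeneModel: a multi-promoter gene for variant annotation
#'
#' Exons are 1-based inclusive genomic intervals, ordered and
#' non-overlapping. The CDS span must lie within the exon union. The
#' promoter window extends `promoterLength` bp upstream (5' on the gene's
#' strand) of the TSS. Isoform-specific first exons are declared by label so
#' the expression module can separate isoform loss from gene-level change.
#'
#' @slot gene gene identifier.
#' @slot strand "+" or "-".
#' @slot tss transcription start site position (1-based).
#' @slot exons data.frame: exon_id, start, end.
#' @slot cdsStart,cdsEnd genomic CDS boundaries (1-based inclusive).
#' @slot promoterLength promoter window length upstream of the TSS (bp).
#' @slot isoformFirstExons named character: isoform -> exon_id.
#' @export
setClass("GeneModel",
  representation(gene = "character", strand = "character", tss = "numeric",
    exons = "data.frame", cdsStart = "numeric", cdsEnd = "numeric",
    promoterLength = "numeric", isoformFirstExons = "character"))

setValidity("GeneModel", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  ex <- object@exons
  if (!all(c("exon_id", "start", "end") %in% names(ex)))
    return("exons needs columns exon_id, start, end")
  if (any(ex$start > ex$end)) return("exon start > end")
  o <- order(ex$start)
  if (!identical(o, seq_len(nrow(ex)))) return("exons must be ordered by start")
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
    return("exons overlap")
  inExon <- function(p) any(p >= ex$start & p <= ex$end)
  if (!inExon(object@cdsStart) || !inExon(object@cdsEnd))
    return("CDS boundaries must fall in exons")
  if (object@cdsStart > object@cdsEnd) return("cdsStart > cdsEnd")
  if (length(object@isoformFirstExons) &&
      !all(object@isoformFirstExons %in% ex$exon_id))
    return("isoform first exons must be declared exon ids")
  TRUE
})

#' Construct a GeneModel
#' @param gene gene id.
#' @param strand "+" or "-".
#' @param tss TSS position (1-based).
#' @param exons data.frame with exon_id, start, end (ordered, non-overlapping).
#' @param cds_start,cds_end genomic CDS span.
#' @param promoter_length promoter window upstream of TSS in bp (default 10000).
#' @param isoform_first_exons named character vector, isoform -> exon_id.
#' @return A [GeneModel-class].
#' @export
geneModel <- function(gene, strand, tss, exons, cds_start, cds_end,
                      promoter_length = 10000,
                      isoform_first_exons = character()) {
  new("GeneModel", gene = gene, strand = strand, tss = as.numeric(tss),
      exons = exons, cdsStart = as.numeric(cds_start),
      cdsEnd = as.numeric(cds_end),
      promoterLength = as.numeric(promoter_length),
      isoformFirstExons = isoform_first_exons)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s): %d exons, TSS %s, promoter %d bp upstream\n",
    object@gene, object@strand, nrow(object@exons),
    format(object@tss, big.mark = ","), object@promoterLength))
})

## ---------------------------------------------------------------------------

#' ExonCountTable: per-exon read counts with lengths and library sizes
#'
#' A `SummarizedExperiment` whose single assay "counts" has one row per exon
#' and one column per sample. `rowData` carries exon_id, exon length (bp)
#' and isoform membership ("shared" or an isoform label for a
#' specific first exon); `colData` carries group and lib_size.
#'
#' @export
setClass("ExonCountTable", contains = "SummarizedExperiment")

setValidity("ExonCountTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("exon_id", "length") %in% names(rd)))
    return("rowData needs exon_id and length")
  if (any(rd$length <= 0)) return("exon lengths must be > 0")
  if (!all(c("group", "lib_size") %in% names(cd)))
    return("colData needs group and lib_size")
  if (any(cd$lib_size <= 0)) return("library sizes must be > 0")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' required")
  TRUE
})

#' Construct an ExonCountTable
#'
#' @param counts numeric matrix, exons x samples.
#' @param exon_info data.frame with exon_id, length and optionally isoform
#'   (default "shared").
#' @param groups character/factor group label per sample.
#' @param lib_sizes numeric library sizes per sample (default column sums).
#' @return An [ExonCountTable-class].
#' @export
exonCountTable <- function(counts, exon_info, groups,
                           lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(exon_info$isoform)) exon_info$isoform <- "shared"
  rownames(counts) <- exon_info$exon_id
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(exon_info),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   lib_size = as.numeric(lib_sizes)))
  new("ExonCountTable", se)
}

#' @describeIn exonCountTable exon lengths in bp
#' @param x an ExonCountTable
#' @export
exonLengths <- function(x) SummarizedExperiment::rowData(x)$length

#' @describeIn exonCountTable per-sample library sizes
#' @export
libSizes <- function(x) SummarizedExperiment::colData(x)$lib_size

#' @describeIn exonCountTable per-sample group labels
#' @export
sampleGroups <- function(x) SummarizedExperiment::colData(x)$group

## ---------------------------------------------------------------------------

#' PromoterPair: reference/alternate promoter alleles with an edit list
#'
#' The alternate sequence must be exactly the reference with the edits
#' applied left-to-right. Edits are recorded in reference coordinates:
#' a SUB replaces `ref_piece` starting at `ref_offset`; an INS inserts
#' `alt_piece` immediately after `ref_offset`; a DEL removes `ref_piece`
#' starting at `ref_offset`. The edit list drives indel-aware coordinate
#' projection between the two alleles.
#'
#' @slot refSeq,altSeq uppercase A/C/G/T strings.
#' @slot edits data.frame: ref_offset, type (INS/SUB/DEL), ref_piece, alt_piece.
#' @slot tssRefOffset TSS position in reference coordinates (1-based).
#' @export
setClass("PromoterPair",
  representation(refSeq = "character", altSeq = "character",
                 edits = "data.frame", tssRefOffset = "numeric"))

#' Apply an edit list to a reference sequence
#'
#' @param ref reference sequence string.
#' @param edits data.frame with ref_offset, type, ref_piece, alt_piece,
#'   sorted and non-overlapping.
#' @return The edited (alternate) sequence.
#' @export
applyEdits <- function(ref, edits) {
  if (nrow(edits) == 0) return(ref)
  out <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(edits))) {
    off <- edits$ref_offset[i]; type <- edits$type[i]
    rp <- edits$ref_piece[i]; ap <- edits$alt_piece[i]
    if (type == "INS") {
      out <- c(out, substr(ref, cur, off), ap)
      cur <- off + 1L
    } else {
      stopifnot(substr(ref, off, off + nchar(rp) - 1L) == rp)
      out <- c(out, substr(ref, cur, off - 1L), ap)
      cur <- off + nchar(rp)
    }
  }
  paste0(paste(out, collapse = ""), substr(ref, cur, nchar(ref)))
}

checkEditsSorted <- function(edits) {
  if (nrow(edits) < 2) return(TRUE)
  # occupied ref span: [offset, offset + nchar(ref_piece) - 1]; INS occupies
  # the junction after offset, modelled as a zero-width span at offset + 0.5
  lo <- edits$ref_offset + ifelse(edits$type == "INS", 0.5, 0)
  hi <- edits$ref_offset + ifelse(edits$type == "INS", 0.5,
                                  nchar(edits$ref_piece) - 1)
  all(lo[-1] > hi[-nrow(edits)])
}

setValidity("PromoterPair", function(object) {
  e <- object@edits
  need <- c("ref_offset", "type", "ref_piece", "alt_piece")
  if (!all(need %in% names(e)))
    return(paste("edits needs columns:", paste(need, collapse = ", ")))
  if (nrow(e) && !all(e$type %in% c("INS", "SUB", "DEL")))
    return("edit types must be INS, SUB or DEL")
  if (!checkEditsSorted(e)) return("edits must be sorted and non-overlapping")
  if (applyEdits(object@refSeq, e) != object@altSeq)
    return("edits applied to refSeq do not reproduce altSeq")
  if (object@tssRefOffset < 1 || object@tssRefOffset > nchar(object@refSeq))
    return("tssRefOffset outside reference sequence")
  TRUE
})

#' Construct a PromoterPair
#' @param ref_seq reference allele sequence.
#' @param edits edit data.frame (ref_offset, type, ref_piece, alt_piece).
#' @param tss_ref_offset TSS position in ref coordinates.
#' @param alt_seq optional; derived from ref + edits when omitted.
#' @return A [PromoterPair-class].
#' @export
promoterPair <- function(ref_seq, edits, tss_ref_offset,
                         alt_seq = applyEdits(ref_seq, edits)) {
  new("PromoterPair", refSeq = toupper(ref_seq), altSeq = toupper(alt_seq),
      edits = edits, tssRefOffset = as.numeric(tss_ref_offset))
}

#' @describeIn promoterPair reference allele sequence
#' @param x a PromoterPair
#' @export
refSeq <- function(x) x@refSeq

#' @describeIn promoterPair alternate allele sequence
#' @export
altSeq <- function(x) x@altSeq

#' @describeIn promoterPair the edit list
#' @export
pairEdits <- function(x) x@edits

#' @describeIn promoterPair TSS offset in reference coordinates
#' @export
tssRefOffset <- function(x) x@tssRefOffset

setMethod("show", "PromoterPair", function(object) {
  cat(sprintf("PromoterPair: ref %d bp, alt %d bp, %d edit(s), TSS at ref %d\n",
    nchar(object@refSeq), nchar(object@altSeq), nrow(object@edits),
    object@tssRefOffset))
  if (nrow(object@edits))
    print(object@edits[c("ref_offset", "type", "ref_piece", "alt_piece")])
})

## ---------------------------------------------------------------------------

#' MotifModel: an IUPAC consensus or PWM binding-site model
#'
#' Either a degenerate IUPAC consensus string (e.g. the SOX HMG-box core
#' `WWCAAWG`) or a 4 x L position weight matrix (rows A, C, G, T) with a
#' score threshold.
#'
#' @slot type "iupac" or "pwm".
#' @slot pattern IUPAC consensus (iupac mode).
#' @slot pwm numeric 4 x L matrix (pwm mode).
#' @slot threshold minimum window score (pwm mode).
#' @export
setClass("MotifModel",
  representation(type = "character", pattern = "character",
                 pwm = "matrix", threshold = "numeric"))

setValidity("MotifModel", function(object) {
  if (!object@type %in% c("iupac", "pwm")) return("type must be iupac or pwm")
  if (object@type == "iupac") {
    if (nchar(object@pattern) < 4) return("pattern length must be >= 4")
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@pattern))
      return("pattern must use IUPAC nucleotide codes")
  } else {
    if (nrow(object@pwm) != 4) return("pwm must have 4 rows (A,C,G,T)")
    if (ncol(object@pwm) < 4) return("pwm length must be >= 4")
    if (!is.finite(object@threshold)) return("pwm threshold must be finite")
  }
  TRUE
})

#' Construct a MotifModel
#' @param iupac IUPAC consensus string (mutually exclusive with `pwm`).
#' @param pwm 4 x L numeric matrix, rows A, C, G, T.
#' @param threshold minimal window score for a PWM hit.
#' @return A [MotifModel-class].
#' @export
motifModel <- function(iupac = NULL, pwm = NULL, threshold = NULL) {
  if (!is.null(iupac)) {
    new("MotifModel", type = "iupac", pattern = toupper(iupac),
        pwm = matrix(numeric(0), 4, 0), threshold = NA_real_)
  } else {
    rownames(pwm) <- c("A", "C", "G", "T")
    new("MotifModel", type = "pwm", pattern = "", pwm = pwm,
        threshold = as.numeric(threshold))
  }
}

#' @describeIn motifModel motif length in bp
#' @param x a MotifModel
#' @export
motifLength <- function(x) if (x@type == "iupac") nchar(x@pattern) else ncol(x@pwm)

setMethod("show", "MotifModel", function(object) {
  if (object@type == "iupac")
    cat(sprintf("MotifModel (IUPAC consensus): %s\n", object@pattern))
  else
    cat(sprintf("MotifModel (PWM): length %d, threshold %.3f\n",
      ncol(object@pwm), object@threshold))
})
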