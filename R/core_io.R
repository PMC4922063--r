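## Readers/writers for the standard formats every stage touches.
## Internal coordinates are 1-based inclusive throughout; the only 0-based
## half-open conversion happens at the BED boundary.

#' Phenotype table constructor
#'
#' @param sample_id character sample names.
#' @param status "AFFECTED", "UNAFFECTED" or "UNKNOWN" per sample.
#' @return A named factor (names = samples) over those three levels.
#' @export
phenotypeTable <- function(sample_id, status) {
  status <- toupper(as.character(status))
  bad <- !status %in% c("AFFECTED", "UNAFFECTED", "UNKNOWN")
  if (any(bad)) stop("unknown phenotype status: ", status[bad][1])
  setNames(factor(status, levels = c("AFFECTED", "UNAFFECTED", "UNKNOWN")),
           sample_id)
}

#' @describeIn phenotypeTable read a TSV with columns sample_id, status
#' @param path file path.
#' @export
readPhenotypeTable <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  phenotypeTable(d$sample_id, d$status)
}

#' @describeIn phenotypeTable write the TSV form
#' @param phen a phenotype table.
#' @export
writePhenotypeTable <- function(phen, path) {
  write.table(data.frame(sample_id = names(phen), status = as.character(phen)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---------------------------------------------------------------------------
## VCF

# quick structural validation so parse failures name the offending line
validateVcfLines <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("VCF parse error at line 1: missing ##fileformat header in ", path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr))
    stop("VCF parse error: no #CHROM header line in ", path)
  for (i in seq(hdr[1] + 1L, length.out = length(lines) - hdr[1])) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10)
      stop("VCF parse error at line ", i, ": expected >= 10 tab-separated ",
           "fields (GT data required), got ", length(f))
    if (is.na(suppressWarnings(as.numeric(f[2]))))
      stop("VCF parse error at line ", i, ": POS not numeric: ", f[2])
  }
  invisible(TRUE)
}

#' Read a VCF into a VariantSet
#'
#' Reads a VCF v4.x with GT genotypes. Positions stay 1-based; missing
#' genotypes (`./.`) become `NA`; multi-allelic records are split into one
#' biallelic variant per alternate allele, with per-sample codes counting
#' copies of that allele.
#'
#' @param path VCF file path (plain text).
#' @param groups optional factor/character of sample groups
#'   (case/control/panel), in VCF sample-column order.
#' @return A [VariantSet-class].
#' @export
readVcfVariants <- function(path, groups = factor()) {
  validateVcfLines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
    dimnames = list(NULL, names(fix)))
  gt <- v@gt
  samples <- colnames(gt)[-1]
  fmt <- gt[, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(z) match("GT", z), integer(1))
  if (any(is.na(gt_idx))) stop("VCF record without GT in FORMAT")
  gtstr <- gt[, -1, drop = FALSE]
  for (i in seq_len(nrow(gtstr))) {
    if (gt_idx[i] > 1)
      gtstr[i, ] <- vapply(strsplit(gtstr[i, ], ":", fixed = TRUE),
                           `[`, character(1), gt_idx[i])
    else
      gtstr[i, ] <- sub(":.*$", "", gtstr[i, ])
  }
  info_list <- list(); call_list <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    al <- strsplit(gsub("\\|", "/", gtstr[i, ]), "/", fixed = TRUE)
    for (k in seq_along(alts)) {
      codes <- vapply(al, function(a) {
        if (any(a == "." | is.na(a))) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      info_list[[length(info_list) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
        id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".")
          paste0(fix[i, "CHROM"], ":", fix[i, "POS"], "_", k)
          else if (length(alts) > 1) paste0(fix[i, "ID"], "_", k)
          else fix[i, "ID"],
        ref = fix[i, "REF"], alt = alts[k], stringsAsFactors = FALSE)
      call_list[[length(call_list) + 1L]] <- codes
    }
  }
  info <- do.call(rbind, info_list)
  rownames(info) <- NULL
  calls <- do.call(rbind, call_list)
  variantSet(info, calls, samples = samples, groups = groups)
}

#' Write a VariantSet as a minimal GT-only VCF
#'
#' @param vs a [VariantSet-class].
#' @param path output path.
#' @export
writeVcfVariants <- function(vs, path) {
  info <- variantInfo(vs); calls <- variantCalls(vs)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs@samples), collapse = "\t")), con)
  code2gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (i in seq_len(nrow(info))) {
    g <- calls[i, ]
    gt <- ifelse(is.na(g), "./.", code2gt[as.character(g)])
    writeLines(paste(c(info$chrom[i], format(info$pos[i], scientific = FALSE),
      info$id[i], info$ref[i], info$alt[i], ".", ".", ".", "GT", gt),
      collapse = "\t"), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Genotype matrices (PED/MAP and TSV dialects)

readMarkerMap <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) == 6) {
    names(d) <- c("chrom", "id", "cm", "pos", "alleleA", "alleleB")
  } else if (ncol(d) == 4) {
    names(d) <- c("chrom", "id", "cm", "pos")
    d$alleleA <- NA_character_; d$alleleB <- NA_character_
  } else stop("marker map must have 4 or 6 tab-separated columns, got ", ncol(d))
  d$chrom <- as.character(d$chrom)
  d[c("id", "chrom", "pos", "alleleA", "alleleB")]
}

#' Read a genotype matrix (PED/MAP or TSV dialect)
#'
#' The TSV dialect has a header row of marker ids (first column `sample_id`)
#' and one row of 0/1/2/NA codes per sample, with a companion marker-map
#' file (tab-separated: chrom, id, cM, pos, alleleA, alleleB). The PED/MAP
#' dialect is PLINK-style text: `<prefix>.ped` with 6 leading columns then
#' two allele symbols per marker ("0 0" = missing), and `<prefix>.map`;
#' a 6-column map declares alleleA/alleleB, a 4-column map leaves them to be
#' inferred (alleleA = major allele). Codes count copies of alleleB.
#'
#' @param path TSV file path, or PED/MAP prefix.
#' @param dialect "tsv" or "pedmap".
#' @param map marker-map path for the TSV dialect
#'   (default `paste0(path, ".map")`).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeMatrix <- function(path, dialect = c("tsv", "pedmap"),
                               map = paste0(path, ".map")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    markers <- readMarkerMap(map)
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    header <- lines[[1]]
    if (header[1] != "sample_id")
      stop("TSV genotype dialect: first header field must be 'sample_id'")
    ids <- header[-1]
    ncols <- length(header)
    rows <- lines[-1]
    ragged <- which(lengths(rows) != ncols)
    if (length(ragged))
      stop("ragged genotype row at line ", ragged[1] + 1L, ": expected ",
           ncols, " fields, got ", lengths(rows)[ragged[1]])
    sample_ids <- vapply(rows, `[`, character(1), 1)
    calls <- t(vapply(rows, function(r) {
      x <- suppressWarnings(as.integer(r[-1]))
      bad <- !is.na(r[-1]) & r[-1] != "NA" & is.na(x)
      if (any(bad)) stop("unknown genotype code: ", r[-1][bad][1])
      x
    }, integer(ncols - 1L)))
    if (!identical(ids, markers$id))
      stop("marker ids in header do not match the marker map")
    genotypeMatrix(calls, markers, sample_ids)
  } else {
    markers <- readMarkerMap(paste0(path, ".map"))
    lines <- strsplit(trimws(readLines(paste0(path, ".ped"))), "[ \t]+")
    ncols <- 6L + 2L * nrow(markers)
    ragged <- which(lengths(lines) != ncols)
    if (length(ragged))
      stop("ragged PED row at line ", ragged[1], ": expected ", ncols,
           " fields, got ", lengths(lines)[ragged[1]])
    sample_ids <- vapply(lines, `[`, character(1), 2)
    nm <- nrow(markers)
    a1 <- t(matrix(vapply(lines, function(r) r[seq(7L, ncols, by = 2L)],
                          character(nm)), nrow = nm))
    a2 <- t(matrix(vapply(lines, function(r) r[seq(8L, ncols, by = 2L)],
                          character(nm)), nrow = nm))
    calls <- matrix(NA_integer_, length(lines), nrow(markers))
    for (j in seq_len(nrow(markers))) {
      obs <- c(a1[, j], a2[, j])
      seen <- setdiff(unique(obs), "0")
      aB <- markers$alleleB[j]; aA <- markers$alleleA[j]
      if (is.na(aB)) {
        # infer: alleleA = major allele among observed calls
        tab <- sort(table(obs[obs != "0"]), decreasing = TRUE)
        aA <- names(tab)[1]
        aB <- if (length(tab) > 1) names(tab)[2] else paste0("not_", aA)
        markers$alleleA[j] <- aA; markers$alleleB[j] <- aB
      }
      unknown <- setdiff(seen, c(aA, aB))
      if (length(unknown))
        stop("unknown allele symbol '", unknown[1], "' at marker ",
             markers$id[j])
      ok <- a1[, j] != "0" & a2[, j] != "0"
      calls[ok, j] <- (a1[ok, j] == aB) + (a2[ok, j] == aB)
    }
    genotypeMatrix(calls, markers, sample_ids)
  }
}

#' Write a genotype matrix (TSV or PED/MAP dialect)
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output TSV path, or PED/MAP prefix.
#' @param dialect "tsv" or "pedmap".
#' @param map companion map path for the TSV dialect.
#' @export
writeGenotypeMatrix <- function(gm, path, dialect = c("tsv", "pedmap"),
                                map = paste0(path, ".map")) {
  dialect <- match.arg(dialect)
  m <- markerInfo(gm); calls <- genotypeCalls(gm)
  mapdf <- data.frame(m$chrom, m$id, 0, format(m$pos, scientific = FALSE,
           trim = TRUE), m$alleleA, m$alleleB)
  if (dialect == "tsv") {
    write.table(mapdf, map, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(c("sample_id", m$id), collapse = "\t"), con)
    for (i in seq_len(nrow(calls)))
      writeLines(paste(c(rownames(calls)[i], calls[i, ]), collapse = "\t"), con)
  } else {
    write.table(mapdf, paste0(path, ".map"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    con <- file(paste0(path, ".ped"), "w"); on.exit(close(con))
    for (i in seq_len(nrow(calls))) {
      g <- calls[i, ]
      a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, m$alleleB, m$alleleA))
      a2 <- ifelse(is.na(g), "0", ifelse(g == 2, m$alleleB, m$alleleA))
      writeLines(paste(c("FAM", rownames(calls)[i], "0", "0", "0", "0",
        as.vector(rbind(a1, a2))), collapse = " "), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED

#' Write candidate intervals as BED
#'
#' Converts internal 1-based inclusive intervals to BED's 0-based half-open
#' convention (emitted start = start - 1, end = end).
#'
#' @param intervals a [CandidateInterval-class] or list of them.
#' @param path output path.
#' @export
writeBed <- function(intervals, path) {
  if (is(intervals, "CandidateInterval")) intervals <- list(intervals)
  con <- file(path, "w"); on.exit(close(con))
  for (iv in intervals)
    writeLines(paste(intervalChrom(iv),
      format(intervalStart(iv) - 1, scientific = FALSE, trim = TRUE),
      format(intervalEnd(iv), scientific = FALSE, trim = TRUE),
      sep = "\t"), con)
  invisible(path)
}

#' @describeIn writeBed read a 3-column BED back into 1-based intervals
#' @return `readBedIntervals`: a list of [CandidateInterval-class].
#' @export
readBedIntervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    candidateInterval(f[1], as.numeric(f[2]) + 1, as.numeric(f[3]))
  })
}

## ---------------------------------------------------------------------------
## Exon count tables

#' Write an ExonCountTable as annotated TSV
#'
#' Two comment lines (`#groups`, `#library_sizes`) carry per-sample
#' metadata; data columns are exon_id, isoform, length, then one count
#' column per sample.
#'
#' @param ect an [ExonCountTable-class].
#' @param path output path.
#' @export
writeExonCountTable <- function(ect, path) {
  counts <- SummarizedExperiment::assay(ect, "counts")
  rd <- SummarizedExperiment::rowData(ect)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("#groups", sampleGroups(ect)), collapse = "\t"), con)
  writeLines(paste(c("#library_sizes",
    format(libSizes(ect), scientific = FALSE, trim = TRUE)),
    collapse = "\t"), con)
  writeLines(paste(c("exon_id", "isoform", "length", colnames(counts)),
    collapse = "\t"), con)
  for (i in seq_len(nrow(counts)))
    writeLines(paste(c(rd$exon_id[i], rd$isoform[i], rd$length[i],
      counts[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' @describeIn writeExonCountTable read the TSV form back
#' @export
readExonCountTable <- function(path) {
  lines <- readLines(path)
  groups <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  libs <- as.numeric(strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1])
  d <- read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(d[, -(1:3), drop = FALSE])
  exonCountTable(counts,
    data.frame(exon_id = d$exon_id, length = d$length, isoform = d$isoform,
               stringsAsFactors = FALSE),
    groups = groups, lib_sizes = libs)
}
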