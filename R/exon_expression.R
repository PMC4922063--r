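## Exon-level normalization and fold-change analysis: resolves
## isoform-specific expression loss that gene-level RPKM cannot separate
## when several isoforms share most exons.

#' Exon-level RPKM normalization
#'
#' value = count / (library_size / 1e6) / (exon_length / 1e3): reads per
#' kilobase of exon per million mapped reads, computed per exon and sample.
#'
#' @param ect an [ExonCountTable-class].
#' @return numeric matrix of normalized values, exons x samples.
#' @export
normalizeExon <- function(ect) {
  libs <- libSizes(ect)
  if (any(libs <= 0)) stop("zero library size")
  counts <- SummarizedExperiment::assay(ect, "counts")
  sweep(sweep(counts, 2, libs / 1e6, "/"), 1, exonLengths(ect) / 1e3, "/")
}

#' Per-exon fold change between two groups
#'
#' fold_change = (mean_ref + pc) / (mean_cmp + pc), where the means are
#' arithmetic means of the per-sample RPKM values and pc is the pseudocount
#' expressed on the normalized scale (a `pseudocount`-read increment in a
#' median-size library for that exon's length), keeping the ratio finite
#' for silenced exons. Direction is reported explicitly: "decrease" means
#' lower expression in the comparison group.
#'
#' @param ect an [ExonCountTable-class].
#' @param ref_group,cmp_group group labels (reference / comparison).
#' @param pseudocount reads added before forming the ratio (default 0.5).
#' @return data.frame: exon_id, isoform, mean_ref, mean_cmp, fold_change,
#'   direction.
#' @export
exonFoldChange <- function(ect, ref_group, cmp_group, pseudocount = 0.5) {
  norm <- normalizeExon(ect)
  g <- sampleGroups(ect)
  stopifnot(ref_group %in% g, cmp_group %in% g)
  mean_ref <- rowMeans(norm[, g == ref_group, drop = FALSE])
  mean_cmp <- rowMeans(norm[, g == cmp_group, drop = FALSE])
  pc <- pseudocount / (median(libSizes(ect)) / 1e6) / (exonLengths(ect) / 1e3)
  fc <- (mean_ref + pc) / (mean_cmp + pc)
  rd <- SummarizedExperiment::rowData(ect)
  data.frame(exon_id = rd$exon_id, isoform = rd$isoform,
    mean_ref = mean_ref, mean_cmp = mean_cmp, fold_change = fc,
    direction = ifelse(mean_cmp < mean_ref, "decrease",
                ifelse(mean_cmp > mean_ref, "increase", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Call isoform-specific expression loss from exon fold changes
#'
#' An isoform is flagged iff its specific first exon shows a fold change at
#' or above `threshold` (reference over comparison) while no shared exon
#' does — separating true isoform-specific loss from a gene-level shift,
#' which moves shared exons too.
#'
#' @param fc data.frame from [exonFoldChange] (needs isoform and
#'   fold_change); exons with isoform != "shared" are isoform-specific
#'   first exons.
#' @param threshold fold-change threshold (default 2).
#' @return data.frame: isoform, specific_fc, max_shared_fc, flagged.
#' @export
callIsoformSpecificLoss <- function(fc, threshold = 2.0) {
  shared_fc <- fc$fold_change[fc$isoform == "shared"]
  max_shared <- if (length(shared_fc)) max(shared_fc) else -Inf
  iso <- fc[fc$isoform != "shared", , drop = FALSE]
  data.frame(isoform = iso$isoform, specific_fc = iso$fold_change,
    max_shared_fc = max_shared,
    flagged = iso$fold_change >= threshold & max_shared < threshold,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-fold-rule differential genes from gene-level normalized values
#'
#' A gene is differential when the ratio of its group means reaches
#' `threshold` in either direction (boundary inclusive).
#'
#' @param values numeric matrix of gene-level normalized values,
#'   genes x samples.
#' @param groups group label per sample (exactly two groups).
#' @param threshold fold threshold (default 2).
#' @param pseudocount added to both means before the ratio (default 0).
#' @return data.frame: gene, mean per group, ratio (max of the two
#'   directions), differential.
#' @export
deGenes <- function(values, groups, threshold = 2.0, pseudocount = 0) {
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  m1 <- rowMeans(values[, groups == lv[1], drop = FALSE]) + pseudocount
  m2 <- rowMeans(values[, groups == lv[2], drop = FALSE]) + pseudocount
  r <- pmax(m1 / m2, m2 / m1)
  r[m1 == 0 & m2 == 0] <- 1
  data.frame(gene = if (is.null(rownames(values)))
      as.character(seq_len(nrow(values))) else rownames(values),
    mean_1 = m1 - pseudocount, mean_2 = m2 - pseudocount, ratio = r,
    differential = r >= threshold, stringsAsFactors = FALSE,
    row.names = NULL)
}
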