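## The variant-filter cascade: recessive co-segregation classification with
## missing-data ambiguity, population-panel private-allele exclusion,
## merging of screening sources, region/coding-effect annotation and
## deterministic candidate ranking.

#' Classify a variant's co-segregation with a recessive phenotype
#'
#' Under the recessive model a variant co-segregates when every case is
#' homozygous for the alternate allele and no control is. CONSISTENT
#' requires all calls present and satisfying that pattern; AMBIGUOUS means
#' at least one call is missing while every observed call is still
#' consistent; INCONSISTENT otherwise. Controls may be heterozygous
#' carriers unless `strict_controls` demands homozygous-reference controls.
#'
#' @param case_calls,control_calls integer codes (0/1/2, NA = missing).
#' @param strict_controls require controls to be 0 rather than != 2.
#' @return "CONSISTENT", "AMBIGUOUS" or "INCONSISTENT".
#' @export
classifyCosegregation <- function(case_calls, control_calls,
                                  strict_controls = FALSE) {
  stopifnot(length(case_calls) >= 1, length(control_calls) >= 1)
  ca <- case_calls[!is.na(case_calls)]
  co <- control_calls[!is.na(control_calls)]
  ok <- all(ca == 2L) &&
    (if (strict_controls) all(co == 0L) else all(co != 2L))
  if (!ok) return("INCONSISTENT")
  if (anyNA(case_calls) || anyNA(control_calls)) return("AMBIGUOUS")
  "CONSISTENT"
}

#' Classify every variant of a grouped VariantSet
#'
#' @param vs a [VariantSet-class] with case/control (and optionally panel)
#'   groups.
#' @param strict_controls see [classifyCosegregation].
#' @return character vector of classes, one per variant.
#' @export
classifyVariantSet <- function(vs, strict_controls = FALSE) {
  ca <- groupCalls(vs, "case"); co <- groupCalls(vs, "control")
  vapply(seq_len(nrow(ca)), function(i)
    classifyCosegregation(ca[i, ], co[i, ], strict_controls), character(1))
}

#' Population-panel private-allele exclusion
#'
#' A variant is excluded iff any panel individual has a non-missing call
#' carrying at least one alternate allele; privacy to the cases is
#' absolute. Enlarging the panel can only exclude more variants.
#'
#' @param panel_calls integer matrix, variants x panel individuals
#'   (0/1/2/NA).
#' @return logical vector: TRUE = private to cases (retained).
#' @export
panelExclude <- function(panel_calls) {
  panel_calls <- as.matrix(panel_calls)
  carried <- rowSums(panel_calls >= 1L, na.rm = TRUE) > 0
  !carried
}

#' Merge two variant screening sources
#'
#' Variants are identified by (chrom, pos, ref, alt) after anchored-base
#' indel normalization; the union keeps one row per key, carries the
#' provenance tag(s) of the contributing source(s), and is ordered by
#' chromosome and position.
#'
#' @param set_a,set_b [VariantSet-class] objects or data.frames with
#'   chrom, pos, ref, alt (id optional).
#' @param names length-2 character: provenance tags.
#' @return data.frame: chrom, pos, id, ref, alt, vclass, source.
#' @export
mergeVariantSets <- function(set_a, set_b, names = c("a", "b")) {
  as_df <- function(x) {
    d <- if (is(x, "VariantSet")) variantInfo(x) else as.data.frame(x)
    if (is.null(d$id))
      d$id <- if (nrow(d)) paste0(d$chrom, ":", d$pos) else character(0)
    d$ref <- toupper(d$ref); d$alt <- toupper(d$alt)
    d$vclass <- variantClass(d$ref, d$alt)
    d[c("chrom", "pos", "id", "ref", "alt", "vclass")]
  }
  a <- as_df(set_a); b <- as_df(set_b)
  a$source <- rep(names[1], nrow(a)); b$source <- rep(names[2], nrow(b))
  all <- rbind(a, b)
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = "\r")
  merged <- all[!duplicated(key), , drop = FALSE]
  mkey <- key[!duplicated(key)]
  src <- vapply(mkey, function(k)
    paste(unique(all$source[key == k]), collapse = ";"), character(1))
  merged$source <- unname(src)
  merged <- merged[order(merged$chrom, merged$pos, merged$ref, merged$alt), ]
  rownames(merged) <- NULL
  merged
}

## ---------------------------------------------------------------------------
## Annotation

cdsPositions <- function(model) {
  ex <- model@exons
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq(ex$start[i], ex$end[i])))
  sort(pos[pos >= model@cdsStart & pos <= model@cdsEnd])
}

complementBase <- function(b)
  c(A = "T", C = "G", G = "C", T = "A")[[b]]

inPromoter <- function(model, pos) {
  if (model@strand == "+")
    pos >= model@tss - model@promoterLength && pos <= model@tss - 1
  else
    pos >= model@tss + 1 && pos <= model@tss + model@promoterLength
}

#' Annotate a variant against a gene model
#'
#' Region is assigned by interval lookup with priority promoter (the
#' strand-aware upstream window of the TSS) > exon > splice boundary
#' (within 2 bp of an exon edge) > intron > intergenic. For coding SNPs the
#' affected codon is translated with the standard genetic code and labelled
#' refAA + codon index + altAA (e.g. N106K); coding indels are labelled
#' frameshift or in-frame by length modulo 3.
#'
#' @param variant list/one-row data.frame with chrom, pos, ref, alt, vclass.
#' @param model a [GeneModel-class].
#' @param cds_sequence the spliced CDS (sense strand), length divisible
#'   by 3.
#' @param check_ref warn when the variant's reference allele disagrees
#'   with the CDS base at its position (default TRUE; synthetic inputs
#'   whose CDS is drawn independently set this FALSE).
#' @return list: region, effect (SYNONYMOUS / NONSYNONYMOUS / frameshift /
#'   in-frame / NA), label (protein change or NA).
#' @export
annotateVariant <- function(variant, model, cds_sequence,
                            check_ref = TRUE) {
  cds_sequence <- toupper(as.character(cds_sequence))
  if (nchar(cds_sequence) %% 3 != 0) stop("CDS length not divisible by 3")
  pos <- variant$pos
  ex <- model@exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  near_edge <- any(abs(pos - c(ex$start, ex$end)) <= 2)
  region <-
    if (inPromoter(model, pos)) "PROMOTER"
    else if (in_exon) "CODING"
    else if (near_edge) "SPLICE_BOUNDARY"
    else if (pos >= min(ex$start) && pos <= max(ex$end)) "INTRON"
    else "INTERGENIC"
  effect <- NA_character_; label <- NA_character_
  if (region == "CODING") {
    if (variant$vclass != "SNP") {
      shift <- abs(nchar(variant$alt) - nchar(variant$ref))
      effect <- if (shift %% 3 == 0) "in-frame" else "frameshift"
    } else {
      cpos <- cdsPositions(model)
      hit <- match(pos, cpos)
      if (!is.na(hit)) {
        off <- if (model@strand == "+") hit else length(cpos) - hit + 1L
        codon_idx <- (off + 2L) %/% 3L
        pos_in_codon <- (off - 1L) %% 3L + 1L
        codon <- substr(cds_sequence, 3L * codon_idx - 2L, 3L * codon_idx)
        ref_b <- variant$ref; alt_b <- variant$alt
        if (model@strand == "-") {
          ref_b <- complementBase(ref_b); alt_b <- complementBase(alt_b)
        }
        if (check_ref && substr(codon, pos_in_codon, pos_in_codon) != ref_b)
          warning("reference allele disagrees with CDS at ", pos)
        alt_codon <- codon
        substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_b
        gc <- Biostrings::GENETIC_CODE
        ref_aa <- unname(gc[codon]); alt_aa <- unname(gc[alt_codon])
        effect <- if (ref_aa == alt_aa) "SYNONYMOUS" else "NONSYNONYMOUS"
        label <- paste0(ref_aa, codon_idx, alt_aa)
      }
    }
  }
  list(region = region, effect = effect, label = label)
}

## ---------------------------------------------------------------------------
## Ranking and the full cascade

regionPriority <- function(region, effect) {
  p <- ifelse(region == "CODING" &
                effect %in% c("NONSYNONYMOUS", "frameshift", "in-frame"), 1,
       ifelse(region == "SPLICE_BOUNDARY", 2,
       ifelse(region == "PROMOTER", 3,
       ifelse(region == "INTRON", 4,
       ifelse(region == "CODING", 5, 6)))))
  p
}

#' Rank candidate variants after the filter cascade
#'
#' Retains variants classified CONSISTENT or AMBIGUOUS, private to the
#' cases, and inside the candidate interval; orders them with
#' focus-region variants first, then by region priority (non-silent coding
#' > splice boundary > promoter > intron > silent coding > intergenic),
#' then position — a deterministic total order.
#'
#' @param classified data.frame with chrom, pos, ref, alt, vclass,
#'   coseg_class, private_to_cases, region, effect, label.
#' @param interval a [CandidateInterval-class].
#' @param focus_region region label put first (default "PROMOTER", the
#'   isoform-specific promoter of the focus isoform).
#' @return the retained rows, ranked, with columns rank, in_focus and
#'   priority added.
#' @export
rankCandidates <- function(classified, interval, focus_region = "PROMOTER") {
  keep <- classified$coseg_class %in% c("CONSISTENT", "AMBIGUOUS") &
    classified$private_to_cases &
    classified$chrom == intervalChrom(interval) &
    classified$pos >= intervalStart(interval) &
    classified$pos <= intervalEnd(interval)
  d <- classified[keep, , drop = FALSE]
  if (!nrow(d)) { d$rank <- integer(0); return(d) }
  d$in_focus <- d$region == focus_region
  d$priority <- regionPriority(d$region, d$effect)
  o <- order(!d$in_focus, d$priority, d$pos, d$alt)
  d <- d[o, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Run the whole variant-filter cascade on a grouped VariantSet
#'
#' Chains [classifyVariantSet], [panelExclude], [annotateVariant] and
#' [rankCandidates], and reports the record counts at each stage.
#'
#' @param vs a [VariantSet-class] with case/control/panel groups.
#' @param interval a [CandidateInterval-class].
#' @param model a [GeneModel-class] for annotation.
#' @param cds_sequence spliced CDS for coding-effect calls.
#' @param strict_controls see [classifyCosegregation].
#' @param focus_region see [rankCandidates].
#' @param check_ref see [annotateVariant].
#' @return list: `candidates` (ranked data.frame), `classified` (all
#'   variants with classification fields), `counts` (named vector of the
#'   cascade record counts).
#' @export
prioritizeVariants <- function(vs, interval, model, cds_sequence,
                               strict_controls = FALSE,
                               focus_region = "PROMOTER",
                               check_ref = TRUE) {
  info <- variantInfo(vs)
  info$coseg_class <- classifyVariantSet(vs, strict_controls)
  info$private_to_cases <- panelExclude(groupCalls(vs, "panel"))
  ann <- lapply(seq_len(nrow(info)), function(i)
    annotateVariant(info[i, ], model, cds_sequence, check_ref = check_ref))
  info$region <- vapply(ann, `[[`, character(1), "region")
  info$effect <- vapply(ann, `[[`, character(1), "effect")
  info$label <- vapply(ann, `[[`, character(1), "label")
  ranked <- rankCandidates(info, interval, focus_region)
  counts <- c(total = nrow(info),
    cosegregated = sum(info$coseg_class %in% c("CONSISTENT", "AMBIGUOUS")),
    ambiguous = sum(info$coseg_class == "AMBIGUOUS"),
    private = sum(info$private_to_cases),
    retained = nrow(ranked))
  list(candidates = ranked, classified = info, counts = counts)
}
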