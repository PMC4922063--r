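## Orchestration: a structured configuration, per-stage record-count
## logging, and an end-to-end demonstration run on simulated data that
## checks planted-truth recovery at every stage.

#' Default pipeline configuration
#'
#' Returns the nested parameter list driving [runDemo]; every tunable of
#' the analysis stages appears here with its default. The permutation
#' counts default to demonstration scale (2,000); the full-scale analyses
#' use 100,000 genome-wide and 25,000 chromosome-wide permutations.
#'
#' @return nested named list.
#' @export
pipelineConfig <- function() {
  list(
    seed = 1,
    litters = list(n_litters = 11, penetrance_hom = 1.0,
                   penetrance_het = 4 / 51),
    cohort = list(n_cases = 28, n_controls = 73, n_markers = 2000,
                  founder_haplotypes = 8, penetrance_hom = 1.0,
                  penetrance_het = 4 / 51, missing_rate = 0.02,
                  switch_rate = 0.01),
    association = list(maf_min = 0.05, call_rate_min = 0.75,
                       n_perm = 2000),
    haplotype = list(min_window = 2, max_window = 10, n_perm = 2000),
    variants = list(n_private_linked = 15, n_shared_common = 50,
                    n_cases = 3, n_controls = 3, panel_size = 103,
                    missing_rate = 0, panel_carries_causal = FALSE),
    prioritize = list(strict_controls = FALSE, focus_region = "PROMOTER",
                      promoter_length = 10000),
    exons = list(group_sizes = c(3, 3), planted_fc = c(M = 11.5),
                 dispersion = 0.1, mean_depth = 1e6, fc_threshold = 2.0),
    promoter = list(ref_length = 8000, motif_payload = "GCTAACAAAGTTGC",
                    deletion_width = 96)
  )
}

mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- mergeConfig(defaults[[k]], as.list(user[[k]]),
                                   paste0(path, k, "."))
    else
      defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [pipelineConfig] defaults; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return nested named list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- mergeConfig(pipelineConfig(), user)
  pf <- cfg$exons$planted_fc
  cfg$exons$planted_fc <- setNames(as.numeric(pf), names(pf))
  cfg
}

demoLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' End-to-end demonstration on simulated data with truth recovery checks
#'
#' Runs the full chain — litter segregation, cohort simulation, marker QC,
#' permutation association, haplotype-concordance mapping, interval
#' definition, the variant-filter cascade, exon-level fold-change
#' analysis, and promoter motif-gain scanning — on synthetic data, and
#' compares every stage's result against the planted truth.
#'
#' @param config nested list from [pipelineConfig] /
#'   [readPipelineConfig].
#' @param out_dir optional directory for stage outputs (interval BED,
#'   candidate TSV, report YAML).
#' @param verbose print per-stage record counts (default TRUE).
#' @param stop_on_failure error when any recovery check fails.
#' @return report list, one element per stage with planted truth,
#'   recovered result and an `ok` flag, plus overall `ok`.
#' @export
runDemo <- function(config = pipelineConfig(), out_dir = NULL,
                    verbose = TRUE, stop_on_failure = FALSE) {
  seed <- config$seed
  report <- list()

  ## 1. segregation
  lit <- simLitters(n_litters = config$litters$n_litters,
    penetrance_hom = config$litters$penetrance_hom,
    penetrance_het = config$litters$penetrance_het, seed = seed + 101)
  obs <- c(sum(lit$litters$unaffected), sum(lit$litters$affected))
  sel <- selectMendelianRatio(obs)
  demoLog(verbose, "[segregation] %d litters, %d offspring (%d affected); selected ratio %d:%d",
    nrow(lit$litters), sum(lit$litters$size), obs[2],
    sel$selected[1], sel$selected[2])
  report$segregation <- list(observed = obs, selected = sel$selected,
    ok = identical(sel$selected, c(3, 1)))

  ## 2. cohort + association mapping
  co <- config$cohort
  sim <- simCohort(n_cases = co$n_cases, n_controls = co$n_controls,
    n_markers = co$n_markers, founder_haplotypes = co$founder_haplotypes,
    penetrance_hom = co$penetrance_hom, penetrance_het = co$penetrance_het,
    missing_rate = co$missing_rate, switch_rate = co$switch_rate,
    seed = seed + 202)
  flt <- filterMarkers(sim$gm, config$association$maf_min,
                       config$association$call_rate_min)
  demoLog(verbose, "[assoc] %d markers -> %d after MAF/call-rate QC",
          nMarkers(sim$gm), nMarkers(flt$gm))
  assoc <- permutationGenomewide(flt$gm, sim$phenotype,
    n_perm = config$association$n_perm, seed = seed + 303)
  top <- assoc[order(-assoc$statistic, assoc$pos)[1], ]
  causal_pos <- sim$truth$causal_pos
  causal_col <- which(markerInfo(sim$gm)$pos == causal_pos)
  top_col <- which(markerInfo(flt$gm)$id == top$marker_id)
  r2 <- suppressWarnings(cor(genotypeCalls(flt$gm)[, top_col],
    genotypeCalls(sim$gm)[, causal_col], use = "pairwise")^2)
  demoLog(verbose,
    "[assoc] top marker %s (pos %d, p_genome %.4g), r2 with causal %.2f",
    top$marker_id, top$pos, top$p_genome, r2)
  report$association <- list(top_marker = top$marker_id,
    top_pos = top$pos, p_genome = top$p_genome, causal_pos = causal_pos,
    r2_with_causal = r2, ok = isTRUE(r2 >= 0.5))

  ## 3. haplotype block + interval
  blocks <- findConcordantBlocks(flt$gm, sim$phenotype,
    config$haplotype$min_window, config$haplotype$max_window)
  if (nrow(blocks) == 0) {
    report$interval <- list(ok = FALSE, note = "no concordant block")
    interval <- NULL
  } else {
    blk <- bestBlock(blocks)
    ba <- blockAssoc(flt$gm, sim$phenotype, blk,
      n_perm = config$haplotype$n_perm, seed = seed + 404,
      min_window = config$haplotype$min_window,
      max_window = config$haplotype$max_window)
    interval <- defineInterval(flt$gm, sim$phenotype, blk)
    contains <- intervalChrom(interval) == markerInfo(sim$gm)$chrom[1] &&
      causal_pos >= intervalStart(interval) &&
      causal_pos <= intervalEnd(interval)
    demoLog(verbose,
      "[hapmap] %d concordant block(s); best: %d risk-hom / %d het (%d affected) / %d prot-hom, fisher p %.3g, p_chr %.3g",
      nrow(blocks), blk$n_risk_hom, blk$n_het, blk$het_affected,
      blk$n_prot_hom, ba$fisher_p, ba$p_chr)
    demoLog(verbose, "[hapmap] interval %s:%d-%d (%d kb), contains causal: %s",
      intervalChrom(interval), intervalStart(interval),
      intervalEnd(interval), lengthKb(interval), contains)
    report$interval <- list(block = blk, fisher_p = ba$fisher_p,
      p_chr = ba$p_chr, start = intervalStart(interval),
      end = intervalEnd(interval), length_kb = lengthKb(interval),
      contains_causal = contains, ok = contains)
  }

  ## 4. variant cascade (within the mapped interval, or the truth region)
  vint <- if (!is.null(interval) && report$interval$ok) interval else
    candidateInterval(markerInfo(sim$gm)$chrom[1], causal_pos - 400000,
                      causal_pos + 400000)
  gmod <- simGeneModel(vint, seed = seed + 505,
    promoter_length = config$prioritize$promoter_length)
  tss <- gmod$model@tss
  prom_span <- c(tss - config$prioritize$promoter_length, tss - 1)
  va <- config$variants
  vsim <- simVariantCalls(vint, n_private_linked = va$n_private_linked,
    n_shared_common = va$n_shared_common, n_cases = va$n_cases,
    n_controls = va$n_controls, panel_size = va$panel_size,
    missing_rate = va$missing_rate, seed = seed + 606,
    causal_pos = tss - 5000, avoid_span = prom_span)
  vs <- vsim$vs
  if (isTRUE(va$panel_carries_causal)) {
    ci <- which(paste(variantInfo(vs)$chrom, variantInfo(vs)$pos,
      variantInfo(vs)$ref, variantInfo(vs)$alt) == vsim$truth$causal_key)
    panel_cols <- which(variantGroups(vs) == "panel")
    vs@calls[ci, panel_cols[1]] <- 1L
  }
  # synthetic variant refs are drawn independently of the synthetic CDS
  pri <- prioritizeVariants(vs, vint, gmod$model, gmod$cds_sequence,
    strict_controls = config$prioritize$strict_controls,
    focus_region = config$prioritize$focus_region, check_ref = FALSE)
  demoLog(verbose,
    "[prioritize] %d variants -> %d co-segregated (%d ambiguous) -> %d private -> %d retained",
    pri$counts["total"], pri$counts["cosegregated"],
    pri$counts["ambiguous"], pri$counts["private"],
    pri$counts["retained"])
  ranked_keys <- if (nrow(pri$candidates)) paste(pri$candidates$chrom,
    pri$candidates$pos, pri$candidates$ref, pri$candidates$alt) else
    character(0)
  causal_rank <- match(vsim$truth$causal_key, ranked_keys)
  retained_ok <- setequal(ranked_keys, vsim$truth$private_keys)
  cascade_ok <- if (isTRUE(va$panel_carries_causal))
    !vsim$truth$causal_key %in% ranked_keys else
    isTRUE(causal_rank == 1L) && retained_ok
  demoLog(verbose, "[prioritize] causal variant rank: %s",
          ifelse(is.na(causal_rank), "excluded", causal_rank))
  report$prioritize <- list(counts = pri$counts,
    causal_rank = causal_rank, retained_equals_private = retained_ok,
    negative_control = isTRUE(va$panel_carries_causal), ok = cascade_ok)

  ## 5. exon-level expression
  exsim <- simExonCounts(group_sizes = config$exons$group_sizes,
    planted_fc = config$exons$planted_fc,
    dispersion = config$exons$dispersion,
    mean_depth = config$exons$mean_depth, seed = seed + 707)
  fc <- exonFoldChange(exsim$ect, "wildtype", "mutant")
  iso <- callIsoformSpecificLoss(fc, config$exons$fc_threshold)
  planted_iso <- names(config$exons$planted_fc)
  flag_ok <- setequal(iso$isoform[iso$flagged], planted_iso)
  mfc <- fc$fold_change[match(planted_iso, fc$exon_id)]
  demoLog(verbose,
    "[exonfc] planted %.1f-fold loss on exon %s; estimated %.1f; flagged isoform(s): %s",
    config$exons$planted_fc[1], planted_iso[1], mfc[1],
    paste(iso$isoform[iso$flagged], collapse = ",") )
  report$exons <- list(estimated_fc = setNames(mfc, planted_iso),
    flagged = iso$isoform[iso$flagged], ok = flag_ok)

  ## 6. promoter motif gain + deletion test
  psim <- simPromoterPair(ref_length = config$promoter$ref_length,
    motif_payload = config$promoter$motif_payload, seed = seed + 808)
  ds <- diffSites(psim$pair, soxConsensusMotif())
  sp <- editSpans(pairEdits(psim$pair))
  del_lo <- min(sp$alt_lo) - 7
  region <- c(del_lo, del_lo + config$promoter$deletion_width - 1)
  dt <- deletionTest(psim$pair, region, soxConsensusMotif())
  demoLog(verbose,
    "[motifscan] gained sites: %d (TSS-relative %s); lost: %d; %d-bp deletion restores: %s",
    nrow(ds$gained), paste(ds$gained$tss_relative, collapse = ","),
    nrow(ds$lost), config$promoter$deletion_width, dt$restored)
  report$motif <- list(n_gained = nrow(ds$gained),
    gained_tss_relative = ds$gained$tss_relative,
    n_lost = nrow(ds$lost), deletion_restored = dt$restored,
    ok = nrow(ds$gained) == 1 && nrow(ds$lost) == 0 && dt$restored)

  report$ok <- all(vapply(report[names(report) != "ok"],
                          function(x) isTRUE(x$ok), logical(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(interval))
      writeBed(interval, file.path(out_dir, "candidate_interval.bed"))
    if (nrow(pri$candidates))
      write.table(pri$candidates, file.path(out_dir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      rapply(report, function(x) if (is.data.frame(x)) as.list(x) else x,
             how = "replace"),
      file.path(out_dir, "report.yaml"))
  }
  if (stop_on_failure && !report$ok)
    stop("planted-truth recovery failed; see report")
  report
}
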