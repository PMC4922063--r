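test_that("all generators are bit-reproducible for a fixed seed", {
  a <- simCohort(n_cases = 6, n_controls = 12, n_markers = 30, seed = 17)
  b <- simCohort(n_cases = 6, n_controls = 12, n_markers = 30, seed = 17)
  expect_identical(genotypeCalls(a$gm), genotypeCalls(b$gm))
  expect_identical(a$truth, b$truth)
  expect_identical(simLitters(seed = 4), simLitters(seed = 4))
  iv <- candidateInterval("13", 1e6, 2e6)
  expect_identical(simVariantCalls(iv, seed = 5), simVariantCalls(iv, seed = 5))
  expect_identical(simExonCounts(seed = 6), simExonCounts(seed = 6))
  p1 <- simPromoterPair(ref_length = 1500, tss_ref_offset = 1400, seed = 7)
  p2 <- simPromoterPair(ref_length = 1500, tss_ref_offset = 1400, seed = 7)
  expect_identical(refSeq(p1$pair), refSeq(p2$pair))
  expect_identical(altSeq(p1$pair), altSeq(p2$pair))
})

test_that("fully recessive, fully penetrant cohorts make every case hom-alt", {
  sim <- simCohort(n_cases = 15, n_controls = 30, n_markers = 30,
                   penetrance_hom = 1, penetrance_het = 0,
                   missing_rate = 0, seed = 21)
  g <- genotypeCalls(sim$gm)[, sim$truth$causal_marker_index]
  aff <- as.character(sim$phenotype[sampleIDs(sim$gm)]) == "AFFECTED"
  expect_true(all(g[aff] == 2L))
  expect_true(all(g[!aff] != 2L))
})

test_that("heterozygote penetrance calibrates to 4/51 across seeds", {
  het <- 0; het_aff <- 0
  for (s in 1:200) {
    sim <- simCohort(n_cases = 10, n_controls = 20, n_markers = 10,
                     missing_rate = 0, seed = 3000 + s)
    ds <- sim$truth$draw_stats
    het <- het + ds["n_het_drawn"]; het_aff <- het_aff + ds["n_het_affected"]
  }
  phat <- unname(het_aff / het)
  p0 <- 4 / 51
  tol <- 3.5 * sqrt(p0 * (1 - p0) / unname(het))
  expect_lt(abs(phat - p0), tol)
})

test_that("unreachable case quotas fail explicitly", {
  expect_error(simCohort(n_cases = 5, n_controls = 5, n_markers = 10,
    penetrance_hom = 0, penetrance_het = 0, seed = 1, max_draws = 2000),
    "unreachable")
})

test_that("litters follow Mendelian expectation under the penetrance model", {
  lit <- simLitters(seed = 9)
  expect_equal(sum(lit$litters$size), 74)
  expect_equal(nrow(lit$litters), 11)
  expect_equal(lit$litters$affected + lit$litters$unaffected,
               lit$litters$size)
  big <- simLitters(n_litters = 40, litter_sizes = rep(100, 40),
                    penetrance_hom = 1, penetrance_het = 0, seed = 10)
  frac <- sum(big$litters$affected) / sum(big$litters$size)
  expect_lt(abs(frac - 0.25), 3.5 * sqrt(0.25 * 0.75 / 4000))
  none <- simLitters(penetrance_hom = 0, penetrance_het = 0, seed = 11)
  expect_equal(sum(none$litters$affected), 0)
})

test_that("simulated variant calls have the private/shared structure", {
  iv <- candidateInterval("13", 56170062, 56933573)
  sim <- simVariantCalls(iv, n_private_linked = 15, n_shared_common = 40,
                         missing_rate = 0, seed = 12)
  vs <- sim$vs
  keep <- panelExclude(groupCalls(vs, "panel"))
  keys <- paste(variantInfo(vs)$chrom, variantInfo(vs)$pos,
                variantInfo(vs)$ref, variantInfo(vs)$alt)
  expect_setequal(keys[keep], sim$truth$private_keys)
  expect_equal(sum(keep), 15)
  # no missing data, so nothing classifies ambiguous downstream
  cls <- classifyVariantSet(vs)
  expect_false(any(cls == "AMBIGUOUS"))
  # every shared variant has at least one panel carrier
  shared <- !keys %in% sim$truth$private_keys
  expect_true(all(rowSums(groupCalls(vs, "panel")[shared, ] >= 1) > 0))
  # the designated causal variant is an insertion
  ci <- match(sim$truth$causal_key, keys)
  expect_equal(variantInfo(vs)$vclass[ci], "INS")
  # without shared-common variants the panel step removes nothing
  sim0 <- simVariantCalls(iv, n_private_linked = 8, n_shared_common = 0,
                          missing_rate = 0, seed = 13)
  expect_true(all(panelExclude(groupCalls(sim0$vs, "panel"))))
})

test_that("exon counts have Poisson moments at dispersion zero", {
  sim <- simExonCounts(group_sizes = c(500, 500), planted_fc = c(M = 1),
                       dispersion = 0, seed = 14)
  counts <- SummarizedExperiment::assay(sim$ect, "counts")
  wt <- sampleGroups(sim$ect) == "wildtype"
  # library sizes vary by sample; standardize to a common scale first
  norm <- normalizeExon(sim$ect)[, wt]
  lens <- exonLengths(sim$ect)
  libs <- libSizes(sim$ect)[wt]
  for (e in seq_len(nrow(counts))) {
    x <- counts[e, wt]
    mu <- sim$truth$abundance[e] * lens[e] / 1e3 * libs / 1e6
    # variance of counts about their per-sample means ~ mean(mu)
    ratio <- mean((x - mu)^2) / mean(mu)
    expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
  }
})

test_that("null exon simulation yields fold changes near one", {
  sim <- simExonCounts(planted_fc = c(M = 1), dispersion = 0.1, seed = 15)
  fc <- exonFoldChange(sim$ect, "wildtype", "mutant")
  expect_true(all(fc$fold_change > 1 / 2 & fc$fold_change < 2))
})

test_that("promoter pairs are motif-free in ref with edits applied in alt", {
  sim <- simPromoterPair(ref_length = 1500, tss_ref_offset = 1400,
                         seed = 16)
  pair <- sim$pair
  expect_equal(nrow(scanMotif(refSeq(pair), soxConsensusMotif())), 0)
  expect_equal(applyEdits(refSeq(pair), pairEdits(pair)), altSeq(pair))
  edits <- pairEdits(pair)
  expect_equal(edits$type, c("INS", "SUB", "INS"))
  expect_equal(nchar(edits$alt_piece), c(9L, 2L, 14L))
  expect_equal(edits$ref_piece[2], "GC")
  expect_equal(edits$alt_piece[2], "TT")
  # the single alt hit sits inside the payload insertion span
  hits <- scanMotif(altSeq(pair), soxConsensusMotif())
  expect_equal(nrow(hits), 1)
  expect_gte(hits$start, sim$truth$planted_motif_span[1])
  expect_lte(hits$end, sim$truth$planted_motif_span[2])
})

test_that("an empty edit list leaves the alternate allele identical", {
  edits <- data.frame(ref_offset = integer(0), type = character(0),
                      ref_piece = character(0), alt_piece = character(0))
  pair <- promoterPair("ACGTACGTACGT", edits, 6)
  expect_equal(refSeq(pair), altSeq(pair))
  ds <- diffSites(pair, motifModel(iupac = "ACGT"))
  expect_equal(nrow(ds$gained), 0)
  expect_equal(nrow(ds$lost), 0)
})

test_that("the deterministic gene model sits inside its interval", {
  iv <- candidateInterval("13", 56170062, 56933573)
  gmod <- simGeneModel(iv, seed = 2)
  ex <- gmod$model@exons
  expect_true(all(ex$start >= intervalStart(iv) &
                  ex$end <= intervalEnd(iv)))
  expect_equal(nchar(gmod$cds_sequence) %% 3, 0)
})
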