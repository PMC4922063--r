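test_that("co-segregation classification follows the recessive trichotomy", {
  expect_equal(classifyCosegregation(c(2, 2, 2), c(0, 1, 0)), "CONSISTENT")
  expect_equal(classifyCosegregation(c(2, NA, 2), c(0, 1)), "AMBIGUOUS")
  expect_equal(classifyCosegregation(c(1, 2, 2), c(0, 0)), "INCONSISTENT")
  expect_equal(classifyCosegregation(c(2, 2), c(2, 0)), "INCONSISTENT")
  # carrier controls are tolerated unless strict mode demands hom-ref
  expect_equal(classifyCosegregation(c(2, 2), c(1, 1)), "CONSISTENT")
  expect_equal(classifyCosegregation(c(2, 2), c(1, 1),
                                     strict_controls = TRUE), "INCONSISTENT")
})

test_that("observing one more genotype can never rescue inconsistency", {
  set.seed(61)
  for (i in 1:300) {
    ca <- sample(c(0:2, NA), sample(1:4, 1), replace = TRUE)
    co <- sample(c(0:2, NA), sample(1:4, 1), replace = TRUE)
    before <- classifyCosegregation(ca, co)
    extra <- sample(c(0:2, NA), 1)
    after <- if (runif(1) < 0.5)
      classifyCosegregation(c(ca, extra), co)
    else classifyCosegregation(ca, c(co, extra))
    if (before == "INCONSISTENT") expect_equal(after, "INCONSISTENT")
    if (before == "CONSISTENT" && !is.na(extra))
      expect_true(after %in% c("CONSISTENT", "INCONSISTENT"))
  }
})

test_that("panel exclusion is an any-carrier rule and panel-monotone", {
  pc <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 2), c(NA, 0, 0))
  keep <- panelExclude(pc)
  expect_equal(keep, c(TRUE, FALSE, FALSE, TRUE))
  set.seed(62)
  for (i in 1:50) {
    base <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                          prob = c(.7, .1, .1, .1)), 10)
    extra <- matrix(sample(c(0:2, NA), 30, replace = TRUE,
                           prob = c(.7, .1, .1, .1)), 10)
    keep_small <- panelExclude(base)
    keep_big <- panelExclude(cbind(base, extra))
    # enlarging the panel never un-excludes a variant
    expect_true(all(keep_big <= keep_small))
  }
})

test_that("merging screening sources deduplicates by allele identity", {
  mk <- function(pos) data.frame(chrom = "13", pos = pos,
    ref = "C", alt = "A", stringsAsFactors = FALSE)
  a <- mk(seq(100, by = 10, length.out = 12))
  b <- mk(c(210, seq(300, by = 10, length.out = 14)))
  a <- rbind(a, mk(210))  # one shared key between the two sources
  merged <- mergeVariantSets(a, b, names = c("sanger", "reseq"))
  expect_equal(nrow(merged), 26)
  expect_equal(sum(merged$source == "sanger;reseq"), 1)
  expect_false(is.unsorted(merged$pos))
  # idempotence (a itself holds a duplicated key) and empty union
  expect_equal(nrow(mergeVariantSets(a, a)), length(unique(a$pos)))
  expect_equal(nrow(mergeVariantSets(a, a[0, ])), length(unique(a$pos)))
})

toy_plus_model <- function(cds) {
  n <- nchar(cds)
  geneModel("toy", "+", tss = 1001,
    exons = data.frame(exon_id = "E1", start = 1001, end = 1000 + n),
    cds_start = 1001, cds_end = 1000 + n)
}

test_that("coding SNPs annotate to the N106K-style protein label", {
  # codon 106 is AAC (Asn); C>A at its third base gives AAA (Lys)
  cds <- paste0(paste(rep("GCT", 105), collapse = ""), "AAC")
  model <- toy_plus_model(cds)
  v <- list(chrom = "13", pos = 1000 + 318, ref = "C", alt = "A",
            vclass = "SNP")
  ann <- annotateVariant(v, model, cds)
  expect_equal(ann$region, "CODING")
  expect_equal(ann$effect, "NONSYNONYMOUS")
  expect_equal(ann$label, "N106K")
  # wobble-position change: GGC -> GGT stays Gly
  cds2 <- paste0(paste(rep("GCT", 9), collapse = ""), "GGC",
                 paste(rep("GCT", 20), collapse = ""))
  model2 <- toy_plus_model(cds2)
  v2 <- list(chrom = "13", pos = 1000 + 30, ref = "C", alt = "T",
             vclass = "SNP")
  ann2 <- annotateVariant(v2, model2, cds2)
  expect_equal(ann2$effect, "SYNONYMOUS")
  expect_equal(ann2$label, "G10G")
})

test_that("every single-base coding change matches a translate oracle", {
  withr::with_seed(63, {
    cds <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                 collapse = "")
  })
  model <- toy_plus_model(cds)
  gc <- Biostrings::GENETIC_CODE
  translate_oracle <- function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(gc[codons], collapse = "")
  }
  ref_aa <- translate_oracle(cds)
  bases <- c("A", "C", "G", "T")
  for (off in 1:90) {
    refb <- substr(cds, off, off)
    for (altb in setdiff(bases, refb)) {
      mut <- cds
      substr(mut, off, off) <- altb
      alt_aa <- translate_oracle(mut)
      ann <- annotateVariant(list(chrom = "13", pos = 1000 + off,
        ref = refb, alt = altb, vclass = "SNP"), model, cds)
      codon_idx <- (off + 2) %/% 3
      if (ref_aa == alt_aa) {
        expect_equal(ann$effect, "SYNONYMOUS")
      } else {
        expect_equal(ann$effect, "NONSYNONYMOUS")
      }
      expect_equal(ann$label, paste0(substr(ref_aa, codon_idx, codon_idx),
        codon_idx, substr(alt_aa, codon_idx, codon_idx)))
    }
  }
})

test_that("minus-strand coding changes are complemented before translation", {
  # genomic CCCGGGTTTCAT on '-' carries sense CDS ATGAAACCCGGG
  cds <- "ATGAAACCCGGG"
  model <- geneModel("rev", "-", tss = 12,
    exons = data.frame(exon_id = "E1", start = 1, end = 12),
    cds_start = 1, cds_end = 12)
  ann <- annotateVariant(list(chrom = "1", pos = 12, ref = "T", alt = "C",
                              vclass = "SNP"), model, cds)
  expect_equal(ann$label, "M1V")
  expect_equal(ann$effect, "NONSYNONYMOUS")
})

test_that("region assignment covers promoter, splice, intron and indels", {
  model <- geneModel("g", "+", tss = 50000,
    exons = data.frame(exon_id = c("E1", "E2"),
      start = c(50000, 60000), end = c(50199, 60599)),
    cds_start = 60000, cds_end = 60599, promoter_length = 10000)
  cds <- paste(rep("GCT", 200), collapse = "")
  ann <- function(pos, ref = "C", alt = "A") {
    vclass <- variantClass(ref, alt)
    annotateVariant(list(chrom = "1", pos = pos, ref = ref, alt = alt,
                         vclass = vclass), model, cds)
  }
  expect_equal(ann(45000)$region, "PROMOTER")
  expect_equal(ann(39999)$region, "INTERGENIC")  # past the 10-kb window
  expect_equal(ann(50201)$region, "SPLICE_BOUNDARY")
  expect_equal(ann(55000)$region, "INTRON")
  expect_equal(ann(70000)$region, "INTERGENIC")
  # coding indels: frameshift vs in-frame by length mod 3
  fs <- ann(60010, "C", "CAT")
  expect_equal(fs$region, "CODING"); expect_equal(fs$effect, "frameshift")
  inf <- ann(60010, "C", "CATG")
  expect_equal(inf$effect, "in-frame")
})

test_that("ranking puts focus-promoter variants first, in a total order", {
  iv <- candidateInterval("13", 1000, 200000)
  classified <- data.frame(chrom = "13",
    pos = c(5000, seq(20000, by = 1000, length.out = 18),
            seq(100000, by = 500, length.out = 7)),
    ref = "C", alt = "A", vclass = "SNP",
    coseg_class = "CONSISTENT", private_to_cases = TRUE,
    region = c(rep("PROMOTER", 8), rep("INTRON", 10),
               rep("CODING", 4), rep("SPLICE_BOUNDARY", 4)),
    effect = NA_character_, label = NA_character_,
    stringsAsFactors = FALSE)
  classified$pos <- seq(2000, by = 1000, length.out = 26)
  classified$effect[classified$region == "CODING"] <- "NONSYNONYMOUS"
  ranked <- rankCandidates(classified, iv)
  expect_equal(nrow(ranked), 26)
  expect_true(all(ranked$region[1:8] == "PROMOTER"))
  expect_equal(ranked$region[9:12], rep("CODING", 4))
  expect_equal(ranked$region[13:16], rep("SPLICE_BOUNDARY", 4))
  # panel-carried and inconsistent variants never appear
  classified$private_to_cases[1] <- FALSE
  classified$coseg_class[2] <- "INCONSISTENT"
  ranked2 <- rankCandidates(classified, iv)
  expect_equal(nrow(ranked2), 24)
})

test_that("the cascade retains exactly the planted private set", {
  iv <- candidateInterval("13", 56170062, 56933573)
  gmod <- simGeneModel(iv, seed = 3)
  tss <- gmod$model@tss
  sim <- simVariantCalls(iv, missing_rate = 0, seed = 64,
    causal_pos = tss - 5000, avoid_span = c(tss - 10000, tss - 1))
  pri <- prioritizeVariants(sim$vs, iv, gmod$model, gmod$cds_sequence,
                            check_ref = FALSE)
  keys <- paste(pri$candidates$chrom, pri$candidates$pos,
                pri$candidates$ref, pri$candidates$alt)
  expect_setequal(keys, sim$truth$private_keys)
  expect_equal(keys[1], sim$truth$causal_key)
  expect_equal(unname(pri$counts["total"]), 65)
  expect_equal(unname(pri$counts["retained"]), 15)
  # with missing data, consistent-but-incomplete calls become ambiguous
  sim2 <- simVariantCalls(iv, missing_rate = 0.2, seed = 65)
  cls <- classifyVariantSet(sim2$vs)
  expect_gt(sum(cls == "AMBIGUOUS"), 0)
  expect_equal(sum(cls == "INCONSISTENT"), 0)
})
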