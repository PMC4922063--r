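test_that("VCF writer and reader are mutually inverse", {
  vs <- random_variant_set(50, 6)
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfVariants(vs, f)
  back <- readVcfVariants(f)
  expect_equal(variantInfo(back), variantInfo(vs))
  expect_equal(unname(variantCalls(back)), unname(variantCalls(vs)))
  expect_equal(back@samples, vs@samples)
})

test_that("VCF parsing maps GT codes, missing calls and multi-allelics", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("13", "56000000", ".", "C", "A", ".", ".", ".", "GT",
            "1/1", "0/1"), collapse = "\t"),
    paste(c("13", "56000010", "rs1", "G", "A,T", ".", ".", ".", "GT",
            "1/2", "./."), collapse = "\t")), f)
  vs <- readVcfVariants(f)
  info <- variantInfo(vs)
  expect_equal(nrow(info), 3)  # multi-allelic split into two records
  expect_equal(info$pos, c(56000000, 56000010, 56000010))
  expect_equal(info$alt, c("A", "A", "T"))
  expect_equal(info$vclass, rep("SNP", 3))
  calls <- variantCalls(vs)
  expect_equal(unname(calls[1, ]), c(2L, 1L))
  expect_equal(unname(calls[2, ]), c(1L, NA))   # one copy of allele 1
  expect_equal(unname(calls[3, ]), c(1L, NA))   # one copy of allele 2
})

test_that("malformed VCF records are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    paste(c("13", "100", ".", "C", "A", ".", ".", ".", "GT", "0/0"),
          collapse = "\t"),
    "13\t200\tbroken"), f)
  expect_error(readVcfVariants(f), "line 4")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S1"), collapse = "\t"),
    paste(c("13", "notanumber", ".", "C", "A", ".", ".", ".", "GT",
            "0/0"), collapse = "\t")), f2)
  expect_error(readVcfVariants(f2), "POS")
})

random_gm <- function(n, m, seed = 5) {
  withr::with_seed(seed, {
    calls <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                           prob = c(.4, .3, .2, .1)), n, m)
    markers <- data.frame(id = paste0("mk", seq_len(m)), chrom = "13",
      pos = sort(sample(1e7, m)),
      alleleA = sample(c("A", "C"), m, replace = TRUE),
      alleleB = sample(c("G", "T"), m, replace = TRUE),
      stringsAsFactors = FALSE)
    genotypeMatrix(calls, markers, paste0("S", seq_len(n)))
  })
}

test_that("genotype matrix TSV dialect round-trips a 100 x 500 matrix", {
  gm <- random_gm(100, 500)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeMatrix(gm, f, "tsv")
  back <- readGenotypeMatrix(f, "tsv")
  expect_equal(genotypeCalls(back), genotypeCalls(gm))
  expect_equal(markerInfo(back), markerInfo(gm))
  expect_equal(sampleIDs(back), sampleIDs(gm))
})

test_that("genotype matrix PED/MAP dialect round-trips", {
  gm <- random_gm(20, 50, seed = 6)
  prefix <- file.path(withr::local_tempdir(), "geno")
  writeGenotypeMatrix(gm, prefix, "pedmap")
  back <- readGenotypeMatrix(prefix, "pedmap")
  expect_equal(genotypeCalls(back), genotypeCalls(gm))
  expect_equal(markerInfo(back)$alleleB, markerInfo(gm)$alleleB)
})

test_that("PED heterozygote codes count copies of the declared alleleB", {
  dir <- withr::local_tempdir()
  writeLines("1\tmk1\t0\t100\tA\tG", file.path(dir, "p.map"))
  writeLines(c("FAM S1 0 0 0 0 A G",
               "FAM S2 0 0 0 0 G G",
               "FAM S3 0 0 0 0 0 0"), file.path(dir, "p.ped"))
  gm <- readGenotypeMatrix(file.path(dir, "p"), "pedmap")
  expect_equal(unname(genotypeCalls(gm)[, 1]), c(1L, 2L, NA))
})

test_that("ragged rows and unknown allele symbols are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tmk1\tmk2", "S1\t0\t1", "S2\t2"),
             file.path(dir, "g.tsv"))
  writeLines(c("1\tmk1\t0\t100\tA\tG", "1\tmk2\t0\t200\tA\tG"),
             file.path(dir, "g.tsv.map"))
  expect_error(readGenotypeMatrix(file.path(dir, "g.tsv"), "tsv"), "ragged")
  writeLines("1\tmk1\t0\t100\tA\tG", file.path(dir, "q.map"))
  writeLines("FAM S1 0 0 0 0 A T", file.path(dir, "q.ped"))
  expect_error(readGenotypeMatrix(file.path(dir, "q"), "pedmap"),
               "unknown allele")
})

test_that("BED output is 0-based half-open and round-trips", {
  iv <- candidateInterval("13", 56170062, 56933573)
  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(iv, f)
  expect_equal(readLines(f), "13\t56170061\t56933573")
  back <- readBedIntervals(f)[[1]]
  expect_equal(intervalStart(back), 56170062)
  expect_equal(intervalEnd(back), 56933573)
  expect_equal(lengthKb(back), 763)
  writeBed(list(), f)
  expect_equal(length(readLines(f)), 0)
})

test_that("exon count tables round-trip through annotated TSV", {
  sim <- simExonCounts(seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExonCountTable(sim$ect, f)
  back <- readExonCountTable(f)
  expect_equal(SummarizedExperiment::assay(back, "counts"),
               SummarizedExperiment::assay(sim$ect, "counts"),
               ignore_attr = TRUE)
  expect_equal(exonLengths(back), exonLengths(sim$ect))
  expect_equal(libSizes(back), libSizes(sim$ect))
  expect_equal(sampleGroups(back), sampleGroups(sim$ect))
})

test_that("phenotype tables validate status labels and round-trip", {
  phen <- phenotypeTable(c("a", "b", "c"),
                         c("AFFECTED", "UNAFFECTED", "UNKNOWN"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePhenotypeTable(phen, f)
  expect_equal(readPhenotypeTable(f), phen)
  expect_error(phenotypeTable("a", "SICK"), "unknown phenotype")
})

test_that("variant class derivation and invariants are enforced", {
  expect_equal(variantClass("C", "A"), "SNP")
  expect_equal(variantClass("C", "CTTAG"), "INS")
  expect_equal(variantClass("CTTAG", "C"), "DEL")
  expect_error(variantClass("CT", "AG"), "unsupported")
  expect_error(variantSet(data.frame(chrom = "1", pos = 10, ref = "C",
    alt = "C"), matrix(0L, 1, 1)))
})
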