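sox <- soxConsensusMotif()

test_that("IUPAC scanning finds degenerate matches on both strands", {
  seq <- paste0("GGGG", "AACAAAG", "GGGG")
  hits <- scanMotif(seq, sox)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5)
  expect_equal(hits$strand, "+")
  expect_equal(hits$match, "AACAAAG")
  # the reverse-complement payload is a minus-strand site
  seqm <- paste0("GGGG", "CTTTGTT", "GGGG")
  hm <- scanMotif(seqm, sox)
  expect_equal(nrow(hm), 1)
  expect_equal(hm$strand, "-")
  expect_equal(hm$match, "AACAAAG")
  # a pattern longer than the sequence yields no hits
  expect_equal(nrow(scanMotif("ACG", sox)), 0)
})

test_that("the scanner agrees with a naive position-by-position oracle", {
  withr::with_seed(81, {
    for (i in 1:30) {
      seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
      mine <- scanMotif(seq, sox)
      oracle <- naive_motif_scan(seq, "WWCAAWG")
      expect_equal(nrow(mine), nrow(oracle))
      expect_setequal(paste(mine$start, mine$strand),
                      paste(oracle$start, oracle$strand))
    }
  })
})

test_that("self-concatenation doubles hits up to junction windows", {
  withr::with_seed(82, {
    for (i in 1:10) {
      seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
      h1 <- nrow(scanMotif(seq, sox))
      h2 <- nrow(scanMotif(paste0(seq, seq), sox))
      expect_gte(h2, 2 * h1)
      expect_lte(h2, 2 * h1 + (motifLength(sox) - 1))
    }
  })
})

test_that("minus-strand scanning equals forward scan of the complement", {
  withr::with_seed(83, {
    seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd_on_rc <- scanMotif(rc, sox, strands = "+")
  minus <- scanMotif(seq, sox, strands = "-")
  # positions mirror: start_rc = len - end + 1
  expect_setequal(fwd_on_rc$start, nchar(seq) - minus$end + 1)
  expect_equal(sort(fwd_on_rc$match), sort(minus$match))
})

test_that("PWM scanning reproduces exact matching at a strict threshold", {
  pat <- "ACGTAC"
  pwm <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:6) pwm[substr(pat, k, k), k] <- 1
  model <- motifModel(pwm = pwm, threshold = 6)
  withr::with_seed(84, {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  })
  hits <- scanMotif(seq, model, strands = "+")
  lit <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq))
  expect_setequal(hits$start, Biostrings::start(lit))
  expect_true(all(hits$score == 6))
  # relaxing the threshold admits 1-mismatch windows
  near <- scanMotif(seq, motifModel(pwm = pwm, threshold = 5),
                    strands = "+")
  mm1 <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                  max.mismatch = 1)
  expect_setequal(near$start, Biostrings::start(mm1))
})

test_that("coordinate projection shifts by indel lengths and round-trips", {
  edits <- data.frame(ref_offset = c(50, 120), type = c("INS", "INS"),
    ref_piece = c("", ""), alt_piece = c("AAAAAAAAA", "CCCCCCCCCCCCCC"),
    stringsAsFactors = FALSE)
  expect_equal(projectRefToAlt(10, edits), 10L)      # left of all edits
  expect_equal(projectRefToAlt(130, edits), 130L + 9L + 14L)
  expect_equal(projectAltToRef(55, edits), NA_integer_)  # inside the INS
  # random edit lists: ref -> alt -> ref is the identity where mappable
  withr::with_seed(85, {
    for (i in 1:20) {
      offs <- sort(sample(seq(10, 180, by = 12), 4))
      types <- sample(c("INS", "SUB", "DEL"), 4, replace = TRUE)
      ref <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                   collapse = "")
      ed <- do.call(rbind, lapply(seq_along(offs), function(k) {
        if (types[k] == "INS")
          data.frame(ref_offset = offs[k], type = "INS", ref_piece = "",
            alt_piece = paste(sample(c("A", "C", "G", "T"),
              sample(1:6, 1), replace = TRUE), collapse = ""))
        else if (types[k] == "SUB")
          data.frame(ref_offset = offs[k], type = "SUB",
            ref_piece = substr(ref, offs[k], offs[k] + 1),
            alt_piece = paste(sample(c("A", "C", "G", "T"), 2,
                                     replace = TRUE), collapse = ""))
        else
          data.frame(ref_offset = offs[k], type = "DEL",
            ref_piece = substr(ref, offs[k], offs[k] + 2), alt_piece = "")
      }))
      for (p in seq_len(200)) {
        pa <- projectRefToAlt(p, ed)
        if (!is.na(pa)) expect_equal(projectAltToRef(pa, ed), p)
      }
    }
  })
})

test_that("gained and lost sites equal a projection-matched set difference", {
  sim <- simPromoterPair(ref_length = 1500, tss_ref_offset = 1400,
                         seed = 86)
  pair <- sim$pair
  ds <- diffSites(pair, sox)
  # oracle: naive scans of both alleles matched through the projection
  rh <- naive_motif_scan(refSeq(pair), "WWCAAWG")
  ah <- naive_motif_scan(altSeq(pair), "WWCAAWG")
  proj <- projectAltToRef(ah$start, pairEdits(pair))
  gained_oracle <- ah[is.na(proj) |
    !(paste(proj, ah$strand) %in% paste(rh$start, rh$strand)), ]
  expect_equal(nrow(ds$gained), nrow(gained_oracle))
  expect_setequal(paste(ds$gained$start, ds$gained$strand),
                  paste(gained_oracle$start, gained_oracle$strand))
  expect_equal(nrow(ds$lost), 0)
  # the single gained site overlaps the payload (third) edit
  expect_equal(ds$gained$edits, "3")
})

test_that("diffSites of a sequence against itself is empty", {
  withr::with_seed(87, {
    seq <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                 collapse = "")
  })
  edits <- data.frame(ref_offset = integer(0), type = character(0),
                      ref_piece = character(0), alt_piece = character(0))
  ds <- diffSites(promoterPair(seq, edits, 700), sox)
  expect_equal(nrow(ds$gained), 0)
  expect_equal(nrow(ds$lost), 0)
})

test_that("deleting the mutation cluster restores the reference prediction", {
  sim <- simPromoterPair(seed = 88)
  pair <- sim$pair
  sp <- semiRecMap:::editSpans(pairEdits(pair))
  lo <- min(sp$alt_lo) - 7
  region <- c(lo, lo + 95)  # 96-bp span covering all three edits
  dt <- deletionTest(pair, region, sox)
  expect_true(dt$restored)
  expect_equal(nrow(dt$gained), 0)
  # deleting a span far from any gained hit changes nothing
  far <- deletionTest(pair, c(1000, 1095), sox)
  expect_false(far$restored)
  expect_equal(nrow(far$gained), 1)
  # deleting exactly the 14-bp payload insertion alone also restores
  payload <- c(sp$alt_lo[3], sp$alt_hi[3])
  expect_true(deletionTest(pair, payload, sox)$restored)
})

test_that("TSS-relative coordinates skip zero and preserve order", {
  expect_equal(tssRelative(7900 - 7532, 7900), -7532)
  expect_equal(tssRelative(7900, 7900), 1)
  expect_equal(tssRelative(7899, 7900), -1)
  pos <- 7890:7910
  rel <- tssRelative(pos, 7900)
  expect_true(all(diff(rel) >= 1))
  expect_false(0 %in% rel)
})

test_that("motif model text IO handles both dialects", {
  f <- withr::local_tempfile()
  writeLines("WWCAAWG", f)
  m <- readMotifModel(f)
  expect_equal(m@type, "iupac")
  expect_equal(m@pattern, "WWCAAWG")
  f2 <- withr::local_tempfile()
  writeLines(c("#threshold 3.5",
               "A 1 0 0 1", "C 0 1 0 0", "G 0 0 1 0", "T 0 0 0 0"), f2)
  m2 <- readMotifModel(f2)
  expect_equal(m2@type, "pwm")
  expect_equal(m2@threshold, 3.5)
  expect_equal(unname(m2@pwm["A", ]), c(1, 0, 0, 1))
})
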