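## Synthetic cohorts, litters, variant calls, exon counts and promoter
## allele pairs with the statistical structure the analysis assumes.
## Every generator takes one integer seed, is bit-reproducible, and
## returns the planted truth alongside the data.
##
## Linkage disequilibrium is induced by a small founder-haplotype pool:
## each transmitted haplotype is a founder mosaic with a uniform per-marker
## switch probability, which creates the multi-marker concordant block the
## haplotype stage must find without an explicit recombination map.

drawMosaicHaplotypes <- function(n_hap, founders, switch_rate, weights) {
  M <- ncol(founders); nf <- nrow(founders)
  path <- matrix(0L, n_hap, M)
  path[, 1] <- sample.int(nf, n_hap, replace = TRUE, prob = weights)
  if (M > 1) {
    sw <- matrix(runif(n_hap * (M - 1)) < switch_rate, n_hap, M - 1)
    for (m in 2:M) {
      new <- sample.int(nf, n_hap, replace = TRUE, prob = weights)
      path[, m] <- ifelse(sw[, m - 1], new, path[, m - 1])
    }
  }
  matrix(founders[cbind(as.vector(path), rep(seq_len(M), each = n_hap))],
         n_hap, M)
}

#' Simulate a case/control cohort segregating a semi-recessive locus
#'
#' Individuals carry two founder-mosaic haplotypes drawn from a pool of
#' `founder_haplotypes` founders (uniform switch probability per marker);
#' the risk allele at the causal marker is carried by founder 1 only, so
#' the causal genotype marks founder-1 homozygosity and nearby markers are
#' in LD with it. Phenotype is sampled from the genotype at the causal
#' marker with the stated penetrances (hom 1.0 and het 4/51 by default,
#' the semi-recessive observation the model emulates); individuals are
#' drawn by rejection sampling until the case/control quotas are met, and
#' calls are masked missing independently at `missing_rate`.
#'
#' The risk founder haplotype is drawn with weight `risk_hap_freq`
#' (default 0.5) and the remaining founders share the rest uniformly:
#' a single ancestral risk haplotype segregating at high frequency, which
#' reproduces the mapping-population composition of roughly 24 risk
#' homozygotes, 51 heterozygotes (~4 of them affected) and 26 protective
#' homozygotes in a 28/73 cohort.
#'
#' @param n_cases,n_controls cohort quotas (defaults 28 and 73).
#' @param n_markers markers on one chromosome.
#' @param causal_index marker index of the causal locus.
#' @param founder_haplotypes founder-pool size (default 8).
#' @param risk_hap_freq sampling weight of the risk founder haplotype
#'   (default 0.5).
#' @param penetrance_hom,penetrance_het P(affected | genotype).
#' @param missing_rate per-call missing probability (default 0.02).
#' @param seed integer seed.
#' @param switch_rate per-marker founder-switch probability (default 0.01).
#' @param chrom chromosome name.
#' @param pos_start,pos_step marker positions (bp).
#' @param max_draws rejection-sampling bound; an unreachable quota (e.g.
#'   `penetrance_hom = 0` with cases requested) fails explicitly.
#' @return list: gm ([GenotypeMatrix-class]), phenotype (named factor),
#'   truth (causal_marker_index, causal_pos, penetrances, seed).
#' @export
simCohort <- function(n_cases = 28, n_controls = 73, n_markers = 2000,
                      causal_index = n_markers %/% 2,
                      founder_haplotypes = 8, risk_hap_freq = 0.5,
                      penetrance_hom = 1.0,
                      penetrance_het = 4 / 51, missing_rate = 0.02,
                      seed = 1, switch_rate = 0.01, chrom = "13",
                      pos_start = 50000000, pos_step = 10000,
                      max_draws = 200000) {
  stopifnot(founder_haplotypes >= 2, causal_index >= 1,
            causal_index <= n_markers)
  withr::with_seed(seed, {
    freq <- runif(n_markers, 0.2, 0.8)
    founders <- matrix(rbinom(founder_haplotypes * n_markers, 1,
      rep(freq, each = founder_haplotypes)), founder_haplotypes, n_markers)
    founders[, causal_index] <- 0L
    founders[1, causal_index] <- 1L
    weights <- c(risk_hap_freq,
                 rep((1 - risk_hap_freq) / (founder_haplotypes - 1),
                     founder_haplotypes - 1))
    pen <- c(0, penetrance_het, penetrance_hom)
    cases <- list(); controls <- list()
    drawn <- 0L
    batch <- 256L
    # unconditional tallies over every drawn individual (before the
    # case/control quota filter), e.g. to verify penetrance calibration
    n_het_drawn <- 0L; n_het_affected <- 0L
    n_hom_drawn <- 0L; n_hom_affected <- 0L
    while ((length(cases) < n_cases || length(controls) < n_controls)) {
      if (drawn >= max_draws)
        stop("case/control quota unreachable after ", drawn,
             " draws (check penetrances)")
      hap <- drawMosaicHaplotypes(2L * batch, founders, switch_rate,
                                  weights)
      geno <- hap[seq(1, 2 * batch, 2), ] + hap[seq(2, 2 * batch, 2), ]
      g <- geno[, causal_index]
      affected <- runif(batch) < pen[g + 1L]
      n_het_drawn <- n_het_drawn + sum(g == 1L)
      n_het_affected <- n_het_affected + sum(g == 1L & affected)
      n_hom_drawn <- n_hom_drawn + sum(g == 2L)
      n_hom_affected <- n_hom_affected + sum(g == 2L & affected)
      for (i in seq_len(batch)) {
        if (affected[i] && length(cases) < n_cases)
          cases[[length(cases) + 1L]] <- geno[i, ]
        else if (!affected[i] && length(controls) < n_controls)
          controls[[length(controls) + 1L]] <- geno[i, ]
      }
      drawn <- drawn + batch
    }
    calls <- do.call(rbind, c(cases, controls))
    storage.mode(calls) <- "integer"
    if (missing_rate > 0) {
      mask <- matrix(runif(length(calls)) < missing_rate, nrow(calls))
      calls[mask] <- NA_integer_
    }
    ids <- c(sprintf("case%02d", seq_len(n_cases)),
             sprintf("ctrl%02d", seq_len(n_controls)))
    markers <- data.frame(id = sprintf("M%05d", seq_len(n_markers)),
      chrom = chrom, pos = pos_start + (seq_len(n_markers) - 1) * pos_step,
      alleleA = "A", alleleB = "G", stringsAsFactors = FALSE)
    gm <- genotypeMatrix(calls, markers, ids)
    phen <- phenotypeTable(ids, rep(c("AFFECTED", "UNAFFECTED"),
                                    c(n_cases, n_controls)))
    truth <- list(causal_marker_index = causal_index,
      causal_pos = markers$pos[causal_index],
      penetrance_hom = penetrance_hom, penetrance_het = penetrance_het,
      founder_freq = freq, seed = seed,
      draw_stats = c(n_het_drawn = n_het_drawn,
                     n_het_affected = n_het_affected,
                     n_hom_drawn = n_hom_drawn,
                     n_hom_affected = n_hom_affected))
    list(gm = gm, phenotype = phen, truth = truth)
  })
}

#' Simulate litters from carrier x carrier matings
#'
#' Offspring genotypes are Mendelian 1:2:1 from heterozygote x
#' heterozygote matings; affection is sampled per genotype class with the
#' stated penetrances.
#'
#' @param n_litters number of litters (default 11).
#' @param litter_sizes integer sizes; the default splits 74 offspring over
#'   11 litters.
#' @param penetrance_hom,penetrance_het per-genotype penetrance.
#' @param seed integer seed.
#' @return list: litters (data.frame litter, size, affected, unaffected),
#'   truth.
#' @export
simLitters <- function(n_litters = 11,
                       litter_sizes = rep(c(7, 6), c(8, 3)),
                       penetrance_hom = 1.0, penetrance_het = 4 / 51,
                       seed = 1) {
  stopifnot(length(litter_sizes) == n_litters, all(litter_sizes > 0))
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_litters), function(i) {
      n <- litter_sizes[i]
      g <- sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4)
      pen <- c(0, penetrance_het, penetrance_hom)
      aff <- sum(runif(n) < pen[g + 1L])
      data.frame(litter = i, size = n, affected = aff,
                 unaffected = n - aff)
    })
    litters <- do.call(rbind, out)
    list(litters = litters,
         truth = list(penetrance_hom = penetrance_hom,
                      penetrance_het = penetrance_het, seed = seed))
  })
}

#' Simulate re-sequencing variant calls for cases, controls and a panel
#'
#' Private-linked variants are homozygous-alternate in every case, absent
#' from every control and every panel individual (the variants "carried
#' exclusively" by the affected line); shared-common variants co-segregate
#' in the small case/control panel but carry alternate alleles in at least
#' one population-panel individual, so only the panel step removes them.
#' One designated causal insertion sits among the private set (placed at
#' `causal_pos` when given, e.g. inside a promoter window); the remaining
#' private variants avoid `avoid_span`. Missingness applies to case and
#' control calls only.
#'
#' @param interval a [CandidateInterval-class] to place variants in.
#' @param n_private_linked,n_shared_common variant counts (defaults 15 and
#'   50).
#' @param n_cases,n_controls,panel_size group sizes (defaults 3, 3, 103).
#' @param missing_rate per-call missing probability for case/control calls.
#' @param seed integer seed.
#' @param causal_pos optional 1-based position for the causal insertion.
#' @param avoid_span optional c(start, end): non-causal variants are kept
#'   out of this span (used to keep the focus promoter private to the
#'   causal insertion).
#' @return list: vs ([VariantSet-class] with case/control/panel groups),
#'   truth (private_keys, causal_key, seed).
#' @export
simVariantCalls <- function(interval, n_private_linked = 15,
                            n_shared_common = 50, n_cases = 3,
                            n_controls = 3, panel_size = 103,
                            missing_rate = 0, seed = 1, causal_pos = NULL,
                            avoid_span = NULL) {
  withr::with_seed(seed, {
    s <- intervalStart(interval); e <- intervalEnd(interval)
    n_total <- n_private_linked + n_shared_common
    pool <- s:e
    if (!is.null(avoid_span))
      pool <- pool[pool < avoid_span[1] | pool > avoid_span[2]]
    pool <- setdiff(pool, causal_pos)
    pos <- sort(sample(pool, n_total - !is.null(causal_pos)))
    if (!is.null(causal_pos)) pos <- sort(c(pos, causal_pos))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    is_private <- rep(FALSE, n_total)
    priv_idx <- if (!is.null(causal_pos)) {
      ci <- which(pos == causal_pos)[1]
      c(ci, sample(setdiff(seq_len(n_total), ci), n_private_linked - 1))
    } else sample(seq_len(n_total), n_private_linked)
    is_private[priv_idx] <- TRUE
    causal_i <- if (!is.null(causal_pos)) which(pos == causal_pos)[1] else
      sample(which(is_private), 1)
    # the causal variant is an insertion (anchored-base convention)
    alt[causal_i] <- paste0(ref[causal_i],
      paste(sample(bases, 14, replace = TRUE), collapse = ""))
    calls <- matrix(0L, n_total, n_cases + n_controls + panel_size)
    calls[, seq_len(n_cases)] <- 2L
    shared <- which(!is_private)
    for (i in shared) {
      f <- runif(1, 0.05, 0.5)
      pg <- rbinom(panel_size, 2, f)
      if (all(pg == 0)) pg[sample.int(panel_size, 1)] <- 1L
      calls[i, n_cases + n_controls + seq_len(panel_size)] <- pg
    }
    if (missing_rate > 0) {
      cc <- seq_len(n_cases + n_controls)
      mask <- matrix(runif(n_total * length(cc)) < missing_rate, n_total)
      block <- calls[, cc]; block[mask] <- NA_integer_
      calls[, cc] <- block
    }
    info <- data.frame(chrom = intervalChrom(interval), pos = pos,
      ref = ref, alt = alt, stringsAsFactors = FALSE)
    groups <- rep(c("case", "control", "panel"),
                  c(n_cases, n_controls, panel_size))
    samples <- c(sprintf("case%d", seq_len(n_cases)),
                 sprintf("ctrl%d", seq_len(n_controls)),
                 sprintf("panel%03d", seq_len(panel_size)))
    vs <- variantSet(info, calls, samples = samples, groups = groups)
    key <- paste(info$chrom, info$pos, info$ref, info$alt)
    list(vs = vs,
         truth = list(private_keys = key[is_private],
                      causal_key = key[causal_i],
                      causal_pos = pos[causal_i], seed = seed))
  })
}

#' A multi-promoter gene exon table for expression simulation
#'
#' Two isoform-specific first exons (M and A, each driven by its own
#' promoter) plus shared downstream exons, mirroring a gene whose
#' melanocyte isoform can be silenced while gene-level expression barely
#' moves.
#' @return data.frame: exon_id, length, isoform.
#' @export
multiPromoterExonModel <- function() {
  data.frame(
    exon_id = c("M", "A", paste0("E", 2:9)),
    length = c(200, 180, 150, 120, 90, 210, 160, 140, 110, 1300),
    isoform = c("M", "A", rep("shared", 8)),
    stringsAsFactors = FALSE)
}

#' Simulate per-exon read counts with planted fold changes
#'
#' Counts are negative-binomial with mean proportional to exon length x
#' library size x a per-exon abundance; the second group's mean is divided
#' by the planted fold change for flagged exons. The NB is parameterized
#' by mean m and variance m + dispersion * m^2 (dispersion 0 gives
#' Poisson).
#'
#' @param exon_model data.frame with exon_id, length, isoform (default
#'   [multiPromoterExonModel]).
#' @param group_sizes length-2 integer (default 3 vs 3).
#' @param planted_fc named numeric of fold changes per exon id (missing
#'   exons default to 1; values > 1 mean loss in the second group).
#' @param dispersion NB dispersion (default 0.1).
#' @param mean_depth mean library size (default 1e6).
#' @param seed integer seed.
#' @param group_labels labels for the two groups.
#' @return list: ect ([ExonCountTable-class]), truth (planted_fc,
#'   abundance, seed).
#' @export
simExonCounts <- function(exon_model = multiPromoterExonModel(),
                          group_sizes = c(3, 3), planted_fc = c(M = 11.5),
                          dispersion = 0.1, mean_depth = 1e6, seed = 1,
                          group_labels = c("wildtype", "mutant")) {
  stopifnot(all(exon_model$length > 0), dispersion >= 0,
            all(planted_fc > 0))
  withr::with_seed(seed, {
    nE <- nrow(exon_model)
    nS <- sum(group_sizes)
    fc <- setNames(rep(1, nE), exon_model$exon_id)
    fc[names(planted_fc)] <- planted_fc
    abundance <- runif(nE, 50, 500)   # RPKM-scale baseline per exon
    libs <- round(mean_depth * runif(nS, 0.8, 1.2))
    groups <- rep(group_labels, group_sizes)
    mu <- outer(abundance * exon_model$length / 1e3, libs / 1e6)
    mu[, groups == group_labels[2]] <-
      mu[, groups == group_labels[2]] / fc
    counts <- if (dispersion == 0)
      matrix(rpois(nE * nS, mu), nE, nS)
    else
      matrix(rnbinom(nE * nS, mu = mu, size = 1 / dispersion), nE, nS)
    ect <- exonCountTable(counts, exon_model, groups, libs)
    list(ect = ect, truth = list(planted_fc = fc, abundance = abundance,
                                 dispersion = dispersion, seed = seed))
  })
}

#' Default promoter edit structure: two insertions and a dinucleotide SUB
#'
#' A 9-bp insertion, a GC>TT substitution and a 14-bp insertion whose
#' payload carries the SOX consensus — the mutation structure of the
#' silenced promoter allele. The payload slot (`sequence = NA`) receives
#' `motif_payload` in [simPromoterPair].
#' @return data.frame: ref_offset, type, sequence, ref_piece.
#' @export
defaultPromoterEdits <- function() {
  data.frame(ref_offset = c(300, 330, 360),
    type = c("INS", "SUB", "INS"),
    sequence = c("CCGGCGGCC", "TT", NA),
    ref_piece = c(NA, "GC", NA), stringsAsFactors = FALSE)
}

#' Simulate a promoter allele pair with a planted de-novo motif site
#'
#' The reference sequence is drawn with uniform base composition and
#' rejected-and-resampled until it is motif-free and until the edited
#' alternate allele's only motif hit lies inside the payload insertion, so
#' the "gained site" count has the unambiguous expected value 1. Edits are
#' applied left-to-right; substitution edits may force the reference
#' content of their span (`ref_piece`) so that e.g. a GC>TT replacement is
#' reproduced literally.
#'
#' @param ref_length reference length in bp (default 8000, a ~8-kb
#'   promoter fragment with the TSS near its right end).
#' @param edits edit table as in [defaultPromoterEdits]; the `sequence =
#'   NA` insertion receives the payload.
#' @param motif_payload inserted sequence carrying one motif match
#'   (default 14 bp around the SOX consensus core).
#' @param motif the [MotifModel-class] defining "motif-free" (default
#'   [soxConsensusMotif]).
#' @param tss_ref_offset TSS position in ref coordinates (default
#'   ref_length - 100).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling bound.
#' @return list: pair ([PromoterPair-class]), truth (planted_motif_span in
#'   alt coordinates, payload, seed).
#' @export
simPromoterPair <- function(ref_length = 8000,
                            edits = defaultPromoterEdits(),
                            motif_payload = "GCTAACAAAGTTGC",
                            motif = soxConsensusMotif(),
                            tss_ref_offset = ref_length - 100, seed = 1,
                            max_attempts = 20000) {
  payload_row <- which(is.na(edits$sequence) & edits$type == "INS")
  if (length(payload_row)) edits$sequence[payload_row[1]] <- motif_payload
  stopifnot(all(edits$ref_offset <= ref_length))
  full <- data.frame(ref_offset = edits$ref_offset, type = edits$type,
    ref_piece = ifelse(edits$type == "INS", "",
                       ifelse(is.na(edits$ref_piece),
                              edits$sequence, edits$ref_piece)),
    alt_piece = ifelse(edits$type == "DEL", "", edits$sequence),
    stringsAsFactors = FALSE)
  payload_hits <- nrow(scanMotif(motif_payload, motif))
  bases <- c("A", "C", "G", "T")
  # fast integer-coded motif presence check (IUPAC consensus); PWM models
  # fall back to the full scanner
  fastStarts <- if (motif@type == "iupac") {
    pats <- c(motif@pattern, revcomp(motif@pattern))
    Lm <- motifLength(motif)
    allow <- lapply(pats, function(p)
      lapply(strsplit(p, "")[[1]],
             function(ch) bases %in% IUPAC_SETS[[ch]]))
    function(ic) {
      n <- length(ic)
      starts <- integer(0)
      for (al in allow) {
        ok <- rep(TRUE, n - Lm + 1L)
        for (k in seq_len(Lm)) ok <- ok & al[[k]][ic[k:(n - Lm + k)]]
        starts <- c(starts, which(ok))
      }
      cbind(start = starts, end = starts + Lm - 1L)
    }
  } else function(ic) {
    h <- scanMotif(paste(bases[ic], collapse = ""), motif)
    cbind(start = h$start, end = h$end)
  }
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      ic <- sample.int(4L, ref_length, replace = TRUE)
      # force declared ref content under SUB/DEL edits
      for (i in which(full$type != "INS")) {
        span_i <- full$ref_offset[i] +
          seq_len(nchar(full$ref_piece[i])) - 1L
        ic[span_i] <- match(strsplit(full$ref_piece[i], "")[[1]], bases)
      }
      if (nrow(fastStarts(ic)) > 0) next
      ref <- paste(bases[ic], collapse = "")
      alt <- applyEdits(ref, full)
      ah <- fastStarts(match(strsplit(alt, "")[[1]], bases))
      if (nrow(ah) != payload_hits) next
      sp <- editSpans(full)
      pr <- payload_row[1]
      span <- c(sp$alt_lo[pr], sp$alt_hi[pr])
      if (any(ah[, "start"] < span[1] | ah[, "end"] > span[2])) next
      pair <- promoterPair(ref, full, tss_ref_offset, alt)
      return(list(pair = pair,
        truth = list(planted_motif_span = span, payload = motif_payload,
                     attempts = attempt, seed = seed)))
    }
    stop("could not draw a motif-free reference in ", max_attempts,
         " attempts")
  })
}

#' Deterministic gene model inside a candidate interval
#'
#' Places a plus-strand gene with an isoform-specific first exon (M) and
#' four downstream coding exons inside the interval, with a 10-kb promoter
#' window upstream of the TSS, and draws a random CDS consistent with the
#' coding-exon lengths. Used to exercise annotation and ranking on
#' simulated variant calls.
#'
#' @param interval a [CandidateInterval-class].
#' @param seed integer seed for the CDS draw.
#' @param promoter_length promoter window (default 10000 bp).
#' @return list: model ([GeneModel-class]), cds_sequence.
#' @export
simGeneModel <- function(interval, seed = 1, promoter_length = 10000) {
  s <- intervalStart(interval); e <- intervalEnd(interval)
  tss <- round(s + 0.6 * (e - s))
  stopifnot(tss - promoter_length > s, tss + 12000 < e)
  coding_starts <- tss + 3000 + (0:3) * 2000
  exons <- data.frame(
    exon_id = c("M", paste0("E", 2:5)),
    start = c(tss, coding_starts),
    end = c(tss + 199, coding_starts + 149))
  model <- geneModel("simgene", "+", tss, exons,
    cds_start = coding_starts[1], cds_end = coding_starts[4] + 149,
    promoter_length = promoter_length,
    isoform_first_exons = c(M = "M"))
  cds <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
          collapse = ""))
  list(model = model, cds_sequence = cds)
}
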