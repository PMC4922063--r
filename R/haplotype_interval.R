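## Haplotype-concordance mapping: find marker windows whose homozygote
## classes perfectly separate phenotype under a semi-recessive model, score
## them by permutation, and define the recombinant-bounded candidate
## interval.
##
## No statistical phasing is performed: haplotypes are read directly from
## window-homozygotes (samples homozygous at every marker of the window);
## heterozygous samples contribute only penetrance counts.

# per-sample window summaries for one chromosome and one window size
# returns matrices/vectors over window starts
windowSummaries <- function(X, w) {
  n <- nrow(X); M <- ncol(X)
  nwin <- M - w + 1L
  if (nwin < 1L) return(NULL)
  miss <- is.na(X)
  code2 <- (!miss) & X == 2L
  het <- (!miss) & X == 1L
  missC <- matrix(0L, n, nwin); hetC <- matrix(0L, n, nwin)
  hap <- matrix(0, n, nwin)
  for (k in 0:(w - 1L)) {
    cols <- (1L + k):(nwin + k)
    missC <- missC + miss[, cols, drop = FALSE]
    hetC <- hetC + het[, cols, drop = FALSE]
    hap <- hap + code2[, cols, drop = FALSE] * 2^k
  }
  complete <- missC == 0L
  hom <- complete & hetC == 0L
  list(nwin = nwin, complete = complete, hom = hom, hap = hap)
}

#' Enumerate concordant marker windows
#'
#' A sample is a window-homozygote iff it is homozygous at every marker of
#' the window with no missing call; its haplotype is then read directly. A
#' window is concordant iff all affected window-homozygotes share a single
#' (risk) haplotype, no unaffected sample is homozygous for that haplotype,
#' and both the affected-homozygote and unaffected-homozygote classes are
#' non-empty.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param phenotype phenotype table (named factor); UNKNOWN dropped.
#' @param min_window,max_window window sizes scanned (markers).
#' @return data.frame, one row per concordant window: chrom, start_idx,
#'   end_idx (global marker indices), width, risk_hap, prot_hap,
#'   n_risk_hom, n_prot_hom, n_het, het_affected.
#' @export
enumerateConcordantWindows <- function(gm, phenotype, min_window = 2,
                                       max_window = 10) {
  ph <- phenoIndicator(gm, phenotype)
  X <- genotypeCalls(gm)[ph$keep, , drop = FALSE]
  aff <- ph$case
  m <- markerInfo(gm)
  out <- list()
  for (ch in unique(m$chrom)) {
    cidx <- which(m$chrom == ch)
    Xc <- X[, cidx, drop = FALSE]
    for (w in min_window:min(max_window, length(cidx))) {
      ws <- windowSummaries(Xc, w)
      if (is.null(ws)) next
      nwin <- ws$nwin
      affHomN <- colSums(ws$hom[aff, , drop = FALSE])
      unaffHomN <- colSums(ws$hom[!aff, , drop = FALSE])
      riskMax <- rep(-Inf, nwin); riskMin <- rep(Inf, nwin)
      for (s in which(aff)) {
        h <- ifelse(ws$hom[s, ], ws$hap[s, ], NA)
        riskMax <- pmax(riskMax, h, na.rm = TRUE)
        riskMin <- pmin(riskMin, h, na.rm = TRUE)
      }
      unaffWithRisk <- rep(0L, nwin)
      for (s in which(!aff))
        unaffWithRisk <- unaffWithRisk +
          (ws$hom[s, ] & !is.na(riskMax) & ws$hap[s, ] == riskMax)
      conc <- affHomN >= 1 & unaffHomN >= 1 & riskMax == riskMin &
        unaffWithRisk == 0
      conc[!is.finite(riskMax)] <- FALSE
      for (j in which(conc)) {
        widx <- cidx[j:(j + w - 1L)]
        inwin <- ws$complete[, j]
        homj <- ws$hom[, j]
        risk <- riskMax[j]
        # decode haplotype strings from allele letters
        sub <- m[widx, ]
        bits <- as.integer(intToBits(risk))[seq_len(w)]
        risk_hap <- paste(ifelse(bits == 1L, sub$alleleB, sub$alleleA),
                          collapse = "")
        prot_codes <- ws$hap[homj & !aff, j]
        prot_mode <- as.numeric(names(sort(table(prot_codes),
                                           decreasing = TRUE))[1])
        pb <- as.integer(intToBits(prot_mode))[seq_len(w)]
        prot_hap <- paste(ifelse(pb == 1L, sub$alleleB, sub$alleleA),
                          collapse = "")
        n_het <- sum(inwin & !homj)
        out[[length(out) + 1L]] <- data.frame(chrom = ch,
          start_idx = widx[1], end_idx = widx[w], width = w,
          risk_hap = risk_hap, prot_hap = prot_hap,
          n_risk_hom = sum(homj & aff & ws$hap[, j] == risk),
          n_prot_hom = sum(homj & !aff),
          n_het = n_het, het_affected = sum(inwin & !homj & aff),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0),
    start_idx = integer(0), end_idx = integer(0), width = integer(0),
    risk_hap = character(0), prot_hap = character(0),
    n_risk_hom = integer(0), n_prot_hom = integer(0), n_het = integer(0),
    het_affected = integer(0)))
  do.call(rbind, out)
}

#' Find maximal concordant haplotype blocks
#'
#' Scans all windows of `min_window` to `max_window` markers with
#' [enumerateConcordantWindows] and merges overlapping concordant windows
#' into maximal blocks. Each block reports the union of merged marker
#' indices plus the statistics of its representative window (the
#' concordant window with the most phenotype-explaining homozygotes; ties
#' to the widest, then leftmost).
#'
#' @inheritParams enumerateConcordantWindows
#' @return data.frame, one row per block: chrom, start_idx, end_idx (union
#'   span), win_start, win_end (representative window), width, risk_hap,
#'   prot_hap, n_risk_hom, n_prot_hom, n_het, het_affected. Empty (zero
#'   rows) when no concordant window exists.
#' @export
findConcordantBlocks <- function(gm, phenotype, min_window = 2,
                                 max_window = 10) {
  wins <- enumerateConcordantWindows(gm, phenotype, min_window, max_window)
  if (!nrow(wins)) {
    wins$win_start <- integer(0); wins$win_end <- integer(0)
    return(wins)
  }
  out <- list()
  for (ch in unique(wins$chrom)) {
    wc <- wins[wins$chrom == ch, , drop = FALSE]
    wc <- wc[order(wc$start_idx, wc$end_idx), , drop = FALSE]
    comp_start <- wc$start_idx[1]; comp_end <- wc$end_idx[1]
    members <- 1L
    flush <- function(start, end, rows) {
      # representative = strongest window (most phenotype-explaining
      # homozygotes), then widest, then leftmost
      strength <- wc$n_risk_hom[rows] + wc$n_prot_hom[rows]
      rep_i <- rows[order(-strength, -wc$width[rows],
                          wc$start_idx[rows])[1]]
      r <- wc[rep_i, , drop = FALSE]
      r$win_start <- r$start_idx; r$win_end <- r$end_idx
      r$start_idx <- start; r$end_idx <- end
      r
    }
    for (i in seq_len(nrow(wc))[-1]) {
      if (wc$start_idx[i] <= comp_end) {
        comp_end <- max(comp_end, wc$end_idx[i])
        members <- c(members, i)
      } else {
        out[[length(out) + 1L]] <- flush(comp_start, comp_end, members)
        comp_start <- wc$start_idx[i]; comp_end <- wc$end_idx[i]
        members <- i
      }
    }
    out[[length(out) + 1L]] <- flush(comp_start, comp_end, members)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @describeIn findConcordantBlocks pick the strongest block (most
#'   phenotype-explaining homozygotes; ties to the leftmost)
#' @param blocks data.frame of blocks.
#' @export
bestBlock <- function(blocks) {
  stopifnot(nrow(blocks) > 0)
  blocks[order(-(blocks$n_risk_hom + blocks$n_prot_hom),
               blocks$start_idx)[1], , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Block association: Fisher exact on the 3x2 class table and a
## chromosome-wide permutation p for the concordance signal.

# phenotype-free sample partition for a window: most common homozygote
# haplotype / other homozygotes / complete heterozygotes. NA class for
# samples with missing calls in the window.
windowClassIndicators <- function(X, widx) {
  Xw <- X[, widx, drop = FALSE]
  complete <- rowSums(is.na(Xw)) == 0
  hom <- complete & rowSums(Xw == 1L) == 0
  hap <- as.vector((Xw == 2L) %*% 2^(seq_along(widx) - 1L))
  hcodes <- hap[hom]
  major <- if (length(hcodes))
    as.numeric(names(sort(table(hcodes), decreasing = TRUE))[1]) else NA
  I1 <- hom & hap == major
  I2 <- hom & hap != major
  I3 <- complete & !hom
  cbind(I1, I2, I3) * 1
}

# 3x2 Pearson chi-square for class-count matrix A (nwin*3 rows arranged as
# list) -- vectorized over permutations: A_c (nwin x P) affected counts per
# class, T_c totals per class (length nwin)
classChisq <- function(A1, A2, A3, T1, T2, T3) {
  # for a k x 2 table, chi2 = N^2/(S1*S2) * sum_c (A_c - T_c*S1/N)^2/T_c
  N <- T1 + T2 + T3
  S1 <- A1 + A2 + A3
  ratio <- S1 / N
  d1 <- A1 - T1 * ratio; d2 <- A2 - T2 * ratio; d3 <- A3 - T3 * ratio
  chi2 <- (d1 * d1 / ifelse(T1 == 0, Inf, T1) +
           d2 * d2 / ifelse(T2 == 0, Inf, T2) +
           d3 * d3 / ifelse(T3 == 0, Inf, T3)) *
    (N * N) / (S1 * (N - S1))
  chi2[!is.finite(chi2)] <- 0
  chi2
}

windowIndicators <- function(X, windows) {
  nwin <- length(windows)
  I1 <- matrix(0, nrow(X), nwin); I2 <- I1; I3 <- I1
  # group windows by width so the per-sample summaries are vectorized
  widths <- vapply(windows, length, integer(1))
  starts <- vapply(windows, `[`, integer(1), 1)
  for (w in unique(widths)) {
    ws <- windowSummaries(X, w)
    sel <- which(widths == w)
    for (j in sel) {
      jj <- starts[j]
      homj <- ws$hom[, jj]
      hapj <- ws$hap[, jj]
      hcodes <- hapj[homj]
      if (length(hcodes)) {
        tab <- tabulate(hcodes + 1L)
        major <- which.max(tab) - 1L
        I1[, j] <- homj & hapj == major
        I2[, j] <- homj & hapj != major
      }
      I3[, j] <- ws$complete[, jj] & !homj
    }
  }
  list(I1 = I1, I2 = I2, I3 = I3,
       T1 = colSums(I1), T2 = colSums(I2), T3 = colSums(I3))
}

# chi-square per window for given label matrix Y (n x P);
# returns nwin x P matrix
indChisq <- function(ind, Y) {
  classChisq(crossprod(ind$I1, Y), crossprod(ind$I2, Y),
             crossprod(ind$I3, Y), ind$T1, ind$T2, ind$T3)
}

windowChisqMatrix <- function(X, windows, Y) {
  indChisq(windowIndicators(X, windows), Y)
}

chromWindows <- function(m, chrom, min_window, max_window) {
  cidx <- which(m$chrom == chrom)
  windows <- list()
  for (w in min_window:min(max_window, length(cidx)))
    for (j in seq_len(length(cidx) - w + 1L))
      windows[[length(windows) + 1L]] <- cidx[j:(j + w - 1L)]
  windows
}

#' Chromosome-wide permutation distribution of the window concordance signal
#'
#' The statistic per window is the Pearson chi-square of the 3x2 table of
#' phenotype against a phenotype-free sample partition (most common
#' window-homozygote haplotype / other window-homozygotes / heterozygotes).
#' Phenotype labels are permuted; the maximum statistic over all windows of
#' the chromosome is recorded per permutation.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param phenotype phenotype table.
#' @param chrom chromosome name.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param min_window,max_window window sizes.
#' @return list: obs_max (observed maximum over windows), obs (per-window
#'   observed statistic), perm_max (length n_perm), p (add-one empirical p
#'   of obs_max against perm_max).
#' @export
chromMaxChisqPermutation <- function(gm, phenotype, chrom, n_perm = 25000,
                                     seed = 1, min_window = 2,
                                     max_window = 10) {
  ph <- phenoIndicator(gm, phenotype)
  X <- genotypeCalls(gm)[ph$keep, , drop = FALSE]
  case <- ph$case
  windows <- chromWindows(markerInfo(gm), chrom, min_window, max_window)
  ind <- windowIndicators(X, windows)
  obs <- as.vector(indChisq(ind, matrix(as.numeric(case))))
  n <- length(case); ncase <- sum(case)
  perm_max <- numeric(n_perm)
  withr::with_seed(seed, {
    chunk <- 250L; done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      Y <- matrix(0, n, m)
      for (i in seq_len(m)) Y[sample.int(n, ncase), i] <- 1
      S <- indChisq(ind, Y)
      perm_max[done + seq_len(m)] <- colMaxFast(S)
      done <- done + m
    }
  })
  obs_max <- max(obs)
  list(obs_max = obs_max, obs = obs, perm_max = perm_max,
       p = (sum(perm_max >= obs_max - 1e-9) + 1) / (n_perm + 1))
}

#' Score a concordant block: Fisher exact and chromosome-wide permutation p
#'
#' `fisher_p` is the two-sided Fisher exact p of the 3x2 table
#' (risk-homozygote / heterozygote / protective-homozygote x affected /
#' unaffected) built from the block's representative window. `p_chr` is the
#' add-one empirical probability that a phenotype permutation yields an
#' equally-or-more concordant window anywhere on the chromosome, measured
#' by the maximum window chi-square of [chromMaxChisqPermutation].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param phenotype phenotype table.
#' @param block one block row from [findConcordantBlocks].
#' @param n_perm permutations for p_chr (default 25000).
#' @param seed integer seed.
#' @param min_window,max_window window sizes for the chromosome scan.
#' @return list: fisher_p, p_chr, chi2 (the block's observed statistic),
#'   table (the 3x2 class table), flagged (degenerate table).
#' @export
blockAssoc <- function(gm, phenotype, block, n_perm = 25000, seed = 1,
                       min_window = 2, max_window = 10) {
  ph <- phenoIndicator(gm, phenotype)
  X <- genotypeCalls(gm)[ph$keep, , drop = FALSE]
  case <- ph$case
  widx <- block$win_start:block$win_end
  I <- windowClassIndicators(X, widx)
  tab <- rbind(
    risk_hom = c(sum(I[, 2] == 1 & case), sum(I[, 2] == 1 & !case)),
    het = c(sum(I[, 3] == 1 & case), sum(I[, 3] == 1 & !case)),
    prot_hom = c(sum(I[, 1] == 1 & case), sum(I[, 1] == 1 & !case)))
  # the phenotype-free partition labels the *major* homozygote class I1;
  # for reporting, orient rows so risk_hom is the class richer in cases
  f1 <- if (any(I[, 1] == 1)) mean(case[I[, 1] == 1]) else -Inf
  f2 <- if (any(I[, 2] == 1)) mean(case[I[, 2] == 1]) else -Inf
  if (f1 > f2) tab[c(1, 3), ] <- tab[c(3, 1), ]
  colnames(tab) <- c("affected", "unaffected")
  flagged <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  fisher_p <- if (flagged) NA_real_ else
    fisher.test(tab[rowSums(tab) > 0, , drop = FALSE])$p.value
  obs_chi2 <- as.vector(windowChisqMatrix(X, list(widx),
                                          matrix(as.numeric(case))))
  perm <- chromMaxChisqPermutation(gm, phenotype, block$chrom,
    n_perm = n_perm, seed = seed, min_window = min_window,
    max_window = max_window)
  p_chr <- (sum(perm$perm_max >= obs_chi2 - 1e-9) + 1) / (n_perm + 1)
  list(fisher_p = fisher_p, p_chr = p_chr, chi2 = obs_chi2, table = tab,
       flagged = flagged)
}

## ---------------------------------------------------------------------------

#' Define the recombinant-bounded candidate interval for a block
#'
#' Walks outward from the block: the left boundary is the position of the
#' nearest flanking marker at which any affected risk-homozygote fails to
#' be consistent with homozygosity for an extended risk haplotype (an
#' informative recombinant: a heterozygous call, or affected
#' risk-homozygotes homozygous for different alleles); symmetrically on the
#' right. If no recombinant is found before the chromosome end, the
#' boundary is the terminal marker and the interval is flagged open.
#' Boundary positions are the recombinant markers themselves, inclusive;
#' length is truncated to whole kb (56,170,062-56,933,573 gives 763 kb).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param phenotype phenotype table.
#' @param block one block row from [findConcordantBlocks].
#' @return A [CandidateInterval-class].
#' @export
defineInterval <- function(gm, phenotype, block) {
  ph <- phenoIndicator(gm, phenotype)
  X <- genotypeCalls(gm)[ph$keep, , drop = FALSE]
  case <- ph$case
  m <- markerInfo(gm)
  widx <- block$win_start:block$win_end
  Xw <- X[, widx, drop = FALSE]
  complete <- rowSums(is.na(Xw)) == 0
  hom <- complete & rowSums(Xw == 1L) == 0
  hap <- as.vector((Xw == 2L) %*% 2^(seq_along(widx) - 1L))
  aff_hom <- which(hom & case)
  stopifnot(length(aff_hom) > 0)
  risk_code <- hap[aff_hom[1]]
  riskers <- aff_hom[hap[aff_hom] == risk_code]
  cidx <- which(m$chrom == block$chrom)
  consistent <- function(j) {
    g <- X[riskers, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(TRUE)          # uninformative marker
    if (any(g == 1L)) return(FALSE)       # heterozygous affected
    length(unique(g)) == 1L               # split homozygotes = recombinant
  }
  left_open <- TRUE; left_pos <- m$pos[cidx[1]]
  for (j in rev(cidx[cidx < block$win_start])) {
    if (!consistent(j)) {
      left_pos <- m$pos[j]; left_open <- FALSE; break
    }
  }
  right_open <- TRUE; right_pos <- m$pos[cidx[length(cidx)]]
  for (j in cidx[cidx > block$win_end]) {
    if (!consistent(j)) {
      right_pos <- m$pos[j]; right_open <- FALSE; break
    }
  }
  candidateInterval(block$chrom, left_pos, right_pos,
                    open = left_open || right_open)
}
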