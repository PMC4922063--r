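## Marker QC, single-marker allelic case/control tests, and max-T
## permutation genome-wide empirical significance.

phenoIndicator <- function(gm, phenotype) {
  ids <- sampleIDs(gm)
  st <- as.character(phenotype[ids])
  if (any(is.na(st))) stop("phenotype missing for sample(s): ",
    paste(head(ids[is.na(st)]), collapse = ", "))
  keep <- st != "UNKNOWN"
  list(keep = keep, case = st[keep] == "AFFECTED")
}

#' Marker QC: minor-allele frequency and call-rate filters
#'
#' MAF is computed on non-missing alleles; call rate is the non-missing
#' fraction per marker. Markers are retained when MAF > `maf_min` AND call
#' rate > `call_rate_min` (strict inequalities).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maf_min minimum minor-allele frequency (exclusive), default 0.05.
#' @param call_rate_min minimum call rate (exclusive), default 0.75.
#' @return list: `gm` (filtered matrix) and `report` (data.frame with id,
#'   maf, call_rate, kept, reason).
#' @export
filterMarkers <- function(gm, maf_min = 0.05, call_rate_min = 0.75) {
  calls <- genotypeCalls(gm)
  nonmiss <- colSums(!is.na(calls))
  call_rate <- nonmiss / nrow(calls)
  f <- colSums(calls, na.rm = TRUE) / (2 * pmax(nonmiss, 1L))
  maf <- pmin(f, 1 - f)
  maf[nonmiss == 0] <- 0
  kept <- maf > maf_min & call_rate > call_rate_min
  reason <- rep("", ncol(calls))
  reason[maf <= maf_min] <- "maf"
  reason[call_rate <= call_rate_min] <-
    ifelse(reason[call_rate <= call_rate_min] == "maf", "maf;call_rate",
           "call_rate")
  report <- data.frame(id = markerInfo(gm)$id, maf = maf,
    call_rate = call_rate, kept = kept, reason = reason,
    stringsAsFactors = FALSE)
  out <- genotypeMatrix(calls[, kept, drop = FALSE],
    markerInfo(gm)[kept, , drop = FALSE], sampleIDs(gm))
  list(gm = out, report = report)
}

colMaxFast <- function(S) {
  tS <- t(S)
  tS[cbind(seq_len(nrow(tS)), max.col(tS, ties.method = "first"))]
}

# vectorized allelic chi-square (no correction) for code matrix G
# (samples x markers) against one or more case-indicator columns Y
allelicChisqMatrix <- function(G, Y) {
  K <- !is.na(G); G0 <- G; G0[!K] <- 0L
  storage.mode(G0) <- "double"; storage.mode(K) <- "double"
  Y <- as.matrix(Y); storage.mode(Y) <- "double"
  A <- crossprod(G0, Y)                    # case alt alleles, markers x perms
  B <- crossprod(K, Y)                     # case genotype calls
  altAll <- colSums(G0); nAll <- colSums(K)
  # 2x2 allele-table chi-square reduced to the two permuted quantities:
  # chi2 = 2*nAll*(A*nAll - B*altAll)^2 / (B*(nAll-B)*altAll*(2*nAll-altAll))
  w <- 2 * nAll / (altAll * (2 * nAll - altAll))
  w[!is.finite(w)] <- 0
  U <- A * nAll - B * altAll
  V <- B * (nAll - B)
  chi2 <- U * U * w / V
  chi2[!is.finite(chi2)] <- 0
  chi2
}

#' Single-marker allelic case/control test
#'
#' Builds the 2x2 allele-count table (case/control x alleleB/alleleA, two
#' alleles per non-missing genotype). The default statistic is the Pearson
#' chi-square without continuity correction; when any expected cell count
#' is below 5, the two-sided Fisher exact p replaces the chi-square p.
#'
#' @param calls integer genotype codes (0/1/2/NA) for one marker.
#' @param case logical case indicator, same length.
#' @return list: statistic (allelic chi-square), p_raw, test ("chisq" or
#'   "fisher"), table, flagged (TRUE when a stratum has no calls).
#' @export
allelicTest <- function(calls, case) {
  ok <- !is.na(calls)
  if (!any(ok & case) || !any(ok & !case))
    return(list(statistic = NA_real_, p_raw = NA_real_, test = "none",
                table = NULL, flagged = TRUE))
  a <- sum(calls[ok & case]); r1 <- 2 * sum(ok & case)
  cc <- sum(calls[ok & !case]); r2 <- 2 * sum(ok & !case)
  tab <- matrix(c(a, r1 - a, cc, r2 - cc), 2, 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("alt", "ref")))
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- if (any(colSums(tab) == 0)) 0 else
    N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab), colSums(tab))
  if (any(expected < 5)) {
    p <- fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    test <- "chisq"
  }
  list(statistic = chi2, p_raw = min(p, 1), test = test, table = tab,
       flagged = FALSE)
}

#' Genome-wide empirical significance by max-T phenotype permutation
#'
#' Computes the observed allelic chi-square per marker, then permutes the
#' phenotype labels (genotypes fixed), records the maximum statistic across
#' markers in each permutation, and reports the family-wise empirical
#' p-value per marker with the add-one estimator
#' p_genome = (#\{max >= observed\} + 1) / (n_perm + 1). The permutation
#' statistic is always the allelic chi-square, even for markers whose
#' per-marker p came from the Fisher exact test, so that one comparable
#' statistic ranks all markers.
#'
#' @param gm a filtered [GenotypeMatrix-class].
#' @param phenotype a phenotype table (named factor); UNKNOWN samples are
#'   dropped.
#' @param n_perm number of phenotype permutations (default 100000).
#' @param seed integer seed; the run is bit-reproducible per seed.
#' @param exhaustive enumerate all distinct case-label assignments instead
#'   of sampling (only feasible for small cohorts); the empirical p is then
#'   #\{max >= observed\} / n_assignments over the exact distribution.
#' @param chunk permutations processed per block (memory control).
#' @return data.frame: marker_id, chrom, pos, statistic, p_raw, test,
#'   p_genome, n_perm, sorted as input.
#' @export
permutationGenomewide <- function(gm, phenotype, n_perm = 100000, seed = 1,
                                  exhaustive = FALSE, chunk = 2000) {
  ph <- phenoIndicator(gm, phenotype)
  G <- genotypeCalls(gm)[ph$keep, , drop = FALSE]
  case <- ph$case
  n <- length(case); ncase <- sum(case)
  stopifnot(ncase > 0, ncase < n)
  obs <- as.vector(allelicChisqMatrix(G, matrix(as.numeric(case))))
  # vectorized per-marker allele tables; Fisher only where an expected
  # cell falls below 5 (same rule as allelicTest)
  K <- !is.na(G); G0 <- G; G0[!K] <- 0L
  a <- colSums(G0[case, , drop = FALSE])
  r1 <- 2 * colSums(K[case, , drop = FALSE])
  cc <- colSums(G0[!case, , drop = FALSE])
  r2 <- 2 * colSums(K[!case, , drop = FALSE])
  b <- r1 - a; d <- r2 - cc
  N <- r1 + r2; c1 <- a + cc; c2 <- b + d
  expected_min <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / N
  p_raw <- pchisq(obs, df = 1, lower.tail = FALSE)
  test <- rep("chisq", ncol(G))
  need_fisher <- which(expected_min < 5 & r1 > 0 & r2 > 0)
  for (j in need_fisher) {
    p_raw[j] <- fisher.test(matrix(c(a[j], b[j], cc[j], d[j]), 2, 2,
                                   byrow = TRUE))$p.value
    test[j] <- "fisher"
  }
  none <- r1 == 0 | r2 == 0
  p_raw[none] <- NA_real_; test[none] <- "none"
  p_raw <- pmin(p_raw, 1)
  count_ge <- numeric(ncol(G))
  tol <- 1e-9
  if (exhaustive) {
    combs <- combn(n, ncase)
    P <- ncol(combs)
    idx <- seq(1, P, by = chunk)
    for (s in idx) {
      cols <- s:min(s + chunk - 1, P)
      Y <- matrix(0, n, length(cols))
      Y[cbind(as.vector(combs[, cols]),
              rep(seq_along(cols), each = ncase))] <- 1
      S <- allelicChisqMatrix(G, Y)
      mx <- colMaxFast(S)
      count_ge <- count_ge + (length(mx) -
        findInterval(obs - tol, sort(mx)))
    }
    p_genome <- count_ge / P
  } else {
    P <- as.integer(n_perm)
    stopifnot(P >= 1)
    withr::with_seed(seed, {
      done <- 0L
      while (done < P) {
        m <- min(chunk, P - done)
        Y <- matrix(0, n, m)
        for (i in seq_len(m)) Y[sample.int(n, ncase), i] <- 1
        S <- allelicChisqMatrix(G, Y)
        mx <- colMaxFast(S)
        count_ge <- count_ge + (length(mx) -
          findInterval(obs - tol, sort(mx)))
        done <- done + m
      }
    })
    p_genome <- (count_ge + 1) / (P + 1)
  }
  data.frame(marker_id = markerInfo(gm)$id, chrom = markerInfo(gm)$chrom,
    pos = markerInfo(gm)$pos, statistic = obs, p_raw = p_raw, test = test,
    p_genome = p_genome, n_perm = P, stringsAsFactors = FALSE)
}
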