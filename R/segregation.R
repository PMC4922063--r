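## Mendelian segregation-ratio testing and penetrance estimation.

#' Chi-square goodness of fit to a Mendelian segregation ratio
#'
#' Tests observed (unaffected, affected) offspring counts against a
#' candidate u:a segregation ratio with the classical df = 1 chi-square
#' goodness-of-fit statistic. The ratio convention is unaffected:affected,
#' so 3:1 is the recessive expectation from carrier x carrier matings.
#'
#' @param observed length-2 numeric: (n_unaffected, n_affected).
#' @param ratio length-2 positive numeric: candidate (u, a) ratio.
#' @param yates apply the Yates continuity correction (default FALSE; the
#'   plain statistic is the default for reproducibility).
#' @return A list of class "SegregationResult": observed, candidate_ratio,
#'   expected, chi2, df, p.
#' @examples
#' gofChisq(c(49, 25), c(3, 1))  # chi2 ~= 3.05, p ~= 0.081
#' @export
gofChisq <- function(observed, ratio, yates = FALSE) {
  stopifnot(length(observed) == 2, length(ratio) == 2, all(ratio > 0))
  total <- sum(observed)
  if (total <= 0) stop("zero total offspring count")
  expected <- total * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  structure(list(observed = observed, candidate_ratio = ratio,
    expected = expected, chi2 = chi2, df = 1L,
    p = pchisq(chi2, df = 1, lower.tail = FALSE)),
    class = "SegregationResult")
}

#' @export
print.SegregationResult <- function(x, ...) {
  cat(sprintf("GOF vs %s:%s  observed (%s unaffected, %s affected)  ",
    x$candidate_ratio[1], x$candidate_ratio[2], x$observed[1], x$observed[2]))
  cat(sprintf("chi2 = %.4f (df = %d), p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Select the best-fitting Mendelian segregation ratio
#'
#' Runs [gofChisq] against each candidate unaffected:affected ratio and
#' returns the candidate with the largest goodness-of-fit p; ties go to the
#' simpler ratio (smaller u + a).
#'
#' @param observed length-2 numeric: (n_unaffected, n_affected).
#' @param candidates list of length-2 ratios
#'   (default 1:1, 3:1, 15:1 — the single-, two- and duplicate-locus
#'   recessive expectations).
#' @param yates passed to [gofChisq].
#' @return A list: selected (the winning ratio), results (one
#'   SegregationResult per candidate).
#' @examples
#' selectMendelianRatio(c(49, 25))$selected  # c(3, 1)
#' @export
selectMendelianRatio <- function(observed,
    candidates = list(c(1, 1), c(3, 1), c(15, 1)), yates = FALSE) {
  stopifnot(length(candidates) > 0)
  res <- lapply(candidates, function(r) gofChisq(observed, r, yates = yates))
  p <- vapply(res, `[[`, numeric(1), "p")
  complexity <- vapply(candidates, sum, numeric(1))
  best <- order(-p, complexity)[1]
  list(selected = candidates[[best]], results = res)
}

#' Penetrance point estimates with Wilson 95% intervals
#'
#' For each genotype class, estimates penetrance as affected/total and
#' attaches the Wilson score interval (z = 1.959964). Classes with zero
#' total are flagged undefined (NA), never reported as 0.
#'
#' @param class_counts data.frame/matrix with columns `affected` and
#'   `total`, one row per genotype class (row names = class labels).
#' @return data.frame: class, affected, total, estimate, lower, upper,
#'   defined.
#' @examples
#' estimatePenetrance(data.frame(affected = 4, total = 51,
#'                               row.names = "het"))
#' @export
estimatePenetrance <- function(class_counts) {
  z <- 1.959964
  cc <- as.data.frame(class_counts)
  stopifnot(all(c("affected", "total") %in% names(cc)))
  out <- data.frame(class = if (is.null(rownames(cc)))
      as.character(seq_len(nrow(cc))) else rownames(cc),
    affected = cc$affected, total = cc$total,
    estimate = NA_real_, lower = NA_real_, upper = NA_real_,
    defined = cc$total > 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cc))) {
    n <- cc$total[i]
    if (n <= 0) next
    p <- cc$affected[i] / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    out$estimate[i] <- p
    out$lower[i] <- max(0, centre - half)
    out$upper[i] <- min(1, centre + half)
  }
  out
}
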