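# Independent oracles: naive scanners, exhaustive enumerations and
# fixture builders kept deliberately separate from the package internals.

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# position-by-position degenerate matcher, both strands
naive_motif_scan <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  n <- length(sc); L <- nchar(pattern)
  out <- list()
  for (st in c("+", "-")) {
    pc <- strsplit(if (st == "+") pattern else oracle_revcomp(pattern),
                   "")[[1]]
    for (i in seq_len(max(n - L + 1, 0))) {
      ok <- TRUE
      for (k in seq_len(L))
        if (!sc[i + k - 1] %in% ORACLE_IUPAC[[pc[k]]]) { ok <- FALSE; break }
      if (ok) out[[length(out) + 1]] <-
        data.frame(start = i, strand = st, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), strand = character(0)))
  do.call(rbind, out)
}

# two-sided Fisher p by exhaustive enumeration of 2x2 tables with fixed
# margins (sum of point probabilities <= observed, relative tol 1e-7)
fisher_enum_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  if (c1 == 0 || c1 == N || r1 == 0 || r2 == 0) return(1)
  x <- max(0, c1 - r2):min(c1, r1)
  p <- exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1))
  pobs <- p[x == tab[1, 1]]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# same for 3x2 tables
fisher_enum_3x2 <- function(tab) {
  r <- rowSums(tab); c1 <- sum(tab[, 1]); N <- sum(tab)
  probs <- numeric(0); pobs <- NA_real_
  for (a1 in 0:min(r[1], c1)) for (a2 in 0:min(r[2], c1 - a1)) {
    a3 <- c1 - a1 - a2
    if (a3 < 0 || a3 > r[3]) next
    p <- exp(lchoose(r[1], a1) + lchoose(r[2], a2) + lchoose(r[3], a3) -
               lchoose(N, c1))
    probs <- c(probs, p)
    if (a1 == tab[1, 1] && a2 == tab[2, 1]) pobs <- p
  }
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# naive concordant-window enumeration straight from the definition
naive_concordant_windows <- function(calls, affected, min_w, max_w) {
  M <- ncol(calls)
  out <- list()
  for (w in min_w:max_w) for (j in seq_len(M - w + 1)) {
    sub <- calls[, j:(j + w - 1), drop = FALSE]
    complete <- apply(sub, 1, function(r) !anyNA(r))
    hom <- complete & apply(sub, 1, function(r) all(r %in% c(0, 2)))
    haps <- apply(sub, 1, paste, collapse = ",")
    ah <- which(hom & affected); uh <- which(hom & !affected)
    if (!length(ah) || !length(uh)) next
    if (length(unique(haps[ah])) != 1) next
    if (any(haps[uh] == haps[ah][1])) next
    out[[length(out) + 1]] <- data.frame(start = j, width = w,
      n_risk = length(ah), n_prot = length(uh))
  }
  if (!length(out))
    return(data.frame(start = integer(0), width = integer(0),
                      n_risk = integer(0), n_prot = integer(0)))
  do.call(rbind, out)
}

# the semi-recessive textbook fixture: a 5-marker core whose risk
# homozygotes (24, all affected) read "GGGGA" and protective homozygotes
# (26, unaffected) read "AAAAG", 51 heterozygotes of which 4 affected,
# bounded by informative recombinant markers on both sides
make_concordant_fixture <- function(open_ended = FALSE) {
  n_risk <- 24; n_prot <- 26; n_het <- 51
  n <- n_risk + n_prot + n_het
  M <- 9  # markers 3..7 form the core
  calls <- matrix(1L, n, M)
  risk_rows <- 1:n_risk
  prot_rows <- n_risk + (1:n_prot)
  het_rows <- n_risk + n_prot + (1:n_het)
  calls[risk_rows, ] <- 2L
  calls[prot_rows, ] <- 0L
  calls[het_rows, ] <- 1L
  if (!open_ended) {
    # split the affected homozygotes at the flanking markers so the
    # extended windows are discordant and the walk meets a recombinant
    calls[risk_rows[1:12], 2] <- 0L
    calls[risk_rows[1:12], 8] <- 0L
  }
  markers <- data.frame(id = paste0("mk", 1:M), chrom = "13",
    pos = 1000 * (1:M),
    alleleA = c("A", "A", "A", "A", "A", "A", "G", "A", "A"),
    alleleB = c("G", "G", "G", "G", "G", "G", "A", "G", "G"),
    stringsAsFactors = FALSE)
  gm <- genotypeMatrix(calls, markers, paste0("S", 1:n))
  status <- rep("UNAFFECTED", n)
  status[risk_rows] <- "AFFECTED"
  status[het_rows[1:4]] <- "AFFECTED"
  phen <- phenotypeTable(paste0("S", 1:n), status)
  list(gm = gm, phen = phen, core = 3:7,
       risk_rows = risk_rows, prot_rows = prot_rows, het_rows = het_rows)
}

# deterministic random VariantSet builder for io round-trips
random_variant_set <- function(n = 50, n_samples = 6, seed = 99) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    pos <- sort(sample(1e6, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(seq_len(n), function(i) {
      k <- sample(3, 1)
      if (k == 1) sample(setdiff(bases, ref[i]), 1)           # SNP
      else if (k == 2) paste0(ref[i], paste(sample(bases,
        sample(1:5, 1), replace = TRUE), collapse = ""))       # INS
      else ref[i]                                              # DEL below
    }, character(1))
    del <- which(alt == ref)
    ref[del] <- vapply(del, function(i) paste0(alt[i], paste(sample(bases,
      sample(1:4, 1), replace = TRUE), collapse = "")), character(1))
    calls <- matrix(sample(c(0:2, NA), n * n_samples, replace = TRUE,
                           prob = c(.4, .3, .2, .1)), n, n_samples)
    variantSet(data.frame(chrom = "13", pos = pos, ref = ref, alt = alt),
               calls, samples = paste0("S", seq_len(n_samples)))
  })
}
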