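## Strand-aware motif scanning over promoter allele pairs with indel-aware
## coordinate projection: de-novo gained/lost binding sites in TSS-relative
## coordinates, plus an in-silico region-deletion test.

#' Default SOX-family binding-site model
#'
#' The HMG-box core consensus `WWCAAWG` (W = A/T) used as the default model
#' for SOX-site prediction; any IUPAC consensus or PWM can be supplied
#' instead.
#' @return A [MotifModel-class].
#' @export
soxConsensusMotif <- function() motifModel(iupac = "WWCAAWG")

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# vectorized forward-strand IUPAC match starts on a character vector;
# fast path for the rejection-sampling generator
iupacStartsFast <- function(chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  L <- length(pat); n <- length(chars)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L))
    ok <- ok & chars[k:(n - L + k)] %in% IUPAC_SETS[[pat[k]]]
  which(ok)
}

pwmScores <- function(seq_int, pwm) {
  L <- ncol(pwm)
  n <- length(seq_int) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(L))
    s <- s + pwm[cbind(seq_int[i:(n + i - 1L)], i)]
  s
}

revcompPwm <- function(pwm) {
  # complement rows (A<->T, C<->G) and reverse columns
  pwm[c(4, 3, 2, 1), rev(seq_len(ncol(pwm))), drop = FALSE]
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Scan a sequence for motif hits on one or both strands
#'
#' IUPAC mode reports every position where the degenerate consensus
#' matches; PWM mode reports every window scoring at or above the model
#' threshold. Minus-strand hits are reported at their forward-strand start
#' (leftmost) coordinate with the site sequence as read on the minus
#' strand. Hits are sorted by position.
#'
#' @param seq sequence string (A/C/G/T).
#' @param motif a [MotifModel-class].
#' @param strands strands to scan, subset of c("+", "-").
#' @return data.frame: start, end (1-based in `seq`), strand, match, score
#'   (NA in IUPAC mode).
#' @export
scanMotif <- function(seq, motif, strands = c("+", "-")) {
  seq <- toupper(seq)
  L <- motifLength(motif)
  empty <- data.frame(start = integer(0), end = integer(0),
    strand = character(0), match = character(0), score = numeric(0),
    stringsAsFactors = FALSE)
  if (nchar(seq) < L) return(empty)
  out <- list()
  if (motif@type == "iupac") {
    subj <- Biostrings::DNAString(seq)
    if ("+" %in% strands) {
      m <- Biostrings::matchPattern(motif@pattern, subj, fixed = "subject")
      if (length(m))
        out[[length(out) + 1L]] <- data.frame(
          start = Biostrings::start(m), end = Biostrings::end(m),
          strand = "+", match = as.character(m), score = NA_real_,
          stringsAsFactors = FALSE)
    }
    if ("-" %in% strands) {
      rcpat <- revcomp(motif@pattern)
      m <- Biostrings::matchPattern(rcpat, subj, fixed = "subject")
      if (length(m))
        out[[length(out) + 1L]] <- data.frame(
          start = Biostrings::start(m), end = Biostrings::end(m),
          strand = "-",
          match = vapply(as.character(m), revcomp, character(1),
                         USE.NAMES = FALSE),
          score = NA_real_, stringsAsFactors = FALSE)
    }
  } else {
    si <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
    if ("+" %in% strands) {
      sc <- pwmScores(si, motif@pwm)
      hit <- which(sc >= motif@threshold)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(start = hit,
          end = hit + L - 1L, strand = "+",
          match = substring(seq, hit, hit + L - 1L), score = sc[hit],
          stringsAsFactors = FALSE)
    }
    if ("-" %in% strands) {
      sc <- pwmScores(si, revcompPwm(motif@pwm))
      hit <- which(sc >= motif@threshold)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(start = hit,
          end = hit + L - 1L, strand = "-",
          match = vapply(substring(seq, hit, hit + L - 1L), revcomp,
                         character(1), USE.NAMES = FALSE),
          score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## ---------------------------------------------------------------------------
## Coordinate projection across the edit list

# ref-coordinate span occupied by each edit, and its alt-coordinate image
editSpans <- function(edits) {
  n <- nrow(edits)
  ref_len <- ifelse(edits$type == "INS", 0L, nchar(edits$ref_piece))
  alt_len <- ifelse(edits$type == "DEL", 0L, nchar(edits$alt_piece))
  shift_after <- cumsum(alt_len - ref_len)
  shift_before <- c(0L, shift_after[-n])[seq_len(n)]
  # ref span [ref_lo, ref_hi] consumed by the edit (INS consumes nothing;
  # its ref_offset base is untouched). alt span likewise.
  ref_lo <- edits$ref_offset + ifelse(edits$type == "INS", 1L, 0L)
  ref_hi <- edits$ref_offset + ifelse(edits$type == "INS", 0L, ref_len - 1L)
  alt_lo <- edits$ref_offset + shift_before + ifelse(edits$type == "INS",
                                                     1L, 0L)
  alt_hi <- alt_lo + alt_len - 1L
  data.frame(ref_lo = ref_lo, ref_hi = ref_hi, alt_lo = alt_lo,
             alt_hi = alt_hi, shift_after = shift_after,
             type = edits$type, stringsAsFactors = FALSE)
}

#' Project positions between the reference and alternate allele
#'
#' Positions left of all edits map identically; positions right of an edit
#' shift by its net length change; positions inside a span that exists in
#' only one allele (an inserted or deleted piece) map to NA. Within
#' substituted spans the mapping is one-to-one. The projection is bijective
#' outside edited spans.
#'
#' @param pos integer positions (1-based).
#' @param edits the edit data.frame of a [PromoterPair-class].
#' @return integer positions in the other coordinate system (NA where
#'   unmappable).
#' @export
projectRefToAlt <- function(pos, edits) {
  if (nrow(edits) == 0) return(as.integer(pos))
  sp <- editSpans(edits)
  vapply(pos, function(p) {
    if (any(sp$type == "DEL" & p >= sp$ref_lo & p <= sp$ref_hi))
      return(NA_integer_)  # position deleted in alt
    left <- which(ifelse(sp$type == "INS", edits$ref_offset < p,
                         sp$ref_hi < p))
    shift <- if (length(left)) sp$shift_after[max(left)] else 0L
    as.integer(p + shift)
  }, integer(1))
}

#' @rdname projectRefToAlt
#' @export
projectAltToRef <- function(pos, edits) {
  if (nrow(edits) == 0) return(as.integer(pos))
  sp <- editSpans(edits)
  vapply(pos, function(p) {
    if (any(sp$type == "INS" & p >= sp$alt_lo & p <= sp$alt_hi))
      return(NA_integer_)  # position inside inserted sequence
    left <- which(sp$alt_hi < p)
    shift <- if (length(left)) sp$shift_after[max(left)] else 0L
    as.integer(p - shift)
  }, integer(1))
}

#' Signed TSS-relative coordinate
#'
#' Upstream positions are negative (-1 is the base immediately upstream of
#' the TSS), the TSS itself is +1, and there is no position 0.
#'
#' @param pos 1-based sequence position(s).
#' @param tss_pos TSS position in the same coordinates.
#' @return signed offset(s).
#' @export
tssRelative <- function(pos, tss_pos) {
  ifelse(pos < tss_pos, pos - tss_pos, pos - tss_pos + 1)
}

## ---------------------------------------------------------------------------

annotateEdits <- function(hits, edits) {
  if (!nrow(hits)) { hits$edits <- character(0); return(hits) }
  sp <- editSpans(edits)
  hits$edits <- vapply(seq_len(nrow(hits)), function(i) {
    # an INS span is [alt_lo, alt_hi]; SUB likewise; DEL has an empty alt
    # span but its junction (between alt_lo-1 and alt_lo) can be covered
    ov <- which((sp$alt_lo <= hits$end[i] & sp$alt_hi >= hits$start[i]) |
      (sp$type == "DEL" & sp$alt_lo > sp$alt_hi &
         hits$start[i] < sp$alt_lo & hits$end[i] >= sp$alt_lo))
    paste(ov, collapse = ",")
  }, character(1))
  hits
}

#' Gained and lost motif sites between promoter alleles
#'
#' Scans both alleles and matches hits across them through the indel-aware
#' projection: an alternate-allele hit is gained when no reference hit
#' exists at the projected position on the same strand (including hits
#' inside inserted sequence, which have no reference counterpart at all);
#' lost is symmetric. Gained hits are annotated with the edit(s) they
#' overlap and with their TSS-relative start.
#'
#' @param pair a [PromoterPair-class].
#' @param motif a [MotifModel-class].
#' @return list: `gained` and `lost` hit data.frames (alt and ref
#'   coordinates respectively), each with `edits` and `tss_relative`
#'   columns.
#' @export
diffSites <- function(pair, motif) {
  edits <- pairEdits(pair)
  ref_hits <- scanMotif(refSeq(pair), motif)
  alt_hits <- scanMotif(altSeq(pair), motif)
  tss_alt <- projectRefToAlt(tssRefOffset(pair), edits)
  ref_key <- paste(ref_hits$start, ref_hits$strand)
  alt_key <- paste(alt_hits$start, alt_hits$strand)
  alt_proj <- projectAltToRef(alt_hits$start, edits)
  gained <- alt_hits[is.na(alt_proj) |
    !(paste(alt_proj, alt_hits$strand) %in% ref_key), , drop = FALSE]
  ref_proj <- projectRefToAlt(ref_hits$start, edits)
  lost <- ref_hits[is.na(ref_proj) |
    !(paste(ref_proj, ref_hits$strand) %in% alt_key), , drop = FALSE]
  gained <- annotateEdits(gained, edits)
  gained$tss_relative <- tssRelative(gained$start, tss_alt)
  lost$edits <- rep("", nrow(lost))
  lost$tss_relative <- tssRelative(lost$start, tssRefOffset(pair))
  rownames(gained) <- NULL; rownames(lost) <- NULL
  list(gained = gained, lost = lost)
}

#' In-silico deletion test: do gained sites survive removing a region?
#'
#' Deletes `region` (alt coordinates, 1-based inclusive) from the
#' alternate allele and recomputes the gained-site set against the
#' reference. An empty result is reported as predicted restoration of the
#' reference behaviour (the deleted construct no longer carries any
#' de-novo site).
#'
#' @param pair a [PromoterPair-class].
#' @param region length-2 integer: deleted alt-coordinate span.
#' @param motif a [MotifModel-class].
#' @return list: `gained` (hits remaining after the deletion, coordinates
#'   in the deleted construct), `restored` (TRUE iff none remain).
#' @export
deletionTest <- function(pair, region, motif) {
  alt <- altSeq(pair)
  stopifnot(length(region) == 2, region[1] >= 1,
            region[2] <= nchar(alt), region[1] <= region[2])
  alt_del <- paste0(substr(alt, 1, region[1] - 1),
                    substr(alt, region[2] + 1, nchar(alt)))
  hits <- scanMotif(alt_del, motif)
  edits <- pairEdits(pair)
  ref_hits <- scanMotif(refSeq(pair), motif)
  ref_key <- paste(ref_hits$start, ref_hits$strand)
  width <- region[2] - region[1] + 1L
  # deleted-construct start -> alt start -> ref start
  to_alt <- ifelse(hits$start >= region[1], hits$start + width, hits$start)
  proj <- projectAltToRef(to_alt, edits)
  gained <- hits[is.na(proj) | !(paste(proj, hits$strand) %in% ref_key), ,
                 drop = FALSE]
  rownames(gained) <- NULL
  list(gained = gained, restored = nrow(gained) == 0)
}

## ---------------------------------------------------------------------------
## Motif model text IO: a single IUPAC line, or a 4-row PWM (rows prefixed
## A/C/G/T) with a "#threshold <x>" line.

#' Read a motif model from text
#' @param path file with one IUPAC consensus line, or four `A/C/G/T`-
#'   prefixed rows of per-position scores plus a `#threshold` line.
#' @return A [MotifModel-class].
#' @export
readMotifModel <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 1 && grepl("^[ACGTRYSWKMBDHVN]+$", lines))
    return(motifModel(iupac = lines))
  thr <- lines[startsWith(lines, "#threshold")]
  stopifnot(length(thr) == 1)
  rows <- lines[!startsWith(lines, "#")]
  stopifnot(length(rows) == 4)
  vals <- lapply(rows, function(l) {
    f <- strsplit(l, "[ \t]+")[[1]]
    setNames(list(as.numeric(f[-1])), f[1])
  })
  vals <- unlist(vals, recursive = FALSE)
  pwm <- do.call(rbind, vals[c("A", "C", "G", "T")])
  motifModel(pwm = pwm,
             threshold = as.numeric(strsplit(thr, "[ \t]+")[[1]][2]))
}
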