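#' @importFrom utils adist
NULL

## Pairwise similarity primitives behind the matching predicate. All four
## are symmetric in their two arguments; threshold comparisons downstream
## are inclusive (>= for similarities, <= for distances).

#' Size similarity of two SVs
#'
#' Shorter SV length divided by the longer one.
#'
#' @param lenA,lenB Positive SV lengths in bp (vectorized).
#' @return Ratio in [0, 1].
#' @examples
#' sizeSimilarity(700, 1000)  # 0.7
#' @export
sizeSimilarity <- function(lenA, lenB) {
  if (any(lenA < 1) || any(lenB < 1)) stop("SV lengths must be >= 1")
  pmin(lenA, lenB) / pmax(lenA, lenB)
}

#' Reciprocal overlap of two half-open intervals
#'
#' Overlap length divided by the length of the longer interval; 0 when
#' disjoint, 1 iff identical. Applied only to deletion-class comparisons.
#'
#' @param aStart,aEnd,bStart,bEnd Half-open interval bounds (vectorized).
#' @return Ratio in [0, 1].
#' @examples
#' reciprocalOverlap(100, 200, 150, 250)  # 0.5
#' @export
reciprocalOverlap <- function(aStart, aEnd, bStart, bEnd) {
  if (any(aEnd <= aStart) || any(bEnd <= bStart))
    stop("intervals must satisfy end > start")
  ov <- pmax(0, pmin(aEnd, bEnd) - pmax(aStart, bStart))
  ov / pmax(aEnd - aStart, bEnd - bStart)
}

#' Reference distance between two SV records
#'
#' For insertions the absolute start difference; for DEL/INV/DUP the maximum
#' of the start and end differences (the breakpoint-shift definition).
#' Records on different chromosomes are infinitely distant.
#'
#' @param recA,recB One-row SV record data.frames (or lists) with
#'   chrom/start/end/svtype fields.
#' @return Distance in bp, possibly `Inf`.
#' @export
referenceDistance <- function(recA, recB) {
  if (recA$chrom != recB$chrom) return(Inf)
  if (recA$svtype == "INS" && recB$svtype == "INS")
    return(abs(recA$start - recB$start))
  max(abs(recA$start - recB$start), abs(recA$end - recB$end))
}

#' Allele-sequence similarity
#'
#' 1 minus the Levenshtein edit distance divided by the longer sequence
#' length. Returns `NA` when either sequence is absent; callers consult the
#' value only when the p threshold is positive.
#'
#' @param seqA,seqB Nucleotide strings (vectorized; NA allowed).
#' @return Similarity in [0, 1], or NA.
#' @examples
#' sequenceSimilarity("AAAA", "AAAT")  # 0.75
#' @export
sequenceSimilarity <- function(seqA, seqB) {
  n <- max(length(seqA), length(seqB))
  seqA <- rep_len(seqA, n); seqB <- rep_len(seqB, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(seqA) & !is.na(seqB) & nzchar(seqA) & nzchar(seqB)
  if (any(ok)) {
    d <- mapply(function(a, b) utils::adist(a, b)[1, 1], seqA[ok], seqB[ok],
                USE.NAMES = FALSE)
    out[ok] <- 1 - d / pmax(nchar(seqA[ok]), nchar(seqB[ok]))
  }
  out
}

## Comparison sequence of a record: inserted ALT for INS, deleted REF for
## DEL (callers usually leave DEL ALT symbolic), NA otherwise.
.compSeq <- function(rec) {
  ifelse(rec$svtype == "INS", rec$alt,
         ifelse(rec$svtype == "DEL" &
                  !is.na(rec$ref) & rec$ref != "N", rec$ref, NA_character_))
}

#' Tolerance-parameterized match predicate
#'
#' Decides whether a call record matches a truth record under a
#' [MatchParams-class] quadruple. The pair passes iff the SV types are equal,
#' size similarity >= P, reference distance <= r, reciprocal overlap >= O
#' (deletions only), and, when p > 0, allele-sequence similarity >= p.
#' When p == 0 the sequence comparison is skipped entirely. When p > 0 and a
#' comparison sequence is missing the pair fails with reason
#' `"no_sequence"`.
#'
#' @param truthRec,callRec One-row SV record data.frames.
#' @param params A [MatchParams-class].
#' @return A one-row data.frame (the match detail): size_sim, overlap,
#'   ref_dist, seq_sim, shift, passed, reason.
#' @export
matchPredicate <- function(truthRec, callRec, params = moderateParams()) {
  detail <- data.frame(size_sim = NA_real_, overlap = NA_real_,
                       ref_dist = NA_real_, seq_sim = NA_real_,
                       shift = NA_real_, passed = FALSE,
                       reason = NA_character_, stringsAsFactors = FALSE)
  if (truthRec$svtype != callRec$svtype) {
    detail$reason <- "type_mismatch"
    return(detail)
  }
  detail$size_sim <- sizeSimilarity(truthRec$svlen, callRec$svlen)
  detail$ref_dist <- referenceDistance(truthRec, callRec)
  detail$shift <- detail$ref_dist
  if (truthRec$svtype == "DEL")
    detail$overlap <- if (is.infinite(detail$ref_dist)) 0 else
      reciprocalOverlap(truthRec$start, truthRec$end,
                        callRec$start, callRec$end)
  if (params@p > 0)
    detail$seq_sim <- sequenceSimilarity(.compSeq(truthRec), .compSeq(callRec))
  fails <- character(0)
  if (detail$size_sim < params@P) fails <- c(fails, "size")
  if (detail$ref_dist > params@r) fails <- c(fails, "refdist")
  if (truthRec$svtype == "DEL" && detail$overlap < params@O)
    fails <- c(fails, "overlap")
  if (params@p > 0) {
    if (is.na(detail$seq_sim)) fails <- c(fails, "no_sequence")
    else if (detail$seq_sim < params@p) fails <- c(fails, "sequence")
  }
  detail$passed <- length(fails) == 0L
  detail$reason <- if (length(fails)) paste(fails, collapse = ",")
                   else NA_character_
  detail
}
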