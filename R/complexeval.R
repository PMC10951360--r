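## Breakend-level evaluation of translocations and criteria-based
## evaluation of inversions and duplications.

#' Construct a table of reciprocal translocation events
#'
#' @param chromA,chromB Chromosome names of the two partners (must differ
#'   pairwise).
#' @param posA,posB 0-based breakpoint positions.
#' @return A data.frame of TRA events (one per row).
#' @export
traEvents <- function(chromA, posA, chromB, posB) {
  ev <- data.frame(chrom_a = chromA, pos_a = as.integer(posA),
                   chrom_b = chromB, pos_b = as.integer(posB),
                   stringsAsFactors = FALSE)
  if (any(ev$chrom_a == ev$chrom_b))
    stop("reciprocal translocations must join two different chromosomes")
  ev
}

#' Expand reciprocal translocations into breakend signatures
#'
#' A balanced reciprocal translocation between loci (A, pA) and (B, pB)
#' produces two derivative chromosomes and hence four breakends; each
#' junction is recorded from both partners' perspectives:
#' (A,pA,+,B,pB,+), (B,pB,+,A,pA,+), (A,pA,-,B,pB,-), (B,pB,-,A,pA,-).
#' The strand convention is internal; truth and calls must share it (they
#' do when both pass through this expansion or [parseBndAlt()]).
#'
#' @param events A data.frame from [traEvents()].
#' @return A breakend data.frame with 4 rows per event.
#' @export
expandReciprocalTra <- function(events) {
  if (any(events$chrom_a == events$chrom_b))
    stop("reciprocal translocations must join two different chromosomes")
  n <- nrow(events)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- events[i, ]
    data.frame(
      id = paste0("tra", i, ".", 1:4),
      chrom1 = c(e$chrom_a, e$chrom_b, e$chrom_a, e$chrom_b),
      pos1 = c(e$pos_a, e$pos_b, e$pos_a, e$pos_b),
      strand1 = c("+", "+", "-", "-"),
      chrom2 = c(e$chrom_b, e$chrom_a, e$chrom_b, e$chrom_a),
      pos2 = c(e$pos_b, e$pos_a, e$pos_b, e$pos_a),
      strand2 = c("+", "+", "-", "-"),
      sc = "truth", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Match translocation breakends against a truth set
#'
#' A call breakend is TP iff some unconsumed truth breakend has equal
#' chrom1 and chrom2, both position differences at most 1 kb (inclusive),
#' and equal strand1 and strand2. Assignment is one-to-one and greedy by
#' ascending max(|delta pos1|, |delta pos2|). Unmatched calls are FP,
#' unconsumed truth breakends FN.
#'
#' @param callBnd,truthBnd Breakend data.frames (see [emptyBreakends()]).
#' @param maxShift Positional tolerance in bp (default 1000).
#' @return A [BenchResult-class]; `gt_match` is NA (breakends carry no
#'   genotype).
#' @export
matchTra <- function(callBnd, truthBnd, maxShift = 1000) {
  cand <- merge(
    cbind(truthBnd[c("id", "chrom1", "pos1", "strand1",
                     "chrom2", "pos2", "strand2")],
          stringsAsFactors = FALSE),
    cbind(callBnd[c("id", "chrom1", "pos1", "strand1",
                    "chrom2", "pos2", "strand2")]),
    by = c("chrom1", "strand1", "chrom2", "strand2"),
    suffixes = c(".t", ".c"))
  if (nrow(cand)) {
    cand$d <- pmax(abs(cand$pos1.t - cand$pos1.c),
                   abs(cand$pos2.t - cand$pos2.c))
    cand <- cand[cand$d <= maxShift, , drop = FALSE]
    cand <- cand[order(cand$d, cand$id.t, cand$id.c), , drop = FALSE]
  } else cand$d <- numeric(0)
  n <- nrow(cand)
  cand <- data.frame(truth_id = cand$id.t, call_id = cand$id.c,
                     size_sim = rep(NA_real_, n), overlap = rep(NA_real_, n),
                     ref_dist = cand$d, seq_sim = rep(NA_real_, n),
                     gt_match = rep(NA, n), stringsAsFactors = FALSE)
  .greedy(cand, truthBnd$id, callBnd$id)
}

#' Evaluate inversions or duplications against a truth set
#'
#' Both sets must contain a single SV type (INV or DUP). A call is TP iff
#' some unconsumed truth record on the same chromosome has
#' |delta start| <= 500 bp, |delta end| <= 500 bp, and size similarity
#' >= 0.5; assignment is greedy by ascending maximum endpoint difference.
#' A TP whose genotype (het/hom) equals the truth genotype is additionally
#' TP_GT (`gt_match`).
#'
#' @param calls,truth [SVCallset-class] objects containing only INV or only
#'   DUP records.
#' @param maxShift Endpoint tolerance in bp (default 500).
#' @param minSizeSim Minimum size similarity (default 0.5).
#' @return A [BenchResult-class].
#' @export
matchInvDup <- function(calls, truth, maxShift = 500, minSizeSim = 0.5) {
  k <- svRecords(calls); t <- svRecords(truth)
  types <- unique(c(k$svtype, t$svtype))
  if (length(types) > 1L || !all(types %in% c("INV", "DUP")))
    stop("matchInvDup expects a single SV type, INV or DUP, per invocation")
  cand <- .candidateDetails(t, k, rMax = maxShift, needSeq = FALSE)
  cand <- cand[cand$size_sim >= minSizeSim, , drop = FALSE]
  cand <- cand[order(cand$ref_dist, cand$truth_id, cand$call_id), ,
               drop = FALSE]
  .greedy(cand, t$id, k$id)
}
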