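#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Candidate pair generation: for each SV type, pairs of truth/call records
## whose reference distance can be <= rMax. Details are computed once per
## pair (vectorized) and reused across grid points.
.candidateDetails <- function(truth, calls, rMax, needSeq) {
  out <- list()
  for (ty in intersect(unique(truth$svtype), unique(calls$svtype))) {
    t <- truth[truth$svtype == ty, , drop = FALSE]
    k <- calls[calls$svtype == ty, , drop = FALSE]
    if (!nrow(t) || !nrow(k)) next
    gt <- GenomicRanges::GRanges(t$chrom,
            IRanges::IRanges(t$start + 1L, pmax(t$end, t$start + 1L)))
    gc <- GenomicRanges::GRanges(k$chrom,
            IRanges::IRanges(k$start + 1L, pmax(k$end, k$start + 1L)))
    hits <- GenomicRanges::findOverlaps(gt, gc, maxgap = rMax + 1L)
    if (!length(hits)) next
    ti <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
    d <- data.frame(
      truth_id = t$id[ti], call_id = k$id[ci], svtype = ty,
      size_sim = sizeSimilarity(t$svlen[ti], k$svlen[ci]),
      ref_dist = if (ty == "INS") abs(t$start[ti] - k$start[ci])
                 else pmax(abs(t$start[ti] - k$start[ci]),
                           abs(t$end[ti] - k$end[ci])),
      overlap = NA_real_, seq_sim = NA_real_,
      gt_match = t$gt[ti] != "missing" & t$gt[ti] == k$gt[ci],
      stringsAsFactors = FALSE)
    if (ty == "DEL")
      d$overlap <- reciprocalOverlap(t$start[ti], t$end[ti],
                                     k$start[ci], k$end[ci])
    if (needSeq) {
      st <- .compSeq(t)[ti]; sk <- .compSeq(k)[ci]
      d$seq_sim <- sequenceSimilarity(st, sk)
    }
    d <- d[d$ref_dist <= rMax, , drop = FALSE]
    out[[ty]] <- d
  }
  if (!length(out)) {
    return(data.frame(truth_id = character(), call_id = character(),
                      svtype = character(), size_sim = numeric(),
                      ref_dist = numeric(), overlap = numeric(),
                      seq_sim = numeric(), gt_match = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## Deterministic sort of candidate pairs: best sequence similarity first
## (not-applicable last), then best size similarity, then smallest
## reference distance, ties broken by record ids.
.sortCandidates <- function(cand) {
  seqKey <- ifelse(is.na(cand$seq_sim), -1, cand$seq_sim)
  cand[order(-seqKey, -cand$size_sim, cand$ref_dist,
             cand$truth_id, cand$call_id), , drop = FALSE]
}

.passMask <- function(cand, p, P, O, r) {
  cand$size_sim >= P & cand$ref_dist <= r &
    (cand$svtype != "DEL" | cand$overlap >= O) &
    (p == 0 | (!is.na(cand$seq_sim) & cand$seq_sim >= p))
}

## Greedy one-to-one assignment over sorted passing candidates.
.greedy <- function(sortedCand, truthIds, callIds) {
  tTaken <- logical(length(truthIds)); names(tTaken) <- truthIds
  cTaken <- logical(length(callIds)); names(cTaken) <- callIds
  keep <- logical(nrow(sortedCand))
  ti <- match(sortedCand$truth_id, truthIds)
  ci <- match(sortedCand$call_id, callIds)
  for (i in seq_len(nrow(sortedCand))) {
    if (!tTaken[ti[i]] && !cTaken[ci[i]]) {
      keep[i] <- TRUE
      tTaken[ti[i]] <- TRUE
      cTaken[ci[i]] <- TRUE
    }
  }
  tp <- sortedCand[keep, , drop = FALSE]
  tp$shift <- tp$ref_dist
  tp <- tp[, c("truth_id", "call_id", "size_sim", "overlap", "ref_dist",
               "seq_sim", "shift", "gt_match")]
  .BenchResult(tp, fp = callIds[!cTaken], fn = truthIds[!tTaken],
               n_truth = length(truthIds), n_calls = length(callIds))
}

#' Assign calls to truth records one-to-one
#'
#' Builds all (truth, call) pairs passing [matchPredicate()] under `params`
#' and assigns them greedily, best pairs first (descending sequence
#' similarity where applicable, then descending size similarity, ascending
#' reference distance, record ids as tie-breaks). The assignment is
#' deterministic and one-to-one; unmatched calls are FP, unmatched truth
#' records are FN.
#'
#' @param truth,calls [SVCallset-class] objects (normalized and filtered).
#' @param params A [MatchParams-class].
#' @return A [BenchResult-class].
#' @export
assignMatches <- function(truth, calls, params = moderateParams()) {
  t <- svRecords(truth); k <- svRecords(calls)
  cand <- .candidateDetails(t, k, rMax = params@r, needSeq = params@p > 0)
  cand <- cand[.passMask(cand, params@p, params@P, params@O, params@r), ,
               drop = FALSE]
  .greedy(.sortCandidates(cand), t$id, k$id)
}

#' Overall and genotype-aware metrics from a benchmark result
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F1 their harmonic mean;
#' the gt_* variants replace TP with TP_GT (genotype-concordant TPs) in the
#' numerator while keeping the same denominators, so a genotype-discordant
#' TP degrades the gt metrics without becoming an FP. Metrics with a zero
#' denominator are reported as 0.
#'
#' @param result A [BenchResult-class].
#' @return A one-row data.frame with tp, fp, fn, tp_gt and the six metrics.
#' @export
computeMetrics <- function(result) {
  tp <- nrow(result@tp); fp <- length(result@fp); fn <- length(result@fn)
  tpGt <- sum(!is.na(result@tp$gt_match) & result@tp$gt_match)
  div <- function(a, b) if (b == 0) 0 else a / b
  rec <- div(tp, tp + fn); prec <- div(tp, tp + fp)
  f1 <- if (rec + prec == 0) 0 else 2 * rec * prec / (rec + prec)
  grec <- div(tpGt, tp + fn); gprec <- div(tpGt, tp + fp)
  gf1 <- if (grec + gprec == 0) 0 else 2 * grec * gprec / (grec + gprec)
  data.frame(tp = tp, fp = fp, fn = fn, tp_gt = tpGt,
             recall = rec, precision = prec, f1 = f1,
             gt_recall = grec, gt_precision = gprec, gt_f1 = gf1)
}

#' Grid search over matching tolerances
#'
#' Evaluates `calls` against `truth` at every combination of the supplied
#' axes and returns one metrics row per grid point. Per-pair similarity
#' measurements are computed once and cached across grid points. The default
#' axes sweep p and O from 0 to 1 in increments of 0.1 at the moderate
#' P = 0.5, r = 500 settings (121 grid points); pass e.g.
#' `rAxis = seq(0, 1000, 100), OAxis = 0` for a p-r sweep.
#'
#' @param truth,calls [SVCallset-class] objects.
#' @param pAxis,PAxis,OAxis,rAxis Numeric vectors of threshold values.
#' @return A data.frame with columns p, P, O, r plus the metrics columns of
#'   [computeMetrics()].
#' @export
gridSearch <- function(truth, calls,
                       pAxis = seq(0, 1, 0.1), PAxis = 0.5,
                       OAxis = seq(0, 1, 0.1), rAxis = 500) {
  stopifnot(length(pAxis) > 0, length(PAxis) > 0,
            length(OAxis) > 0, length(rAxis) > 0)
  t <- svRecords(truth); k <- svRecords(calls)
  cand <- .candidateDetails(t, k, rMax = max(rAxis),
                            needSeq = any(pAxis > 0))
  cand <- .sortCandidates(cand)
  grid <- expand.grid(p = pAxis, P = PAxis, O = OAxis, r = rAxis,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sub <- cand[.passMask(cand, g$p, g$P, g$O, g$r), , drop = FALSE]
    res[[i]] <- computeMetrics(.greedy(sub, t$id, k$id))
  }
  cbind(grid, do.call(rbind, res))
}

#' Breakpoint-shift histogram of true-positive pairs
#'
#' Per-TP breakpoint shift (maximum endpoint difference for deletion-class
#' records, start difference for insertions) binned at 1 bp resolution from
#' 0 to 200 bp; shifts larger than 200 bp are merged into the "200+" bin.
#'
#' @param result A [BenchResult-class].
#' @return A data.frame with columns `bin` (character, "0".."200", "200+")
#'   and `count`.
#' @export
shiftDistribution <- function(result) {
  shifts <- result@tp$shift
  bins <- c(as.character(0:200), "200+")
  lab <- ifelse(shifts > 200, "200+", as.character(as.integer(shifts)))
  counts <- table(factor(lab, levels = bins))
  data.frame(bin = bins, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Sequence-similarity histogram of true-positive pairs
#'
#' Per-TP allele-sequence similarity binned in [0, 1] at 0.01 resolution.
#' Pairs lacking a comparison sequence are excluded; their count is attached
#' as attribute `"excluded"`. When the result was computed with p = 0 (so
#' similarities were never measured), supply `truth` and `calls` to compute
#' them for the matched pairs.
#'
#' @param result A [BenchResult-class].
#' @param truth,calls Optional [SVCallset-class] objects used to compute
#'   similarities missing from the result.
#' @return A data.frame with columns `bin` (lower edge) and `count`.
#' @export
seqsimDistribution <- function(result, truth = NULL, calls = NULL) {
  sims <- result@tp$seq_sim
  if (all(is.na(sims)) && nrow(result@tp) && !is.null(truth) &&
      !is.null(calls)) {
    t <- svRecords(truth); k <- svRecords(calls)
    st <- .compSeq(t)[match(result@tp$truth_id, t$id)]
    sk <- .compSeq(k)[match(result@tp$call_id, k$id)]
    sims <- sequenceSimilarity(st, sk)
  }
  excluded <- sum(is.na(sims))
  sims <- sims[!is.na(sims)]
  edges <- seq(0, 1, 0.01)
  lab <- pmin(floor(sims * 100) / 100, 1)
  counts <- table(factor(sprintf("%.2f", lab),
                         levels = sprintf("%.2f", edges)))
  out <- data.frame(bin = edges, count = as.integer(counts))
  attr(out, "excluded") <- excluded
  out
}
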