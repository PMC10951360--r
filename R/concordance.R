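## Iterative multi-caller merge with source-caller (SC) tracking, and
## support-count analysis of the merged callset against a truth set.

#' Iteratively merge callsets with source-caller tracking
#'
#' The first callset seeds the merge. Each subsequent callset is assigned
#' against the current merge with [assignMatches()] under `params`: matched
#' merge records keep their coordinates (first-seen representative) and
#' append the new caller's name to their SC field; unmatched merge records
#' pass through; unmatched new records are added. All unmatched merge
#' records remain in the pool at every iteration. The result size is at most
#' the sum of the input sizes.
#'
#' @param callsets A list of [SVCallset-class] objects, in merge order.
#'   Caller names must be distinct.
#' @param params A [MatchParams-class]; defaults to the moderate preset.
#' @return An [SVCallset-class] named "merged" whose records carry
#'   accumulated SC fields. Attribute `"provenance"` records the input
#'   order.
#' @export
iterativeMerge <- function(callsets, params = moderateParams()) {
  stopifnot(length(callsets) >= 1L)
  nms <- vapply(callsets, callsetName, character(1))
  if (anyDuplicated(nms)) stop("duplicate caller names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  merged <- svRecords(callsets[[1L]])
  mergedBnd <- breakends(callsets[[1L]])
  for (i in seq_along(callsets)[-1L]) {
    cur <- svRecords(callsets[[i]])
    curBnd <- breakends(callsets[[i]])
    br <- assignMatches(SVCallset("merged", merged),
                        SVCallset(nms[i], cur), params)
    tp <- tpPairs(br)
    hit <- match(tp$truth_id, merged$id)
    merged$sc[hit] <- paste(merged$sc[hit],
                            cur$sc[match(tp$call_id, cur$id)], sep = ",")
    newRecs <- cur[cur$id %in% fpIds(br), , drop = FALSE]
    if (nrow(newRecs)) {
      clash <- newRecs$id %in% merged$id
      newRecs$id[clash] <- paste0(nms[i], ":", newRecs$id[clash])
      merged <- rbind(merged, newRecs)
    }
    if (nrow(curBnd)) {
      clash <- curBnd$id %in% c(merged$id, mergedBnd$id)
      curBnd$id[clash] <- paste0(nms[i], ":", curBnd$id[clash])
      mergedBnd <- rbind(mergedBnd, curBnd)
    }
  }
  out <- SVCallset("merged", merged, mergedBnd)
  attr(out, "provenance") <- nms
  out
}

#' Support-count analysis of a merged callset against truth
#'
#' Classifies every merged record as TP or FP against `truth` via
#' [assignMatches()] (unmatched truth records are FN) and tabulates, per
#' caller and per category, the distribution of support counts (the number
#' of callers in the record's SC field). Support 1 identifies exclusive
#' calls.
#'
#' @param merged A merged [SVCallset-class] from [iterativeMerge()].
#' @param truth The truth [SVCallset-class].
#' @param params A [MatchParams-class].
#' @param regions Optional [GenomicRanges::GRanges] of high-confidence
#'   regions, applied first when `mode = "with_constraints"`.
#' @param mode `"without_constraints"` (default) or `"with_constraints"`.
#' @return A data.frame with columns caller, category ("TP"/"FP"), support,
#'   n. Attribute `"n_fn"` gives the number of unmatched truth records.
#' @export
supportCounts <- function(merged, truth, params = moderateParams(),
                          regions = NULL,
                          mode = c("without_constraints",
                                   "with_constraints")) {
  mode <- match.arg(mode)
  if (mode == "with_constraints") {
    if (is.null(regions))
      stop("'regions' is required for mode = 'with_constraints'")
    merged <- filterByRegions(merged, regions, mode)
    truth <- filterByRegions(truth, regions, mode)
  }
  br <- assignMatches(truth, merged, params)
  m <- svRecords(merged)
  category <- ifelse(m$id %in% tpPairs(br)$call_id, "TP", "FP")
  scList <- strsplit(m$sc, ",", fixed = TRUE)
  support <- lengths(scList)
  rows <- data.frame(caller = unlist(scList),
                     category = rep(category, support),
                     support = rep(support, support),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = rep(1L, nrow(rows))),
                          rows[c("caller", "category", "support")], sum)
  agg <- agg[order(agg$caller, agg$category, agg$support), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_fn") <- length(fnIds(br))
  agg
}
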