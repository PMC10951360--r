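## Tumor-normal somatic SV extraction: split by type and size window,
## merge the paired callsets per partition with a window-dependent
## breakpoint-distance threshold, keep tumor-only records, and evaluate
## against a somatic truth set.

## The five non-TRA size windows (inclusive bounds, by svlen).
.SIZE_WINDOWS <- data.frame(
  label = c("50-100", "101-500", "501-1000", "1001-30000", ">30000"),
  lower = c(50L, 101L, 501L, 1001L, 30001L),
  upper = c(100L, 500L, 1000L, 30000L, NA),
  stringsAsFactors = FALSE)

#' The somatic size windows
#'
#' @return A data.frame with columns label, lower, upper (bp; upper NA for
#'   the unbounded window). The merge threshold for a window is its lower
#'   bound, except that the smallest window uses 50 bp.
#' @export
sizeWindows <- function() .SIZE_WINDOWS

#' Merge distance threshold of a size window
#'
#' The breakpoint-distance threshold used when merging tumor and normal
#' records of one size window: the window's lower bound (50 bp for the
#' smallest window).
#'
#' @param label A window label from [sizeWindows()].
#' @return Threshold in bp.
#' @export
windowMergeThreshold <- function(label) {
  w <- .SIZE_WINDOWS[.SIZE_WINDOWS$label == label, ]
  if (!nrow(w)) stop("unknown size window '", label, "'")
  if (label == "50-100") 50L else w$lower
}
.windowThreshold <- windowMergeThreshold

#' Split a callset by SV type and size window
#'
#' Partitions a callset into its translocation breakends and five non-TRA
#' subsets by svlen: 50-100, 101-500, 501-1000, 1001-30000 and >30000 bp
#' (inclusive bounds). Records under 50 bp are dropped. The partition is
#' exhaustive and disjoint.
#'
#' @param callset An [SVCallset-class].
#' @return A list with elements `TRA` (breakend data.frame) and `windows`
#'   (named list of record data.frames, one per size window).
#' @export
splitByTypeAndSize <- function(callset) {
  r <- svRecords(callset)
  r <- r[r$svlen >= 50L, , drop = FALSE]
  windows <- lapply(seq_len(nrow(.SIZE_WINDOWS)), function(i) {
    w <- .SIZE_WINDOWS[i, ]
    keep <- r$svlen >= w$lower & (is.na(w$upper) | r$svlen <= w$upper)
    r[keep, , drop = FALSE]
  })
  names(windows) <- .SIZE_WINDOWS$label
  list(TRA = breakends(callset), windows = windows)
}

## Single-linkage clustering of records within one partition: two records
## merge iff same svtype and breakpoint distance <= threshold. Union-find.
.clusterIds <- function(df, threshold, isBnd = FALSE) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (isBnd) {
        ## strand equality keeps the two strand-paired signatures of one
        ## reciprocal junction from collapsing into each other
        ok <- df$chrom1[i] == df$chrom1[j] && df$chrom2[i] == df$chrom2[j] &&
          df$strand1[i] == df$strand1[j] && df$strand2[i] == df$strand2[j] &&
          max(abs(df$pos1[i] - df$pos1[j]),
              abs(df$pos2[i] - df$pos2[j])) <= threshold
      } else {
        ok <- df$svtype[i] == df$svtype[j] && df$chrom[i] == df$chrom[j] &&
          (if (df$svtype[i] == "INS" && df$svtype[j] == "INS")
            abs(df$start[i] - df$start[j])
           else max(abs(df$start[i] - df$start[j]),
                    abs(df$end[i] - df$end[j]))) <= threshold
      }
      if (ok) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge a tumor/normal partition pair
#'
#' Single-linkage clustering of the combined tumor and normal records of
#' one partition: two records join a cluster iff they have the same SV type
#' and a breakpoint distance at most `distThreshold` (reference distance
#' for non-TRA records; the maximum of the two locus distances for
#' breakends). Each cluster is represented by its first-seen record (tumor
#' records listed first) flagged with whether any member came from the
#' tumor and/or the normal set.
#'
#' @param tumor,normal Record (or breakend) data.frames from the same
#'   partition of [splitByTypeAndSize()].
#' @param distThreshold Breakpoint distance threshold in bp; for size
#'   windows use the window's lower bound (50 bp for the smallest window);
#'   for TRA the default is 1000 bp.
#' @param isBnd TRUE when merging breakend tables.
#' @return The representative records with logical columns `in_tumor` and
#'   `in_normal`.
#' @export
mergePairedCallsets <- function(tumor, normal, distThreshold,
                                isBnd = FALSE) {
  tumor$origin <- rep("tumor", nrow(tumor))
  normal$origin <- rep("normal", nrow(normal))
  all <- rbind(tumor, normal)
  if (!nrow(all)) {
    all$in_tumor <- logical(0); all$in_normal <- logical(0)
    all$origin <- NULL
    return(all)
  }
  cl <- .clusterIds(all, distThreshold, isBnd = isBnd)
  reps <- !duplicated(cl)
  inT <- tapply(all$origin == "tumor", cl, any)
  inN <- tapply(all$origin == "normal", cl, any)
  out <- all[reps, , drop = FALSE]
  out$in_tumor <- as.logical(inT[as.character(cl[reps])])
  out$in_normal <- as.logical(inN[as.character(cl[reps])])
  out$origin <- NULL
  rownames(out) <- NULL
  out
}

#' Extract somatic SVs from merged tumor/normal partitions
#'
#' Keeps, across all partitions, the merged records supported by the tumor
#' callset but not by the normal callset.
#'
#' @param mergedPartitions A list with elements `TRA` (merged breakends)
#'   and `windows` (list of merged record tables), each as produced by
#'   [mergePairedCallsets()].
#' @return An [SVCallset-class] named "somatic".
#' @export
extractSomatic <- function(mergedPartitions) {
  pick <- function(df) df[df$in_tumor & !df$in_normal, , drop = FALSE]
  recs <- do.call(rbind, lapply(mergedPartitions$windows, pick))
  bnd <- pick(mergedPartitions$TRA)
  recs$in_tumor <- recs$in_normal <- NULL
  bnd$in_tumor <- bnd$in_normal <- NULL
  SVCallset("somatic", recs, bnd)
}

#' Somatic SV extraction pipeline
#'
#' Splits tumor and normal callsets by type and size window, merges each
#' partition pair with the window's breakpoint-distance threshold (the
#' window lower bound; `traThreshold` for breakends) and returns the
#' tumor-only records as the somatic callset.
#'
#' @param tumor,normal [SVCallset-class] objects.
#' @param traThreshold Breakpoint-distance threshold for TRA merging
#'   (default 1000 bp).
#' @return An [SVCallset-class] named "somatic".
#' @export
callSomatic <- function(tumor, normal, traThreshold = 1000) {
  st <- splitByTypeAndSize(tumor)
  sn <- splitByTypeAndSize(normal)
  merged <- list(
    TRA = mergePairedCallsets(st$TRA, sn$TRA, traThreshold, isBnd = TRUE),
    windows = lapply(names(st$windows), function(lab)
      mergePairedCallsets(st$windows[[lab]], sn$windows[[lab]],
                          .windowThreshold(lab))))
  extractSomatic(merged)
}

#' Evaluate somatic calls against a somatic truth set
#'
#' Per SV type, calls are assigned one-to-one to truth records greedily by
#' ascending breakpoint shift B. A TRA breakend is TP iff B <= 1 kb; a
#' non-TRA record is TP iff B <= 500 bp and size similarity >= 0.5 (both
#' inclusive). Recall and precision are reported per type separately, as a
#' somatic truth set is typically incomplete.
#'
#' @param somatic,truth [SVCallset-class] objects.
#' @return A data.frame with one row per SV type: n_truth, n_calls, tp,
#'   recall, precision.
#' @export
evaluateSomatic <- function(somatic, truth) {
  rows <- list()
  s <- svRecords(somatic); t <- svRecords(truth)
  for (ty in sort(union(unique(s$svtype), unique(t$svtype)))) {
    st <- s[s$svtype == ty, , drop = FALSE]
    tt <- t[t$svtype == ty, , drop = FALSE]
    cand <- .candidateDetails(tt, st, rMax = 500, needSeq = FALSE)
    cand <- cand[cand$size_sim >= 0.5, , drop = FALSE]
    cand <- cand[order(cand$ref_dist, cand$truth_id, cand$call_id), ,
                 drop = FALSE]
    br <- .greedy(cand, tt$id, st$id)
    m <- computeMetrics(br)
    rows[[ty]] <- data.frame(type = ty, n_truth = nrow(tt),
                             n_calls = nrow(st), tp = m$tp,
                             recall = m$recall, precision = m$precision)
  }
  if (nrow(breakends(somatic)) || nrow(breakends(truth))) {
    br <- matchTra(breakends(somatic), breakends(truth), maxShift = 1000)
    m <- computeMetrics(br)
    rows[["TRA"]] <- data.frame(type = "TRA",
                                n_truth = nrow(breakends(truth)),
                                n_calls = nrow(breakends(somatic)),
                                tp = m$tp, recall = m$recall,
                                precision = m$precision)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
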