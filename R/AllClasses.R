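#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

## Canonical column sets for the two record tables carried by an SVCallset.
.REC_COLS <- c("id", "chrom", "start", "end", "svtype", "svlen",
               "ref", "alt", "gt", "sc")
.BND_COLS <- c("id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
               "strand2", "sc")
.SVTYPES  <- c("DEL", "INS", "DUP", "INV")
.GTS      <- c("het", "hom_alt", "missing")

#' Empty SV record table
#'
#' Returns a zero-row data.frame with the canonical columns used for
#' sequence-resolved / symbolic SV records (0-based half-open coordinates).
#'
#' @return A zero-row data.frame.
#' @export
emptySVRecords <- function() {
  data.frame(id = character(), chrom = character(),
             start = integer(), end = integer(),
             svtype = character(), svlen = integer(),
             ref = character(), alt = character(),
             gt = character(), sc = character(),
             stringsAsFactors = FALSE)
}

#' Empty breakend signature table
#'
#' Breakends are 6-tuples (chrom1, pos1, strand1, chrom2, pos2, strand2)
#' with 0-based positions; translocation calls and truth sets are compared
#' at this level.
#'
#' @return A zero-row data.frame.
#' @export
emptyBreakends <- function() {
  data.frame(id = character(), chrom1 = character(), pos1 = integer(),
             strand1 = character(), chrom2 = character(), pos2 = integer(),
             strand2 = character(), sc = character(),
             stringsAsFactors = FALSE)
}

#' SVCallset: a normalized set of SV calls from one source
#'
#' Container for a normalized callset or truth set: a table of DEL/INS/INV/DUP
#' records (0-based half-open internal coordinates) and a table of breakend
#' signatures for translocations. The `sc` column holds the comma-joined
#' source-caller list (the SC field of the uniform VCF representation).
#'
#' @slot name Callset name (typically the caller name).
#' @slot records data.frame of SV records, see [emptySVRecords()].
#' @slot breakends data.frame of breakend signatures, see [emptyBreakends()].
#' @export
setClass("SVCallset",
         representation(name = "character",
                        records = "data.frame",
                        breakends = "data.frame"))

setValidity("SVCallset", function(object) {
  msg <- character()
  r <- object@records
  b <- object@breakends
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single string")
  if (!all(.REC_COLS %in% names(r)))
    msg <- c(msg, paste("records missing columns:",
                        paste(setdiff(.REC_COLS, names(r)), collapse = ", ")))
  if (!all(.BND_COLS %in% names(b)))
    msg <- c(msg, paste("breakends missing columns:",
                        paste(setdiff(.BND_COLS, names(b)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(c(r$id, b$id)))
    msg <- c(msg, "record ids must be unique within a callset")
  if (nrow(r)) {
    if (!all(r$svtype %in% .SVTYPES))
      msg <- c(msg, "svtype must be one of DEL, INS, DUP, INV")
    if (!all(r$gt %in% .GTS))
      msg <- c(msg, "gt must be one of het, hom_alt, missing")
    if (any(r$end < r$start)) msg <- c(msg, "end must be >= start")
    if (any(r$svlen < 1L)) msg <- c(msg, "svlen must be >= 1")
    del <- r$svtype == "DEL"
    if (any(del & (r$end - r$start) != r$svlen))
      msg <- c(msg, "for DEL records end - start must equal svlen")
    ins <- r$svtype == "INS"
    if (any(ins & r$end != r$start))
      msg <- c(msg, "for INS records end must equal start")
    if (any(is.na(r$sc) | r$sc == ""))
      msg <- c(msg, "source callers (sc) must be non-empty")
  }
  if (nrow(b)) {
    if (!all(b$strand1 %in% c("+", "-")) || !all(b$strand2 %in% c("+", "-")))
      msg <- c(msg, "breakend strands must be '+' or '-'")
    if (any(b$pos1 < 0L) || any(b$pos2 < 0L))
      msg <- c(msg, "breakend positions must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SVCallset
#'
#' @param name Callset name (caller name).
#' @param records data.frame of SV records (defaults to empty).
#' @param breakends data.frame of breakend signatures (defaults to empty).
#' @return An [SVCallset-class] object.
#' @examples
#' cs <- SVCallset("toy")
#' numRecords(cs)
#' @export
SVCallset <- function(name, records = emptySVRecords(),
                      breakends = emptyBreakends()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  breakends <- as.data.frame(breakends, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  rownames(breakends) <- NULL
  new("SVCallset", name = name,
      records = records[, .REC_COLS, drop = FALSE],
      breakends = breakends[, .BND_COLS, drop = FALSE])
}

#' @describeIn SVCallset Accessor for the SV record table.
#' @param x,object An SVCallset.
#' @export
svRecords <- function(x) x@records

#' @describeIn SVCallset Accessor for the breakend signature table.
#' @export
breakends <- function(x) x@breakends

#' @describeIn SVCallset Accessor for the callset name.
#' @export
callsetName <- function(x) x@name

#' @describeIn SVCallset Number of SV records (breakends excluded).
#' @export
numRecords <- function(x) nrow(x@records)

setMethod("show", "SVCallset", function(object) {
  cat("SVCallset '", object@name, "': ", nrow(object@records),
      " records, ", nrow(object@breakends), " breakends\n", sep = "")
  if (nrow(object@records)) {
    tab <- table(object@records$svtype)
    cat("  types:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

#' MatchParams: the matching tolerance quadruple (p, P, O, r)
#'
#' Thresholds governing when a call and a truth record are considered the
#' same SV: minimum allele-sequence similarity `p` (0 disables sequence
#' comparison), minimum size similarity `P`, minimum reciprocal overlap `O`
#' (applied to deletions only), and maximum reference distance `r` in bp.
#'
#' @slot p,P,O Numeric thresholds in [0, 1].
#' @slot r Non-negative distance threshold in bp.
#' @export
setClass("MatchParams",
         representation(p = "numeric", P = "numeric",
                        O = "numeric", r = "numeric"))

setValidity("MatchParams", function(object) {
  bad01 <- function(v) length(v) != 1L || is.na(v) || v < 0 || v > 1
  if (bad01(object@p) || bad01(object@P) || bad01(object@O))
    return("p, P and O must be single values in [0, 1]")
  if (length(object@r) != 1L || is.na(object@r) || object@r < 0)
    return("r must be a single non-negative value")
  TRUE
})

#' Construct matching parameters
#'
#' @param p Minimum allele-sequence similarity in [0, 1]; 0 disables the
#'   sequence comparison entirely.
#' @param P Minimum size similarity in [0, 1].
#' @param O Minimum reciprocal overlap in [0, 1] (deletions only).
#' @param r Maximum reference distance in bp.
#' @return A [MatchParams-class] object.
#' @examples
#' matchParams(p = 0, P = 0.5, O = 0, r = 500)
#' @export
matchParams <- function(p = 0, P = 0.5, O = 0, r = 500) {
  new("MatchParams", p = p, P = P, O = O, r = r)
}

#' @describeIn matchParams The moderate-tolerance preset
#'   (p = 0, P = 0.5, O = 0, r = 500).
#' @export
moderateParams <- function() matchParams(p = 0, P = 0.5, O = 0, r = 500)

#' @describeIn matchParams The strict exact-match preset
#'   (p = 1, P = 1, O = 1, r = 0).
#' @export
strictParams <- function() matchParams(p = 1, P = 1, O = 1, r = 0)

setMethod("show", "MatchParams", function(object) {
  cat(sprintf("MatchParams(p=%g, P=%g, O=%g, r=%g)\n",
              object@p, object@P, object@O, object@r))
})

#' BenchResult: TP/FP/FN partition of a call-vs-truth comparison
#'
#' One-to-one assignment of calls to truth records. `tp` carries one row per
#' matched pair with the per-pair similarity measurements (size similarity,
#' reciprocal overlap, reference distance, sequence similarity, breakpoint
#' shift) and a `gt_match` flag for the genotype-concordant subset TP_GT.
#'
#' @slot tp data.frame with columns truth_id, call_id, size_sim, overlap,
#'   ref_dist, seq_sim, shift, gt_match.
#' @slot fp Character vector of unmatched call ids.
#' @slot fn Character vector of unmatched truth ids.
#' @slot n_truth,n_calls Total record counts of the compared sets.
#' @export
setClass("BenchResult",
         representation(tp = "data.frame", fp = "character",
                        fn = "character", n_truth = "integer",
                        n_calls = "integer"))

setValidity("BenchResult", function(object) {
  msg <- character()
  if (nrow(object@tp) + length(object@fn) != object@n_truth)
    msg <- c(msg, "TP + FN must equal the truth count")
  if (nrow(object@tp) + length(object@fp) != object@n_calls)
    msg <- c(msg, "TP + FP must equal the call count")
  if (anyDuplicated(object@tp$truth_id) || anyDuplicated(object@tp$call_id))
    msg <- c(msg, "assignment must be one-to-one")
  if (length(msg)) msg else TRUE
})

.BenchResult <- function(tp, fp, fn, n_truth, n_calls) {
  rownames(tp) <- NULL
  new("BenchResult", tp = tp, fp = as.character(fp), fn = as.character(fn),
      n_truth = as.integer(n_truth), n_calls = as.integer(n_calls))
}

#' @describeIn BenchResult data.frame of matched truth/call pairs.
#' @param x,object A BenchResult.
#' @export
tpPairs <- function(x) x@tp

#' @describeIn BenchResult Genotype-concordant subset of the TP pairs.
#' @export
tpGtPairs <- function(x) x@tp[!is.na(x@tp$gt_match) & x@tp$gt_match, ,
                              drop = FALSE]

#' @describeIn BenchResult Unmatched call ids (false positives).
#' @export
fpIds <- function(x) x@fp

#' @describeIn BenchResult Unmatched truth ids (false negatives).
#' @export
fnIds <- function(x) x@fn

setMethod("show", "BenchResult", function(object) {
  cat(sprintf("BenchResult: TP=%d FP=%d FN=%d (truth=%d, calls=%d)\n",
              nrow(object@tp), length(object@fp), length(object@fn),
              object@n_truth, object@n_calls))
})
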