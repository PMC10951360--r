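#' @importFrom GenomicAlignments explodeCigarOps explodeCigarOpLengths
#' @importFrom Biostrings DNAStringSet subseq
NULL

.FLANK <- 10000L   # flanking sequence on each side of the target SV
.SEG_PAD <- 100L   # segment extends 100 bp into each flank

#' Build the pseudo-read for a candidate SV
#'
#' A pseudo-read carries the candidate SV with 10 kb of flanking reference
#' sequence on each side. For an insertion the read is left flank +
#' inserted sequence + right flank (20 kb + svlen); for a deletion the two
#' flanks are joined directly across the deleted segment (exactly 20 kb).
#' Records whose flanks would run off the chromosome, or insertions without
#' an ALT sequence, are unvalidatable.
#'
#' @param reference A named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param sv A one-row SV record data.frame (DEL or INS).
#' @return A list with elements `seq` (character or NA), `validatable`
#'   (logical) and `reason` (character or NA).
#' @export
buildPseudoread <- function(reference, sv) {
  if (!sv$chrom %in% names(reference))
    return(list(seq = NA_character_, validatable = FALSE,
                reason = "unknown_chromosome"))
  chromSeq <- as.character(reference[[sv$chrom]])
  L <- nchar(chromSeq)
  if (!sv$svtype %in% c("DEL", "INS"))
    return(list(seq = NA_character_, validatable = FALSE,
                reason = "unsupported_type"))
  rightAnchor <- if (sv$svtype == "DEL") sv$end else sv$start
  if (sv$start - .FLANK < 0L || rightAnchor + .FLANK > L)
    return(list(seq = NA_character_, validatable = FALSE,
                reason = "flank_out_of_bounds"))
  left <- substring(chromSeq, sv$start - .FLANK + 1L, sv$start)
  right <- substring(chromSeq, rightAnchor + 1L, rightAnchor + .FLANK)
  if (sv$svtype == "INS") {
    if (is.na(sv$alt) || !nzchar(sv$alt))
      return(list(seq = NA_character_, validatable = FALSE,
                  reason = "missing_sequence"))
    seq <- paste0(left, sv$alt, right)
  } else {
    seq <- paste0(left, right)
  }
  list(seq = seq, validatable = TRUE, reason = NA_character_)
}

#' Build pseudo-reads for a whole callset
#'
#' @param reference As in [buildPseudoread()].
#' @param callset An [SVCallset-class] of DEL/INS candidates.
#' @return A list with `reads` (named [Biostrings::DNAStringSet], one per
#'   validatable record, named by record id) and `status` (data.frame with
#'   id, validatable, reason).
#' @export
buildPseudoreads <- function(reference, callset) {
  r <- svRecords(callset)
  res <- lapply(seq_len(nrow(r)), function(i)
    buildPseudoread(reference, r[i, ]))
  ok <- vapply(res, `[[`, logical(1), "validatable")
  reads <- Biostrings::DNAStringSet(
    vapply(res[ok], `[[`, character(1), "seq"))
  names(reads) <- r$id[ok]
  list(reads = reads,
       status = data.frame(id = r$id, validatable = ok,
                           reason = vapply(res, `[[`, character(1),
                                           "reason"),
                           stringsAsFactors = FALSE))
}

#' Read-coordinate segment of interest of a pseudo-read
#'
#' The scored segment spans the SV plus 100 bp into each flank: insertions
#' `[9900, 10100 + svlen)`, deletions `[9900, 10100)` (the novel adjacency
#' plus context).
#'
#' @param svtype `"DEL"` or `"INS"`.
#' @param svlen SV length in bp (>= 1 for INS).
#' @return Named numeric vector with `start`, `end` (0-based half-open) and
#'   `n_seg` (segment length).
#' @export
segmentOfInterest <- function(svtype, svlen = NULL) {
  if (!svtype %in% c("DEL", "INS"))
    stop("segment of interest is defined for DEL and INS only")
  s <- .FLANK - .SEG_PAD
  if (svtype == "INS") {
    if (is.null(svlen) || svlen < 1L) stop("INS requires svlen >= 1")
    e <- .FLANK + .SEG_PAD + svlen
  } else {
    e <- .FLANK + .SEG_PAD
  }
  c(start = s, end = e, n_seg = e - s)
}

#' Score a pseudo-read alignment for orthogonal SV support
#'
#' Walks the CIGAR of the pseudo-read's primary alignment restricted to the
#' segment of interest and computes the matching percentage
#' `M = n_matching / n_seg * 100` (counting `=` operations; bare `M`
#' operations count as match, flagged via attribute `"m_op_caveat"`), the
#' deletion percentage `D = sum(CDL_i) / svlen * 100` over deletion
#' operations anchored in the segment, and the base shift `B`, the absolute
#' difference between the target coordinate reached after consuming the
#' 10 kb left flank and the candidate's source position. `B` is infinite
#' when the read is unmapped or aligned to a different chromosome.
#'
#' Support requires `M > 95` and `D < 5` (strict inequalities) and, in
#' `"t2t"` mode, additionally `B < 10` Mb; `"verkko"` mode skips the
#' chromosome and base-shift checks.
#'
#' @param alignment A one-row data.frame or list with fields read_name,
#'   target_chrom, target_start (0-based), cigar, mapped, is_primary.
#' @param sv One-row SV record data.frame (DEL or INS).
#' @param sourceChrom,sourcePos Chromosome and 0-based position of the
#'   candidate breakpoint on the source reference; default to the record's.
#' @param mode `"t2t"` or `"verkko"`.
#' @return One-row data.frame: n_matching, n_seg, M, cdl_sum, D, B,
#'   supported, mode.
#' @export
scoreAlignment <- function(alignment, sv, sourceChrom = sv$chrom,
                           sourcePos = sv$start,
                           mode = c("t2t", "verkko")) {
  mode <- match.arg(mode)
  seg <- segmentOfInterest(sv$svtype, sv$svlen)
  nSeg <- unname(seg["n_seg"])
  if (!isTRUE(alignment$mapped)) {
    return(data.frame(n_matching = 0, n_seg = nSeg, M = 0, cdl_sum = 0,
                      D = 0, B = Inf, supported = FALSE, mode = mode))
  }
  ops <- GenomicAlignments::explodeCigarOps(alignment$cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(alignment$cigar)[[1]]
  readLen <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  expLen <- if (sv$svtype == "INS") 2L * .FLANK + sv$svlen else 2L * .FLANK
  if (readLen != expLen)
    stop("cigar consumes ", readLen, " read bases; pseudo-read has ", expLen)
  readConsume <- ifelse(ops %in% c("M", "=", "X", "I", "S"), lens, 0L)
  rpos0 <- cumsum(c(0L, readConsume))[seq_along(ops)]  # read pos before op
  segOv <- pmax(0, pmin(rpos0 + readConsume, seg["end"]) -
                  pmax(rpos0, seg["start"]))
  mCaveat <- any(ops == "M")
  nMatch <- sum(segOv[ops %in% c("=", "M")])
  dIn <- ops == "D" & (rpos0 - 1L) >= seg["start"] & (rpos0 - 1L) < seg["end"]
  cdl <- sum(lens[dIn])
  ## project the left-flank end (10 kb of read) onto the target
  refConsume <- ifelse(ops %in% c("M", "=", "X", "D", "N"), lens, 0L)
  tpos0 <- alignment$target_start + cumsum(c(0L, refConsume))[seq_along(ops)]
  proj <- alignment$target_start + sum(refConsume)
  for (i in seq_along(ops)) {
    if (readConsume[i] > 0L && rpos0[i] + readConsume[i] >= .FLANK) {
      proj <- if (refConsume[i] > 0L) tpos0[i] + (.FLANK - rpos0[i])
              else tpos0[i]
      break
    }
  }
  B <- if (!identical(alignment$target_chrom, sourceChrom)) Inf
       else abs(proj - sourcePos)
  M <- nMatch / nSeg * 100
  D <- cdl / sv$svlen * 100
  supported <- M > 95 && D < 5 && (mode == "verkko" || B < 1e7)
  out <- data.frame(n_matching = nMatch, n_seg = nSeg, M = M,
                    cdl_sum = cdl, D = D, B = B, supported = supported,
                    mode = mode)
  attr(out, "m_op_caveat") <- mCaveat
  out
}

#' Validate a candidate callset against an orthogonal assembly
#'
#' Scores each validatable candidate's primary alignment with
#' [scoreAlignment()] and summarizes the supported fraction per caller and
#' per SV type. Candidates without a primary alignment are unvalidatable
#' and excluded from the denominator; secondary/supplementary alignments
#' are ignored.
#'
#' @param candidates An [SVCallset-class] of DEL/INS candidates.
#' @param alignments A data.frame of alignment records (read_name matching
#'   candidate record ids, target_chrom, target_start, cigar, mapped,
#'   is_primary), e.g. from [simulateAlignments()] or [readSamRecords()].
#' @param mode `"t2t"` or `"verkko"`.
#' @return A list with `scores` (one row per validated record, with id,
#'   caller and svtype), `summary` (per caller x svtype supported
#'   fraction), `n_unvalidatable` and `n_secondary`.
#' @export
validateCallset <- function(candidates, alignments,
                            mode = c("t2t", "verkko")) {
  mode <- match.arg(mode)
  r <- svRecords(candidates)
  r <- r[r$svtype %in% c("DEL", "INS"), , drop = FALSE]
  nSecondary <- sum(!alignments$is_primary)
  alignments <- alignments[alignments$is_primary, , drop = FALSE]
  scores <- list()
  nUnval <- 0L
  for (i in seq_len(nrow(r))) {
    rec <- r[i, ]
    hit <- which(alignments$read_name == rec$id)
    if (!length(hit)) { nUnval <- nUnval + 1L; next }
    sc <- scoreAlignment(alignments[hit[1L], ], rec, mode = mode)
    scores[[rec$id]] <- cbind(data.frame(id = rec$id, caller = rec$sc,
                                         svtype = rec$svtype,
                                         stringsAsFactors = FALSE), sc)
  }
  scores <- if (length(scores)) do.call(rbind, scores)
            else data.frame(id = character(), caller = character(),
                            svtype = character(), supported = logical())
  rownames(scores) <- NULL
  summary <- if (nrow(scores)) {
    agg <- stats::aggregate(list(n_supported = scores$supported,
                                 n_validatable = rep(1L, nrow(scores))),
                            scores[c("caller", "svtype")], sum)
    agg$fraction <- agg$n_supported / agg$n_validatable
    agg
  } else data.frame(caller = character(), svtype = character(),
                    n_supported = integer(), n_validatable = integer(),
                    fraction = numeric())
  list(scores = scores, summary = summary,
       n_unvalidatable = nUnval, n_secondary = nSecondary)
}

## ---- minimal SAM text I/O -------------------------------------------------

#' Read alignment records from a SAM text file
#'
#' Parses the mandatory SAM columns into the alignment data.frame consumed
#' by [scoreAlignment()]; FLAG bits 0x4 (unmapped) and 0x100/0x800
#' (secondary/supplementary) are honored.
#'
#' @param path Path to a SAM file.
#' @return data.frame with read_name, target_chrom, target_start (0-based),
#'   cigar, mapped, is_primary.
#' @export
readSamRecords <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_name = character(), target_chrom = character(),
                      target_start = integer(), cigar = character(),
                      mapped = logical(), is_primary = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  data.frame(
    read_name = vapply(f, `[`, character(1), 1),
    target_chrom = vapply(f, `[`, character(1), 3),
    target_start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    cigar = vapply(f, `[`, character(1), 6),
    mapped = bitwAnd(flag, 4L) == 0L,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    stringsAsFactors = FALSE)
}

#' Write alignment records as SAM text
#'
#' @param alignments Alignment data.frame (see [readSamRecords()]).
#' @param path Output path.
#' @param refLengths Optional named integer vector for `@SQ` header lines.
#' @return Invisibly, `path`.
#' @export
writeSamRecords <- function(alignments, path, refLengths = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(refLengths))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                          as.integer(refLengths)))
  flag <- ifelse(!alignments$mapped, 4L,
                 ifelse(alignments$is_primary, 0L, 256L))
  body <- paste(alignments$read_name, flag,
                ifelse(alignments$mapped, alignments$target_chrom, "*"),
                ifelse(alignments$mapped, alignments$target_start + 1L, 0L),
                ifelse(alignments$mapped, 60L, 0L),
                ifelse(alignments$mapped, alignments$cigar, "*"),
                "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
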