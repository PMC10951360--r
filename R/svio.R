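#' @importFrom VariantAnnotation readVcf rowRanges ref alt info geno
#' @importFrom GenomicRanges GRanges seqnames start countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom rtracklayer import
NULL

## ---- breakend ALT parsing -------------------------------------------------

# The four VCF bracket forms map to strand pairs as:
#   t[p[ -> (+,+)   t]p] -> (+,-)   [p[t -> (-,+)   ]p]t -> (-,-)
# Any fixed bijection works as long as truth and calls pass through the
# same parser; this one is used for both reading and writing.
.BND_RE <- list(
  list(re = "^([A-Za-z.*]*)\\[([^:]+):([0-9]+)\\[$", s1 = "+", s2 = "+"),
  list(re = "^([A-Za-z.*]*)\\]([^:]+):([0-9]+)\\]$", s1 = "+", s2 = "-"),
  list(re = "^\\[([^:]+):([0-9]+)\\[([A-Za-z.*]*)$", s1 = "-", s2 = "+"),
  list(re = "^\\]([^:]+):([0-9]+)\\]([A-Za-z.*]*)$", s1 = "-", s2 = "-")
)

#' Parse a VCF breakend ALT string into a breakend signature
#'
#' Maps the four VCF BND bracket forms to a deterministic
#' (chrom1, pos1, strand1, chrom2, pos2, strand2) signature. Positions are
#' converted to 0-based.
#'
#' @param alt ALT string, e.g. `"N[chr2:1001["`.
#' @param chrom Chromosome of the local breakend.
#' @param pos 0-based position of the local breakend.
#' @return A one-row data.frame with the breakend signature columns.
#' @examples
#' parseBndAlt("N[chr2:1001[", "chr1", 500)
#' @export
parseBndAlt <- function(alt, chrom, pos) {
  for (form in .BND_RE) {
    m <- regmatches(alt, regexec(form$re, alt))[[1]]
    if (length(m)) {
      mate_first <- startsWith(form$re, "^\\[") || startsWith(form$re, "^\\]")
      mchrom <- if (mate_first) m[2] else m[3]
      mpos   <- as.integer(if (mate_first) m[3] else m[4])
      return(data.frame(id = NA_character_, chrom1 = chrom,
                        pos1 = as.integer(pos), strand1 = form$s1,
                        chrom2 = mchrom, pos2 = mpos - 1L,
                        strand2 = form$s2, sc = NA_character_,
                        stringsAsFactors = FALSE))
    }
  }
  stop("unrecognized breakend ALT syntax: '", alt, "' at ", chrom, ":", pos)
}

.bndAltString <- function(chrom2, pos2, strand1, strand2) {
  p <- paste0(chrom2, ":", pos2 + 1L)
  if (strand1 == "+" && strand2 == "+") paste0("N[", p, "[")
  else if (strand1 == "+" && strand2 == "-") paste0("N]", p, "]")
  else if (strand1 == "-" && strand2 == "+") paste0("[", p, "[N")
  else paste0("]", p, "]N")
}

## ---- helpers --------------------------------------------------------------

.firstElt <- function(x, n, as = as.character) {
  if (is.null(x)) return(rep(as(NA), n))
  if (is.list(x) || inherits(x, "List"))
    return(vapply(x, function(e) if (length(e)) as(e[1]) else as(NA), as(NA)))
  as(x)
}

.normGt <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  out <- rep("missing", length(gt))
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt == "1/1"] <- "hom_alt"
  out
}

.gtString <- c(het = "0/1", hom_alt = "1/1", missing = "./.")

## ---- reading --------------------------------------------------------------

#' Read an SV callset from VCF
#'
#' Normalizes a VCF of SV calls into an [SVCallset-class]: 1-based POS is
#' converted to 0-based internal coordinates, symbolic ALTs
#' (`<DEL>`, `<INS>`, `<INV>`, `<DUP>`) are resolved via END/SVLEN INFO,
#' sequence-resolved indels are classified by allele-length difference, and
#' BND records are routed through [parseBndAlt()]. TRA records expressed via
#' CHR2/END INFO are converted to one breakend signature with strands (+,+)
#' unless a STRANDS INFO field is present.
#'
#' Symbolic records lacking both END and SVLEN are skipped with a warning;
#' the skip count is attached as attribute `"n_skipped"`. Malformed
#' genotypes become `"missing"`.
#'
#' @param path Path to a VCF file.
#' @param caller Caller name; initializes the source-caller (SC) field unless
#'   the file already carries SC INFO (as uniform VCFs written by
#'   [writeSVVcf()] do).
#' @return An [SVCallset-class].
#' @export
readSVVcf <- function(path, caller) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)                      # 1-based POS
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- vapply(VariantAnnotation::alt(vcf),
                 function(a) if (length(a)) as.character(a[1]) else NA_character_,
                 character(1))
  inf <- VariantAnnotation::info(vcf)
  svtype <- .firstElt(inf$SVTYPE, n)
  svlen  <- abs(.firstElt(inf$SVLEN, n, as.integer))
  endi   <- .firstElt(inf$END, n, as.integer)
  chr2   <- .firstElt(inf$CHR2, n)
  strands <- .firstElt(inf$STRANDS, n)
  sc <- if (is.null(inf$SC)) rep(NA_character_, n)
        else if (is.list(inf$SC) || inherits(inf$SC, "List"))
          vapply(inf$SC, function(e)
            if (length(e)) paste(e, collapse = ",") else NA_character_,
            character(1))
        else as.character(inf$SC)
  sc[is.na(sc) | sc == ""] <- caller
  ids <- names(rr)
  ids[is.na(ids) | ids == "" | ids == "."] <- paste0(caller, "_", which(
    is.na(ids) | ids == "" | ids == "."))
  ids <- make.unique(ids, sep = "_")
  gtm <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  gts <- if (!is.null(gtm) && ncol(gtm) >= 1L) .normGt(gtm[, 1L])
         else rep("missing", n)

  recs <- emptySVRecords()
  bnds <- emptyBreakends()
  n_skipped <- 0L
  for (i in seq_len(n)) {
    a <- alts[i]
    if (is.na(a)) { n_skipped <- n_skipped + 1L; next }
    is_bracket <- grepl("\\[|\\]", a)
    is_symbolic <- grepl("^<.+>$", a)
    if (is_bracket) {
      b <- parseBndAlt(a, chrom[i], pos[i] - 1L)
      b$id <- ids[i]; b$sc <- sc[i]
      bnds <- rbind(bnds, b)
      next
    }
    if (!is.na(svtype[i]) && svtype[i] %in% c("TRA", "BND") && !is_symbolic) {
      ## CHR2/END-style translocation without bracket notation
      if (!is.na(chr2[i]) && !is.na(endi[i])) {
        st <- if (!is.na(strands[i]) && nchar(strands[i]) == 2L)
          c(substr(strands[i], 1, 1), substr(strands[i], 2, 2)) else c("+", "+")
        bnds <- rbind(bnds, data.frame(
          id = ids[i], chrom1 = chrom[i], pos1 = pos[i] - 1L, strand1 = st[1],
          chrom2 = chr2[i], pos2 = endi[i] - 1L, strand2 = st[2],
          sc = sc[i], stringsAsFactors = FALSE))
      } else n_skipped <- n_skipped + 1L
      next
    }
    start0 <- pos[i] - 1L
    if (is_symbolic || (!is.na(svtype[i]) && svtype[i] %in%
                        c("TRA", "BND", .SVTYPES) && nchar(refs[i]) <= 1L &&
                        is_symbolic)) {
      ty <- sub("^<([A-Za-z]+).*>$", "\\1", a)
      if (!ty %in% c(.SVTYPES, "TRA", "BND")) ty <- svtype[i]
      if (ty %in% c("TRA", "BND")) {
        if (!is.na(chr2[i]) && !is.na(endi[i])) {
          st <- if (!is.na(strands[i]) && nchar(strands[i]) == 2L)
            c(substr(strands[i], 1, 1), substr(strands[i], 2, 2))
          else c("+", "+")
          bnds <- rbind(bnds, data.frame(
            id = ids[i], chrom1 = chrom[i], pos1 = start0, strand1 = st[1],
            chrom2 = chr2[i], pos2 = endi[i] - 1L, strand2 = st[2],
            sc = sc[i], stringsAsFactors = FALSE))
        } else n_skipped <- n_skipped + 1L
        next
      }
      if (is.na(ty) || !ty %in% .SVTYPES) { n_skipped <- n_skipped + 1L; next }
      if (ty == "INS") {
        if (is.na(svlen[i])) { n_skipped <- n_skipped + 1L; next }
        recs <- rbind(recs, data.frame(
          id = ids[i], chrom = chrom[i], start = start0, end = start0,
          svtype = "INS", svlen = svlen[i], ref = "N", alt = NA_character_,
          gt = gts[i], sc = sc[i], stringsAsFactors = FALSE))
      } else {
        if (!is.na(endi[i])) { e <- endi[i]; l <- e - start0 }
        else if (!is.na(svlen[i])) { l <- svlen[i]; e <- start0 + l }
        else { n_skipped <- n_skipped + 1L; next }
        recs <- rbind(recs, data.frame(
          id = ids[i], chrom = chrom[i], start = start0, end = e,
          svtype = ty, svlen = l, ref = "N", alt = NA_character_,
          gt = gts[i], sc = sc[i], stringsAsFactors = FALSE))
      }
      next
    }
    ## sequence-resolved indel: classify by allele-length difference
    diff <- nchar(a) - nchar(refs[i])
    if (diff > 0L) {
      seq <- if (startsWith(a, refs[i])) substring(a, nchar(refs[i]) + 1L) else a
      recs <- rbind(recs, data.frame(
        id = ids[i], chrom = chrom[i], start = start0, end = start0,
        svtype = "INS", svlen = nchar(seq), ref = "N", alt = seq,
        gt = gts[i], sc = sc[i], stringsAsFactors = FALSE))
    } else if (diff < 0L) {
      seq <- if (startsWith(refs[i], a)) substring(refs[i], nchar(a) + 1L)
             else refs[i]
      recs <- rbind(recs, data.frame(
        id = ids[i], chrom = chrom[i], start = start0,
        end = start0 + nchar(seq), svtype = "DEL", svlen = nchar(seq),
        ref = seq, alt = NA_character_,
        gt = gts[i], sc = sc[i], stringsAsFactors = FALSE))
    } else n_skipped <- n_skipped + 1L
  }
  if (n_skipped > 0L)
    warning(n_skipped, " record(s) skipped while reading ", path)
  cs <- SVCallset(caller, recs, bnds)
  attr(cs, "n_skipped") <- n_skipped
  cs
}

## ---- writing --------------------------------------------------------------

#' Write an SVCallset as a uniform VCF
#'
#' Emits VCF 4.2 with SVTYPE, SVLEN, END and the comma-joined SC
#' (source caller) INFO field, plus a GT sample column. Records carrying a
#' comparison sequence (inserted sequence for INS, deleted sequence for DEL)
#' are written sequence-resolved with a padding base so that
#' `readSVVcf(writeSVVcf(x))` preserves all fields; other records are
#' written with symbolic ALTs. Breakends are written as BND records with
#' bracketed ALT.
#'
#' @param callset An [SVCallset-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSVVcf <- function(callset, path) {
  stopifnot(is(callset, "SVCallset"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lrsvbench",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
    '##INFO=<ID=SC,Number=.,Type=String,Description="Source caller list">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE", sep = "\t"))
  r <- callset@records
  lines <- character(0)
  if (nrow(r)) {
    pos1 <- r$start + 1L
    refv <- altv <- character(nrow(r))
    for (i in seq_len(nrow(r))) {
      if (r$svtype[i] == "INS" && !is.na(r$alt[i])) {
        refv[i] <- "N"; altv[i] <- paste0("N", r$alt[i])
      } else if (r$svtype[i] == "DEL" && !is.na(r$ref[i]) && r$ref[i] != "N" &&
                 nchar(r$ref[i]) == r$svlen[i]) {
        refv[i] <- paste0("N", r$ref[i]); altv[i] <- "N"
      } else {
        refv[i] <- "N"; altv[i] <- paste0("<", r$svtype[i], ">")
      }
    }
    infov <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SC=%s",
                     r$svtype, r$svlen, r$end, r$sc)
    lines <- c(lines, paste(r$chrom, pos1, r$id, refv, altv, ".", "PASS",
                            infov, "GT", .gtString[r$gt], sep = "\t"))
  }
  b <- callset@breakends
  if (nrow(b)) {
    altb <- mapply(.bndAltString, b$chrom2, b$pos2, b$strand1, b$strand2)
    infob <- sprintf("SVTYPE=BND;SC=%s", b$sc)
    lines <- c(lines, paste(b$chrom1, b$pos1 + 1L, b$id, "N", altb, ".",
                            "PASS", infob, "GT", "./.", sep = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

## ---- regions and filters --------------------------------------------------

#' Read high-confidence regions from BED
#'
#' @param path Path to a 3-column BED file.
#' @return A reduced (sorted, disjoint) [GenomicRanges::GRanges] object.
#' @export
readRegionsBed <- function(path) {
  GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
}

#' Restrict a callset to high-confidence regions
#'
#' With `mode = "with_constraints"` only records whose reference span
#' `[start, end)` lies fully inside a single region are kept (insertions:
#' the start position must lie inside); `"without_constraints"` returns the
#' input unchanged. Breakend records are not filtered.
#'
#' @param callset An [SVCallset-class].
#' @param regions A [GenomicRanges::GRanges] of regions (as from
#'   [readRegionsBed()]).
#' @param mode `"with_constraints"` or `"without_constraints"`.
#' @return A filtered [SVCallset-class].
#' @export
filterByRegions <- function(callset, regions,
                            mode = c("with_constraints",
                                     "without_constraints")) {
  mode <- match.arg(mode)
  if (mode == "without_constraints") return(callset)
  r <- callset@records
  if (!nrow(r)) return(callset)
  gr <- GenomicRanges::GRanges(
    r$chrom, IRanges::IRanges(start = r$start + 1L,
                              end = pmax(r$end, r$start + 1L)))
  keep <- GenomicRanges::countOverlaps(gr, regions, type = "within") > 0L
  SVCallset(callset@name, r[keep, , drop = FALSE], callset@breakends)
}

#' Remove records below a minimum SV size
#'
#' SVs are conventionally defined as alterations of at least 50 bp; records
#' with `svlen < minSize` are removed. Breakends are kept.
#'
#' @param callset An [SVCallset-class].
#' @param minSize Minimum svlen in bp (default 50).
#' @return A filtered [SVCallset-class].
#' @export
filterBySize <- function(callset, minSize = 50) {
  stopifnot(minSize >= 0)
  r <- callset@records
  SVCallset(callset@name, r[r$svlen >= minSize, , drop = FALSE],
            callset@breakends)
}
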