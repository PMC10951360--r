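# Fixture builders and independent oracles used across the suite.

mkRec <- function(id, chrom = "chr1", start, svtype, svlen,
                  end = if (svtype == "INS") start else start + svlen,
                  ref = "N", alt = NA_character_, gt = "het", sc = "test") {
  data.frame(id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), svtype = svtype,
             svlen = as.integer(svlen), ref = ref, alt = alt, gt = gt,
             sc = sc, stringsAsFactors = FALSE)
}

mkCallset <- function(name, ...) {
  SVCallset(name, do.call(rbind, list(...)))
}

# Plain dynamic-programming Levenshtein distance, independent of the
# implementation path under test.
dpLevenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[n + 1, m + 1]
}

# Exhaustive maximum-cardinality bipartite matching over a logical
# truth x call pass matrix (small instances only).
maxMatching <- function(pass) {
  if (!nrow(pass) || !ncol(pass)) return(0L)
  best <- 0L
  recur <- function(ti, usedCalls, count) {
    if (count + (nrow(pass) - ti + 1L) <= best) return()
    if (ti > nrow(pass)) { best <<- max(best, count); return() }
    for (ci in which(pass[ti, ] & !usedCalls)) {
      usedCalls[ci] <- TRUE
      recur(ti + 1L, usedCalls, count + 1L)
      usedCalls[ci] <- FALSE
    }
    recur(ti + 1L, usedCalls, count)
  }
  recur(1L, rep(FALSE, ncol(pass)), 0L)
  best
}

# Minimal VCF writer for handcrafted malformed/edge-case inputs.
writeTestVcf <- function(path, bodyLines,
                         sample = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##INFO=<ID=SC,Number=1,Type=String,Description="s">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (sample) c("FORMAT", "S1")), collapse = "\t"))
  writeLines(c(hdr, bodyLines), path)
  path
}

zeroNoiseConfig <- function(seed = 3, ...) {
  synthConfig(seed = seed, max_shift = 0, corruption_rate = 0, fp_rate = 0,
              fn_rate = 0, gt_error_rate = 0, ...)
}
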