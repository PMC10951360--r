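localRef <- function(seed = 73, len = 1e5) {
  cfg <- synthConfig(seed = seed, n_chromosomes = 1,
                     chromosome_length = len)
  makeReference(cfg)
}

test_that("pseudo-reads are 20 kb for DEL and 20 kb + svlen for INS", {
  ref <- localRef()
  del <- mkRec("d", start = 40000, svtype = "DEL", svlen = 500)
  pr <- buildPseudoread(ref, del)
  expect_true(pr$validatable)
  expect_equal(nchar(pr$seq), 20000L)
  ins <- mkRec("i", start = 40000, svtype = "INS", svlen = 780,
               alt = paste(rep("ACGT", 195), collapse = ""))
  pri <- buildPseudoread(ref, ins)
  expect_equal(nchar(pri$seq), 20780L)
  ## flanks must match the reference around the breakpoints
  chrom <- as.character(ref[[1]])
  expect_equal(substr(pr$seq, 1, 10000), substr(chrom, 30001, 40000))
  expect_equal(substr(pr$seq, 10001, 20000), substr(chrom, 40501, 50500))
})

test_that("records too close to chromosome ends are unvalidatable", {
  ref <- localRef()
  near <- mkRec("n", start = 5000, svtype = "DEL", svlen = 100)
  pr <- buildPseudoread(ref, near)
  expect_false(pr$validatable)
  expect_equal(pr$reason, "flank_out_of_bounds")
  noseq <- mkRec("s", start = 40000, svtype = "INS", svlen = 100)
  expect_equal(buildPseudoread(ref, noseq)$reason, "missing_sequence")
})

test_that("the segment of interest covers the SV plus 100 bp flanks", {
  segI <- segmentOfInterest("INS", 500)
  expect_equal(unname(segI["start"]), 9900)
  expect_equal(unname(segI["end"]), 10600)
  expect_equal(unname(segI["n_seg"]), 700)
  segD <- segmentOfInterest("DEL", 12345)
  expect_equal(unname(segD["n_seg"]), 200)
  expect_error(segmentOfInterest("INS", 0), "svlen")
  expect_error(segmentOfInterest("INV", 100), "DEL and INS")
})

test_that("a perfect alignment scores M=100, D=0, B=0 and is supported", {
  del <- mkRec("d", start = 40000, svtype = "DEL", svlen = 500)
  aln <- data.frame(read_name = "d", target_chrom = "chr1",
                    target_start = 30000, cigar = "20000=",
                    mapped = TRUE, is_primary = TRUE)
  sc <- scoreAlignment(aln, del)
  expect_equal(sc$M, 100)
  expect_equal(sc$D, 0)
  expect_equal(sc$B, 0)
  expect_true(sc$supported)
})

test_that("a deletion CIGAR of svlen in the segment gives D=100", {
  del <- mkRec("d", start = 40000, svtype = "DEL", svlen = 500)
  aln <- data.frame(read_name = "d", target_chrom = "chr1",
                    target_start = 30000, cigar = "10000=500D10000=",
                    mapped = TRUE, is_primary = TRUE)
  sc <- scoreAlignment(aln, del)
  expect_equal(sc$D, 100)
  expect_false(sc$supported)
  expect_equal(sc$M, 100)  # every segment base still matches
})

test_that("support thresholds are strict inequalities", {
  del <- mkRec("d", start = 40000, svtype = "DEL", svlen = 500)
  ## 10 mismatching bases inside the 200 bp segment: M = 95.0 exactly
  aln <- data.frame(read_name = "d", target_chrom = "chr1",
                    target_start = 30000, cigar = "9990=10X10000=",
                    mapped = TRUE, is_primary = TRUE)
  sc <- scoreAlignment(aln, del)
  expect_equal(sc$M, 95)
  expect_false(sc$supported)
  ## B = 10 Mb exactly is not supported; just under is
  alnB <- data.frame(read_name = "d", target_chrom = "chr1",
                     target_start = 30000 + 1e7, cigar = "20000=",
                     mapped = TRUE, is_primary = TRUE)
  expect_false(scoreAlignment(alnB, del)$supported)
  alnB2 <- alnB; alnB2$target_start <- 30000 + 1e7 - 1
  expect_true(scoreAlignment(alnB2, del)$supported)
})

test_that("verkko mode skips the chromosome and base-shift checks", {
  del <- mkRec("d", start = 40000, svtype = "DEL", svlen = 500)
  cross <- data.frame(read_name = "d", target_chrom = "contig_17",
                      target_start = 30000, cigar = "20000=",
                      mapped = TRUE, is_primary = TRUE)
  expect_false(scoreAlignment(cross, del, mode = "t2t")$supported)
  expect_true(scoreAlignment(cross, del, mode = "verkko")$supported)
  expect_true(is.infinite(scoreAlignment(cross, del, mode = "t2t")$B))
})

test_that("anything supported in t2t mode is supported in verkko mode", {
  cfg <- zeroNoiseConfig(seed = 79, n_del = 10, n_ins = 10, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  for (scen in c("supported", "unsupported", "cross_chrom", "unmapped")) {
    aln <- simulateAlignments(truth, scen, divergence = 0.02, seed = 5)
    t2t <- validateCallset(truth, aln, "t2t")$scores
    verkko <- validateCallset(truth, aln, "verkko")$scores
    expect_true(all(!t2t$supported | verkko$supported), info = scen)
  }
})

test_that("validateCallset reports per-caller supported fractions", {
  cfg <- zeroNoiseConfig(seed = 83, n_del = 5, n_ins = 5, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  good <- simulateAlignments(truth, "supported")
  bad <- simulateAlignments(truth, "unsupported")
  ## 7 true, 3 fabricated
  mixed <- rbind(good[1:7, ], bad[8:10, ])
  val <- validateCallset(truth, mixed, "t2t")
  expect_equal(sum(val$scores$supported) / nrow(val$scores), 0.7)
  ## a record without alignment is unvalidatable, excluded from denominator
  val2 <- validateCallset(truth, good[1:9, ], "t2t")
  expect_equal(val2$n_unvalidatable, 1L)
  expect_equal(nrow(val2$scores), 9L)
})

test_that("SAM records round-trip through text", {
  aln <- data.frame(read_name = c("r1", "r2", "r3"),
                    target_chrom = c("chr1", "chr2", NA),
                    target_start = c(100L, 5000L, NA),
                    cigar = c("500=", "100=5D395=", NA),
                    mapped = c(TRUE, TRUE, FALSE),
                    is_primary = c(TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".sam")
  writeSamRecords(aln, p, refLengths = c(chr1 = 100000L, chr2 = 100000L))
  back <- readSamRecords(p)
  expect_equal(back$read_name, aln$read_name)
  expect_equal(back$mapped, aln$mapped)
  expect_equal(back$is_primary, aln$is_primary)
  expect_equal(back$target_start[1:2], aln$target_start[1:2])
  expect_equal(back$cigar[1:2], aln$cigar[1:2])
})
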