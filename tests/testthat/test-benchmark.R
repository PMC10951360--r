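test_that("self-comparison yields all TP and conservation holds", {
  cfg <- zeroNoiseConfig(seed = 17, n_del = 10, n_ins = 10, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  br <- assignMatches(truth, truth, moderateParams())
  m <- computeMetrics(br)
  expect_equal(m$tp, 20)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  expect_equal(m$f1, 1)
  expect_equal(nrow(tpPairs(br)) + length(fnIds(br)), numRecords(truth))
  expect_equal(nrow(tpPairs(br)) + length(fpIds(br)), numRecords(truth))
})

test_that("dropping every second call halves recall at full precision", {
  cfg <- zeroNoiseConfig(seed = 19, n_del = 10, n_ins = 10, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  r <- svRecords(truth)
  calls <- SVCallset("half", r[seq(1, nrow(r), by = 2), ])
  m <- computeMetrics(assignMatches(truth, calls, moderateParams()))
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 1.0)
})

test_that("greedy picks the higher-scoring of two competing calls", {
  t <- mkCallset("truth",
                 mkRec("t1", start = 10000, svtype = "DEL", svlen = 200))
  calls <- mkCallset("c",
                     mkRec("near", start = 10010, svtype = "DEL", svlen = 200),
                     mkRec("far", start = 10150, svtype = "DEL", svlen = 200))
  br <- assignMatches(t, calls, moderateParams())
  expect_equal(nrow(tpPairs(br)), 1L)
  expect_equal(tpPairs(br)$call_id, "near")
  expect_equal(fpIds(br), "far")
  ## brute force over the two possible assignments agrees: both single
  ## matchings have cardinality 1, greedy must keep the smaller shift
  expect_lt(tpPairs(br)$ref_dist, 150)
})

test_that("metrics follow the standard definitions and degenerate to 0", {
  mk <- function(tp, fp, fn, tpGt = tp) {
    tpdf <- data.frame(truth_id = as.character(seq_len(tp) * 1000),
                       call_id = as.character(seq_len(tp)),
                       size_sim = rep(1, tp), overlap = rep(NA_real_, tp),
                       ref_dist = rep(0, tp), seq_sim = rep(NA_real_, tp),
                       shift = rep(0, tp), gt_match = seq_len(tp) <= tpGt)
    lrsvbench:::.BenchResult(tpdf, as.character(seq_len(fp) + 9000),
                             as.character(seq_len(fn) + 8000),
                             tp + fn, tp + fp)
  }
  m <- computeMetrics(mk(9, 1, 1))
  expect_equal(c(m$recall, m$precision, m$f1), c(0.9, 0.9, 0.9))
  m0 <- computeMetrics(mk(0, 0, 5))
  expect_equal(c(m0$recall, m0$precision, m0$f1), c(0, 0, 0))
  mg <- computeMetrics(mk(10, 0, 0, tpGt = 8))
  expect_equal(mg$gt_f1, 0.8)
  expect_lte(mg$gt_f1, mg$f1)
})

test_that("grid search is exhaustive, cached and conserves counts", {
  cfg <- zeroNoiseConfig(seed = 23, n_del = 15, n_ins = 15, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  g <- gridSearch(truth, truth)
  expect_equal(nrow(g), 121L)
  expect_true(all(g$f1 == 1))
  expect_true(all(g$tp + g$fn == numRecords(truth)))
  expect_true(all(g$tp + g$fp == numRecords(truth)))
})

test_that("calls shifted beyond r never match when r is tight", {
  cfg <- zeroNoiseConfig(seed = 29, n_del = 10, n_ins = 10, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  r <- svRecords(truth)
  r$start <- r$start + 600L
  r$end <- r$end + 600L
  shifted <- SVCallset("shifted", r)
  g <- gridSearch(truth, shifted, pAxis = 0, OAxis = 0,
                  rAxis = seq(0, 1000, 100))
  expect_true(all(g$f1[g$r <= 500] == 0))
  expect_true(all(g$f1[g$r >= 600] == 1))
})

test_that("shift histogram bins at 1 bp with a 200+ overflow bin", {
  cfg <- zeroNoiseConfig(seed = 31, n_del = 8, n_ins = 8, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  br <- assignMatches(truth, truth)
  h <- shiftDistribution(br)
  expect_equal(h$count[h$bin == "0"], numRecords(truth))
  expect_equal(sum(h$count), numRecords(truth))
  ## a DEL matched 20 bp off lands in bin 20; a 250 bp shift in 200+
  t <- mkCallset("t",
                 mkRec("t1", start = 10100, svtype = "DEL", svlen = 500,
                       end = 10600),
                 mkRec("t2", start = 50000, svtype = "INS", svlen = 100))
  calls <- mkCallset("c",
                     mkRec("c1", start = 10120, svtype = "DEL", svlen = 470,
                           end = 10590),
                     mkRec("c2", start = 50250, svtype = "INS", svlen = 100))
  h2 <- shiftDistribution(assignMatches(t, calls, moderateParams()))
  expect_equal(h2$count[h2$bin == "20"], 1L)
  expect_equal(h2$count[h2$bin == "200+"], 1L)
})

test_that("sequence-similarity histogram reports excluded pairs", {
  t <- mkCallset("t",
                 mkRec("t1", start = 10000, svtype = "INS", svlen = 100,
                       alt = strrep("ACGT", 25)),
                 mkRec("t2", start = 20000, svtype = "INV", svlen = 300))
  br <- assignMatches(t, t, matchParams(p = 0.1))
  ## INV has no sequence so it fails under p > 0; rerun at p = 0 and
  ## recompute similarities from the callsets
  br0 <- assignMatches(t, t, moderateParams())
  h <- seqsimDistribution(br0, t, t)
  expect_equal(attr(h, "excluded"), 1L)
  expect_equal(h$count[h$bin == 1], 1L)
  hEmpty <- seqsimDistribution(assignMatches(SVCallset("e"), SVCallset("e")))
  expect_equal(sum(hEmpty$count), 0L)
})

test_that("greedy equals exhaustive maximum matching when spacing > 2r", {
  set.seed(37)
  params <- matchParams(p = 0, P = 0.5, O = 0, r = 200)
  for (k in 1:25) {
    nT <- sample(3:8, 1)
    starts <- cumsum(sample(500:900, nT, TRUE)) + 10000
    truth <- do.call(mkCallset, c(list("t"), lapply(seq_len(nT), function(i)
      mkRec(paste0("t", i), start = starts[i], svtype = "DEL", svlen = 100))))
    keep <- runif(nT) < 0.7
    callRows <- lapply(which(keep), function(i)
      mkRec(paste0("c", i), start = starts[i] + sample(-180:180, 1),
            svtype = "DEL", svlen = sample(60:140, 1)))
    if (!length(callRows)) next
    calls <- do.call(mkCallset, c(list("c"), callRows))
    br <- assignMatches(truth, calls, params)
    tdf <- svRecords(truth); cdf <- svRecords(calls)
    pass <- outer(seq_len(nrow(tdf)), seq_len(nrow(cdf)),
                  Vectorize(function(i, j)
                    matchPredicate(tdf[i, ], cdf[j, ], params)$passed))
    expect_equal(nrow(tpPairs(br)), maxMatching(pass))
  }
})
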