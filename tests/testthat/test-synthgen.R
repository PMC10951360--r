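test_that("the generator is fully deterministic per seed", {
  cfg <- synthConfig(seed = 1, n_tra = 4)
  r1 <- makeReference(cfg); r2 <- makeReference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  t1 <- sampleTruth(r1, cfg); t2 <- sampleTruth(r2, cfg)
  expect_identical(svRecords(t1), svRecords(t2))
  expect_identical(breakends(t1), breakends(t2))
  c1 <- simulateCallset(t1, cfg); c2 <- simulateCallset(t2, cfg)
  expect_identical(svRecords(c1), svRecords(c2))
  cfgB <- synthConfig(seed = 2, n_tra = 4)
  expect_false(identical(as.character(makeReference(cfgB)),
                         as.character(r1)))
})

test_that("the reference has the configured geometry", {
  cfg <- synthConfig(seed = 2, n_chromosomes = 2,
                     chromosome_length = 2e5)
  ref <- makeReference(cfg)
  expect_equal(length(ref), 2L)
  expect_equal(sum(Biostrings::width(ref)), 400000L)
  expect_equal(names(ref), c("chr1", "chr2"))
})

test_that("truth placement honors spacing, sizes and genotype scheme", {
  cfg <- synthConfig(seed = 5, n_del = 10, n_ins = 10, n_inv = 0,
                     n_dup = 0, n_tra = 0, min_spacing = 5000)
  truth <- sampleTruth(makeReference(cfg), cfg)
  r <- svRecords(truth)
  expect_equal(nrow(r), 20L)
  expect_true(all(r$svlen >= 50))
  for (ch in unique(r$chrom)) {
    rc <- r[r$chrom == ch, ]
    rc <- rc[order(rc$start), ]
    if (nrow(rc) > 1)
      expect_true(all(rc$start[-1] - rc$end[-nrow(rc)] >= 5000))
  }
  ## per-chromosome genotypes are uniform (hom chromosome => all hom_alt)
  expect_true(all(tapply(r$gt, r$chrom,
                         function(g) length(unique(g)) == 1L)))
  cfgH <- synthConfig(seed = 5, n_del = 10, n_ins = 10, n_inv = 0,
                      n_dup = 0, n_tra = 0, hom_fraction = 1)
  rh <- svRecords(sampleTruth(makeReference(cfgH), cfgH))
  expect_true(all(rh$gt == "hom_alt"))
})

test_that("TRA truth expands to four breakends per event", {
  cfg <- synthConfig(seed = 7, n_del = 0, n_ins = 0, n_inv = 0, n_dup = 0,
                     n_tra = 10)
  truth <- sampleTruth(makeReference(cfg), cfg)
  expect_equal(nrow(breakends(truth)), 40L)
  expect_equal(nrow(attr(truth, "tra_events")), 10L)
})

test_that("diploid construction follows the per-chromosome genotype scheme", {
  cfg <- synthConfig(seed = 11, n_chromosomes = 4, chromosome_length = 1e5,
                     n_del = 4, n_ins = 4, n_inv = 0, n_dup = 0, n_tra = 0,
                     hom_fraction = 0.5)
  ref <- makeReference(cfg)
  truth <- sampleTruth(ref, cfg)
  dip <- buildDiploid(ref, truth, cfg)
  gmap <- dip$genotype_map
  r <- svRecords(truth)
  for (ch in names(ref)) {
    rc <- r[r$chrom == ch, ]
    expLen <- cfg$chromosome_length +
      sum(rc$svlen[rc$svtype == "INS"]) - sum(rc$svlen[rc$svtype == "DEL"])
    expect_equal(nchar(as.character(dip$hap1[[ch]])), expLen)
    if (gmap[[ch]] == "hom")
      expect_identical(as.character(dip$hap2[[ch]]),
                       as.character(dip$hap1[[ch]]))
    else
      expect_identical(as.character(dip$hap2[[ch]]),
                       as.character(ref[[ch]]))
  }
})

test_that("a single deletion shortens haplotype 1 by its length", {
  cfg <- synthConfig(seed = 13, n_chromosomes = 1,
                     chromosome_length = 1e5, n_del = 1, n_ins = 0,
                     n_inv = 0, n_dup = 0, n_tra = 0)
  ref <- makeReference(cfg)
  truth <- sampleTruth(ref, cfg)
  dip <- buildDiploid(ref, truth, cfg)
  expect_equal(nchar(as.character(dip$hap1[[1]])),
               1e5 - svRecords(truth)$svlen)
})

test_that("zero noise reproduces the truth callset exactly", {
  cfg <- zeroNoiseConfig(seed = 17, n_del = 10, n_ins = 10, n_inv = 5,
                         n_dup = 5, n_tra = 2)
  truth <- sampleTruth(makeReference(cfg), cfg)
  calls <- simulateCallset(truth, cfg)
  r1 <- svRecords(truth); r2 <- svRecords(calls)
  for (col in c("chrom", "start", "end", "svtype", "svlen", "ref", "alt",
                "gt"))
    expect_equal(unname(r2[[col]]), unname(r1[[col]]), info = col)
  b1 <- breakends(truth); b2 <- breakends(calls)
  for (col in c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2"))
    expect_equal(unname(b2[[col]]), unname(b1[[col]]), info = col)
})

test_that("false-negative thinning follows the binomial model", {
  cfg <- synthConfig(seed = 19, n_del = 500, n_ins = 500, n_inv = 0,
                     n_dup = 0, n_tra = 0, n_chromosomes = 2,
                     chromosome_length = 2e6, min_spacing = 1000,
                     max_shift = 0, fn_rate = 0.5, fp_rate = 0,
                     corruption_rate = 0, gt_error_rate = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  calls <- simulateCallset(truth, cfg)
  ## Binomial(1000, 0.5): 3 sigma is about 47
  expect_gt(numRecords(calls), 453)
  expect_lt(numRecords(calls), 547)
})

test_that("constructed alignments realize their scenario exactly", {
  cfg <- zeroNoiseConfig(seed = 23, n_del = 3, n_ins = 3, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  sup <- simulateAlignments(truth, "supported")
  expect_true(all(sup$cigar == paste0(
    ifelse(svRecords(truth)$svtype == "INS",
           20000 + svRecords(truth)$svlen, 20000), "=")))
  uns <- simulateAlignments(truth, "unsupported")
  del <- svRecords(truth)$svtype == "DEL"
  expect_true(all(grepl("D", uns$cigar[del])))
  expect_true(all(grepl("I", uns$cigar[!del])))
  expect_identical(simulateAlignments(truth, "supported", seed = 9),
                   simulateAlignments(truth, "supported", seed = 9))
})

test_that("overlapping germline and somatic truth is refused", {
  cfg <- zeroNoiseConfig(seed = 29, n_del = 5, n_ins = 5, n_inv = 0,
                         n_dup = 0, n_tra = 0)
  truth <- sampleTruth(makeReference(cfg), cfg)
  expect_error(simulateTumorNormal(truth, truth, cfg), "disjoint")
})
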