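#' @importFrom Biostrings DNAStringSet DNAString reverseComplement writeXStringSet
#' @importFrom stats runif rbinom
NULL

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG
## state afterwards, so generator calls are reproducible and side-effect
## free.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Synthetic-data generator configuration
#'
#' Bundles every tunable of the generator: reference geometry, per-type SV
#' counts, the bounded log-uniform size distribution, minimum inter-SV
#' spacing, the breakpoint jitter model (a single shift magnitude per
#' record drawn uniformly from 0..`max_shift`, random sign, applied to both
#' endpoints so SV size is preserved), the per-base substitution rate
#' corrupting comparison sequences, false-positive / false-negative /
#' genotype-error rates, and the fraction of chromosomes made homozygous.
#' Spacing must exceed twice the maximum jitter so that distinct truth
#' records cannot compete for the same call.
#'
#' @param seed Base RNG seed; every generator derives its stream from it.
#' @param n_chromosomes,chromosome_length Reference geometry (bp).
#' @param n_del,n_ins,n_inv,n_dup,n_tra Per-type SV counts.
#' @param size_range Two-element bp range for log-uniform SV sizes.
#' @param min_spacing Minimum distance between placed SVs (bp).
#' @param max_shift Maximum breakpoint jitter magnitude (bp).
#' @param corruption_rate Per-base substitution rate on allele sequences.
#' @param fp_rate,fn_rate,gt_error_rate Error rates in [0, 1].
#' @param hom_fraction Fraction of chromosomes that are homozygous.
#' @param margin Exclusion zone at chromosome ends (bp); at least 10.1 kb
#'   so pseudo-read flanks stay on-chromosome.
#' @return A classed list of settings.
#' @export
synthConfig <- function(seed = 1L, n_chromosomes = 2L,
                        chromosome_length = 1e6, n_del = 30L, n_ins = 30L,
                        n_inv = 20L, n_dup = 40L, n_tra = 20L,
                        size_range = c(50, 1000), min_spacing = 2000L,
                        max_shift = 50L, corruption_rate = 0.05,
                        fp_rate = 0.05, fn_rate = 0.05,
                        gt_error_rate = 0.05, hom_fraction = 0.5,
                        margin = 12000L) {
  rates <- c(corruption_rate, fp_rate, fn_rate, gt_error_rate, hom_fraction)
  stopifnot(all(rates >= 0 & rates <= 1), min_spacing > 2 * max_shift,
            length(size_range) == 2L, size_range[1] >= 50)
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 n_del = as.integer(n_del), n_ins = as.integer(n_ins),
                 n_inv = as.integer(n_inv), n_dup = as.integer(n_dup),
                 n_tra = as.integer(n_tra), size_range = size_range,
                 min_spacing = as.integer(min_spacing),
                 max_shift = as.integer(max_shift),
                 corruption_rate = corruption_rate, fp_rate = fp_rate,
                 fn_rate = fn_rate, gt_error_rate = gt_error_rate,
                 hom_fraction = hom_fraction, margin = as.integer(margin)),
            class = "lrsv_synth_config")
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Generate a seeded random reference genome
#'
#' @param config A [synthConfig()].
#' @return A named [Biostrings::DNAStringSet] ("chr1", "chr2", ...),
#'   deterministic per seed.
#' @export
makeReference <- function(config) {
  .withSeed(config$seed, {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i)
      .randSeq(config$chromosome_length), character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(config$n_chromosomes))
    out
  })
}

## Non-overlapping placement of n intervals with given spans on [margin,
## L - margin] with minimum spacing; returns 0-based starts.
.placeSpaced <- function(n, spans, L, margin, spacing) {
  if (n == 0L) return(integer(0))
  need <- 2 * margin + sum(spans) + (n - 1) * spacing
  if (need > L)
    stop("cannot place ", n, " SVs (", need,
         " bp needed) on a chromosome of ", L,
         " bp; increase chromosome_length or reduce counts/spacing")
  leftover <- L - need
  gaps <- diff(c(0, sort(stats::runif(n, 0, leftover)), leftover))[seq_len(n)]
  starts <- integer(n)
  pos <- margin
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- as.integer(floor(pos))
    pos <- pos + spans[i] + spacing
  }
  starts
}

#' Sample a truth SV set on a reference
#'
#' Places the configured number of DELs, INSs, INVs and DUPs on the
#' reference with at least `min_spacing` between records, draws sizes
#' log-uniformly from `size_range`, fills in allele sequences (inserted
#' sequence for INS, deleted reference sequence for DEL), and assigns
#' genotypes per chromosome: each chromosome is homozygous with probability
#' `hom_fraction` (all its SVs 1/1) and heterozygous otherwise (0/1).
#' Reciprocal translocation events are placed between chromosome pairs and
#' expanded to four breakends each via [expandReciprocalTra()].
#'
#' @param reference A [Biostrings::DNAStringSet] from [makeReference()].
#' @param config A [synthConfig()].
#' @return An [SVCallset-class] named "truth"; attributes `"tra_events"`
#'   (the TRA event table) and `"genotype_map"` (hom/het per chromosome).
#' @export
sampleTruth <- function(reference, config) {
  chroms <- names(reference)
  L <- config$chromosome_length
  .withSeed(config$seed + 1L, {
    hom <- stats::runif(length(chroms)) < config$hom_fraction
    names(hom) <- chroms
    types <- c(rep("DEL", config$n_del), rep("INS", config$n_ins),
               rep("INV", config$n_inv), rep("DUP", config$n_dup))
    n <- length(types)
    recs <- emptySVRecords()
    if (n > 0L) {
      types <- sample(types)
      chromOf <- sample(rep_len(chroms, n))
      lsz <- log(config$size_range)
      sizes <- as.integer(round(exp(stats::runif(n, lsz[1], lsz[2]))))
      sizes <- pmax(sizes, 50L)
      pieces <- lapply(chroms, function(ch) {
        idx <- which(chromOf == ch)
        if (!length(idx)) return(NULL)
        spans <- ifelse(types[idx] == "INS", 0L, sizes[idx])
        starts <- .placeSpaced(length(idx), spans, L, config$margin,
                               config$min_spacing)
        data.frame(idx = idx, chrom = ch, start = starts,
                   stringsAsFactors = FALSE)
      })
      pl <- do.call(rbind, pieces)
      pl <- pl[order(pl$idx), , drop = FALSE]
      refSeq <- alleles <- rep(NA_character_, n)
      ends <- integer(n)
      for (k in seq_len(n)) {
        i <- pl$idx[k]
        ty <- types[i]
        st <- pl$start[k]
        if (ty == "INS") {
          ends[i] <- st
          alleles[i] <- .randSeq(sizes[i])
          refSeq[i] <- "N"
        } else {
          ends[i] <- st + sizes[i]
          refSeq[i] <- if (ty == "DEL")
            substring(as.character(reference[[pl$chrom[k]]]), st + 1L,
                      st + sizes[i]) else "N"
        }
      }
      starts <- integer(n); chromv <- character(n)
      starts[pl$idx] <- pl$start; chromv[pl$idx] <- pl$chrom
      recs <- data.frame(
        id = paste0("truth_", seq_len(n)), chrom = chromv, start = starts,
        end = ends, svtype = types, svlen = sizes, ref = refSeq,
        alt = alleles, gt = ifelse(hom[chromv], "hom_alt", "het"),
        sc = "truth", stringsAsFactors = FALSE)
    }
    events <- NULL
    bnds <- emptyBreakends()
    if (config$n_tra > 0L) {
      if (length(chroms) < 2L)
        stop("reciprocal translocations need at least 2 chromosomes")
      ia <- ((seq_len(config$n_tra) - 1L) %% length(chroms)) + 1L
      ib <- (ia %% length(chroms)) + 1L
      posPool <- lapply(chroms, function(ch) {
        cnt <- sum(chroms[ia] == ch) + sum(chroms[ib] == ch)
        .placeSpaced(cnt, rep(0L, cnt), L, config$margin,
                     config$min_spacing)
      })
      names(posPool) <- chroms
      used <- stats::setNames(rep(0L, length(chroms)), chroms)
      posA <- posB <- integer(config$n_tra)
      for (k in seq_len(config$n_tra)) {
        ca <- chroms[ia[k]]; cb <- chroms[ib[k]]
        used[ca] <- used[ca] + 1L; posA[k] <- posPool[[ca]][used[ca]]
        used[cb] <- used[cb] + 1L; posB[k] <- posPool[[cb]][used[cb]]
      }
      events <- traEvents(chroms[ia], posA, chroms[ib], posB)
      bnds <- expandReciprocalTra(events)
    }
    out <- SVCallset("truth", recs, bnds)
    attr(out, "tra_events") <- events
    attr(out, "genotype_map") <- ifelse(hom, "hom", "het")
    out
  })
}

#' Build a diploid genome carrying the truth SVs
#'
#' Haplotype 1 is the reference with every truth SV applied (DEL removes
#' the segment, INS inserts the allele, INV reverse-complements, DUP
#' tandem-duplicates); edits are applied in descending coordinate order so
#' truth coordinates stay in reference space. Haplotype 2 is, per
#' chromosome, a copy of haplotype 1 (homozygous chromosomes) or of the
#' reference (heterozygous chromosomes). Reciprocal translocation arm
#' exchanges are applied on chromosomes that carry no other edits (mixing
#' both on one chromosome is refused, as coordinates would shift).
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @param truth The truth [SVCallset-class] from [sampleTruth()].
#' @param config A [synthConfig()].
#' @return A list: `hap1`, `hap2` ([Biostrings::DNAStringSet]) and
#'   `genotype_map`.
#' @export
buildDiploid <- function(reference, truth, config) {
  gmap <- attr(truth, "genotype_map")
  if (is.null(gmap))
    gmap <- stats::setNames(rep("het", length(reference)), names(reference))
  events <- attr(truth, "tra_events")
  r <- svRecords(truth)
  if (!is.null(events) && nrow(events) &&
      any(c(events$chrom_a, events$chrom_b) %in% r$chrom))
    stop("cannot mix translocation arm exchanges and intra-chromosomal ",
         "edits on one chromosome; simulate per SV type")
  hap1 <- vapply(names(reference), function(ch) {
    seq <- as.character(reference[[ch]])
    rc <- r[r$chrom == ch, , drop = FALSE]
    rc <- rc[order(-rc$start), , drop = FALSE]
    for (i in seq_len(nrow(rc))) {
      x <- rc[i, ]
      left <- substring(seq, 1L, x$start)
      if (x$svtype == "DEL") {
        seq <- paste0(left, substring(seq, x$end + 1L))
      } else if (x$svtype == "INS") {
        seq <- paste0(left, x$alt, substring(seq, x$start + 1L))
      } else if (x$svtype == "INV") {
        seg <- substring(seq, x$start + 1L, x$end)
        seg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seg)))
        seq <- paste0(left, seg, substring(seq, x$end + 1L))
      } else if (x$svtype == "DUP") {
        seg <- substring(seq, x$start + 1L, x$end)
        seq <- paste0(substring(seq, 1L, x$end), seg,
                      substring(seq, x$end + 1L))
      }
    }
    seq
  }, character(1))
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      a <- hap1[[e$chrom_a]]; b <- hap1[[e$chrom_b]]
      newA <- paste0(substring(a, 1L, e$pos_a), substring(b, e$pos_b + 1L))
      newB <- paste0(substring(b, 1L, e$pos_b), substring(a, e$pos_a + 1L))
      hap1[[e$chrom_a]] <- newA
      hap1[[e$chrom_b]] <- newB
    }
  }
  refChar <- vapply(names(reference),
                    function(ch) as.character(reference[[ch]]),
                    character(1))
  hap2 <- ifelse(gmap[names(reference)] == "hom", hap1, refChar)
  h1 <- Biostrings::DNAStringSet(hap1); names(h1) <- names(reference)
  h2 <- Biostrings::DNAStringSet(hap2); names(h2) <- names(reference)
  list(hap1 = h1, hap2 = h2, genotype_map = gmap)
}

.corrupt <- function(seq, rate) {
  if (is.na(seq) || rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    repl <- vapply(bases[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    bases[hit] <- repl
  }
  paste(bases, collapse = "")
}

#' Simulate a caller-like callset from a truth set
#'
#' Emulates the error structure of a real SV caller: each truth record is
#' dropped with probability `fn_rate`; survivors get a breakpoint jitter
#' (one magnitude drawn uniformly from 0..`max_shift`, random sign, applied
#' to both endpoints, size preserved), their comparison sequence is
#' corrupted base-by-base at `corruption_rate` (substitutions only), and
#' their genotype is flipped (het/hom) with probability `gt_error_rate`.
#' Fabricated false positives are added at rate `fp_rate` at random loci at
#' least `min_spacing` away from truth records. Truth breakends are
#' likewise thinned and jittered. With all rates and jitter zero the output
#' equals the truth.
#'
#' @param truth The truth [SVCallset-class].
#' @param config A [synthConfig()].
#' @param name Caller name for the output callset.
#' @param seed RNG seed for this callset (defaults to `config$seed + 11`;
#'   give each simulated caller its own).
#' @return An [SVCallset-class]; attribute `"sim_params"` records the
#'   generating parameters.
#' @export
simulateCallset <- function(truth, config, name = "sim",
                            seed = config$seed + 11L) {
  r <- svRecords(truth)
  b <- breakends(truth)
  .withSeed(seed, {
    keep <- stats::runif(nrow(r)) >= config$fn_rate
    out <- r[keep, , drop = FALSE]
    n <- nrow(out)
    if (n > 0L) {
      mag <- if (config$max_shift > 0L)
        sample(0:config$max_shift, n, replace = TRUE) else rep(0L, n)
      sgn <- sample(c(-1L, 1L), n, replace = TRUE)
      delta <- mag * sgn
      out$start <- pmax(0L, out$start + delta)
      out$end <- ifelse(out$svtype == "INS", out$start, out$end + delta)
      if (config$corruption_rate > 0) {
        ins <- out$svtype == "INS" & !is.na(out$alt)
        out$alt[ins] <- vapply(out$alt[ins], .corrupt, character(1),
                               rate = config$corruption_rate)
        del <- out$svtype == "DEL" & !is.na(out$ref) & out$ref != "N"
        out$ref[del] <- vapply(out$ref[del], .corrupt, character(1),
                               rate = config$corruption_rate)
      }
      flip <- stats::runif(n) < config$gt_error_rate & out$gt != "missing"
      out$gt[flip] <- ifelse(out$gt[flip] == "het", "hom_alt", "het")
      out$id <- paste0(name, "_", seq_len(n))
      out$sc <- name
    }
    nFp <- stats::rbinom(1L, nrow(r), config$fp_rate)
    if (nFp > 0L && nrow(r) > 0L) {
      L <- config$chromosome_length
      fps <- lapply(seq_len(nFp), function(k) {
        ty <- sample(unique(r$svtype), 1L)
        sz <- as.integer(round(exp(stats::runif(
          1, log(config$size_range[1]), log(config$size_range[2])))))
        sz <- max(sz, 50L)
        ch <- sample(unique(r$chrom), 1L)
        occupied <- r$start[r$chrom == ch]
        for (try in 1:200) {
          st <- as.integer(floor(stats::runif(
            1, config$margin, L - config$margin - sz)))
          if (!length(occupied) ||
              min(abs(occupied - st)) > config$min_spacing) break
        }
        data.frame(
          id = paste0(name, "_fp", k), chrom = ch, start = st,
          end = if (ty == "INS") st else st + sz, svtype = ty, svlen = sz,
          ref = if (ty == "DEL") .randSeq(sz) else "N",
          alt = if (ty == "INS") .randSeq(sz) else NA_character_,
          gt = sample(c("het", "hom_alt"), 1L), sc = name,
          stringsAsFactors = FALSE)
      })
      out <- rbind(out, do.call(rbind, fps))
    }
    bo <- b
    if (nrow(b)) {
      keepB <- stats::runif(nrow(b)) >= config$fn_rate
      bo <- b[keepB, , drop = FALSE]
      m <- nrow(bo)
      if (m > 0L) {
        magB <- if (config$max_shift > 0L)
          sample(0:config$max_shift, m, replace = TRUE) else rep(0L, m)
        sgnB <- sample(c(-1L, 1L), m, replace = TRUE)
        bo$pos1 <- pmax(0L, bo$pos1 + magB * sgnB)
        bo$pos2 <- pmax(0L, bo$pos2 + magB * sgnB)
        bo$id <- paste0(name, "_bnd", seq_len(m))
        bo$sc <- name
      }
    }
    cs <- SVCallset(name, out, bo)
    attr(cs, "sim_params") <- config[c("fn_rate", "fp_rate", "max_shift",
                                       "corruption_rate", "gt_error_rate")]
    cs
  })
}

#' Simulate a tumor/normal callset pair
#'
#' The normal callset is a noisy observation of the germline truth; the
#' tumor callset observes the union of germline and somatic truth. The
#' somatic truth is returned unchanged for downstream evaluation.
#'
#' @param germlineTruth,somaticTruth [SVCallset-class] objects with
#'   disjoint loci.
#' @param config A [synthConfig()].
#' @return A list: `tumor`, `normal`, `somatic_truth`.
#' @export
simulateTumorNormal <- function(germlineTruth, somaticTruth, config) {
  g <- svRecords(germlineTruth); s <- svRecords(somaticTruth)
  if (nrow(g) && nrow(s)) {
    for (ch in intersect(unique(g$chrom), unique(s$chrom))) {
      gi <- g[g$chrom == ch, ]; si <- s[s$chrom == ch, ]
      ov <- outer(gi$start, si$end, `<=`) & outer(gi$end, si$start, `>=`)
      if (any(ov))
        stop("germline and somatic truth loci must be disjoint")
    }
  }
  s2 <- s
  clash <- s2$id %in% g$id
  s2$id[clash] <- paste0("som.", s2$id[clash])
  sb <- breakends(somaticTruth)
  gb <- breakends(germlineTruth)
  clashB <- sb$id %in% gb$id
  sb$id[clashB] <- paste0("som.", sb$id[clashB])
  tumorTruth <- SVCallset("tumor_truth", rbind(g, s2), rbind(gb, sb))
  list(tumor = simulateCallset(tumorTruth, config, "tumor",
                               seed = config$seed + 211L),
       normal = simulateCallset(germlineTruth, config, "normal",
                                seed = config$seed + 101L),
       somatic_truth = somaticTruth)
}

#' Construct alignment records for pseudo-reads analytically
#'
#' Builds, per DEL/INS candidate, the alignment its pseudo-read would get
#' against a chosen target, without running an aligner:
#' `"supported"` (target carries the SV) gives an all-match CIGAR with `X`
#' substitutions sprinkled at `divergence`; `"unsupported"` (target lacks
#' the SV) gives flank matches around a `D` (deletion candidates) or `I`
#' (insertion candidates) operation of length svlen; `"cross_chrom"` is the
#' supported alignment on a differently named chromosome; `"unmapped"`
#' produces unmapped records. Target starts are chosen so the left-flank
#' projection lands on the source breakpoint (base shift 0 for mapped
#' same-chromosome records).
#'
#' @param callset An [SVCallset-class] of DEL/INS candidates.
#' @param scenario One of `"supported"`, `"unsupported"`, `"cross_chrom"`,
#'   `"unmapped"`.
#' @param divergence Per-base substitution rate of the target (default 0).
#' @param seed RNG seed for the divergence draws.
#' @return An alignment data.frame consumable by [validateCallset()].
#' @export
simulateAlignments <- function(callset, scenario = c("supported",
                                                     "unsupported",
                                                     "cross_chrom",
                                                     "unmapped"),
                               divergence = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  r <- svRecords(callset)
  r <- r[r$svtype %in% c("DEL", "INS"), , drop = FALSE]
  .withSeed(seed, {
    rows <- lapply(seq_len(nrow(r)), function(i) {
      rec <- r[i, ]
      readLen <- if (rec$svtype == "INS") 2L * .FLANK + rec$svlen
                 else 2L * .FLANK
      if (scenario == "unmapped")
        return(data.frame(read_name = rec$id, target_chrom = NA_character_,
                          target_start = NA_integer_, cigar = NA_character_,
                          mapped = FALSE, is_primary = TRUE,
                          stringsAsFactors = FALSE))
      if (scenario == "unsupported") {
        cigar <- if (rec$svtype == "DEL")
          sprintf("%d=%dD%d=", .FLANK, rec$svlen, .FLANK)
        else sprintf("%d=%dI%d=", .FLANK, rec$svlen, .FLANK)
      } else {
        mism <- stats::runif(readLen) < divergence
        rl <- rle(mism)
        cigar <- paste0(rl$lengths, ifelse(rl$values, "X", "="),
                        collapse = "")
      }
      chrom <- if (scenario == "cross_chrom") paste0(rec$chrom, "_alt")
               else rec$chrom
      data.frame(read_name = rec$id, target_chrom = chrom,
                 target_start = rec$start - .FLANK, cigar = cigar,
                 mapped = TRUE, is_primary = TRUE, stringsAsFactors = FALSE)
    })
    if (!length(rows))
      return(data.frame(read_name = character(), target_chrom = character(),
                        target_start = integer(), cigar = character(),
                        mapped = logical(), is_primary = logical()))
    do.call(rbind, rows)
  })
}
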