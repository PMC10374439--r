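test_that("PAM scan emits one pair per 4-nt PAM", {
  lib <- buildLibrary(libraryDesign(n_guides = 1,
                                    mismatch_targets_per_guide = 0,
                                    pam_scan = TRUE), seed = 5)
  p <- as.data.frame(pairData(lib))
  scan <- p[grepl("_pam", p$pair_id), ]
  expect_equal(nrow(scan), 256L)
  expect_equal(length(unique(scan$pam4)), 256L)
  expect_equal(length(lib), 257L) # plus the matched pair
})

test_that("mismatch panel design emits 30 x 98 mismatched plus 30 matched pairs", {
  lib <- buildLibrary(libraryDesign(n_guides = 30,
                                    mismatch_targets_per_guide = 98),
                      seed = 9)
  p <- as.data.frame(pairData(lib))
  expect_equal(sum(p$n_mismatch == 0L), 30L)
  expect_equal(sum(p$n_mismatch > 0L), 30L * 98L)
  expect_true(all(p$n_mismatch <= 3L))
  mm <- as.data.frame(mismatchData(lib))
  designed <- mm[!mm$five_prime_g, ]
  expect_true(all(designed$position_pam >= 1 & designed$position_pam <= 20))
  expect_true(all(designed$mclass %in%
                    c("wobble", "nonwobble_transition", "transversion")))
  # designed annotations round-trip through the annotator
  idx <- sample(nrow(p), 50)
  for (i in idx) {
    ann <- annotateMismatches(p$spacer[i],
                              substr(p$context[i], 5, 24),
                              p$expression_system[i])
    stored <- mm[mm$pair_id == p$pair_id[i], ]
    expect_equal(ann$position_pam, stored$position_pam)
    expect_equal(ann$mclass, stored$mclass)
  }
})

test_that("library generation is reproducible given the seed", {
  spec <- libraryDesign(n_guides = 4, mismatch_targets_per_guide = 6)
  a <- buildLibrary(spec, seed = 42)
  b <- buildLibrary(spec, seed = 42)
  c <- buildLibrary(spec, seed = 43)
  expect_identical(as.data.frame(pairData(a)), as.data.frame(pairData(b)))
  expect_false(identical(as.data.frame(pairData(a)),
                         as.data.frame(pairData(c))))
})

test_that("infeasible class requests raise a design error naming the position", {
  spec <- libraryDesign(n_guides = 1, mismatch_targets_per_guide = 5,
                        class_mix = c(wobble = 1, nonwobble_transition = 0,
                                      transversion = 0))
  # a spacer always contains at least one A/C position among 20 random
  # bases, where wobble is infeasible; with wobble-only weights the build
  # must fail once such a position is drawn
  expect_error(
    for (s in 1:50) buildLibrary(spec, seed = s),
    "infeasible class_mix.*position")
})

test_that("landscape activity encodes PAM and mismatch penalties", {
  lib <- buildLibrary(libraryDesign(n_guides = 5,
                                    mismatch_targets_per_guide = 0),
                      seed = 2)
  p <- as.data.frame(pairData(lib))
  # non-NG twin of each NGG pair
  twin <- p
  twin$pair_id <- paste0(p$pair_id, "_t")
  substr(twin$context, 26, 26) <- "T"
  both <- GuideTargetLibrary(rbind(p, twin))
  # under a flat position-weight matrix the twins differ by the PAM factor
  # exactly; under the default weights the changed PAM base also moves the
  # logistic score, so only a loose ratio bound applies
  flat <- defaultLandscape()
  flat$pwm[] <- 0
  act_flat <- landscapeActivity(both, flat)
  expect_equal(unname(act_flat[twin$pair_id] / act_flat[p$pair_id]),
               rep(0.01, nrow(p)))
  act <- landscapeActivity(both)
  ngg <- act[p$pair_id]
  nng <- act[twin$pair_id]
  expect_true(all(nng <= 0.05 * ngg))
  # three transversion mismatches cut activity to below 5 percent
  spec3 <- libraryDesign(n_guides = 5, mismatch_targets_per_guide = 3,
                         mismatch_counts = c(`1` = 0, `2` = 0, `3` = 1),
                         class_mix = c(wobble = 0, nonwobble_transition = 0,
                                       transversion = 1))
  lib3 <- buildLibrary(spec3, seed = 3)
  act3 <- landscapeActivity(lib3)
  p3 <- as.data.frame(pairData(lib3))
  on <- act3[p3$pair_id[p3$n_mismatch == 0]]
  for (g in unique(p3$guide_id)) {
    offs <- act3[p3$pair_id[p3$guide_id == g & p3$n_mismatch == 3L]]
    expect_true(all(offs / on[paste0(g, "_on")] < 0.05))
  }
  # per-pair values are order-invariant
  shuf <- sample(length(both))
  act_perm <- landscapeActivity(both[shuf])
  expect_equal(act_perm, act[pairIds(both)[shuf]])
})

test_that("simulated counts have binomial moments around the truth", {
  truth0 <- data.frame(pair_id = "x", true_pct = 10, background_pct = 0,
                       day7_factor = 1)
  z <- simulateCounts(truth0, depth = 0, seed = 1)
  expect_true(all(z$total_reads == 0L & z$indel_reads == 0L))
  n <- 1000
  truth <- data.frame(pair_id = sprintf("p%04d", 1:n), true_pct = 25,
                      background_pct = 0, day7_factor = 1)
  cnt <- simulateCounts(truth, depth = 10000, seed = 8, days = 4,
                        replicates = 1)
  frac <- cnt$indel_reads / cnt$total_reads
  se <- sd(frac) / sqrt(n)
  expect_lt(abs(mean(frac) - 0.25), 3 * se + 1e-12)
  # reproducibility
  expect_identical(cnt, simulateCounts(truth, depth = 10000, seed = 8,
                                       days = 4, replicates = 1))
})

test_that("background-only counts correct to zero on average", {
  n <- 500
  truth <- data.frame(pair_id = sprintf("p%04d", 1:n), true_pct = 0,
                      background_pct = 8, day7_factor = 1)
  cnt <- simulateCounts(truth, depth = 5000, seed = 4, days = 4,
                        replicates = 1)
  corr <- correctBackground(cnt$indel_reads, cnt$total_reads,
                            cnt$background_pct, clip = FALSE)
  expect_lt(abs(mean(corr)), 3 * sd(corr) / sqrt(n))
})

test_that("simulated reads honor the planting probability", {
  lib <- buildLibrary(libraryDesign(n_guides = 3,
                                    mismatch_targets_per_guide = 0),
                      seed = 6)
  refs <- referenceAmplicons(lib)
  clean <- simulateReads(lib, n_reads = 50, p_indel = 0, seed = 1,
                         error_rate = 0)
  expect_true(all(clean$reads == refs[clean$truth$pair_id]))
  all_indel <- simulateReads(lib, n_reads = 200, p_indel = 1, seed = 2,
                             error_rate = 0)
  q <- quantifyReads(all_indel$reads, lib)
  expect_true(all(q$indel_reads == q$total_reads))
  expect_true(all(q$total_reads > 0))
})

test_that("FASTQ output carries no truth and round-trips", {
  lib <- buildLibrary(libraryDesign(n_guides = 2,
                                    mismatch_targets_per_guide = 0),
                      seed = 6)
  rr <- simulateReads(lib, n_reads = 20, p_indel = 0.5, seed = 3)
  fq <- tempfile(fileext = ".fastq")
  writeReadsFastq(rr$reads, fq)
  back <- readReadsFastq(fq)
  expect_equal(unname(back), unname(rr$reads))
  expect_false(any(grepl("pair|indel|g00", names(back))))
})

test_that("trace simulation respects population fractions and determinism", {
  sp <- fretSpec(donor_only_frac = 1, f_unwound_true = 0.5)
  tr <- simulateTraces(sp, n_molecules = 100, seed = 1)
  E <- fretEfficiency(tr)
  expect_lt(mean(E), 0.12)
  expect_lt(mean(acceptorIntensity(tr)), 0.12 * 1000)
  tr2 <- simulateTraces(fretSpec(), n_molecules = 50, seed = 9)
  tr3 <- simulateTraces(fretSpec(), n_molecules = 50, seed = 9)
  expect_identical(donorIntensity(tr2), donorIntensity(tr3))
  # no transitions when the flip probability is zero
  expect_equal(transitionFraction(tr2), 0)
})
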