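test_that("specificity and relative activity are exact complements", {
  expect_equal(specificity(50, 0), 1)
  expect_equal(specificity(50, 50), 0)
  expect_equal(specificity(80, 20), 0.75)
  expect_equal(relativeActivity(0, 50), 0)
  expect_equal(relativeActivity(25, 50), 0.5)
  expect_true(is.na(specificity(0, 10)))
  set.seed(2)
  on <- runif(100, 1, 90)
  off <- runif(100, 0, 90)
  expect_equal(specificity(on, off) + relativeActivity(off, on),
               rep(1, 100))
})

# shared simulated screen: 12 guides x 30 single-mismatch targets at depth
# 2000 with a position-only penalty landscape (class tolerances = 1)
sim_screen <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    params <- defaultLandscape(class_tolerance = c(
      wobble = 1, nonwobble_transition = 1, transversion = 1))
    lib <- buildLibrary(libraryDesign(
      n_guides = 12, mismatch_targets_per_guide = 30,
      mismatch_counts = c(`1` = 1, `2` = 0, `3` = 0),
      expression_system = "tRNA_N20"), seed = 31)
    truth <- makeGroundTruth(lib, params, bg_mean_pct = 1, seed = 32)
    cnt <- simulateCounts(truth, depth = 2000, seed = 33)
    freq <- applyFilters(mergeReplicates(cnt))
    freq <- freq[freq$day == 4, ]
    cache <<- list(lib = lib, params = params, freq = freq,
                   recs = specificityRecords(freq[freq$day == 4, ], lib))
    cache
  }
})

test_that("specificity records join on-targets correctly", {
  s <- sim_screen()
  expect_true(all(s$recs$n_mismatch >= 1))
  expect_true(all(s$recs$specificity <= 1 + 1e-9))
  # with clipped corrected frequencies and off <= on, specificity in [0,1]
  sub <- s$recs[s$recs$off_pct <= s$recs$on_pct, ]
  expect_true(all(sub$specificity >= 0 & sub$specificity <= 1))
  # permutation invariance of the summaries
  shuf <- s$recs[sample(nrow(s$recs)), ]
  expect_equal(positionwiseSpecificity(shuf),
               positionwiseSpecificity(s$recs))
})

test_that("PAM profile ranks NGG first under the synthetic landscape", {
  lib <- buildLibrary(libraryDesign(n_guides = 4,
                                    mismatch_targets_per_guide = 0,
                                    pam_scan = TRUE), seed = 41)
  truth <- makeGroundTruth(lib, bg_mean_pct = 0.5, seed = 42)
  cnt <- simulateCounts(truth, depth = 1500, seed = 43, days = 4,
                        replicates = 1:2)
  freq <- applyFilters(mergeReplicates(cnt))
  prof <- pamProfile(freq, lib)
  expect_identical(prof$by_class$pam_class[1], "NGG")
  expect_true(all(diff(prof$by_class$mean_pct) <= 0))
  expect_equal(sum(prof$by_class$n), sum(freq$passed_filters))
  # single record per group equals that record
  one <- freq[freq$pair_id == pairIds(lib)[1], , drop = FALSE]
  p1 <- pamProfile(one, lib)
  expect_equal(p1$by_pam4$mean_pct, one$corrected_pct)
})

test_that("position-wise specificity tracks the per-position penalties", {
  s <- sim_screen()
  prof <- positionwiseSpecificity(s$recs)
  tol <- s$params$position_tolerance
  expect_true(all(prof$n >= 1))
  rho <- cor(prof$mean_specificity, (1 - tol)[prof$position_pam],
             method = "spearman")
  expect_gte(rho, 0.9)
  # per-guide averaging agrees in rank
  prof_g <- positionwiseSpecificity(s$recs, per_guide = TRUE)
  expect_gte(cor(prof$mean_specificity, prof_g$mean_specificity,
                 method = "spearman"), 0.9)
})

test_that("tolerant positions show low specificity, intolerant high", {
  # complete intolerance everywhere -> specificity near 1 at every position
  params0 <- defaultLandscape(position_tolerance = rep(0.001, 20),
                              class_tolerance = c(
                                wobble = 1, nonwobble_transition = 1,
                                transversion = 1))
  lib <- buildLibrary(libraryDesign(
    n_guides = 10, mismatch_targets_per_guide = 20,
    mismatch_counts = c(`1` = 1, `2` = 0, `3` = 0),
    expression_system = "tRNA_N20"), seed = 51)
  truth <- makeGroundTruth(lib, params0, bg_mean_pct = 0.2, seed = 52)
  freq <- applyFilters(mergeReplicates(simulateCounts(truth, depth = 4000,
                                                      seed = 53)))
  recs <- specificityRecords(freq[freq$day == 4, ], lib)
  prof <- positionwiseSpecificity(recs)
  expect_true(all(prof$mean_specificity > 0.9))
  # full tolerance at position 18 only -> profile dips there
  tol <- rep(0.001, 20)
  tol[18] <- 1
  params18 <- defaultLandscape(position_tolerance = tol,
                               class_tolerance = c(
                                 wobble = 1, nonwobble_transition = 1,
                                 transversion = 1))
  truth18 <- makeGroundTruth(lib, params18, bg_mean_pct = 0.2, seed = 54)
  freq18 <- applyFilters(mergeReplicates(simulateCounts(truth18,
                                                        depth = 4000,
                                                        seed = 55)))
  recs18 <- specificityRecords(freq18[freq18$day == 4, ], lib)
  prof18 <- positionwiseSpecificity(recs18)
  at18 <- prof18$mean_specificity[prof18$position_pam == 18]
  expect_lt(at18, 0.1)
  expect_true(all(prof18$mean_specificity[prof18$position_pam != 18] > 0.9))
})

test_that("mismatch strata order by designed tolerance", {
  params <- defaultLandscape(
    position_tolerance = rep(1, 20),
    class_tolerance = c(wobble = 0.8, nonwobble_transition = 0.4,
                        transversion = 0.1))
  lib <- buildLibrary(libraryDesign(
    n_guides = 10, mismatch_targets_per_guide = 40), seed = 61)
  truth <- makeGroundTruth(lib, params, bg_mean_pct = 0.5, seed = 62)
  freq <- applyFilters(mergeReplicates(simulateCounts(truth, depth = 2000,
                                                      seed = 63)))
  recs <- specificityRecords(freq[freq$day == 4, ], lib)
  strat <- stratifyByMismatch(recs)
  bc <- strat$by_class
  expect_gt(bc$median[bc$mclass == "wobble"],
            bc$median[bc$mclass == "transversion"])
  # multiplicative penalties < 1: more mismatches, lower relative activity
  ct <- strat$by_count
  expect_lte(ct$median[ct$n_mismatch == "3"],
             ct$median[ct$n_mismatch == "1"])
})

test_that("trade-off points order variants as designed", {
  lib <- buildLibrary(libraryDesign(
    n_guides = 10, mismatch_targets_per_guide = 20,
    mismatch_counts = c(`1` = 1, `2` = 0, `3` = 0)), seed = 71)
  hi_spec <- defaultLandscape(class_tolerance = c(
    wobble = 0.1, nonwobble_transition = 0.1, transversion = 0.05))
  lo_spec <- defaultLandscape(class_tolerance = c(
    wobble = 0.95, nonwobble_transition = 0.9, transversion = 0.85))
  tabs <- list()
  recs <- list()
  for (v in c("A_precise", "B_sloppy")) {
    par <- if (v == "A_precise") hi_spec else lo_spec
    truth <- makeGroundTruth(lib, par, bg_mean_pct = 0.5, seed = 72)
    f <- applyFilters(mergeReplicates(
      simulateCounts(truth, depth = 2000, seed = 73, variant = v)))
    f <- f[f$day == 4, ]
    tabs[[v]] <- f
    recs[[v]] <- specificityRecords(f, lib)
  }
  freq <- do.call(rbind, tabs)
  rr <- do.call(rbind, recs)
  pts <- tradeoffSummary(freq, rr, lib)
  expect_gt(pts$general_specificity[pts$variant == "A_precise"],
            pts$general_specificity[pts$variant == "B_sloppy"])
  # medians invariant to record order
  pts2 <- tradeoffSummary(freq[sample(nrow(freq)), ],
                          rr[sample(nrow(rr)), ], lib)
  expect_equal(pts, pts2)
  # one variant, one record: the point equals that record
  one_on <- freq[freq$pair_id == paste0(pairData(lib)$guide_id[1], "_on") &
                   freq$variant == "A_precise", ][1, , drop = FALSE]
  one_rec <- rr[rr$variant == "A_precise", ][1, , drop = FALSE]
  pt1 <- tradeoffSummary(one_on, one_rec, lib)
  expect_equal(pt1$general_activity, one_on$corrected_pct)
  expect_equal(pt1$general_specificity, one_rec$specificity)
})

test_that("comparable-guide selection applies the range criterion", {
  grid <- expand.grid(guide_id = sprintf("g%03d", 1:100),
                      variant = c("v1", "v2", "v3"), day = c(4, 7),
                      stringsAsFactors = FALSE)
  set.seed(81)
  base <- runif(100, 20, 60)
  names(base) <- sprintf("g%03d", 1:100)
  grid$on_pct <- base[grid$guide_id]
  divergent <- sprintf("g%03d", 31:100)
  bump <- grid$guide_id %in% divergent & grid$variant == "v3"
  grid$on_pct[bump] <- grid$on_pct[bump] + runif(sum(bump), 10, 30)
  sel <- selectComparableGuides(grid, tolerance = 5)
  expect_equal(sel, sprintf("g%03d", 1:30))
  expect_equal(length(selectComparableGuides(grid, tolerance = 100)), 100L)
  expect_equal(selectComparableGuides(grid, tolerance = 0),
               sprintf("g%03d", 1:30)) # identical across variants
})
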