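test_that("background correction matches the closed-form expression", {
  expect_equal(correctBackground(50, 1000, 0), 5.0)
  expect_equal(correctBackground(10, 1000, 1), 0.0)
  expect_equal(correctBackground(110, 1000, 1), 100 * (110 - 10) / (1000 - 10))
  # equals the raw percentage at zero background
  expect_equal(correctBackground(c(3, 77), c(120, 300), 0),
               100 * c(3, 77) / c(120, 300))
  # undefined cases
  expect_true(is.na(correctBackground(0, 0, 1)))
  expect_true(is.na(correctBackground(10, 100, 100)))
  # clipping keeps the raw value recoverable
  expect_equal(correctBackground(1, 1000, 5), 0)
  expect_lt(correctBackground(1, 1000, 5, clip = FALSE), 0)
})

test_that("background correction is monotone in its arguments", {
  set.seed(21)
  total <- 1000L
  indel <- sort(sample(0:total, 50))
  val <- correctBackground(indel, total, 3, clip = FALSE)
  expect_true(all(diff(val) >= 0))
  bgs <- seq(0, 20, by = 0.5)
  val2 <- correctBackground(250, total, bgs, clip = FALSE)
  expect_true(all(diff(val2) <= 0))
})

test_that("replicate pooling sums counts and never averages ratios", {
  rec <- data.frame(pair_id = "p1", variant = "v", day = 4,
                    replicate = 1:2,
                    total_reads = c(100L, 100L), indel_reads = c(10L, 10L),
                    background_pct = 0)
  m <- mergeReplicates(rec)
  expect_equal(m$total_reads, 200L)
  expect_equal(m$indel_reads, 20L)
  expect_equal(100 * m$indel_reads / m$total_reads, 10)
  # unequal replicates pool to the count-weighted frequency
  rec2 <- data.frame(pair_id = "p1", variant = "v", day = 4,
                     replicate = 1:2,
                     total_reads = c(100L, 100L), indel_reads = c(0L, 20L),
                     background_pct = 0)
  m2 <- mergeReplicates(rec2)
  expect_equal(100 * m2$indel_reads / m2$total_reads, 10)
  # merging a record with itself doubles counts, leaves the corrected
  # frequency unchanged
  rec3 <- data.frame(pair_id = "p9", variant = "v", day = 7, replicate = 1:2,
                     total_reads = 400L, indel_reads = 60L,
                     background_pct = 2)
  m3 <- mergeReplicates(rec3)
  expect_equal(m3$total_reads, 800L)
  expect_equal(correctBackground(m3$indel_reads, m3$total_reads,
                                 m3$background_pct),
               correctBackground(60, 400, 2))
  expect_error(mergeReplicates(rec[, setdiff(names(rec), "pair_id")]),
               "pair_id")
})

test_that("pooled background uses control counts when available", {
  rec <- data.frame(pair_id = "p1", variant = "v", day = 4, replicate = 1:2,
                    total_reads = c(500L, 1000L), indel_reads = c(50L, 80L),
                    background_pct = c(1, 4),
                    control_total_reads = c(1000L, 500L),
                    control_indel_reads = c(10L, 20L))
  m <- mergeReplicates(rec)
  expect_equal(m$background_pct, 100 * 30 / 1500)
})

test_that("exclusion rules are strict as printed, boundaries retained", {
  rec <- data.frame(pair_id = c("a", "b", "c", "d", "e"),
                    total_reads = c(99L, 100L, 5000L, 5000L, 5000L),
                    indel_reads = c(10L, 10L, 100L, 100L, 100L),
                    background_pct = c(1, 1, 8, 8.5, 1))
  out <- applyFilters(rec)
  expect_equal(out$passed_filters, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$fail_reason, c("low_reads", NA, NA, "high_background", NA))
})

test_that("filter fixture: planted failures are excluded exactly", {
  set.seed(30)
  n <- 1000
  rec <- data.frame(pair_id = sprintf("p%04d", 1:n),
                    total_reads = sample(200:5000, n, replace = TRUE),
                    background_pct = runif(n, 0, 7.5))
  low <- 1:100
  high <- 101:150
  rec$total_reads[low] <- sample(0:99, 100, replace = TRUE)
  rec$background_pct[high] <- runif(50, 8.01, 30)
  rec$indel_reads <- rbinom(n, rec$total_reads, 0.2)
  out <- applyFilters(rec)
  expect_equal(sum(out$passed_filters), 850L)
  expect_identical(which(!out$passed_filters), 1:150)
})

test_that("reads assign by barcode with ambiguity protection", {
  lib <- tiny_library(barcodes = c("AAAAAAAA", "AAAACCCC"))
  refs <- referenceAmplicons(lib)
  expect_equal(unname(assignReads(unname(refs), lib)), c("p1", "p2"))
  # one barcode mismatch still assigns
  r <- refs[["p1"]]
  bpos <- nchar(r) - 12 - 8 + 1
  substr(r, bpos, bpos) <- "G"
  expect_equal(unname(assignReads(r, lib)), "p1")
  # equidistant key -> unassigned
  r2 <- refs[["p1"]]
  substr(r2, bpos, bpos + 7) <- "AAAAAACC" # distance 2 from both barcodes
  expect_true(is.na(assignReads(r2, lib)))
  # duplicate index keys are a library error
  dup <- tiny_library(barcodes = c("AAAAAAAA", "AAAAAAAA"))
  expect_error(assignReads(refs[[1]], dup), "duplicate")
})

test_that("indel calls respect the cut-site window", {
  lib <- tiny_library()
  ref <- referenceAmplicons(lib)[["p1"]]
  cut <- ampliconCutSite()
  expect_identical(callIndels(ref, ref), "no_indel")
  # 2-bp deletion spanning the cut site
  del <- paste0(substr(ref, 1, cut - 1), substr(ref, cut + 2, nchar(ref)))
  expect_identical(callIndels(del, ref), "indel")
  # insertion at the cut site
  ins <- paste0(substr(ref, 1, cut), "GTCA", substr(ref, cut + 1, nchar(ref)))
  expect_identical(callIndels(ins, ref), "indel")
  # substitutions never count
  sub <- ref
  substr(sub, cut, cut) <- setdiff(DNA, substr(ref, cut, cut))[1]
  expect_identical(callIndels(sub, ref), "no_indel")
  # deletion far outside the window is not an indel call
  far <- paste0(substr(ref, 1, 2), substr(ref, 5, nchar(ref)))
  expect_identical(callIndels(far, ref), "no_indel")
  # unalignable read is excluded
  expect_true(is.na(callIndels(paste(rep("A", 60), collapse = ""), ref)))
})

test_that("error-free planted reads are called at 99.5 percent accuracy", {
  lib <- buildLibrary(libraryDesign(n_guides = 4,
                                    mismatch_targets_per_guide = 0),
                      seed = 17)
  rr <- simulateReads(lib, n_reads = 500, p_indel = 0.5, seed = 18,
                      error_rate = 0)
  refs <- referenceAmplicons(lib)
  calls <- rep(NA_character_, length(rr$reads))
  for (ix in split(seq_along(rr$reads), rr$truth$pair_id))
    calls[ix] <- callIndels(rr$reads[ix], refs[[rr$truth$pair_id[ix[1]]]])
  truth <- ifelse(rr$truth$planted_indel, "indel", "no_indel")
  acc <- mean(calls == truth, na.rm = TRUE)
  expect_gte(acc, 0.995)
})

test_that("simulated reads with errors assign at 99 percent accuracy", {
  lib <- buildLibrary(libraryDesign(n_guides = 20,
                                    mismatch_targets_per_guide = 0),
                      seed = 19)
  rr <- simulateReads(lib, n_reads = 500, p_indel = 0.2, seed = 20,
                      error_rate = 0.001)
  assigned <- assignReads(rr$reads, lib)
  ok <- !is.na(assigned) & assigned == rr$truth$pair_id
  expect_gte(mean(ok), 0.99)
  expect_true(all(assigned[!is.na(assigned)] == rr$truth$pair_id[!is.na(assigned)]))
})

test_that("pooling invariance: corrected frequency of merged replicates", {
  lib <- buildLibrary(libraryDesign(n_guides = 10,
                                    mismatch_targets_per_guide = 5),
                      seed = 23)
  truth <- makeGroundTruth(lib, seed = 24)
  cnt <- simulateCounts(truth, depth = 800, seed = 25)
  pooled <- mergeReplicates(cnt)
  # manual summation per pair x day
  key <- paste(cnt$pair_id, cnt$day)
  manual_tot <- tapply(cnt$total_reads, key, sum)
  manual_ind <- tapply(cnt$indel_reads, key, sum)
  pkey <- paste(pooled$pair_id, pooled$day)
  expect_equal(as.numeric(manual_tot[pkey]), as.numeric(pooled$total_reads))
  expect_equal(as.numeric(manual_ind[pkey]), as.numeric(pooled$indel_reads))
  expect_equal(correctBackground(pooled$indel_reads, pooled$total_reads,
                                 pooled$background_pct),
               correctBackground(as.numeric(manual_ind[pkey]),
                                 as.numeric(manual_tot[pkey]),
                                 pooled$background_pct))
})
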