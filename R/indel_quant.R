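## Read assignment, indel calling, background correction, replicate pooling
## and the screen's exclusion rules.

#' Quantification configuration
#'
#' @param cut_site_offset Distance (bp) of the blunt cut site 5' of the PAM.
#' @param indel_window_halfwidth Half-width (bp) of the window around the cut
#'   site within which an insertion/deletion op counts as an indel.
#' @param min_total_reads Pairs with fewer total reads are excluded
#'   (strictly fewer: exactly `min_total_reads` passes).
#' @param max_background_pct Pairs with higher background indel frequency are
#'   excluded (strictly greater: exactly `max_background_pct` passes).
#' @param max_assign_mismatches Barcode mismatches tolerated by the
#'   assignment fallback after the exact-match pass.
#' @param match,mismatch,gap Alignment scores for indel calling.
#' @param min_align_frac Score floor, as a fraction of the perfect-match
#'   score; reads below it are unassignable and excluded from totals.
#' @return A `QuantConfig` list.
#' @export
quantConfig <- function(cut_site_offset = 3L, indel_window_halfwidth = 4L,
                        min_total_reads = 100L, max_background_pct = 8,
                        max_assign_mismatches = 2L,
                        match = 2L, mismatch = -2L, gap = -5L,
                        min_align_frac = 0.5) {
  cut_after <- .PAM_START - 1L - as.integer(cut_site_offset)
  w <- as.integer(indel_window_halfwidth)
  if (cut_after - w + 1L < 1L || cut_after + w > .CONTEXT_LEN)
    stop("indel window must lie within the 30-nt context", call. = FALSE)
  structure(list(cut_site_offset = as.integer(cut_site_offset),
                 indel_window_halfwidth = w,
                 cut_after_context = cut_after,
                 min_total_reads = as.integer(min_total_reads),
                 max_background_pct = max_background_pct,
                 max_assign_mismatches = as.integer(max_assign_mismatches),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), min_align_frac = min_align_frac),
            class = "QuantConfig")
}

#' Assign reads to library pairs
#'
#' Reads are assigned on the per-pair barcode embedded in the amplicon
#' (3'-anchored, so upstream indels do not shift it): an exact hash lookup
#' first, then a fallback accepting up to `max_assign_mismatches` barcode
#' mismatches.  A read matching two pairs equally well is left unassigned.
#'
#' @param reads Character vector of read sequences.
#' @param library A [GuideTargetLibrary-class]; barcodes must be unique
#'   (duplicate index keys are an error).
#' @param config A [quantConfig()].
#' @return Character vector of pair ids (NA = unassigned), parallel to
#'   `reads`.
#' @export
assignReads <- function(reads, library, config = quantConfig()) {
  p <- pairData(library)
  if (anyDuplicated(p$barcode))
    stop("duplicate index keys: library barcodes are not unique",
         call. = FALSE)
  rp <- nchar(.RIGHT_PRIMER)
  n <- nchar(reads)
  key <- substring(reads, n - rp - .BARCODE_LEN + 1L, n - rp)
  hit <- p$pair_id[match(key, p$barcode)]
  miss <- which(is.na(hit) & nchar(key) == .BARCODE_LEN)
  if (length(miss) && config$max_assign_mismatches > 0L) {
    bc <- .char_matrix(p$barcode)
    for (i in miss) {
      km <- strsplit(key[i], "", fixed = TRUE)[[1]]
      d <- rowSums(bc != matrix(km, nrow(bc), .BARCODE_LEN, byrow = TRUE))
      dm <- min(d)
      if (dm <= config$max_assign_mismatches && sum(d == dm) == 1L)
        hit[i] <- p$pair_id[which.min(d)]
    }
  }
  hit
}

#' Call indels in reads against a reference amplicon
#'
#' Reads identical to the reference are called `no_indel` directly; all other
#' reads are aligned (pairwise, end-free) and called `indel` iff an
#' insertion/deletion op overlaps the window
#' `[cut - w + 1, cut + w]` around the cut site.  Substitutions never count.
#' Reads whose alignment score falls below the floor are `NA` (excluded from
#' totals).
#'
#' @param reads Character vector of read sequences (assigned to this
#'   reference).
#' @param reference Reference amplicon sequence (from
#'   [referenceAmplicons()]), or a bare 30-nt context.
#' @param config A [quantConfig()].
#' @return Character vector `"indel"` / `"no_indel"` / `NA`.
#' @export
callIndels <- function(reads, reference, config = quantConfig()) {
  has_primer <- nchar(reference) > .CONTEXT_LEN
  cut <- config$cut_after_context + if (has_primer) nchar(.LEFT_PRIMER) else 0L
  w <- config$indel_window_halfwidth
  out <- rep(NA_character_, length(reads))
  exact <- !is.na(reads) & reads == reference
  out[exact] <- "no_indel"
  todo <- which(!exact & !is.na(reads))
  if (length(todo)) {
    code <- .align_indel_window(reads[todo], reference,
                                cut - w + 1L, cut + w,
                                config$match, config$mismatch, config$gap,
                                config$min_align_frac)
    out[todo] <- c("no_indel", "indel")[code + 1L]
  }
  out
}

#' Quantify reads into per-pair counts
#'
#' Assigns reads, calls indels against each pair's reference amplicon and
#' tabulates total (assigned and callable) and indel read counts per pair.
#'
#' @param reads Named character vector of read sequences.
#' @param library A [GuideTargetLibrary-class].
#' @param config A [quantConfig()].
#' @return data.frame with `pair_id`, `total_reads`, `indel_reads` (one row
#'   per library pair, zero counts included), with the number of unassigned
#'   reads in attribute `"n_unassigned"`.
#' @export
quantifyReads <- function(reads, library, config = quantConfig()) {
  assigned <- assignReads(reads, library, config)
  refs <- referenceAmplicons(library)
  ids <- pairIds(library)
  total <- setNames(integer(length(ids)), ids)
  indel <- setNames(integer(length(ids)), ids)
  keep <- !is.na(assigned)
  sp <- split(which(keep), assigned[keep])
  for (pid in names(sp)) {
    calls <- callIndels(reads[sp[[pid]]], refs[[pid]], config)
    total[pid] <- sum(!is.na(calls))
    indel[pid] <- sum(calls == "indel", na.rm = TRUE)
  }
  out <- data.frame(pair_id = ids, total_reads = as.integer(total),
                    indel_reads = as.integer(indel),
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- sum(!keep)
  out
}

#' Background-corrected indel frequency
#'
#' Removes the background indel frequency measured in a no-nuclease control:
#' `100 * (indel - total * bg/100) / (total - total * bg/100)`.
#' Values below 0 are clipped to 0 when `clip = TRUE` (the raw value can be
#' recovered with `clip = FALSE`).  Records with `total_reads = 0` or
#' `background_pct >= 100` are undefined (`NA`).
#'
#' @param indel_reads,total_reads Integer counts.
#' @param background_pct Background indel frequency (percent).
#' @param clip Clip negative corrected values to 0?
#' @return Corrected indel frequency in percent.
#' @examples
#' correctBackground(110, 1000, 1) # 100 * (110 - 10) / (1000 - 10)
#' @export
correctBackground <- function(indel_reads, total_reads, background_pct,
                              clip = TRUE) {
  bgr <- total_reads * background_pct / 100
  out <- 100 * (indel_reads - bgr) / (total_reads - bgr)
  out[total_reads == 0 | background_pct >= 100] <- NA_real_
  if (clip) out <- pmax(out, 0)
  out
}

#' Pool replicate read counts
#'
#' Combines replicates by summing read counts per `pair_id` x `variant` x
#' `day` (never by averaging per-replicate frequencies: pooled counts weight
#' replicates by their depth).  Background is pooled the same way from
#' control counts when `control_total_reads` / `control_indel_reads` columns
#' are present; otherwise the per-replicate `background_pct` is combined as a
#' read-weighted mean.
#'
#' @param records data.frame of read-count records with columns `pair_id`,
#'   `total_reads`, `indel_reads`, `background_pct` and the grouping columns.
#' @param by Grouping columns.
#' @return data.frame of pooled records (one row per group).
#' @export
mergeReplicates <- function(records, by = c("pair_id", "variant", "day")) {
  by <- intersect(by, names(records))
  if (!"pair_id" %in% by)
    stop("aggregation error: records must be grouped by pair_id",
         call. = FALSE)
  g <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  idx <- !duplicated(g)
  out <- records[idx, by, drop = FALSE]
  key <- g[idx]
  out$total_reads <- as.integer(rowsum(records$total_reads, g)[as.character(key), 1])
  out$indel_reads <- as.integer(rowsum(records$indel_reads, g)[as.character(key), 1])
  if (all(c("control_total_reads", "control_indel_reads") %in% names(records))) {
    ct <- rowsum(records$control_total_reads, g)[as.character(key), 1]
    ci <- rowsum(records$control_indel_reads, g)[as.character(key), 1]
    out$control_total_reads <- as.integer(ct)
    out$control_indel_reads <- as.integer(ci)
    out$background_pct <- ifelse(ct > 0, 100 * ci / ct, NA_real_)
  } else {
    wsum <- rowsum(records$background_pct * records$total_reads, g)
    tsum <- rowsum(records$total_reads, g)
    out$background_pct <- ifelse(
      tsum[as.character(key), 1] > 0,
      wsum[as.character(key), 1] / tsum[as.character(key), 1],
      rowsum(records$background_pct, g)[as.character(key), 1] /
        as.integer(table(g)[as.character(key)]))
  }
  rownames(out) <- NULL
  out
}

#' Apply the screen's exclusion rules and tabulate frequencies
#'
#' Excludes records with fewer than `min_total_reads` total reads or with
#' background indel frequencies greater than `max_background_pct`; boundary
#' values (exactly at either threshold) are retained, matching the strict
#' inequalities of the filtering rules.  Adds raw and background-corrected
#' frequencies.
#'
#' @param records data.frame with `pair_id`, `total_reads`, `indel_reads`,
#'   `background_pct` (and any condition columns, which are carried
#'   through).
#' @param config A [quantConfig()].
#' @return data.frame with added columns `raw_pct`, `corrected_pct`
#'   (clipped at 0), `corrected_unclipped`, `passed_filters`, `fail_reason`.
#' @export
applyFilters <- function(records, config = quantConfig()) {
  out <- records
  out$raw_pct <- ifelse(records$total_reads > 0,
                        100 * records$indel_reads / records$total_reads,
                        NA_real_)
  out$corrected_pct <- correctBackground(records$indel_reads,
                                         records$total_reads,
                                         records$background_pct)
  out$corrected_unclipped <- correctBackground(records$indel_reads,
                                               records$total_reads,
                                               records$background_pct,
                                               clip = FALSE)
  low <- records$total_reads < config$min_total_reads
  high <- records$background_pct > config$max_background_pct
  out$passed_filters <- !low & !high & !is.na(out$corrected_pct)
  reason <- character(nrow(records))
  reason[high] <- "high_background"
  reason[low] <- ifelse(reason[low] == "", "low_reads",
                        "low_reads;high_background")
  reason[reason == ""] <- NA_character_
  out$fail_reason <- reason
  out
}

#' Background rates from a no-nuclease control run
#'
#' @param control_counts Count table from [quantifyReads()] (or
#'   [simulateCounts()]) for the control condition.
#' @return data.frame `pair_id`, `background_pct`, plus the control counts.
#' @export
backgroundFromControl <- function(control_counts) {
  g <- control_counts$pair_id
  ct <- rowsum(control_counts$total_reads, g)
  ci <- rowsum(control_counts$indel_reads, g)
  data.frame(pair_id = rownames(ct),
             control_total_reads = as.integer(ct[, 1]),
             control_indel_reads = as.integer(ci[, 1]),
             background_pct = ifelse(ct[, 1] > 0, 100 * ci[, 1] / ct[, 1],
                                     NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
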