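## Specificity, PAM-compatibility, mismatch-stratification and
## activity-specificity trade-off summaries over filtered frequency tables.

#' Specificity and relative activity
#'
#' `specificity()` is `1 - off/on`: 1 means no off-target activity, 0 full
#' tolerance of the mismatch.  `relativeActivity()` is its complement
#' `off/on`, so `specificity + relativeActivity = 1` per record.  Both are
#' undefined (NA) when the on-target frequency is not positive.
#'
#' @param on_pct On-target corrected indel frequency (percent).
#' @param off_pct Off-target corrected indel frequency (percent).
#' @return Numeric fraction (vectorized); NA where `on_pct <= 0`.
#' @examples
#' specificity(80, 20) # 0.75
#' relativeActivity(25, 50) # 0.5
#' @export
specificity <- function(on_pct, off_pct) {
  ifelse(on_pct > 0, 1 - off_pct / on_pct, NA_real_)
}

#' @rdname specificity
#' @export
relativeActivity <- function(off_pct, on_pct) {
  ifelse(on_pct > 0, off_pct / on_pct, NA_real_)
}

#' Pair off-target records with their on-target reference
#'
#' Joins each mismatched pair's filtered frequency with the matched
#' (0-mismatch) pair of the same guide under the same condition, producing
#' one specificity record per off-target measurement.  Records whose
#' on-target frequency is zero (specificity undefined) are dropped and
#' counted in attribute `"n_undefined"`.
#'
#' @param freq_table Filtered frequency table from [applyFilters()]
#'   (only rows with `passed_filters` are used), with condition columns
#'   `variant` and `day` if present.
#' @param library The [GuideTargetLibrary-class] the table was measured on.
#' @return data.frame of specificity records: `guide_id`, `pair_id`,
#'   condition columns, `on_pct`, `off_pct`, `specificity`,
#'   `relative_activity`, `n_mismatch`, `positions`, `classes`.
#' @export
specificityRecords <- function(freq_table, library) {
  p <- as.data.frame(pairData(library))
  tab <- freq_table[freq_table$passed_filters, , drop = FALSE]
  tab$guide_id <- p$guide_id[match(tab$pair_id, p$pair_id)]
  tab$n_mismatch <- p$n_mismatch[match(tab$pair_id, p$pair_id)]
  cond <- intersect(c("variant", "day"), names(tab))
  key <- function(d) do.call(paste, c(d[c("guide_id", cond)], sep = "\r"))
  on <- tab[tab$n_mismatch == 0L, , drop = FALSE]
  off <- tab[tab$n_mismatch > 0L, , drop = FALSE]
  on_pct <- on$corrected_pct[match(key(off), key(on))]
  mm <- as.data.frame(mismatchData(library))
  mm <- mm[!mm$five_prime_g, , drop = FALSE]
  pos <- vapply(split(mm$position_pam, mm$pair_id), paste, "",
                collapse = ",")
  cls <- vapply(split(mm$mclass, mm$pair_id), paste, "", collapse = ",")
  out <- data.frame(guide_id = off$guide_id, pair_id = off$pair_id,
                    off[cond],
                    on_pct = on_pct, off_pct = off$corrected_pct,
                    specificity = specificity(on_pct, off$corrected_pct),
                    relative_activity = relativeActivity(off$corrected_pct,
                                                         on_pct),
                    n_mismatch = off$n_mismatch,
                    positions = unname(pos[off$pair_id]),
                    classes = unname(cls[off$pair_id]),
                    stringsAsFactors = FALSE)
  defined <- !is.na(out$specificity)
  res <- out[defined, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_undefined") <- sum(!defined)
  res
}

#' PAM compatibility profile
#'
#' Mean corrected indel frequency per 4-nt PAM and per 3-nt PAM class over
#' filtered matched-target records, ordered by decreasing mean.  Empty
#' groups are omitted (with a message).
#'
#' @param freq_table Filtered frequency table ([applyFilters()] output).
#' @param library The [GuideTargetLibrary-class].
#' @return List with data.frames `by_pam4` and `by_class` (columns group,
#'   `mean_pct`, `n`).
#' @export
pamProfile <- function(freq_table, library) {
  p <- as.data.frame(pairData(library))
  tab <- freq_table[freq_table$passed_filters, , drop = FALSE]
  tab$pam4 <- p$pam4[match(tab$pair_id, p$pair_id)]
  tab$pam_class <- classifyPam(tab$pam4)
  keep <- !is.na(tab$corrected_pct)
  if (sum(!keep)) message(sum(!keep), " records without defined frequency omitted")
  tab <- tab[keep, , drop = FALSE]
  agg <- function(g) {
    m <- tapply(tab$corrected_pct, tab[[g]], mean)
    d <- data.frame(group = names(m), mean_pct = as.numeric(m),
                    n = as.integer(table(tab[[g]])[names(m)]),
                    stringsAsFactors = FALSE)
    names(d)[1] <- g
    d[order(-d$mean_pct), , drop = FALSE]
  }
  list(by_pam4 = agg("pam4"), by_class = agg("pam_class"))
}

#' Mean specificity by mismatch position
#'
#' Restricted to single-mismatch records; reports the mean specificity per
#' PAM-anchored position with the number of contributing records.  With
#' `per_guide = TRUE`, specificities are averaged within guide before
#' averaging across guides.
#'
#' @param spec_records [specificityRecords()] output.
#' @param per_guide Average per guide first?
#' @return data.frame `position_pam`, `mean_specificity`, `n`.
#' @export
positionwiseSpecificity <- function(spec_records, per_guide = FALSE) {
  one <- spec_records[spec_records$n_mismatch == 1L, , drop = FALSE]
  if (nrow(one) == 0L)
    return(data.frame(position_pam = integer(0), mean_specificity = numeric(0),
                      n = integer(0)))
  one$position_pam <- as.integer(one$positions)
  if (per_guide) {
    byg <- aggregate(specificity ~ position_pam + guide_id, one, mean)
    m <- tapply(byg$specificity, byg$position_pam, mean)
  } else {
    m <- tapply(one$specificity, one$position_pam, mean)
  }
  n <- table(one$position_pam)[names(m)]
  out <- data.frame(position_pam = as.integer(names(m)),
                    mean_specificity = as.numeric(m), n = as.integer(n))
  out[order(out$position_pam), , drop = FALSE]
}

#' Stratify relative activity by mismatch number and class
#'
#' Summaries of the relative-activity distribution per mismatch count (1, 2,
#' 3) and, over single-mismatch records, per mismatch class.  Empty strata
#' are omitted (with a message).
#'
#' @param spec_records [specificityRecords()] output.
#' @return List of data.frames `by_count` and `by_class` with `n`, `median`
#'   and `mean` relative activity.
#' @export
stratifyByMismatch <- function(spec_records) {
  strat <- function(x, g, label) {
    g <- factor(g)
    present <- levels(g)[tabulate(g, nlevels(g)) > 0L]
    if (length(present) < nlevels(g))
      message("empty ", label, " strata omitted: ",
              paste(setdiff(levels(g), present), collapse = ","))
    d <- data.frame(stratum = present,
                    n = as.integer(table(g)[present]),
                    median = as.numeric(tapply(x, g, median)[present]),
                    mean = as.numeric(tapply(x, g, mean)[present]),
                    stringsAsFactors = FALSE)
    names(d)[1] <- label
    d
  }
  one <- spec_records[spec_records$n_mismatch == 1L, , drop = FALSE]
  list(by_count = strat(spec_records$relative_activity,
                        factor(spec_records$n_mismatch, levels = 1:3),
                        "n_mismatch"),
       by_class = strat(one$relative_activity,
                        factor(one$classes, levels = .MM_CLASSES),
                        "mclass"))
}

#' Activity-specificity trade-off points
#'
#' One point per variant: general activity as the median on-target corrected
#' frequency over filtered matched NGG pairs, and general specificity as the
#' median single-mismatch specificity.  Medians match the box-plot-centric
#' presentation of variant comparisons; means are available via `center`.
#'
#' @param freq_table Filtered frequency table with a `variant` column.
#' @param spec_records [specificityRecords()] output (same variants).
#' @param library The [GuideTargetLibrary-class].
#' @param center `"median"` (default) or `"mean"`.
#' @return data.frame `variant`, `general_activity`, `general_specificity`,
#'   `n_on`, `n_off`.
#' @export
tradeoffSummary <- function(freq_table, spec_records, library,
                            center = c("median", "mean")) {
  center <- match.fun(match.arg(center))
  p <- as.data.frame(pairData(library))
  tab <- freq_table[freq_table$passed_filters, , drop = FALSE]
  tab$n_mismatch <- p$n_mismatch[match(tab$pair_id, p$pair_id)]
  tab$pam_class <- classifyPam(p$pam4[match(tab$pair_id, p$pair_id)])
  on <- tab[tab$n_mismatch == 0L & tab$pam_class == "NGG", , drop = FALSE]
  one <- spec_records[spec_records$n_mismatch == 1L, , drop = FALSE]
  if (is.null(on$variant)) on$variant <- "variant"
  if (is.null(one$variant)) one$variant <- "variant"
  variants <- sort(unique(c(on$variant, one$variant)))
  data.frame(
    variant = variants,
    general_activity = vapply(variants, function(v)
      if (any(on$variant == v)) center(on$corrected_pct[on$variant == v])
      else NA_real_, 0),
    general_specificity = vapply(variants, function(v)
      if (any(one$variant == v)) center(one$specificity[one$variant == v])
      else NA_real_, 0),
    n_on = vapply(variants, function(v) sum(on$variant == v), 0L),
    n_off = vapply(variants, function(v) sum(one$variant == v), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select guides with comparable on-target activity across variants
#'
#' A guide is comparable when the across-variant range (max - min) of its
#' on-target corrected frequency is at most `tolerance` percentage points at
#' day 4 or at day 7 (either day qualifies).  Used to de-bias mismatch
#' comparisons between variants with different general activity.
#'
#' @param on_table data.frame with columns `guide_id`, `variant`, `day`,
#'   `on_pct` (one row per guide x variant x day).
#' @param tolerance Maximum across-variant range (absolute percent).
#' @return Character vector of comparable guide ids.
#' @export
selectComparableGuides <- function(on_table, tolerance) {
  need <- c("guide_id", "variant", "day", "on_pct")
  stopifnot(all(need %in% names(on_table)))
  nv <- length(unique(on_table$variant))
  complete <- tapply(on_table$variant, on_table[c("guide_id", "day")],
                     function(v) length(unique(v)) == nv)
  rng <- tapply(on_table$on_pct, on_table[c("guide_id", "day")],
                function(x) diff(range(x)))
  ok <- !is.na(rng) & rng <= tolerance & !is.na(complete) & complete
  guides <- rownames(ok)[rowSums(ok, na.rm = TRUE) > 0L]
  if (length(guides) == 0L && !any(complete, na.rm = TRUE))
    stop("selection error: no guide is measured in every variant",
         call. = FALSE)
  sort(guides)
}
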