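## Single-molecule FRET two-state analysis: efficiencies, first-five-frame
## histograms, population fractions, unwound fractions, unwinding
## specificity and transition statistics.

#' FretTraceSet: per-molecule donor/acceptor intensity traces
#'
#' Background-corrected donor and acceptor intensities, one row per molecule
#' and one column per frame (arbitrary units), with the acquisition frame
#' interval in seconds.
#'
#' @slot donor,acceptor Numeric matrices (molecules x frames).
#' @slot frame_interval Seconds per frame.
#' @slot molecule_ids Character vector of molecule identifiers.
#' @export
setClass("FretTraceSet",
         representation(donor = "matrix", acceptor = "matrix",
                        frame_interval = "numeric",
                        molecule_ids = "character"))

setValidity("FretTraceSet", function(object) {
  if (!all(dim(object@donor) == dim(object@acceptor)))
    return("donor and acceptor channels must have equal dimensions")
  if (length(object@molecule_ids) != nrow(object@donor))
    return("one molecule id per trace required")
  if (anyNA(object@donor) || anyNA(object@acceptor) ||
      any(!is.finite(object@donor)) || any(!is.finite(object@acceptor)))
    return("intensities must be finite")
  if (length(object@frame_interval) != 1L || object@frame_interval <= 0)
    return("frame_interval must be a positive scalar")
  TRUE
})

#' Construct a FretTraceSet
#'
#' @param donor,acceptor Numeric matrices (molecules x frames).
#' @param frame_interval Seconds per frame.
#' @param molecule_ids Optional molecule identifiers.
#' @return A [FretTraceSet-class].
#' @export
FretTraceSet <- function(donor, acceptor, frame_interval = 0.1,
                         molecule_ids = NULL) {
  donor <- as.matrix(donor)
  acceptor <- as.matrix(acceptor)
  if (is.null(molecule_ids))
    molecule_ids <- sprintf("mol_%05d", seq_len(nrow(donor)))
  new("FretTraceSet", donor = donor, acceptor = acceptor,
      frame_interval = frame_interval,
      molecule_ids = as.character(molecule_ids))
}

#' @describeIn FretTraceSet Number of molecules.
#' @param x A `FretTraceSet`.
#' @export
setMethod("length", "FretTraceSet", function(x) nrow(x@donor))

setMethod("show", "FretTraceSet", function(object) {
  cat(sprintf("FretTraceSet: %d molecules x %d frames (%.0f ms/frame)\n",
              nrow(object@donor), ncol(object@donor),
              1000 * object@frame_interval))
})

#' Accessors for FretTraceSet
#' @param x A [FretTraceSet-class].
#' @name fret-accessors
NULL

#' @rdname fret-accessors
#' @export
donorIntensity <- function(x) x@donor

#' @rdname fret-accessors
#' @export
acceptorIntensity <- function(x) x@acceptor

#' @rdname fret-accessors
#' @export
frameInterval <- function(x) x@frame_interval

#' @rdname fret-accessors
#' @export
moleculeIds <- function(x) x@molecule_ids

#' Read / write trace tables
#'
#' Long TSV/CSV format with columns `molecule_id`, `frame`, `donor`,
#' `acceptor`.
#'
#' @param x A [FretTraceSet-class].
#' @param file Path (.tsv or .csv by extension).
#' @param frame_interval Seconds per frame (on read).
#' @export
writeTraceTable <- function(x, file) {
  long <- data.frame(molecule_id = rep(x@molecule_ids, ncol(x@donor)),
                     frame = rep(seq_len(ncol(x@donor)),
                                 each = nrow(x@donor)),
                     donor = as.vector(x@donor),
                     acceptor = as.vector(x@acceptor))
  long <- long[order(long$molecule_id, long$frame), ]
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  write.table(long, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTraceTable
#' @export
readTraceTable <- function(file, frame_interval = 0.1) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  long <- read.delim(file, sep = sep)
  ids <- unique(long$molecule_id)
  frames <- sort(unique(long$frame))
  shape <- function(col) {
    m <- matrix(NA_real_, length(ids), length(frames),
                dimnames = list(ids, frames))
    m[cbind(match(long$molecule_id, ids), match(long$frame, frames))] <-
      long[[col]]
    m
  }
  FretTraceSet(shape("donor"), shape("acceptor"), frame_interval,
               molecule_ids = as.character(ids))
}

#' FRET efficiency
#'
#' `E = IA / (ID + IA)` per frame; frames with non-positive total intensity
#' are invalid (`NA`).
#'
#' @param donor,acceptor Intensities (vectors or matrices), or pass a
#'   [FretTraceSet-class] as `donor`.
#' @return Efficiencies with the shape of the input.
#' @examples
#' fretEfficiency(300, 700) # 0.7
#' @export
fretEfficiency <- function(donor, acceptor = NULL) {
  if (is(donor, "FretTraceSet")) {
    acceptor <- donor@acceptor
    donor <- donor@donor
  }
  tot <- donor + acceptor
  out <- acceptor / tot
  out[tot <= 0] <- NA_real_
  out
}

#' First-n-frame efficiency samples for histograms
#'
#' Takes the first `first_n` valid frames of each molecule's E trace as
#' histogram samples.  Molecules lacking acceptor signal (maximum acceptor
#' intensity below `acceptor_threshold`, emulating the acceptor-channel spot
#' selection) and molecules with fewer than `first_n` valid frames are
#' excluded.
#'
#' @param traces A [FretTraceSet-class].
#' @param first_n Samples per molecule.
#' @param acceptor_threshold Minimum of the per-molecule maximum acceptor
#'   intensity (0 = no exclusion).
#' @return Matrix (qualifying molecules x `first_n`) of E samples, rownames
#'   = molecule ids.
#' @export
histogramSamples <- function(traces, first_n = 5L, acceptor_threshold = 0) {
  E <- fretEfficiency(traces)
  keep <- apply(traces@acceptor, 1, max) >= acceptor_threshold &
    rowSums(!is.na(E)) >= first_n
  if (!any(keep))
    stop("empty-histogram error: no molecule qualifies", call. = FALSE)
  E <- E[keep, , drop = FALSE]
  out <- t(apply(E, 1, function(e) head(e[!is.na(e)], first_n)))
  if (first_n == 1L) out <- matrix(out, ncol = 1L)
  rownames(out) <- traces@molecule_ids[keep]
  out
}

# per-sample class over the three characteristic populations
.e_class <- function(E, low_range, high_min) {
  ifelse(E < low_range[1], 1L, ifelse(E < high_min, 2L, 3L))
}

#' Classify molecules into donor-only / low-FRET / high-FRET populations
#'
#' The three characteristic populations of an E histogram: donor-only
#' (E near 0), low-FRET (unwound; `low_range`, default 0.2-0.6) and
#' high-FRET (rewound; above `high_min`).  Each molecule is assigned the
#' modal class of its samples (ties broken toward the lower-E class); with
#' `per_molecule = FALSE` fractions are computed over samples instead.
#'
#' @param samples Matrix from [histogramSamples()] (or a numeric vector of
#'   E samples when `per_molecule = FALSE`).
#' @param low_range Bounds of the low-FRET band; the upper bound is the
#'   low/high boundary (0.6, 0.65 or 0.70 depending on the experiment).
#' @param high_min Lower bound of the high-FRET band; must equal
#'   `low_range[2]`.
#' @param per_molecule Assign per molecule (default) or per sample?
#' @return Named numeric vector `donor_only`, `low_fret`, `high_fret`
#'   summing to 1, with attribute `n` (classified units).
#' @export
classifyPopulations <- function(samples, low_range = c(0.2, 0.6),
                                high_min = low_range[2],
                                per_molecule = TRUE) {
  if (length(low_range) != 2L || low_range[1] >= low_range[2] ||
      !isTRUE(all.equal(high_min, low_range[2])))
    stop("config error: bounds must satisfy low_range[1] < low_range[2] ",
         "= high_min", call. = FALSE)
  if (per_molecule && is.matrix(samples)) {
    cls <- apply(samples, 1, function(e) {
      k <- tabulate(.e_class(e[!is.na(e)], low_range, high_min), 3L)
      which.max(k) # ties go to the lower-E class
    })
  } else {
    cls <- .e_class(as.numeric(samples[!is.na(samples)]), low_range,
                    high_min)
  }
  n <- length(cls)
  k <- tabulate(cls, 3L)
  structure(setNames(k / n, c("donor_only", "low_fret", "high_fret")),
            n = n)
}

#' Fraction of unwound DNA
#'
#' `f_unwound = low / (low + high)`: the relative size of the low-FRET
#' (unwound) population among target-bound molecules; donor-only molecules
#' are excluded.  Undefined (`NA`) when no molecule is in either band.
#'
#' @param fractions A [classifyPopulations()] result (or any named vector
#'   with `low_fret` and `high_fret`).
#' @return Fraction in `[0, 1]`.
#' @export
fUnwound <- function(fractions) {
  lo <- fractions[["low_fret"]]
  hi <- fractions[["high_fret"]]
  if (lo + hi <= 0) return(NA_real_)
  lo / (lo + hi)
}

#' @rdname fUnwound
#' @param traces A [FretTraceSet-class].
#' @param ... Passed to [histogramSamples()] and [classifyPopulations()].
#' @export
fUnwoundFromTraces <- function(traces, low_range = c(0.2, 0.6),
                               high_min = low_range[2], first_n = 5L, ...) {
  fUnwound(classifyPopulations(histogramSamples(traces, first_n, ...),
                               low_range, high_min))
}

#' Unwinding specificity
#'
#' `1 - f_unwound(mismatched) / f_unwound(matched)`; undefined when the
#' matched fraction is not positive.  Invariant to rescaling both fractions
#' by a common factor.
#'
#' @param f_mismatch,f_matched Unwound fractions for the mismatched and
#'   perfectly matched target.
#' @return Specificity fraction (<= 1).
#' @export
unwindingSpecificity <- function(f_mismatch, f_matched) {
  ifelse(f_matched > 0, 1 - f_mismatch / f_matched, NA_real_)
}

#' Smallest number of PAM-distal mismatches with a twofold unwinding drop
#'
#' Given `f_unwound` indexed by the number of consecutive PAM-distal
#' mismatches n_PD = 0, 1, 2, ..., returns the smallest n_PD whose unwound
#' fraction is less than half that of the matched target, or `NA` when no
#' such n_PD exists.
#'
#' @param f_by_npd Numeric vector of unwound fractions, first element =
#'   n_PD 0 (must be positive).
#' @return Integer n_PD or `NA`.
#' @examples
#' twofoldThreshold(c(0.8, 0.3, 0.1)) # 1
#' @export
twofoldThreshold <- function(f_by_npd) {
  if (length(f_by_npd) < 1L || is.na(f_by_npd[1]) || f_by_npd[1] <= 0)
    stop("f_unwound at n_PD = 0 must be present and > 0", call. = FALSE)
  hit <- which(f_by_npd[-1] < f_by_npd[1] / 2)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Fraction of molecules with low/high state transitions
#'
#' Per-molecule state sequences are obtained by thresholding the 3-frame
#' median-filtered E trace at the low/high boundary; dwells shorter than
#' `min_dwell` frames are absorbed into their neighbors.  Reported is the
#' fraction of molecules (with at least two classified frames) whose state
#' sequence changes at least once -- stably unwound or stably rewound
#' molecules contribute 0.
#'
#' @param traces A [FretTraceSet-class].
#' @param low_range,high_min Population bounds as in
#'   [classifyPopulations()].
#' @param min_dwell Minimum dwell length (frames).
#' @param median_k Median filter width (odd).
#' @return Fraction in `[0, 1]`.
#' @export
transitionFraction <- function(traces, low_range = c(0.2, 0.6),
                               high_min = low_range[2], min_dwell = 2L,
                               median_k = 3L) {
  E <- fretEfficiency(traces)
  n <- nrow(E)
  has_change <- logical(n)
  counted <- logical(n)
  for (i in seq_len(n)) {
    e <- E[i, ]
    e <- e[!is.na(e)]
    if (length(e) < 2L) next
    if (length(e) > median_k) e <- runmed(e, median_k)
    s <- .e_class(e, low_range, high_min)
    s <- s[s > 1L] # low/high frames only
    if (length(s) < 2L) next
    counted[i] <- TRUE
    r <- rle(s)
    # absorb dwells shorter than min_dwell into the preceding run
    while (length(r$lengths) > 1L && any(r$lengths < min_dwell)) {
      j <- which(r$lengths < min_dwell)[1]
      keep <- setdiff(seq_along(r$lengths), j)
      merged <- rle(inverse.rle(list(
        lengths = r$lengths[keep], values = r$values[keep])))
      if (identical(merged, r[c("lengths", "values")])) break
      r <- merged
    }
    has_change[i] <- length(r$values) > 1L
  }
  if (!any(counted)) return(NA_real_)
  sum(has_change[counted]) / sum(counted)
}
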