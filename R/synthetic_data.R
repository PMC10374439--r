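## Synthetic study generator: library designs, ground-truth activity
## landscapes, amplicon reads and count tables with known parameters.

#' Library design specification
#'
#' Describes a paired sgRNA-target library to be generated by
#' [buildLibrary()].  The default emulates the mismatch-tolerance panel of a
#' variant screen: 30 guides, each paired with one perfectly matched target
#' and 98 targets harboring one-, two- or three-base mismatches (their
#' composition is not fixed by the screen design, so positions, counts and
#' classes are spread uniformly by default and are fully configurable).
#' With `pam_scan = TRUE` every guide is additionally paired with all 256
#' 4-nt PAM variants of its matched target, emulating a PAM-compatibility
#' panel.
#'
#' @param n_guides Number of guides.
#' @param mismatch_targets_per_guide Mismatched targets per guide.
#' @param mismatch_counts Proportions over 1, 2 and 3 planted mismatches.
#' @param class_mix Proportions over mismatch classes `wobble`,
#'   `nonwobble_transition`, `transversion`.  At a given spacer position only
#'   one transition class is chemically realizable (wobble where the spacer
#'   base is G/U, non-wobble where it is A/C); weights are renormalized over
#'   the feasible classes per position.
#' @param pam_scan Emit all 256 4-nt PAM variants per guide?
#' @param expression_system Expression system for all guides: `"gN19"`
#'   (U6-driven, obligatory 5' g that may mismatch position 20), `"GN19"`
#'   (targets constrained to start with G) or `"tRNA_N20"` (perfect-match
#'   guides from tRNA processing).
#' @return A `LibraryDesignSpec` (list).
#' @export
libraryDesign <- function(n_guides = 30L,
                          mismatch_targets_per_guide = 98L,
                          mismatch_counts = c(`1` = 1 / 3, `2` = 1 / 3,
                                              `3` = 1 / 3),
                          class_mix = c(wobble = 1 / 3,
                                        nonwobble_transition = 1 / 3,
                                        transversion = 1 / 3),
                          pam_scan = FALSE,
                          expression_system = "gN19") {
  stopifnot(n_guides >= 1L, mismatch_targets_per_guide >= 0L)
  mismatch_counts <- mismatch_counts / sum(mismatch_counts)
  if (!setequal(names(mismatch_counts), c("1", "2", "3")))
    stop("mismatch_counts must be named '1','2','3'", call. = FALSE)
  if (!setequal(names(class_mix), .MM_CLASSES))
    stop("class_mix must be named over the three mismatch classes",
         call. = FALSE)
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop("class_mix must be non-negative and sum > 0", call. = FALSE)
  class_mix <- class_mix / sum(class_mix)
  expression_system <- match.arg(expression_system, .EXPR_SYSTEMS)
  structure(list(n_guides = as.integer(n_guides),
                 mismatch_targets_per_guide =
                   as.integer(mismatch_targets_per_guide),
                 mismatch_counts = mismatch_counts,
                 class_mix = class_mix,
                 pam_scan = isTRUE(pam_scan),
                 expression_system = expression_system),
            class = "LibraryDesignSpec")
}

# protospacer base realizing a requested mismatch class against a spacer base
# (RNA).  Returns NA when the class is infeasible at that base.
.mutant_base <- function(spacer_base, mclass) {
  sdna <- chartr("U", "T", spacer_base)
  switch(mclass,
    wobble = switch(spacer_base, G = "A", U = "C", T = "C", NA_character_),
    nonwobble_transition = switch(spacer_base, A = "G", C = "T",
                                  NA_character_),
    transversion = {
      pur <- c("A", "G")
      opp <- if (sdna %in% pur) c("C", "T") else c("A", "G")
      sample(opp, 1L)
    },
    stop("unknown mismatch class"))
}

#' Generate a paired sgRNA-target library
#'
#' Deterministic given `(spec, seed)`.  Every emitted pair satisfies the
#' `GuideTargetLibrary` invariants, and its stored mismatch annotations are
#' recomputed from the sequences, so the designed and annotated mismatches
#' agree by construction (this round trip is also asserted in the test
#' suite).  Matched targets carry NGG PAMs; assignment barcodes are unique
#' per pair.
#'
#' @param spec A [libraryDesign()] specification.
#' @param seed Integer seed.
#' @return A [GuideTargetLibrary-class].
#' @export
buildLibrary <- function(spec = libraryDesign(), seed = 1L) {
  stopifnot(inherits(spec, "LibraryDesignSpec"))
  with_seed(seed, .build_library_impl(spec))
}

.build_library_impl <- function(spec) {
  ng <- spec$n_guides
  proto <- .rand_dna(ng, .PROTO_LEN)
  if (spec$expression_system == "GN19")
    substr(proto, 1L, 1L) <- "G"
  up <- .rand_dna(ng, .CONTEXT_UP)
  down <- .rand_dna(ng, .CONTEXT_DOWN)
  pam <- paste0(sample(.DNA, ng, replace = TRUE), "G", "G")
  spacer <- proto
  if (spec$expression_system %in% c("gN19", "GN19"))
    substr(spacer, 1L, 1L) <- "G"
  guide_id <- sprintf("g%03d", seq_len(ng))
  rows <- list()
  # matched pair per guide
  rows[[1]] <- data.frame(
    pair_id = paste0(guide_id, "_on"), guide_id = guide_id,
    spacer = spacer, context = paste0(up, proto, pam, down),
    expression_system = spec$expression_system, stringsAsFactors = FALSE)
  # PAM scan: all 256 4-nt PAMs per guide
  if (spec$pam_scan) {
    pam4 <- as.vector(outer(
      as.vector(outer(as.vector(outer(.DNA, .DNA, paste0)), .DNA, paste0)),
      .DNA, paste0))
    for (g in seq_len(ng)) {
      ctx <- paste0(up[g], proto[g], pam4,
                    substr(down[g], 2L, .CONTEXT_DOWN))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("%s_pam%03d", guide_id[g], seq_along(pam4)),
        guide_id = guide_id[g], spacer = spacer[g], context = ctx,
        expression_system = spec$expression_system, stringsAsFactors = FALSE)
    }
  }
  # mismatched targets
  nmm <- spec$mismatch_targets_per_guide
  if (nmm > 0L) {
    counts <- c(1L, 2L, 3L)
    for (g in seq_len(ng)) {
      sp <- strsplit(chartr("T", "U", spacer[g]), "")[[1]]
      k <- sample(counts, nmm, replace = TRUE, prob = spec$mismatch_counts)
      ctx <- character(nmm)
      # gN19 guides: the 5'-g expression artifact makes a designed
      # position-20 mismatch indistinguishable from it, so the designable
      # range is 1-19 there
      pos_max <- if (spec$expression_system == "gN19") .PROTO_LEN - 1L
                 else .PROTO_LEN
      for (j in seq_len(nmm)) {
        pos <- sample.int(pos_max, k[j]) # PAM-anchored positions
        target <- rows[[1]]$context[g]
        for (p in pos) {
          sb <- sp[.PROTO_LEN + 1L - p] # spacer base at that position (RNA)
          feas <- vapply(.MM_CLASSES, function(cl)
            !is.na(suppressWarnings(.mutant_base(sb, cl))) ||
              cl == "transversion", logical(1))
          w <- spec$class_mix[.MM_CLASSES] * feas
          if (sum(w) <= 0)
            stop(sprintf(
              "infeasible class_mix: no requested class realizable at position %d (spacer base %s)",
              p, sb), call. = FALSE)
          cl <- sample(.MM_CLASSES, 1L, prob = w)
          ci <- .PAM_START - p # context index of PAM-anchored position p
          substr(target, ci, ci) <- .mutant_base(sb, cl)
        }
        ctx[j] <- target
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("%s_mm%03d", guide_id[g], seq_len(nmm)),
        guide_id = guide_id[g], spacer = spacer[g], context = ctx,
        expression_system = spec$expression_system, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$barcode <- .make_barcodes(nrow(pairs))
  GuideTargetLibrary(pairs)
}

## ---- activity landscape ------------------------------------------------

#' Ground-truth activity landscape parameters
#'
#' A deterministic map from a pair to its true indel frequency: a logistic
#' function of a fixed 4 x 30 position-weight sum over the context (weights
#' shipped in `inst/extdata/landscape_weights.tsv`), multiplied by a PAM
#' factor (NGG 1.0, NGH 0.08, non-NG 0.01) and by one penalty factor per
#' designed mismatch, `position_tolerance[p] * class_tolerance[class]`.
#' Position tolerances rise from the PAM-proximal seed toward the PAM-distal
#' end with local intolerance dips at positions 5 and 15, mirroring the
#' specificity maxima typical of high-fidelity variants; class tolerances
#' order wobble > non-wobble transition > transversion.
#'
#' @param pam_factor Named multipliers for the three PAM classes.
#' @param position_tolerance Length-20 vector in `[0,1]`, PAM-anchored.
#' @param class_tolerance Named multipliers per mismatch class.
#' @param five_prime_g_tolerance Multiplier for the gN19 expression-system 5'
#'   g mismatch (close to 1: it barely affects activity).
#' @param intercept Added to the position-weight score before the logistic.
#' @return A `LandscapeParams` list.
#' @export
defaultLandscape <- function(pam_factor = c(NGG = 1.0, NGH = 0.08,
                                            nonNG = 0.01),
                             position_tolerance = c(
                               0.05, 0.08, 0.11, 0.07, 0.03, 0.13, 0.19,
                               0.26, 0.33, 0.41, 0.48, 0.54, 0.58, 0.52,
                               0.22, 0.62, 0.70, 0.78, 0.84, 0.90),
                             class_tolerance = c(wobble = 0.8,
                                                 nonwobble_transition = 0.5,
                                                 transversion = 0.1),
                             five_prime_g_tolerance = 0.9,
                             intercept = 0.5) {
  stopifnot(length(position_tolerance) == .PROTO_LEN,
            all(position_tolerance >= 0 & position_tolerance <= 1))
  pwm <- as.matrix(read.delim(
    system.file("extdata", "landscape_weights.tsv", package = "sniperkit"),
    row.names = 1))
  colnames(pwm) <- NULL
  structure(list(pwm = pwm, pam_factor = pam_factor,
                 position_tolerance = position_tolerance,
                 class_tolerance = class_tolerance,
                 five_prime_g_tolerance = five_prime_g_tolerance,
                 intercept = intercept),
            class = "LandscapeParams")
}

#' True indel frequency of each pair under a synthetic activity landscape
#'
#' Deterministic and order-invariant; see [defaultLandscape()] for the
#' functional form.
#'
#' @param library A [GuideTargetLibrary-class].
#' @param params A [defaultLandscape()] parameter set.
#' @return Named numeric vector of true indel frequencies in percent
#'   `[0, 100]`, one per pair.
#' @export
landscapeActivity <- function(library, params = defaultLandscape()) {
  p <- as.data.frame(pairData(library))
  if (nrow(p) == 0L) return(setNames(numeric(0), character(0)))
  cm <- .char_matrix(p$context)
  idx <- matrix(match(cm, .DNA), nrow(cm), ncol(cm))
  score <- numeric(nrow(p))
  for (j in seq_len(.CONTEXT_LEN))
    score <- score + params$pwm[cbind(idx[, j], j)]
  act <- 100 * plogis(params$intercept + score)
  act <- act * params$pam_factor[classifyPam(p$pam4)]
  mm <- as.data.frame(mismatchData(library))
  if (nrow(mm)) {
    fac <- ifelse(mm$five_prime_g, params$five_prime_g_tolerance,
                  pmin(1, params$position_tolerance[mm$position_pam] *
                         params$class_tolerance[mm$mclass]))
    pen <- tapply(fac, factor(mm$pair_id, levels = p$pair_id), prod,
                  default = 1)
    act <- act * as.numeric(pen)
  }
  setNames(pmin(100, pmax(0, act)), p$pair_id)
}

#' Ground truth table for a library
#'
#' Combines the landscape activity with per-pair background error rates
#' (gamma-distributed around `bg_mean_pct`, emulating position-dependent
#' synthesis/PCR/sequencing error) and a day-7 saturation multiplier.
#'
#' @param library A [GuideTargetLibrary-class].
#' @param params Landscape parameters.
#' @param bg_mean_pct Mean background indel frequency (percent).
#' @param bg_shape Gamma shape of the background distribution.
#' @param day7_factor Multiplier applied to the true frequency at day 7
#'   (capped at 100 percent).
#' @param seed Integer seed.
#' @return data.frame with columns `pair_id`, `true_pct`, `background_pct`,
#'   `day7_factor`.
#' @export
makeGroundTruth <- function(library, params = defaultLandscape(),
                            bg_mean_pct = 1, bg_shape = 4,
                            day7_factor = 1.25, seed = 1L) {
  act <- landscapeActivity(library, params)
  with_seed(seed, {
    bg <- if (bg_mean_pct > 0)
      pmin(50, rgamma(length(act), shape = bg_shape,
                      rate = bg_shape / bg_mean_pct))
    else rep(0, length(act))
    data.frame(pair_id = names(act), true_pct = as.numeric(act),
               background_pct = bg, day7_factor = day7_factor,
               stringsAsFactors = FALSE)
  })
}

## ---- read-count simulation --------------------------------------------

#' Simulate per-pair read counts
#'
#' Total reads follow an overdispersed (negative-binomial) model around
#' `depth` (variance = `overdispersion * depth`); indel reads are binomial
#' with observed probability `p_obs = p + (1 - p) * bg`, where `p` is the
#' day-adjusted true frequency and `bg` the background rate -- the model the
#' background-correction formula inverts exactly.  Two replicates and two
#' days are emitted per pair by default.  Deterministic given `seed`.
#'
#' @param truth Ground-truth table from [makeGroundTruth()].
#' @param depth Expected total reads per pair and condition.
#' @param seed Integer seed.
#' @param variant Variant label for the emitted records.
#' @param overdispersion Variance inflation factor (>= 1) of total reads.
#' @param days,replicates Conditions to emit.
#' @return data.frame of read-count records: `pair_id`, `variant`, `day`,
#'   `replicate`, `total_reads`, `indel_reads`, `background_pct`.
#' @export
simulateCounts <- function(truth, depth = 1000, seed = 1L,
                           variant = "variant", overdispersion = 1.5,
                           days = c(4L, 7L), replicates = 1:2) {
  stopifnot(depth >= 0)
  grid <- expand.grid(replicate = replicates, day = days,
                      idx = seq_len(nrow(truth)))
  n <- nrow(grid)
  with_seed(seed, {
    total <- if (depth == 0) integer(n)
             else if (overdispersion > 1)
               rnbinom(n, mu = depth, size = depth / (overdispersion - 1))
             else rpois(n, depth)
    p <- truth$true_pct[grid$idx] / 100
    p <- pmin(1, p * ifelse(grid$day == 7L, truth$day7_factor[grid$idx], 1))
    bg <- truth$background_pct[grid$idx] / 100
    p_obs <- p + (1 - p) * bg
    indel <- rbinom(n, total, p_obs)
    data.frame(pair_id = truth$pair_id[grid$idx], variant = variant,
               day = grid$day, replicate = grid$replicate,
               total_reads = total, indel_reads = indel,
               background_pct = truth$background_pct[grid$idx],
               stringsAsFactors = FALSE)
  })
}

## ---- amplicon read simulation -----------------------------------------

.LEFT_PRIMER <- "ACACGACGCTCT"
.RIGHT_PRIMER <- "AGATCGGAAGAG"
.BARCODE_LEN <- 8L

#' Reference amplicon sequences for a library
#'
#' Amplicon layout: `[left primer][30-nt context][8-nt pair barcode][right
#' primer]`; the cut site sits 3 bp 5' of the PAM, i.e. after amplicon
#' position `ampliconCutSite()`.
#'
#' @param library A [GuideTargetLibrary-class].
#' @return Named character vector of reference amplicons.
#' @export
referenceAmplicons <- function(library) {
  p <- pairData(library)
  setNames(paste0(.LEFT_PRIMER, p$context, p$barcode, .RIGHT_PRIMER),
           p$pair_id)
}

#' @rdname referenceAmplicons
#' @export
ampliconCutSite <- function() nchar(.LEFT_PRIMER) + .CUT_AFTER

# insert/delete around the cut site of a set of amplicons (vectorized)
.plant_indels <- function(reads, cut, geom_prob, max_len, del_frac) {
  n <- length(reads)
  if (n == 0L) return(reads)
  len <- pmin(rgeom(n, geom_prob) + 1L, max_len)
  is_del <- runif(n) < del_frac
  out <- reads
  if (any(is_del)) {
    L <- len[is_del]
    dstart <- cut - floor(L / 2) + 1L
    out[is_del] <- paste0(substring(reads[is_del], 1L, dstart - 1L),
                          substring(reads[is_del], dstart + L,
                                    nchar(reads[is_del])))
  }
  if (any(!is_del)) {
    L <- len[!is_del]
    ins <- vapply(L, function(k)
      paste(sample(.DNA, k, replace = TRUE), collapse = ""), "")
    out[!is_del] <- paste0(substring(reads[!is_del], 1L, cut), ins,
                           substring(reads[!is_del], cut + 1L,
                                     nchar(reads[!is_del])))
  }
  out
}

# per-base substitution errors (vectorized over error events)
.add_subst_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  k <- rbinom(length(reads), nchar(reads), rate)
  idx <- rep(seq_along(reads), k)
  if (length(idx) == 0L) return(reads)
  pos <- floor(runif(length(idx)) * nchar(reads)[idx]) + 1L
  repl <- sample(.DNA, length(idx), replace = TRUE)
  while (length(idx)) {
    first <- !duplicated(idx)
    i <- idx[first]; p <- pos[first]
    substr(reads[i], p, p) <- repl[first]
    idx <- idx[!first]; pos <- pos[!first]; repl <- repl[!first]
  }
  reads
}

#' Simulate amplicon sequencing reads
#'
#' Emits reads of each pair's reference amplicon.  With probability
#' `p_obs = p_indel + (1 - p_indel) * background_rate` a read carries an
#' indel (geometric length truncated at `max_indel`, deletions:insertions
#' 2:1) centered at the cut site; independent substitution sequencing errors
#' are applied at `error_rate` per base.  Read names carry no truth; the
#' planted truth is returned separately for benchmarking.
#'
#' @param library A [GuideTargetLibrary-class].
#' @param n_reads Reads per pair (scalar or per-pair vector).
#' @param p_indel True indel probability per pair (scalar or vector,
#'   fraction in `[0,1]`).
#' @param seed Integer seed.
#' @param background_rate Background indel rate (fraction) applied to
#'   non-edited reads.
#' @param error_rate Per-base substitution error rate.
#' @param indel_geom_prob,max_indel,del_frac Indel length/type model.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `pair_id`, `planted_indel`).
#' @export
simulateReads <- function(library, n_reads, p_indel, seed = 1L,
                          background_rate = 0, error_rate = 0.001,
                          indel_geom_prob = 0.5, max_indel = 10L,
                          del_frac = 2 / 3) {
  p <- pairData(library)
  np <- nrow(p)
  n_reads <- rep_len(as.integer(n_reads), np)
  p_indel <- rep_len(p_indel, np)
  stopifnot(all(n_reads >= 0L), all(p_indel >= 0 & p_indel <= 1))
  refs <- referenceAmplicons(library)
  cut <- ampliconCutSite()
  with_seed(seed, {
    pair_of <- rep(seq_len(np), n_reads)
    reads <- refs[pair_of]
    p_obs <- p_indel + (1 - p_indel) * background_rate
    has_indel <- runif(length(reads)) < p_obs[pair_of]
    reads[has_indel] <- .plant_indels(reads[has_indel], cut,
                                      indel_geom_prob, max_indel, del_frac)
    reads <- .add_subst_errors(reads, error_rate)
    ids <- sprintf("read_%07d", seq_along(reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids,
                            pair_id = p$pair_id[pair_of],
                            planted_indel = has_indel,
                            stringsAsFactors = FALSE))
  })
}

#' Write simulated reads as FASTQ
#'
#' Phred+33 FASTQ with a constant Q40 quality line (the simulator's error
#' model is parameterized directly, not through qualities).
#'
#' @param reads Named character vector of read sequences.
#' @param file Output path.
#' @export
writeReadsFastq <- function(reads, file) {
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), "")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(x, file)
  invisible(file)
}

#' Read FASTQ into the read vector used by the quantification step
#'
#' @param file FASTQ path.
#' @return Named character vector of read sequences.
#' @export
readReadsFastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  setNames(as.character(x), names(x))
}

## ---- smFRET trace simulation ------------------------------------------

#' smFRET population specification
#'
#' Parameters of the two-state (plus donor-only) trace generator.  Defaults
#' reflect the experimental regime: low-FRET (unwound) efficiency centered in
#' the 0.2-0.6 band, high-FRET (rewound) above it, 100-ms frames, and well
#' over 5 frames per molecule so first-five-frame histograms are defined.
#'
#' @param f_unwound_true True fraction of non-donor-only molecules in the
#'   unwound (low-FRET) state.
#' @param donor_only_frac Fraction of molecules with no active acceptor.
#' @param E_low_mean,E_low_sd,E_high_mean,E_high_sd Efficiency parameters of
#'   the two populations (means separated by > 2 sd for resolvability).
#' @param E_donor_mean,E_donor_sd Residual efficiency of donor-only
#'   molecules (peak at E = 0).
#' @param transition_prob Per-frame probability of flipping between the low
#'   and high state.
#' @param n_frames Frames per molecule.
#' @param frame_interval Seconds per frame.
#' @param total_intensity,intensity_cv Mean and coefficient of variation of
#'   per-frame total (donor + acceptor) intensity, arbitrary units.
#' @return A `FretPopulationSpec` list.
#' @export
fretSpec <- function(f_unwound_true = 0.7, donor_only_frac = 0.1,
                     E_low_mean = 0.40, E_low_sd = 0.06,
                     E_high_mean = 0.82, E_high_sd = 0.06,
                     E_donor_mean = 0.03, E_donor_sd = 0.025,
                     transition_prob = 0, n_frames = 50L,
                     frame_interval = 0.1, total_intensity = 1000,
                     intensity_cv = 0.1) {
  stopifnot(f_unwound_true >= 0, f_unwound_true <= 1,
            donor_only_frac >= 0, donor_only_frac <= 1,
            E_low_mean > 0, E_low_mean < 1, E_high_mean > 0, E_high_mean < 1,
            transition_prob >= 0, transition_prob <= 1, n_frames >= 1L)
  if (E_high_mean - E_low_mean <= 2 * max(E_low_sd, E_high_sd))
    stop("low/high E means must be separated by > 2 sd", call. = FALSE)
  structure(as.list(environment()), class = "FretPopulationSpec")
}

#' Simulate per-molecule donor/acceptor intensity traces
#'
#' Each molecule is assigned donor-only, unwound (low-FRET) or rewound
#' (high-FRET) according to the specification; per-frame efficiencies are
#' drawn around the state mean (state flips with `transition_prob` per frame
#' for non-donor-only molecules) and converted to donor/acceptor intensities
#' with `E = IA / (ID + IA)` holding by construction.  Deterministic given
#' `seed`.
#'
#' @param spec A [fretSpec()].
#' @param n_molecules Number of molecules.
#' @param seed Integer seed.
#' @return A [FretTraceSet-class].
#' @export
simulateTraces <- function(spec = fretSpec(), n_molecules = 2000L,
                           seed = 1L) {
  stopifnot(inherits(spec, "FretPopulationSpec"), n_molecules >= 1L)
  nm <- as.integer(n_molecules)
  nf <- spec$n_frames
  with_seed(seed, {
    u <- runif(nm)
    state0 <- ifelse(u < spec$donor_only_frac, 0L,
                     ifelse(runif(nm) < spec$f_unwound_true, 1L, 2L))
    # state paths: 1 = low/unwound, 2 = high/rewound; 0 = donor-only (fixed)
    flips <- matrix(runif(nm * (nf - 1L)) < spec$transition_prob, nm,
                    nf - 1L)
    states <- matrix(0L, nm, nf)
    states[, 1] <- state0
    for (f in seq_len(nf - 1L)) {
      s <- states[, f]
      flip <- flips[, f] & s > 0L
      states[, f + 1L] <- ifelse(flip, 3L - s, s)
    }
    mu <- matrix(spec$E_donor_mean, nm, nf)
    sdv <- matrix(spec$E_donor_sd, nm, nf)
    mu[states == 1L] <- spec$E_low_mean
    sdv[states == 1L] <- spec$E_low_sd
    mu[states == 2L] <- spec$E_high_mean
    sdv[states == 2L] <- spec$E_high_sd
    E <- matrix(pmin(1, pmax(0, rnorm(nm * nf, mu, sdv))), nm, nf)
    tot <- matrix(pmax(50, rnorm(nm * nf, spec$total_intensity,
                                 spec$intensity_cv * spec$total_intensity)),
                  nm, nf)
    FretTraceSet(donor = (1 - E) * tot, acceptor = E * tot,
                 frame_interval = spec$frame_interval,
                 molecule_ids = sprintf("mol_%05d", seq_len(nm)))
  })
}
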