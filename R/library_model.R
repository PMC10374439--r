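#' Classify a 3-nt PAM
#'
#' Partitions 3-nt protospacer-adjacent motifs into the three classes used
#' throughout variant screens: `NGG` (second and third base G), `NGH`
#' (second base G, third base A/C/T) and `nonNG` (second base not G).
#'
#' @param pam Character vector of 3-nt DNA strings (longer strings are
#'   classified on their first three bases, so 4-nt PAM scans can be passed
#'   directly).
#' @return Character vector with values `"NGG"`, `"NGH"` or `"nonNG"`.
#' @examples
#' classifyPam(c("TGG", "AGA", "ATC"))
#' @export
classifyPam <- function(pam) {
  pam <- toupper(pam)
  if (any(nchar(pam) < 3L))
    stop("PAM strings must have at least 3 nt", call. = FALSE)
  p3 <- substr(pam, 1L, 3L)
  .check_alphabet(p3, .DNA, "pam")
  b2 <- substr(p3, 2L, 2L)
  b3 <- substr(p3, 3L, 3L)
  ifelse(b2 != "G", "nonNG", ifelse(b3 == "G", "NGG", "NGH"))
}

# class of a single sgRNA:DNA mismatch, given the spacer base (RNA) and the
# protospacer base (DNA, non-target strand).  Wobble = rG:dT or rU:dG pairing
# with the target strand, i.e. spacer G over protospacer A, or spacer U over
# protospacer C.  Transitions at the protospacer level are A<->G and C<->T.
.mismatch_class <- function(spacer_base, proto_base) {
  sdna <- chartr("U", "T", spacer_base)
  wob <- (spacer_base == "G" & proto_base == "A") |
    (spacer_base == "U" & proto_base == "C")
  pur <- c("A", "G")
  transition <- (sdna %in% pur) == (proto_base %in% pur) & sdna != proto_base
  ifelse(wob, "wobble",
         ifelse(transition, "nonwobble_transition", "transversion"))
}

#' Annotate mismatches between a spacer and a protospacer
#'
#' Compares a 20-nt RNA spacer (U read as T) with a 20-nt DNA protospacer and
#' reports every differing position with its mismatch class.  Positions are
#' PAM-anchored by default: position 1 is adjacent to the PAM, position 20 is
#' the PAM-distal (5') end.  For `gN19` expression (U6-driven guides with an
#' obligatory 5' g), a difference at the 5'-most position where the spacer
#' base is G is flagged `five_prime_g` -- an expression-system artifact, not a
#' designed mismatch -- and is excluded from mismatch-count summaries
#' downstream.
#'
#' @param spacer 20-nt RNA string (alphabet ACGU; case-insensitive).
#' @param protospacer 20-nt DNA string (alphabet ACGT; case-insensitive).
#' @param expression_system One of `"gN19"`, `"GN19"`, `"tRNA_N20"`.
#' @param numbering `"pam"` (default; 1 = PAM-proximal) or `"five_prime"`
#'   (1 = 5' end of the protospacer).
#' @return A data.frame with one row per differing position and columns
#'   `position_pam` (or `position_five_prime`), `spacer_base`,
#'   `protospacer_base`, `mclass` and `five_prime_g`.
#' @examples
#' annotateMismatches("gcgccacUgguugaugugau", "gcgccacCggttgatgtgat")
#' @export
annotateMismatches <- function(spacer, protospacer,
                               expression_system = "gN19",
                               numbering = c("pam", "five_prime")) {
  numbering <- match.arg(numbering)
  expression_system <- match.arg(expression_system, .EXPR_SYSTEMS)
  spacer <- toupper(spacer)
  protospacer <- toupper(protospacer)
  .check_len(spacer, .PROTO_LEN, "spacer")
  .check_len(protospacer, .PROTO_LEN, "protospacer")
  .check_alphabet(spacer, c(.DNA, "U"), "spacer")
  .check_alphabet(protospacer, .DNA, "protospacer")
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  pr <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  diff5 <- which(chartr("U", "T", sp) != pr) # 5'-anchored indices
  ann <- data.frame(
    position_pam = .PROTO_LEN + 1L - diff5,
    spacer_base = sp[diff5],
    protospacer_base = pr[diff5],
    mclass = if (length(diff5)) .mismatch_class(sp[diff5], pr[diff5])
             else character(0),
    five_prime_g = (expression_system == "gN19") & diff5 == 1L &
      sp[diff5] == "G",
    stringsAsFactors = FALSE
  )
  ann <- ann[order(ann$position_pam), , drop = FALSE]
  rownames(ann) <- NULL
  if (numbering == "five_prime") {
    ann$position_pam <- pamToFivePrime(ann$position_pam)
    names(ann)[names(ann) == "position_pam"] <- "position_five_prime"
  }
  ann
}

#' Convert between PAM-anchored and 5'-anchored protospacer positions
#'
#' The two numbering conventions are mirror images over a 20-nt protospacer,
#' so the same involution converts in both directions.
#'
#' @param position Integer vector of positions in 1..20.
#' @return Positions in the other convention.
#' @export
pamToFivePrime <- function(position) {
  stopifnot(all(position >= 1L & position <= .PROTO_LEN))
  .PROTO_LEN + 1L - as.integer(position)
}

#' Length of the PAM-distal consecutive mismatch run
#'
#' Returns `n_PD`: the length of the maximal consecutive run of mismatched
#' positions anchored at the PAM-distal end (position 20 inward); 0 when
#' position 20 matches.  Expression-system 5' g differences (flag
#' `five_prime_g`) are not designed mismatches and are excluded by default.
#'
#' @param mismatches Annotation data.frame from [annotateMismatches()] (one
#'   pair), or an integer vector of PAM-anchored mismatch positions.
#' @param include_five_prime_g Count flagged 5' g differences as mismatches?
#' @return Integer n_PD.
#' @export
pamDistalRun <- function(mismatches, include_five_prime_g = FALSE) {
  if (is.data.frame(mismatches)) {
    keep <- if (include_five_prime_g) rep(TRUE, nrow(mismatches))
            else !mismatches$five_prime_g
    pos <- mismatches$position_pam[keep]
  } else {
    pos <- as.integer(mismatches)
  }
  n <- 0L
  while ((.PROTO_LEN - n) %in% pos) n <- n + 1L
  n
}

## ---- GuideTargetLibrary -----------------------------------------------

#' GuideTargetLibrary: a set of sgRNA-target pairs
#'
#' Container for a paired sgRNA-target library: one row per pair holding the
#' 20-nt spacer, the 30-nt integrated target context
#' (`[4 up][20 protospacer][3 PAM][3 down]`), the 4-nt PAM slice used for
#' NNNN scans, the sgRNA expression system and a per-pair assignment barcode,
#' together with a long table of per-pair mismatch annotations.
#'
#' @slot pairs A [S4Vectors::DataFrame] with columns `pair_id`, `guide_id`,
#'   `spacer`, `context`, `pam4`, `expression_system`, `barcode`,
#'   `n_mismatch`.
#' @slot mismatches A [S4Vectors::DataFrame] with columns `pair_id`,
#'   `position_pam`, `spacer_base`, `protospacer_base`, `mclass`,
#'   `five_prime_g`.
#' @export
setClass("GuideTargetLibrary",
         representation(pairs = "DataFrame", mismatches = "DataFrame"))

setValidity("GuideTargetLibrary", function(object) {
  p <- object@pairs
  need <- c("pair_id", "guide_id", "spacer", "context", "pam4",
            "expression_system", "barcode", "n_mismatch")
  if (!all(need %in% colnames(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$pair_id)) return("pair_id values must be unique")
  if (nrow(p)) {
    if (any(nchar(p$spacer) != .PROTO_LEN)) return("spacers must be 20 nt")
    if (any(nchar(p$context) != .CONTEXT_LEN)) return("contexts must be 30 nt")
    if (any(nchar(p$pam4) != 4L)) return("pam4 must be 4 nt")
    if (!all(p$expression_system %in% .EXPR_SYSTEMS))
      return("unknown expression_system")
    if (any(substr(p$context, .PAM_START, .PAM_START + 3L) != p$pam4))
      return("pam4 must equal context positions 25-28")
  }
  m <- object@mismatches
  mneed <- c("pair_id", "position_pam", "spacer_base", "protospacer_base",
             "mclass", "five_prime_g")
  if (!all(mneed %in% colnames(m)))
    return(paste("mismatches must have columns:", paste(mneed, collapse = ", ")))
  if (nrow(m) && !all(m$pair_id %in% p$pair_id))
    return("mismatch annotations reference unknown pair_ids")
  TRUE
})

#' Construct a GuideTargetLibrary from per-pair tables
#'
#' Mismatch annotations are recomputed from the spacer and the protospacer
#' slice of the context with [annotateMismatches()], so stored annotations
#' always agree with the sequences.
#'
#' @param pairs data.frame (or DataFrame) with columns `pair_id`, `guide_id`,
#'   `spacer`, `context`, `expression_system`, and optionally `barcode`.
#' @return A [GuideTargetLibrary-class] object.
#' @export
GuideTargetLibrary <- function(pairs) {
  pairs <- as.data.frame(pairs)
  pairs$spacer <- toupper(pairs$spacer)
  pairs$context <- toupper(pairs$context)
  if (is.null(pairs$barcode))
    pairs$barcode <- .make_barcodes(nrow(pairs), seed = 20L)
  pairs$pam4 <- substr(pairs$context, .PAM_START, .PAM_START + 3L)
  proto <- substr(pairs$context, .PROTO_START, .PROTO_END)
  ann <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- annotateMismatches(pairs$spacer[i], proto[i],
                            pairs$expression_system[i])
    if (nrow(a)) a <- cbind(pair_id = pairs$pair_id[i], a)
    ann[[i]] <- a
  }
  ann <- ann[vapply(ann, nrow, 1L) > 0L]
  mm <- if (length(ann)) do.call(rbind, ann)
        else data.frame(pair_id = character(0), position_pam = integer(0),
                        spacer_base = character(0),
                        protospacer_base = character(0),
                        mclass = character(0), five_prime_g = logical(0))
  designed <- mm[!mm$five_prime_g, , drop = FALSE]
  tab <- table(designed$pair_id)
  pairs$n_mismatch <- as.integer(tab[pairs$pair_id])
  pairs$n_mismatch[is.na(pairs$n_mismatch)] <- 0L
  canon <- c("pair_id", "guide_id", "spacer", "context", "pam4",
             "expression_system", "barcode", "n_mismatch")
  pairs <- pairs[, c(canon, setdiff(names(pairs), canon)), drop = FALSE]
  new("GuideTargetLibrary",
      pairs = S4Vectors::DataFrame(pairs),
      mismatches = S4Vectors::DataFrame(mm))
}

# unique fixed-length DNA barcodes
.make_barcodes <- function(n, len = 8L, seed = NULL) {
  if (n == 0L) return(character(0))
  if (n > 4^len) stop("too many pairs for barcode length", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(4^len, n) - 1L
    sapply(idx, function(k) {
      paste(.DNA[(k %/% 4^(seq_len(len) - 1L)) %% 4L + 1L], collapse = "")
    })
  })
}

#' @describeIn GuideTargetLibrary Number of pairs in the library.
#' @param x A `GuideTargetLibrary`.
#' @export
setMethod("length", "GuideTargetLibrary", function(x) nrow(x@pairs))

#' Accessors for GuideTargetLibrary
#'
#' `pairData()` returns the per-pair table, `mismatchData()` the long
#' mismatch-annotation table, `pairIds()` the pair identifiers, `spacers()`
#' the spacers as an [Biostrings::RNAStringSet], `contexts()` the 30-nt
#' contexts as a [Biostrings::DNAStringSet], `protospacers()` the 20-nt
#' protospacer slices and `pamClasses()` the 3-nt PAM classes.
#'
#' @param x A [GuideTargetLibrary-class].
#' @name library-accessors
NULL

#' @rdname library-accessors
#' @export
pairData <- function(x) x@pairs

#' @rdname library-accessors
#' @export
mismatchData <- function(x) x@mismatches

#' @rdname library-accessors
#' @export
pairIds <- function(x) x@pairs$pair_id

#' @rdname library-accessors
#' @export
spacers <- function(x) {
  s <- chartr("T", "U", x@pairs$spacer)
  Biostrings::RNAStringSet(setNames(s, x@pairs$pair_id))
}

#' @rdname library-accessors
#' @export
contexts <- function(x) {
  Biostrings::DNAStringSet(setNames(x@pairs$context, x@pairs$pair_id))
}

#' @rdname library-accessors
#' @export
protospacers <- function(x) {
  p <- substr(x@pairs$context, .PROTO_START, .PROTO_END)
  Biostrings::DNAStringSet(setNames(p, x@pairs$pair_id))
}

#' @rdname library-accessors
#' @export
pamClasses <- function(x) classifyPam(x@pairs$pam4)

#' @describeIn GuideTargetLibrary Subset a library by index or pair id.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "GuideTargetLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@pairs$pair_id)
  p <- x@pairs[i, , drop = FALSE]
  m <- x@mismatches[x@mismatches$pair_id %in% p$pair_id, , drop = FALSE]
  new("GuideTargetLibrary", pairs = p, mismatches = m)
})

setMethod("show", "GuideTargetLibrary", function(object) {
  p <- object@pairs
  cat("GuideTargetLibrary with", nrow(p), "sgRNA-target pairs\n")
  if (nrow(p)) {
    cat("  guides:", length(unique(p$guide_id)),
        " expression:", paste(unique(p$expression_system), collapse = ","),
        "\n")
    cls <- table(classifyPam(p$pam4))
    cat("  PAM classes:",
        paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
    cat("  mismatch counts:",
        paste(sprintf("%s:%d", names(table(p$n_mismatch)),
                      table(p$n_mismatch)), collapse = " "), "\n")
  }
})

#' Read / write library definition tables
#'
#' The on-disk format is TSV with columns `pair_id`, `guide_id`, `spacer`,
#' `context30`, `pam4`, `expression_system`, `barcode`.  Annotations are
#' recomputed on read.
#'
#' @param x A [GuideTargetLibrary-class].
#' @param file Path to a TSV file.
#' @return `readLibraryTable()` returns a `GuideTargetLibrary`;
#'   `writeLibraryTable()` returns `file` invisibly.
#' @export
writeLibraryTable <- function(x, file) {
  p <- as.data.frame(pairData(x))
  out <- data.frame(pair_id = p$pair_id, guide_id = p$guide_id,
                    spacer = p$spacer, context30 = p$context,
                    pam4 = p$pam4, expression_system = p$expression_system,
                    barcode = p$barcode)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeLibraryTable
#' @export
readLibraryTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "context30"] <- "context"
  GuideTargetLibrary(tab)
}

#' Export target contexts as FASTA
#'
#' Writes the 30-nt contexts (named by pair id) for use with external
#' alignment tools.
#'
#' @param x A [GuideTargetLibrary-class].
#' @param file Output FASTA path.
#' @export
writeContextsFasta <- function(x, file) {
  Biostrings::writeXStringSet(contexts(x), file)
  invisible(file)
}
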