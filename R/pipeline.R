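## End-to-end orchestration: simulate -> quantify -> stats -> model -> fret
## from one configuration, with a deterministic provenance manifest.

#' Pipeline configuration
#'
#' One configuration drives a full synthetic run.  Stages execute in
#' dependency order; every stage has its own seed so reruns with identical
#' configuration are bit-identical.  A configuration can also be read from a
#' YAML file with [readPipelineConfig()].
#'
#' @param stages Subset of `c("library", "counts", "stats", "model",
#'   "fret")`; `character(0)` runs nothing.
#' @param design A [libraryDesign()] for the library stage.
#' @param landscape A [defaultLandscape()] parameter set.
#' @param quant A [quantConfig()].
#' @param depth Sequencing depth per pair and condition.
#' @param bg_mean_pct Mean background indel frequency (percent).
#' @param model_n Training examples for the model stage.
#' @param model_epochs,model_config Model stage schedule and architecture.
#' @param fret Named list of [fretSpec()]s for the fret stage (one result
#'   row each); defaults to a matched/mismatched pair of conditions.
#' @param n_molecules Molecules per fret condition.
#' @param seeds Named per-stage integer seeds.
#' @return A `RunConfig` list.
#' @export
pipelineConfig <- function(stages = c("library", "counts", "stats"),
                           design = libraryDesign(),
                           landscape = defaultLandscape(),
                           quant = quantConfig(),
                           depth = 1000, bg_mean_pct = 1,
                           model_n = 5000L, model_epochs = 10L,
                           model_config = onTargetConfig(),
                           fret = list(
                             matched = fretSpec(f_unwound_true = 0.60),
                             mismatched = fretSpec(f_unwound_true = 0.102)),
                           n_molecules = 2000L,
                           seeds = list(library = 101L, counts = 102L,
                                        model = 103L, fret = 104L)) {
  if (length(stages))
    stages <- match.arg(stages, c("library", "counts", "stats", "model",
                                  "fret"), several.ok = TRUE)
  structure(list(stages = stages, design = design, landscape = landscape,
                 quant = quant, depth = depth, bg_mean_pct = bg_mean_pct,
                 model_n = as.integer(model_n),
                 model_epochs = as.integer(model_epochs),
                 model_config = model_config, fret = fret,
                 n_molecules = as.integer(n_molecules), seeds = seeds),
            class = "RunConfig")
}

#' @rdname pipelineConfig
#' @param file YAML file with fields matching the `pipelineConfig()`
#'   arguments (scalar fields and `seeds` only; nested specs use their
#'   defaults).
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  args <- list()
  for (nm in c("stages", "depth", "bg_mean_pct", "model_n", "model_epochs",
               "n_molecules", "seeds"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$design)) args$design <- do.call(libraryDesign, y$design)
  do.call(pipelineConfig, args)
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order (`counts`, `stats`,
#' `model` and `fret` require `library` outputs, which are generated on the
#' fly if the stage is enabled), writes every artifact as TSV/JSON under
#' `outdir` and returns a manifest listing each file with its MD5 content
#' hash, the per-stage seeds and summaries.  The manifest contains no
#' timestamps, so a rerun with an identical configuration yields an
#' identical manifest for deterministic stages.
#'
#' @param config A [pipelineConfig()].
#' @param outdir Output directory (created if missing).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summaries <- list()
  lib <- NULL
  truth <- NULL
  need_lib <- length(config$stages) > 0L
  if (need_lib) {
    lib <- buildLibrary(config$design, seed = config$seeds$library)
    truth <- makeGroundTruth(lib, config$landscape,
                             bg_mean_pct = config$bg_mean_pct,
                             seed = config$seeds$library)
  }
  if ("library" %in% config$stages) {
    files <- c(files, writeLibraryTable(lib, file.path(outdir, "library.tsv")),
               .write_tsv(truth, file.path(outdir, "truth.tsv")))
    summaries$library <- list(n_pairs = length(lib),
                              n_guides = length(unique(pairData(lib)$guide_id)))
  }
  freq <- NULL
  if (any(c("counts", "stats") %in% config$stages)) {
    counts <- simulateCounts(truth, depth = config$depth,
                             seed = config$seeds$counts)
    pooled <- mergeReplicates(counts)
    freq <- applyFilters(pooled, config$quant)
    files <- c(files, .write_tsv(counts, file.path(outdir, "counts.tsv")),
               .write_tsv(freq, file.path(outdir, "frequencies.tsv")))
    summaries$counts <- list(n_records = nrow(counts),
                             n_passed = sum(freq$passed_filters))
  }
  if ("stats" %in% config$stages) {
    recs <- specificityRecords(freq, lib)
    pam <- pamProfile(freq[pairData(lib)$n_mismatch[
      match(freq$pair_id, pairIds(lib))] == 0L, , drop = FALSE], lib)
    pos <- positionwiseSpecificity(recs)
    strat <- stratifyByMismatch(recs)
    trade <- tradeoffSummary(freq, recs, lib)
    files <- c(files,
               .write_tsv(recs, file.path(outdir, "specificity_records.tsv")),
               .write_tsv(pam$by_class, file.path(outdir, "pam_profile.tsv")),
               .write_tsv(pos, file.path(outdir, "position_specificity.tsv")),
               .write_tsv(strat$by_count,
                          file.path(outdir, "mismatch_strata.tsv")),
               .write_tsv(trade, file.path(outdir, "tradeoff.tsv")))
    summaries$stats <- list(n_specificity_records = nrow(recs),
                            median_specificity =
                              median(recs$specificity[recs$n_mismatch == 1L]))
  }
  if ("model" %in% config$stages) {
    mdesign <- libraryDesign(
      n_guides = ceiling(config$model_n / 2L),
      mismatch_targets_per_guide = 1L)
    mlib <- buildLibrary(mdesign, seed = config$seeds$model)
    mlib <- mlib[seq_len(min(config$model_n, length(mlib)))]
    act <- landscapeActivity(mlib, config$landscape)
    enc <- encodeOnTarget(as.data.frame(pairData(mlib))$context,
                          as.data.frame(pairData(mlib))$expression_system)
    n <- length(act)
    n_val <- max(1L, round(n / 6))
    val_idx <- with_seed(config$seeds$model, sample.int(n, n_val))
    model <- buildModel(config$model_config, seed = config$seeds$model)
    model <- trainModel(model, .enc_subset(enc, setdiff(seq_len(n), val_idx)),
                        act[setdiff(seq_len(n), val_idx)],
                        epochs = config$model_epochs,
                        validation = list(enc = .enc_subset(enc, val_idx),
                                          activity = act[val_idx]),
                        seed = config$seeds$model)
    pred <- predict(model, .enc_subset(enc, val_idx))
    r <- cor(pred, act[val_idx])
    mfile <- file.path(outdir, "model_metrics.json")
    jsonlite::write_json(list(n_train = n - n_val, n_val = n_val,
                              holdout_pearson = r,
                              history = trainingHistory(model)),
                         mfile, auto_unbox = TRUE, digits = NA)
    files <- c(files, mfile)
    summaries$model <- list(holdout_pearson = r)
  }
  if ("fret" %in% config$stages) {
    res <- do.call(rbind, lapply(names(config$fret), function(nm) {
      tr <- simulateTraces(config$fret[[nm]], config$n_molecules,
                           seed = config$seeds$fret + match(nm, names(config$fret)))
      fr <- classifyPopulations(histogramSamples(tr))
      data.frame(condition = nm, n_molecules = attr(fr, "n"),
                 donor_only = fr[["donor_only"]],
                 low_fret = fr[["low_fret"]], high_fret = fr[["high_fret"]],
                 f_unwound = fUnwound(fr))
    }))
    if (all(c("matched", "mismatched") %in% res$condition))
      summaries$fret <- list(
        unwinding_specificity = unwindingSpecificity(
          res$f_unwound[res$condition == "mismatched"],
          res$f_unwound[res$condition == "matched"]))
    files <- c(files, .write_tsv(res, file.path(outdir, "fret_results.tsv")))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("sniperkit")),
    stages = config$stages,
    seeds = config$seeds,
    files = if (length(files))
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
    else data.frame(file = character(0), md5 = character(0)),
    summaries = summaries)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
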