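#' Read and validate a run configuration
#'
#' Configuration is a single YAML file (key-value) because per-reference
#' numbering offsets are per-file data, not flags. Recognized keys:
#' \code{seed}, \code{outdir}, \code{construct} (\code{"htt17q"} or a map
#' with \code{sequence}/\code{head}/\code{polyq}/\code{cterm}),
#' \code{normalize_by}, \code{thresholds} (\code{exact_match},
#' \code{tm_cutoff}, \code{min_consecutive_q}), \code{simulate}
#' (\code{n_runs}, \code{models_per_run}, \code{noise_sigma},
#' \code{n_references}, \code{reference_noise_sigma}), \code{models}
#' (\code{dir}) and \code{references} (\code{dir} + \code{chain} +
#' \code{offset}, or \code{entries} with per-file \code{path},
#' \code{chain}, \code{offset}, \code{label}).
#'
#' @param path YAML file, or a list already parsed.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, outdir = "polyqeval_out", construct = "htt17q",
    normalize_by = "reference",
    thresholds = list(exact_match = 5.0, tm_cutoff = 0.5,
                      min_consecutive_q = 9L),
    simulate = list(n_runs = 10L, models_per_run = 5L, noise_sigma = 1.0,
                    n_references = 21L, reference_noise_sigma = 0.3))
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]])) {
      for (k2 in names(defaults[[k]]))
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- defaults[[k]][[k2]]
    }
  }
  th <- cfg$thresholds
  bad <- names(th)[vapply(th, function(x) !is.numeric(x) || x <= 0,
                          logical(1))]
  if (length(bad) > 0)
    stop("config validation: thresholds must be positive: ",
         paste(bad, collapse = ", "))
  if (!cfg$normalize_by %in% c("reference", "model", "shorter"))
    stop("config validation: normalize_by must be reference/model/shorter")
  cfg$constructDef <- if (identical(cfg$construct, "htt17q")) {
    htt17qConstruct()
  } else {
    ConstructDef(cfg$construct$sequence, unlist(cfg$construct$head),
                 unlist(cfg$construct$polyq), unlist(cfg$construct$cterm))
  }
  cfg
}

# deterministic 31-bit polynomial hash for provenance stamps
configHash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

provenanceLine <- function(config) {
  ser <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "constructDef")])), collapse = "\n")
  sprintf("# polyQeval %s | seed=%s | config=%s",
          as.character(utils::packageVersion("polyQeval")),
          config$seed, configHash(ser))
}

writeTsvWithHeader <- function(df, path, config, rowNames = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceLine(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
  invisible(path)
}

readTsvWithHeader <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Generate a synthetic study fixture tree
#'
#' Writes a predicted-model ensemble (PDB per model plus a score table)
#' and a masked reference set (PDB per chain) under
#' \code{config$outdir}, together with a ground-truth JSON sidecar
#' (masks, resolved-Q counts, generation parameters). Deterministic given
#' the config seed.
#'
#' @param config a [readRunConfig()] result (or path to one).
#' @return invisibly, a list with the generated \code{ensemble},
#'   \code{references} and output \code{paths}.
#' @export
runSimulate <- function(config) {
  config <- readRunConfig(config)
  sim <- config$simulate
  cd <- config$constructDef
  ens <- generateEnsemble(cd, nRuns = sim$n_runs,
                          modelsPerRun = sim$models_per_run,
                          noiseSigma = sim$noise_sigma,
                          seed = config$seed)
  refs <- generateReferenceSet(cd, n = sim$n_references,
                               noiseSigma = sim$reference_noise_sigma,
                               seed = config$seed + 1L)
  mdir <- file.path(config$outdir, "models")
  rdir <- file.path(config$outdir, "references")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(ens@models))
    writePdbModel(ens@models[[lab]], file.path(mdir, paste0(lab, ".pdb")))
  for (lab in names(refs$models))
    writePdbModel(refs$models[[lab]], file.path(rdir, paste0(lab, ".pdb")))
  scores <- data.frame(label = names(ens@models),
                       score = vapply(ens@models, modelScore, numeric(1)),
                       run = unname(ens@run[names(ens@models)]))
  writeTsvWithHeader(scores, file.path(config$outdir, "scores.tsv"), config)
  jsonlite::write_json(
    list(provenance = provenanceLine(config),
         seed = config$seed,
         simulate = config$simulate,
         resolved_q = refs$resolvedQ,
         masks = refs$masks),
    file.path(config$outdir, "ground_truth.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(ensemble = ens, references = refs$models,
                 paths = list(models = mdir, references = rdir)))
}

loadEnsemble <- function(config) {
  dir <- config$models$dir
  if (is.null(dir)) dir <- file.path(config$outdir, "models")
  files <- list.files(dir, pattern = "^run[0-9]+_model[0-9]+\\.pdb$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no model PDB files found in ", dir)
  labs <- sub("\\.pdb$", "", basename(files))
  run <- as.integer(sub("^run([0-9]+)_model[0-9]+$", "\\1", labs))
  rank <- as.integer(sub("^run[0-9]+_model([0-9]+)$", "\\1", labs))
  ord <- order(run, rank)
  models <- lapply(ord, function(i) {
    readPdbChain(files[i], "A", config$constructDef, 0L, label = labs[i],
                 source = "predicted")
  })
  EnsembleSet(models, run[ord], rank[ord])
}

loadReferences <- function(config) {
  rcfg <- config$references
  if (!is.null(rcfg$entries)) {
    models <- lapply(rcfg$entries, function(e) {
      readPdbChain(e$path, e$chain %||% "A", config$constructDef,
                   as.integer(e$offset %||% 0L), label = e$label)
    })
    return(models)
  }
  dir <- rcfg$dir
  if (is.null(dir)) dir <- file.path(config$outdir, "references")
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  if (length(files) == 0L) stop("no reference PDB files found in ", dir)
  lapply(files, function(f) {
    readPdbChain(f, rcfg$chain %||% "A", config$constructDef,
                 as.integer(rcfg$offset %||% 0L))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproducibility study
#'
#' Loads the run-grouped ensemble, computes the full pairwise TM matrix,
#' the rank-1 best-model matrix with its above-cutoff count, and the
#' run-level cross-run counts, and writes them as TSV plus a statistics
#' JSON (distribution summary of pairwise TM values). Outputs are
#' deterministic given config + seed and carry a provenance header.
#'
#' @param config a [readRunConfig()] result (or path).
#' @param ensemble optional in-memory [EnsembleSet-class] overriding the
#'   configured model directory.
#' @return invisibly: list with \code{matrix}, \code{best},
#'   \code{runCounts}, \code{summary}.
#' @export
runReproducibility <- function(config, ensemble = NULL) {
  config <- readRunConfig(config)
  if (is.null(ensemble)) ensemble <- loadEnsemble(config)
  cutoff <- config$thresholds$tm_cutoff
  pm <- pairwiseTmMatrix(ensemble)
  best <- bestModelMatrix(ensemble, cutoff = cutoff)
  rc <- runLevelCounts(ensemble, cutoff = cutoff, matrix = pm)
  vals <- pm@values[upper.tri(pm@values)]
  summ <- summarizeMetric(vals)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writeTsvWithHeader(as.data.frame(round(pm@values, 4)),
                     file.path(config$outdir, "pairwise_tm.tsv"),
                     config, rowNames = TRUE)
  writeTsvWithHeader(as.data.frame(round(best$matrix@values, 4)),
                     file.path(config$outdir, "best_model_matrix.tsv"),
                     config, rowNames = TRUE)
  writeTsvWithHeader(as.data.frame(rc),
                     file.path(config$outdir, "run_level_counts.tsv"),
                     config, rowNames = TRUE)
  jsonlite::write_json(
    list(provenance = provenanceLine(config),
         n_pairs = length(vals), count_above_cutoff = countAbove(pm, cutoff),
         best_model_count_above = best$countAbove,
         tm_cutoff = cutoff, summary = as.list(summ)),
    file.path(config$outdir, "reproducibility_stats.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(matrix = pm, best = best, runCounts = rc, summary = summ))
}

#' Validity study
#'
#' Loads ensemble and references, applies the consecutive-Q reference
#' filter, writes the per-reference resolved-Q report and the full
#' model-versus-reference metric panel with its per-metric summaries.
#'
#' @inheritParams runReproducibility
#' @param references optional list of [StructureModel-class] overriding
#'   the configured reference inputs.
#' @return invisibly: list with \code{panel}, \code{qCounts},
#'   \code{references} (the retained ones).
#' @export
runValidate <- function(config, ensemble = NULL, references = NULL) {
  config <- readRunConfig(config)
  if (is.null(ensemble)) ensemble <- loadEnsemble(config)
  if (is.null(references)) references <- loadReferences(config)
  qc <- data.frame(
    label = vapply(references, modelLabel, character(1)),
    resolved_q = vapply(references, resolvedQCount, integer(1)),
    max_consecutive_q = vapply(references, maxConsecutiveResolvedQ,
                               integer(1)))
  kept <- filterReferences(references,
                           config$thresholds$min_consecutive_q)
  if (length(kept) == 0L) stop("no usable references")
  qc$passes_filter <- qc$max_consecutive_q >=
    config$thresholds$min_consecutive_q
  panel <- validityPanel(ensemble, kept,
                         threshold = config$thresholds$exact_match,
                         normalizeBy = config$normalize_by)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writeTsvWithHeader(qc, file.path(config$outdir, "reference_q_counts.tsv"),
                     config)
  writeTsvWithHeader(panel$records,
                     file.path(config$outdir, "validity_panel.tsv"), config)
  jsonlite::write_json(
    list(provenance = provenanceLine(config),
         n_records = nrow(panel$records),
         n_references_used = length(kept),
         summary = panel$summary),
    file.path(config$outdir, "validity_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(panel = panel, qCounts = qc, references = kept))
}

#' Secondary-structure logo profiles
#'
#' Assigns secondary structure to every model and reference and writes
#' position-frequency TSVs (model and reference panels) plus the SS
#' strings as FASTA-like text.
#'
#' @inheritParams runValidate
#' @return invisibly: list with \code{modelProfile},
#'   \code{referenceProfile}.
#' @export
runSsLogo <- function(config, ensemble = NULL, references = NULL) {
  config <- readRunConfig(config)
  if (is.null(ensemble)) ensemble <- loadEnsemble(config)
  if (is.null(references)) references <- loadReferences(config)
  mss <- lapply(ensemble@models, assignDssp)
  rss <- lapply(references, assignDssp)
  names(rss) <- vapply(references, modelLabel, character(1))
  mp <- ssProfile(mss)
  rp <- ssProfile(rss)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writeSsFasta(mss, file.path(config$outdir, "models_ss.fasta"))
  writeSsFasta(rss, file.path(config$outdir, "references_ss.fasta"))
  writeTsvWithHeader(
    data.frame(position = seq_len(nrow(mp@counts)), mp@counts,
               check.names = FALSE),
    file.path(config$outdir, "models_ss_profile.tsv"), config)
  writeTsvWithHeader(
    data.frame(position = seq_len(nrow(rp@counts)), rp@counts,
               check.names = FALSE),
    file.path(config$outdir, "references_ss_profile.tsv"), config)
  invisible(list(modelProfile = mp, referenceProfile = rp))
}
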