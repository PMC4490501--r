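# End-to-end pipeline wiring with a validated flat config and a run
# manifest. The command-line entry point (inst/scripts/combiphore) is a
# thin wrapper around runPipeline().

#' Default run configuration
#'
#' Flat named list of every stage parameter with the method's reference
#' defaults: minimum group size 15, 2:1 train/test split, pharmacophore
#' sizes 4-6, top 10 percent of hypotheses kept, vector score threshold
#' 0.5, site/distance RMSD threshold 1.2 A, conformer dedup RMSD 1.00 A,
#' 1 A grid cubes, 3 PLS factors, activity cutoffs 7.0/5.0, screening
#' threshold 5.0 and top 100, decoy ratio 36.
#'
#' @return named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    min_group_size = 15L, split_ratio = 2, k_values = c(4L, 5L, 6L),
    keep_fraction = 0.10, vector_min = 0.5, rmsd_max = 1.2,
    conformer_rmsd = 1.00, max_conformers = 32L, grid_spacing = 1.0,
    pls_factors = 3L, active_cutoff = 7.0, inactive_cutoff = 5.0,
    activity_min = 5.0, top_n = 100L, decoy_ratio = 36L,
    seed = 1L)
}

configRanges <- list(
  min_group_size = c(1, Inf), split_ratio = c(0.1, 100),
  keep_fraction = c(0, 1), vector_min = c(0, 1), rmsd_max = c(0, 100),
  conformer_rmsd = c(0, 100), max_conformers = c(1, 10000),
  grid_spacing = c(0.1, 10), pls_factors = c(1, 100),
  active_cutoff = c(-100, 100), inactive_cutoff = c(-100, 100),
  activity_min = c(-100, 100), top_n = c(1, 1e9),
  decoy_ratio = c(0, 1e6), seed = c(-2^31, 2^31))

#' Validate a run configuration
#'
#' Unknown keys and out-of-range values raise errors naming the key.
#'
#' @param config partial named list; missing keys take defaults.
#' @return the completed, validated config.
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  full <- utils::modifyList(def, config)
  for (key in names(configRanges)) {
    v <- full[[key]]
    rg <- configRanges[[key]]
    if (!all(is.finite(v)) || any(v < rg[1]) || any(v > rg[2]))
      stop("config key out of range: ", key)
  }
  if (!all(full$k_values %in% 4:6))
    stop("config key out of range: k_values")
  full
}

writeManifest <- function(path, command, config, artifacts, counts) {
  manifest <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = hashMix(utf8ToInt(paste(
      names(config), vapply(config, function(v)
        paste(format(v, digits = 15), collapse = ","), character(1)),
      collapse = ";"))),
    package_version = as.character(utils::packageVersion("combiphore")),
    artifacts = artifacts, counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a pipeline command
#'
#' Commands: \code{simulate} (generate the synthetic dataset + truth),
#' \code{build} (scaffold partition + combinatorial model),
#' \code{predict} (dispatch + QSAR prediction for query structures),
#' \code{validate} (EF curve against actives + decoys), \code{screen}
#' (Lipinski filter + hypothesis match + prediction + ranking). Each run
#' writes its artifacts and a JSON manifest (config hash, seed, per-stage
#' counts) into \code{outDir}.
#'
#' @param command one of simulate, build, predict, validate, screen.
#' @param config partial config list (see \code{defaultConfig}).
#' @param inputs named list of input paths/objects; see details per
#'   command in the function body (train, activities, model, query,
#'   actives, decoys, library).
#' @param outDir output directory (created if needed).
#' @return named list of produced artifact paths, invisibly.
#' @export
runPipeline <- function(command = c("simulate", "build", "predict",
                                    "validate", "screen"),
                        config = list(), inputs = list(),
                        outDir = ".") {
  command <- match.arg(command)
  config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list(); counts <- list()
  fail <- function(e) stop("stage '", command, "' failed: ",
                           conditionMessage(e), call. = FALSE)
  if (command == "simulate") {
    ds <- tryCatch(generateDataset(syntheticSpec(seed = config$seed)),
                   error = fail)
    sdfPath <- file.path(outDir, "synthetic.sdf")
    writeSdf(ds$molecules, sdfPath)
    actPath <- file.path(outDir, "synthetic_activities.csv")
    utils::write.csv(data.frame(
      id = vapply(ds$molecules, molId, character(1)),
      pic50 = vapply(ds$molecules, activity, numeric(1))),
      actPath, row.names = FALSE)
    truthPath <- file.path(outDir, "truth.json")
    tr <- ds$truth
    jsonlite::write_json(list(
      spec = unclass(tr$spec),
      groups = lapply(tr$groups, function(g) list(
        group = g$group, planted_label = g$plantedLabel,
        planted_sites = g$plantedSites,
        planted_distances = g$plantedDistances,
        weights = as.list(g$weights), intercept = g$intercept)),
      members = lapply(tr$members, function(m) list(
        id = m$id, group = m$group, config = m$config,
        noise = m$noise, activity = m$activity))),
      truthPath, auto_unbox = TRUE, digits = NA)
    artifacts <- list(sdf = sdfPath, activities = actPath,
                      truth = truthPath)
    counts <- list(molecules = length(ds$molecules))
  } else if (command == "build") {
    mols <- tryCatch(loadInputMolecules(inputs), error = fail)
    grouped <- tryCatch(
      partitionByScaffold(mols, minSize = config$min_group_size),
      error = fail)
    model <- tryCatch(
      buildCombinatorial(mols, grouped, kValues = config$k_values,
                         nFactors = config$pls_factors,
                         seed = config$seed),
      error = fail)
    modelPath <- file.path(outDir, "model.json")
    writeCombinatorialModel(model, modelPath)
    groupPath <- file.path(outDir, "groups.json")
    writeGroupedDataset(grouped, groupPath)
    reportPath <- file.path(outDir, "group_stats.csv")
    utils::write.csv(attr(model, "report"), reportPath,
                     row.names = FALSE)
    artifacts <- list(model = modelPath, groups = groupPath,
                      report = reportPath)
    counts <- list(molecules = length(mols),
                   groups = length(grouped@groups),
                   models = length(model@entries))
  } else if (command == "predict") {
    model <- tryCatch(loadModel(inputs), error = fail)
    queries <- tryCatch(loadInputMolecules(inputs, key = "query"),
                        error = fail)
    rows <- lapply(queries, function(q) {
      pr <- predictCombinatorial(model, q)
      data.frame(id = molId(q), group_id = pr$group_id,
                 matched = pr$matched, mean_tc = pr$mean_tc,
                 predicted_pic50 = pr$predicted)
    })
    predPath <- file.path(outDir, "predictions.csv")
    utils::write.csv(do.call(rbind, rows), predPath, row.names = FALSE)
    artifacts <- list(predictions = predPath)
    counts <- list(queries = length(queries),
                   matched = sum(vapply(rows, function(r) r$matched,
                                        logical(1))))
  } else if (command == "validate") {
    model <- tryCatch(loadModel(inputs), error = fail)
    actives <- tryCatch(loadInputMolecules(inputs, key = "actives"),
                        error = fail)
    decoys <- tryCatch(loadInputMolecules(inputs, key = "decoys"),
                       error = fail)
    ranked <- rankForValidation(model, actives, decoys)
    fractions <- if (!is.null(inputs$fractions)) inputs$fractions else
      c(0.01, 0.02, 0.05, 0.10, 1.0)
    ef <- efCurve(ranked, fractions)
    efPath <- file.path(outDir, "ef.csv")
    utils::write.csv(data.frame(fraction = ef$fractions,
                                ef = ef$ef_values), efPath,
                     row.names = FALSE)
    artifacts <- list(ef = efPath)
    counts <- list(actives = length(actives), decoys = length(decoys),
                   hits_t = ef$hits_t, n_t = ef$n_t)
  } else {
    model <- tryCatch(loadModel(inputs), error = fail)
    library_ <- tryCatch(loadInputMolecules(inputs, key = "library"),
                         error = fail)
    hits <- screenLibrary(model, library_,
                          activityMin = config$activity_min,
                          topN = config$top_n)
    hitsPath <- file.path(outDir, "hits.csv")
    utils::write.csv(hits, hitsPath, row.names = FALSE)
    provPath <- file.path(outDir, "provenance.csv")
    prov <- attr(hits, "provenance")
    utils::write.csv(data.frame(id = names(prov), stage = unname(prov)),
                     provPath, row.names = FALSE)
    artifacts <- list(hits = hitsPath, provenance = provPath)
    counts <- list(library = length(library_), ranked = nrow(hits))
  }
  writeManifest(file.path(outDir, paste0(command, "_manifest.json")),
                command, config, artifacts, counts)
  artifacts$manifest <- file.path(outDir,
                                  paste0(command, "_manifest.json"))
  invisible(artifacts)
}

# Accept either in-memory molecule lists or file paths (SDF; an optional
# activities CSV with id + pic50/ic50_nM merges by id).
loadInputMolecules <- function(inputs, key = "train") {
  x <- inputs[[key]]
  if (is.null(x)) stop("missing input: ", key)
  mols <- if (is.character(x)) readMolecules(x, format = "sdf") else x
  actKey <- paste0(key, "_activities")
  actPath <- if (!is.null(inputs$activities) && key == "train")
    inputs$activities else inputs[[actKey]]
  if (!is.null(actPath)) {
    tab <- utils::read.csv(actPath, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    ids <- vapply(mols, molId, character(1))
    for (i in seq_len(nrow(tab))) {
      j <- match(as.character(tab$id[i]), ids)
      if (is.na(j)) next
      act <- if ("pic50" %in% names(tab)) tab$pic50[i] else
        pIC50FromIC50(tab$ic50_nm[i])
      activity(mols[[j]]) <- act
    }
  }
  mols
}

loadModel <- function(inputs) {
  x <- inputs$model
  if (is.null(x)) stop("missing input: model")
  if (is.character(x)) readCombinatorialModel(x) else x
}

# Validation ranking: every compound is predicted; unmatched compounds
# rank last (the default accounting; see the screening docs).
rankForValidation <- function(model, actives, decoys) {
  all_ <- c(actives, decoys)
  lab <- c(rep(TRUE, length(actives)), rep(FALSE, length(decoys)))
  preds <- vapply(all_, function(m) {
    pr <- predictCombinatorial(model, m)
    if (pr$matched) pr$predicted else -Inf
  }, numeric(1))
  ord <- order(-preds)
  data.frame(id = vapply(all_, molId, character(1))[ord],
             score = preds[ord], is_active = lab[ord])
}
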