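#' Experiment configuration
#'
#' A single serializable object that, together with the package version,
#' determines every output of [runExperiment()]: generator parameters,
#' components and states to analyze, connection selections, CV and
#' repetition seeds, and permutation counts.
#'
#' @param cohortCfg A [cohortConfig()].
#' @param connCfg A [connectomeConfig()].
#' @param atlasNodes Node count of the synthetic atlas.
#' @param components Components to predict: subset of "g", "gc", "gf".
#' @param states States to analyze (default all generated states).
#' @param latentStates Append the two latent-FC states?
#' @param selections Character vector of selection specs: any of
#'   "whole_brain", "networks" (the full network enumeration),
#'   "random_edges:k", "random_nodes:m".
#' @param nFolds Outer CV folds.
#' @param repetitions Number of fold-seed repetitions.
#' @param control A [predictControl()].
#' @param permutations Permutations for the performance test (0 = skip).
#' @param lockboxFraction Optional family-aware lockbox fraction (NULL =
#'   no lockbox split).
#' @return List of class \code{experimentConfig}.
#' @export
experimentConfig <- function(cohortCfg = cohortConfig(),
                             connCfg = connectomeConfig(),
                             atlasNodes = 100,
                             components = c("g", "gc", "gf"),
                             states = NULL, latentStates = FALSE,
                             selections = "whole_brain",
                             nFolds = 5, repetitions = 1,
                             control = predictControl(),
                             permutations = 0,
                             lockboxFraction = NULL) {
  structure(list(cohortCfg = cohortCfg, connCfg = connCfg,
                 atlasNodes = atlasNodes, components = components,
                 states = states, latentStates = latentStates,
                 selections = selections, nFolds = nFolds,
                 repetitions = repetitions, control = control,
                 permutations = permutations,
                 lockboxFraction = lockboxFraction),
            class = "experimentConfig")
}

resolveSelections <- function(specs, atlasObj, seed) {
  out <- list()
  for (sp in specs) {
    if (sp == "whole_brain") {
      out$whole_brain <- wholeBrainSelection(atlasObj)
    } else if (sp == "networks") {
      out <- c(out, enumerateNetworkSelections(atlasObj))
    } else if (grepl("^random_edges:", sp)) {
      k <- as.integer(sub("^random_edges:", "", sp))
      sel <- randomEdgeSelection(k, atlasObj, seed)
      out[[provenance(sel)]] <- sel
    } else if (grepl("^random_nodes:", sp)) {
      m <- as.integer(sub("^random_nodes:", "", sp))
      sel <- randomNodeSelection(m, atlasObj, seed)
      out[[provenance(sel)]] <- sel
    } else stop("unknown selection spec: ", sp)
  }
  out[!duplicated(names(out))]
}

#' Run a configuration-driven synthetic experiment
#'
#' Executes the study design end to end on synthetic data: generate a
#' cohort (with motion exclusion), estimate the intelligence components
#' from the cognitive measures, generate multi-state connectomes
#' (optionally appending the two latent-FC states), materialize the
#' configured connection selections, run family-aware cross-validated
#' prediction for every (component, state, selection) cell, and
#' optionally a permutation performance test per cell. Deterministic for
#' a fixed config and seed; rerunning an identical config yields
#' identical tables.
#'
#' @param config An [experimentConfig()].
#' @param seed Integer master seed.
#' @param outDir Optional output directory; when given, the result table,
#'   per-cell predictions, selections, and a machine-readable run
#'   manifest (seeds, sizes, timings) are written as delimited text /
#'   JSON.
#' @return List: \code{results} (one row per component x state x
#'   selection x repetition with r/MSE/RMSE/MAE and chosen
#'   hyperparameters), \code{predictions}, \code{scores},
#'   \code{connectomes} (the [ConnectomeSet-class]), \code{selections},
#'   \code{permutation} (if requested), \code{manifest}.
#' @export
runExperiment <- function(config, seed = 1, outDir = NULL) {
  stopifnot(inherits(config, "experimentConfig"))
  t0 <- Sys.time()
  stage <- "generate"
  res <- tryCatch({
    atlasObj <- syntheticAtlas(config$atlasNodes, seed = seed)
    cset <- simulateStudy(config$cohortCfg, config$connCfg, atlasObj,
                          seed = seed)
    if (isTRUE(config$latentStates)) {
      stage <- "latent FC"
      cset <- appendLatentStates(cset)
    }
    stage <- "score"
    ch <- cohort(cset)
    scores <- scoreIntelligence(ch)
    stage <- "select"
    sels <- resolveSelections(config$selections, atlasObj, seed)
    stateNames <- if (is.null(config$states)) states(cset)
    else config$states
    confounds <- as.matrix(ch[, c("age", "sex", "handedness", "mean_fd",
                                  "spike_prop")])
    foldSeeds <- seed + seq_len(config$repetitions)

    stage <- "predict"
    rows <- list()
    predRows <- list()
    permRows <- list()
    for (comp in config$components) {
      y <- scores[[comp]]
      for (st in stateNames) {
        for (selName in names(sels)) {
          X <- selectionFeatures(cset, st, sels[[selName]])
          pr <- crossValidatedPredict(X, y, confounds, ch$family_id,
                                      nFolds = config$nFolds,
                                      foldSeeds = foldSeeds,
                                      control = config$control)
          mm <- metrics(pr)
          rows[[length(rows) + 1L]] <- data.frame(
            component = comp, state = st, selection = selName,
            repetition = mm$repetition, r = mm$r, mse = mm$mse,
            rmse = mm$rmse, mae = mm$mae, stringsAsFactors = FALSE)
          pp <- predictions(pr)
          pp$component <- comp; pp$state <- st; pp$selection <- selName
          pp$subject <- ch$id[pp$subject]
          predRows[[length(predRows) + 1L]] <- pp
          if (config$permutations > 0) {
            runner <- function(yy) meanPerformance(
              crossValidatedPredict(X, yy, confounds, ch$family_id,
                                    nFolds = config$nFolds,
                                    foldSeeds = foldSeeds[1],
                                    control = config$control))
            pt <- permutationTestPerformance(runner, y,
                                             m = config$permutations,
                                             seed = seed,
                                             observed = mean(mm$r))
            permRows[[length(permRows) + 1L]] <- data.frame(
              component = comp, state = st, selection = selName,
              observed_r = pt$observed, p = pt$p, m = pt$m,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    results <- do.call(rbind, rows)
    list(results = results,
         predictions = do.call(rbind, predRows),
         scores = scores, connectomes = cset, selections = sels,
         permutation = if (length(permRows)) do.call(rbind, permRows),
         manifest = list(seed = seed, nSubjects = ncol(cset),
                         nEdges = nEdges(cset),
                         states = stateNames,
                         selections = names(sels),
                         components = config$components,
                         nFolds = config$nFolds,
                         repetitions = config$repetitions,
                         edgeConvention = edgeConvention(),
                         elapsedSec = as.numeric(
                           difftime(Sys.time(), t0, units = "secs"))))
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTableTsv(res$results, file.path(outDir, "results.tsv"))
    writeTableTsv(res$predictions, file.path(outDir, "predictions.tsv"))
    writeTableTsv(res$scores, file.path(outDir, "scores.tsv"))
    if (!is.null(res$permutation))
      writeTableTsv(res$permutation, file.path(outDir, "permutation.tsv"))
    seldir <- file.path(outDir, "selections")
    dir.create(seldir, showWarnings = FALSE)
    for (nm in names(res$selections))
      writeSelection(res$selections[[nm]],
                     file.path(seldir, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                                   nm), ".json")))
    jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
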