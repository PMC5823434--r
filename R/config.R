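#' RunConfig: shared thresholds and paths for a pipeline run
#'
#' Every default equals the analysis constant it governs: gap threshold
#' 0.64 (minimum non-gap fraction for a defined entropy), SC cutoff 1.7
#' (high specific conservation), insertion cutoff 3.3 (conserved
#' insertion entropy), signal floor 1000 intensity units, binding-fraction
#' cutoff 0.5.
#'
#' @slot gapThreshold minimum non-gap fraction.
#' @slot scCutoff high-SC flag threshold.
#' @slot insertionCutoff conserved-insertion entropy cutoff.
#' @slot minSum binding intensity signal floor.
#' @slot bfCutoff specific-call binding-fraction cutoff.
#' @slot kmeansK clusters for k-means surface clustering.
#' @slot clusterSeed k-means seed.
#' @slot seed seed for synthetic generation.
#' @slot scheme equivalency scheme (named list of residue vectors).
#' @slot surfaces named list of surface position sets.
#' @slot inputs named list of input paths (`paralog`, `orthologDir`,
#'   `referenceTable`, `bindingDir`, `mergeRules`) or `simulate = TRUE`
#'   to run on generated data.
#' @export
setClass("RunConfig",
  representation(gapThreshold = "numeric", scCutoff = "numeric",
                 insertionCutoff = "numeric", minSum = "numeric",
                 bfCutoff = "numeric", kmeansK = "integer",
                 clusterSeed = "integer", seed = "integer",
                 scheme = "list", surfaces = "list", inputs = "list"))

setValidity("RunConfig", function(object) {
  thr <- c(object@gapThreshold, object@scCutoff, object@insertionCutoff,
           object@minSum, object@bfCutoff)
  if (any(thr <= 0)) return("thresholds must be positive")
  ok <- tryCatch({ validateScheme(object@scheme); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  if (!all(vapply(object@surfaces, function(s)
        all(s >= 1 & s <= 60), logical(1))))
    return("surface positions must lie in 1..60")
  TRUE
})

#' Construct a RunConfig
#'
#' @param gapThreshold,scCutoff,insertionCutoff,minSum,bfCutoff,kmeansK,clusterSeed,seed,scheme,surfaces,inputs
#'   see [RunConfig-class].
#' @return A [RunConfig-class].
#' @export
runConfig <- function(gapThreshold = 0.64, scCutoff = 1.7,
                      insertionCutoff = 3.3, minSum = 1000, bfCutoff = 0.5,
                      kmeansK = 4L, clusterSeed = 0L, seed = 0L,
                      scheme = defaultEquivalencyGroups(),
                      surfaces = defaultSurfaces(),
                      inputs = list(simulate = TRUE)) {
  new("RunConfig", gapThreshold = gapThreshold, scCutoff = scCutoff,
      insertionCutoff = insertionCutoff, minSum = minSum,
      bfCutoff = bfCutoff, kmeansK = as.integer(kmeansK),
      clusterSeed = as.integer(clusterSeed), seed = as.integer(seed),
      scheme = scheme, surfaces = surfaces, inputs = inputs)
}

#' Serialise / deserialise a RunConfig as flat JSON
#'
#' @param config a [RunConfig-class].
#' @param path JSON file path.
#' @return `writeRunConfig`: `path`, invisibly. `readRunConfig`: a
#'   [RunConfig-class] equivalent to the one written.
#' @export
writeRunConfig <- function(config, path) {
  obj <- list(
    gap_threshold = config@gapThreshold, sc_cutoff = config@scCutoff,
    insertion_cutoff = config@insertionCutoff, min_sum = config@minSum,
    bf_cutoff = config@bfCutoff, kmeans_k = config@kmeansK,
    cluster_seed = config@clusterSeed, seed = config@seed,
    scheme = lapply(config@scheme, paste0, collapse = ""),
    surfaces = config@surfaces, inputs = config@inputs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  runConfig(
    gapThreshold = obj$gap_threshold, scCutoff = obj$sc_cutoff,
    insertionCutoff = obj$insertion_cutoff, minSum = obj$min_sum,
    bfCutoff = obj$bf_cutoff, kmeansK = obj$kmeans_k,
    clusterSeed = obj$cluster_seed, seed = obj$seed,
    scheme = lapply(obj$scheme, function(s) strsplit(s, "")[[1]]),
    surfaces = lapply(obj$surfaces, as.integer),
    inputs = as.list(obj$inputs))
}
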