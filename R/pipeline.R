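#' Run the full specific-conservation pipeline
#'
#' Orchestrates every stage on one family: canonical mapping, entropy and
#' SC profiling per domain, surface averages and insertion counts, PSSMs,
#' the family master matrix, SI/SII k-means and hierarchical clustering,
#' and (when binding data are present) paralog merging, binding fractions,
#' specific calls and per-domain binding summaries. All stage outputs are
#' written as TSV under `outDir` together with a JSON manifest recording
#' the configuration, seeds, input checksums and package version. Reruns
#' with identical inputs and configuration are bit-identical.
#'
#' With `inputs$simulate = TRUE` (the default config) the family and the
#' binding matrices are generated by [generateFamily()] and
#' [generateBinding()] from the config's seed. Otherwise `inputs` must
#' name a paralog alignment file, a directory of per-domain ortholog
#' alignments (`<domain>.fasta`), and a reference TSV with columns
#' `domain`, `paralog_reference_id`, `ortholog_reference_id`,
#' `span_start`, `span_end`; binding data (`bindingDir` with
#' `<species>.tsv` files, optional `mergeRules` TSV) are optional.
#'
#' @param config a [RunConfig-class].
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the computed objects: `profiles`,
#'   `summary`, `pssms`, `master`, `clusters`, `binding` and
#'   `manifest_path`.
#' @export
runPipeline <- function(config = runConfig(), outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  inp <- config@inputs
  checksums <- list()

  if (isTRUE(inp$simulate)) {
    fam <- generateFamily(familySpec(seed = config@seed),
                          scheme = config@scheme)
    paralog <- fam$paralog
    orthologs <- fam$orthologs
    refTable <- data.frame(
      domain = names(orthologs),
      paralog_reference_id = names(orthologs),
      ortholog_reference_id = vapply(orthologs, function(a)
        alignmentIds(a)[1L], character(1)),
      span_start = 1L, span_end = fam$spec@nPositions)
    write.table(fam$truth, file.path(outDir, "family_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bindingData <- generateBinding(bindingSpec(seed = config@seed + 1L))
    bindingMatrices <- bindingData$matrices
    write.table(bindingData$truth, file.path(outDir, "binding_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mergeRules <- NULL
  } else {
    paralog <- readAlignment(inp$paralog, kind = "paralog")
    refTable <- utils::read.delim(inp$referenceTable,
                                  stringsAsFactors = FALSE)
    orthologs <- stats::setNames(vector("list", nrow(refTable)),
                                 refTable$domain)
    for (i in seq_len(nrow(refTable))) {
      f <- file.path(inp$orthologDir,
                     paste0(refTable$domain[i], ".fasta"))
      if (!file.exists(f))
        stop("stage alignment_io failed: missing ortholog alignment for ",
             "domain '", refTable$domain[i], "' (", f, ")")
      orthologs[[i]] <- readAlignment(f, kind = "ortholog")
    }
    checksums$paralog <- unname(tools::md5sum(inp$paralog))
    checksums$reference_table <- unname(tools::md5sum(inp$referenceTable))
    bindingMatrices <- NULL
    mergeRules <- NULL
    if (!is.null(inp$bindingDir)) {
      files <- list.files(inp$bindingDir, pattern = "\\.tsv$",
                          full.names = TRUE)
      species <- sub("\\.tsv$", "", basename(files))
      bindingMatrices <- stats::setNames(
        Map(readBindingMatrix, files, species), species)
      if (!is.null(inp$mergeRules))
        mergeRules <- utils::read.delim(inp$mergeRules,
                                        stringsAsFactors = FALSE)
    }
  }

  ## conservation stage ------------------------------------------------
  nPositions <- max(refTable$span_end - refTable$span_start + 1L)
  profDir <- file.path(outDir, "profiles")
  dir.create(profDir, showWarnings = FALSE)
  profiles <- stats::setNames(vector("list", nrow(refTable)),
                              refTable$domain)
  pssms <- profiles
  for (i in seq_len(nrow(refTable))) {
    dom <- refTable$domain[i]
    span <- c(refTable$span_start[i], refTable$span_end[i])
    pMap <- buildCanonicalMap(paralog, refTable$paralog_reference_id[i],
                              span, nPositions)
    oMap <- buildCanonicalMap(orthologs[[dom]],
                              refTable$ortholog_reference_id[i],
                              span, nPositions)
    pProf <- profileAlignment(paralog, pMap, config@scheme,
                              config@gapThreshold)
    oProf <- profileAlignment(orthologs[[dom]], oMap, config@scheme,
                              config@gapThreshold)
    profiles[[dom]] <- scProfile(pProf, oProf, dom, nPositions,
                                 config@gapThreshold)
    pssms[[dom]] <- buildPSSM(orthologs[[dom]], oMap, config@scheme,
                              domainName = dom, nPositions = nPositions)
    out <- profiles[[dom]]@positions
    write.table(out, file.path(profDir, paste0(dom, "_sc.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  scMat <- familySCMatrix(profiles)
  write.table(data.frame(domain = rownames(scMat), scMat,
                         check.names = FALSE),
              file.path(outDir, "family_sc_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- do.call(rbind, lapply(profiles, summarizeConservation,
                                   surfaces = config@surfaces,
                                   scCutoff = config@scCutoff,
                                   insertionCutoff = config@insertionCutoff))
  summary <- summary[order(-summary$avg_sc_SII), , drop = FALSE]
  write.table(summary, file.path(outDir, "family_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## PSSM + clustering stage -------------------------------------------
  master <- buildMasterMatrix(pssms)
  write.table(data.frame(domain = rownames(master), unclass(master),
                         check.names = FALSE),
              file.path(outDir, "master_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- list()
  for (surf in intersect(c("SI", "SII"), names(config@surfaces))) {
    sub <- subsetSurface(master, config@surfaces[[surf]])
    km <- clusterKmeans(sub, config@kmeansK, seed = config@clusterSeed,
                        surface = surf)
    hc <- clusterHierarchical(sub, surface = surf)
    clusters[[surf]] <- list(kmeans = km, hierarchical = hc)
    write.table(data.frame(domain = names(clusterLabels(km)),
                           cluster = unname(clusterLabels(km))),
                file.path(outDir, paste0("clusters_", surf, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(exportNewick(hc),
               file.path(outDir, paste0("dendrogram_", surf, ".nwk")))
  }

  ## binding stage ------------------------------------------------------
  binding <- NULL
  if (!is.null(bindingMatrices)) {
    tables <- lapply(bindingMatrices, function(bm) {
      if (!is.null(mergeRules)) bm <- mergeParalogs(bm, mergeRules)
      bindingFraction(bm, config@minSum)
    })
    for (sp in names(tables)) {
      f <- tables[[sp]]@fractions
      write.table(data.frame(peptide = rownames(f), f, check.names = FALSE),
                  file.path(outDir, paste0("binding_fractions_", sp, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    calls <- callSpecific(tables, config@bfCutoff)
    write.table(calls, file.path(outDir, "specific_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bindingSummary <- summarizeAllDomains(tables, config@bfCutoff)
    write.table(bindingSummary, file.path(outDir, "binding_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    binding <- list(tables = tables, calls = calls,
                    summary = bindingSummary)
  }

  ## manifest -----------------------------------------------------------
  outputs <- sort(setdiff(list.files(outDir, recursive = TRUE),
                          "manifest.json"))
  manifest <- list(
    package = "specon",
    version = as.character(utils::packageVersion("specon")),
    config = jsonlite::fromJSON(configAsJSON(config)),
    input_checksums = checksums,
    output_checksums = as.list(
      tools::md5sum(file.path(outDir, outputs))[file.path(outDir, outputs)] |>
        stats::setNames(outputs)))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, summary = summary, pssms = pssms,
                 master = master, clusters = clusters, binding = binding,
                 manifest_path = manifestPath))
}

# config as a JSON string (shared by writeRunConfig and the manifest)
configAsJSON <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeRunConfig(config, tmp)
  paste(readLines(tmp), collapse = "\n")
}
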