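#' Run the full pigment-network pipeline
#'
#' Parse -> membrane frame -> leaflets -> contact graph -> layers ->
#' coupled pairs -> EET steps -> pathways -> census, collecting all
#' results in one summary and (optionally) writing TSV/JSON artifacts
#' plus a provenance block (input checksum, parameters, package
#' version).  Any stage error is re-signalled with the stage name and
#' partial outputs are removed, so a run directory is either complete or
#' empty.
#'
#' @param input coordinate file (mmCIF or PDB).
#' @param chainConfig chain annotation config (path or data.frame).
#' @param classMap class map (path or list); packaged default when NULL.
#' @param outDir output directory; when NULL nothing is written.
#' @param contactCutoff,stepCutoff,pairCutoff analysis cutoffs (A).
#' @param stromalReference optional 3-vector for membrane orientation.
#' @return invisible list: model, frame, graph, shells, pairs, steps,
#'   pathways, census, provenance.
#' @export
runPipeline <- function(input, chainConfig, classMap = NULL, outDir = NULL,
                        contactCutoff = 4, stepCutoff = 26, pairCutoff = 12,
                        stromalReference = NULL) {
  if (!is.null(chainConfig) && is.character(chainConfig) &&
      !file.exists(chainConfig))
    .stopf("config error: chain config not found: %s", chainConfig)
  if (is.character(chainConfig)) chainConfig <- readChainConfig(chainConfig)
  if (is.null(classMap)) classMap <- defaultClassMap()
  if (is.character(classMap)) classMap <- readClassMap(classMap)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s': %s", name, conditionMessage(e)))
  }
  model <- stage("parse", parseStructure(input, classMap, chainConfig))
  frame <- stage("frame", estimateFrame(model, stromalReference))
  model <- stage("leaflets", assignLeaflets(model, frame))
  graph <- stage("contacts", buildContactGraph(model, contactCutoff))
  shells <- stage("layers", assignLayers(graph))
  pairs <- stage("pairs", findCoupledPairs(model, pairCutoff))
  steps <- stage("steps", deriveEETSteps(model, shells, stepCutoff))
  paths <- stage("pathways", assemblePathways(steps,
                                              chainAnnotations(model)))
  cens <- stage("census", pigmentCensus(model))
  prov <- list(input = basename(input),
               md5 = unname(tools::md5sum(input)),
               parameters = list(contact_cutoff = contactCutoff,
                                 step_cutoff = stepCutoff,
                                 pair_cutoff = pairCutoff),
               package = "pigmentNet",
               version = as.character(utils::packageVersion("pigmentNet")))
  res <- list(model = model, frame = frame, graph = graph, shells = shells,
              pairs = pairs, steps = steps, pathways = paths, census = cens,
              provenance = prov)
  if (!is.null(outDir)) .writeRunArtifacts(res, outDir)
  invisible(res)
}

.writeRunArtifacts <- function(res, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character()
  emit <- function(fn, name) {
    p <- file.path(outDir, name)
    written <<- c(written, p)
    fn(p)
  }
  tryCatch({
    emit(function(p) utils::write.table(
      pigmentTable(res$model), p, sep = "\t", quote = FALSE,
      row.names = FALSE), "pigments.tsv")
    emit(function(p) utils::write.table(
      layerTable(res$graph, res$shells), p, sep = "\t", quote = FALSE,
      row.names = FALSE), "layers.tsv")
    emit(function(p) jsonlite::write_json(
      igraph::as_data_frame(res$graph), p, auto_unbox = TRUE, digits = NA),
      "contact_graph.json")
    emit(function(p) utils::write.table(
      res$pairs, p, sep = "\t", quote = FALSE, row.names = FALSE),
      "pairs.tsv")
    emit(function(p) utils::write.table(
      res$steps, p, sep = "\t", quote = FALSE, row.names = FALSE),
      "steps.tsv")
    emit(function(p) utils::write.table(
      pathwayReport(res$pathways), p, sep = "\t", quote = FALSE,
      row.names = FALSE), "pathways.tsv")
    emit(function(p) jsonlite::write_json(list(
      census = res$census$counts,
      total_pigments = res$census$total_pigments,
      ratios = res$census$ratios[c("chl_a_to_c", "avg_chl_c_per_antenna",
                                   "chl_to_car")],
      shells = as.list(res$shells),
      pathway_codes = pathwayCodes(res$pathways),
      frame = list(normal = res$frame@normal,
                   midplane_offset = res$frame@midplaneOffset,
                   origin = res$frame@origin),
      provenance = res$provenance),
      p, auto_unbox = TRUE, digits = NA, dataframe = "columns"),
      "summary.json")
  }, error = function(e) {
    unlink(written)
    .stopf("stage 'write': %s", conditionMessage(e))
  })
  invisible(outDir)
}
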