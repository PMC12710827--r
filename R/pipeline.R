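#' Three-layer Sankey export
#'
#' Builds the machine-readable node/edge lists of a three-layer summary
#' linking signature metabolites, enriched metabolite sets and enriched
#' gene sets. Edges between the metabolite and metabolite-set layers
#' connect each signature metabolite to the enriched metabolite sets
#' containing it (unit weight; a set's incoming weight sum is its
#' shared-metabolite count). Edges between the metabolite-set and
#' gene-set layers are weighted by the number of mapped genes that are
#' supported by the set's metabolites and belong to the gene set.
#' Rendering is left to external tools; the structure serializes
#' directly to JSON.
#'
#' @param mapping a \linkS4class{MappingResult}.
#' @param msetCollection \linkS4class{GeneSetCollection} whose members
#'   are metabolite names (a metabolite-set GMT).
#' @param msetEnriched character vector of enriched metabolite-set
#'   names.
#' @param gsetCollection \linkS4class{GeneSetCollection} of gene sets.
#' @param gsetEnriched character vector of enriched gene-set names.
#' @return list with \code{nodes} (data.frame: \code{id}, \code{layer})
#'   and \code{edges} (data.frame: \code{from}, \code{to},
#'   \code{weight}).
#' @export
sankeyData <- function(mapping, msetCollection, msetEnriched,
                       gsetCollection, gsetEnriched) {
  stopifnot(is(mapping, "MappingResult"),
            is(msetCollection, "GeneSetCollection"),
            is(gsetCollection, "GeneSetCollection"))
  sigMets <- names(mapping@resolvedSignature@resolved)
  msetEnriched <- intersect(msetEnriched, names(msetCollection@sets))
  gsetEnriched <- intersect(gsetEnriched, names(gsetCollection@sets))

  mg <- mappedGenes(mapping)
  geneSupport <- strsplit(mg$metabolites, ";", fixed = TRUE)
  names(geneSupport) <- mg$geneId

  e1 <- do.call(rbind, lapply(msetEnriched, function(ms) {
    shared <- intersect(sigMets, msetCollection@sets[[ms]])
    if (length(shared) == 0L) return(NULL)
    data.frame(from = shared, to = ms, weight = 1, stringsAsFactors = FALSE)
  }))
  e2 <- do.call(rbind, lapply(msetEnriched, function(ms) {
    shared <- intersect(sigMets, msetCollection@sets[[ms]])
    genes <- names(geneSupport)[vapply(geneSupport, function(s)
      length(intersect(s, shared)) > 0L, NA)]
    rows <- lapply(gsetEnriched, function(gs) {
      ov <- length(intersect(genes, gsetCollection@sets[[gs]]))
      if (ov == 0L) return(NULL)
      data.frame(from = ms, to = gs, weight = ov, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  edges <- rbind(e1, e2)
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(id = sigMets, layer = "metabolite",
               stringsAsFactors = FALSE),
    data.frame(id = msetEnriched, layer = "metabolite_set",
               stringsAsFactors = FALSE),
    data.frame(id = gsetEnriched, layer = "gene_set",
               stringsAsFactors = FALSE))
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Run the full mapping and enrichment workflow
#'
#' Convenience driver: loads the model (unless given as an object),
#' reads and resolves the signatures, maps them to ranked gene lists,
#' runs weighted ORA against each GMT collection, and writes all
#' artifacts to \code{outDir}: one mapping TSV per signature, one
#' enrichment TSV per signature/collection pair, and a JSON run
#' manifest recording parameters, package version and input file
#' digests. A signature that resolves nothing yields an empty mapping
#' TSV and a warning; enrichment for it is skipped.
#'
#' @param model a \linkS4class{GEMModel} or a model file path.
#' @param signatures a \linkS4class{MetaboliteSignature}, a list of
#'   them, or a character vector of signature file paths.
#' @param gmtFiles character vector of GMT file paths (may be empty to
#'   run mapping only).
#' @param outDir output directory, created if needed.
#' @param rule,params,collapseCompartments,universe passed to
#'   \code{\link{signatureToGenes}}.
#' @param background,useWeights,alpha passed to \code{\link{runORA}}.
#' @param modelFormat passed to \code{\link{loadGEM}} when \code{model}
#'   is a path.
#' @return invisibly, a list with the mapping results, the ORA reports
#'   and the manifest.
#' @export
runPipeline <- function(model, signatures, gmtFiles = character(0),
                        outDir = ".",
                        rule = c("non-directional", "directional"),
                        params = weightParams(),
                        collapseCompartments = TRUE,
                        universe = c("collapsed", "species"),
                        background = NULL, useWeights = TRUE, alpha = 0.05,
                        modelFormat = "auto") {
  rule <- match.arg(rule)
  universe <- match.arg(universe)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  modelPath <- NULL
  if (is.character(model)) {
    modelPath <- model
    model <- loadGEM(model, format = modelFormat)
  }
  sigPaths <- NULL
  if (is.character(signatures)) {
    sigPaths <- signatures
    signatures <- unlist(lapply(signatures, function(p) {
      s <- readSignature(p)
      if (is(s, "MetaboliteSignature")) list(s) else s
    }))
  }
  if (is(signatures, "MetaboliteSignature")) signatures <- list(signatures)

  mappings <- signatureToGenes(signatures, model, rule = rule,
                               params = params,
                               collapseCompartments = collapseCompartments,
                               universe = universe)
  collections <- lapply(gmtFiles, readGMT)

  reports <- list()
  for (lab in names(mappings)) {
    mres <- mappings[[lab]]
    writeMappingTSV(mres, file.path(outDir, sprintf("mapping_%s.tsv", lab)))
    if (nrow(mappedGenes(mres)) == 0L) {
      if (length(collections))
        warning(sprintf("signature '%s': empty mapping, enrichment skipped",
                        lab), call. = FALSE)
      next
    }
    for (coll in collections) {
      rep <- runORA(mres, coll, background = background,
                    useWeights = useWeights, alpha = alpha)
      writeORATSV(rep, file.path(outDir,
        sprintf("enrichment_%s_%s.tsv", lab, coll@name)))
      reports[[lab]][[coll@name]] <- rep
    }
  }

  digest <- function(paths) {
    if (is.null(paths)) return(NULL)
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    package = "gemsig",
    version = as.character(utils::packageVersion("gemsig")),
    parameters = list(rule = rule, universe = universe,
                      collapseCompartments = collapseCompartments,
                      useWeights = useWeights, alpha = alpha,
                      weight_a = params$a, weight_b = params$b),
    model = list(path = modelPath, stats = as.list(modelStats(model)),
                 digest = digest(modelPath)),
    signatures = lapply(signatures, function(s)
      list(label = s@label, n = length(s@names), direction = s@direction)),
    signatureDigests = digest(sigPaths),
    gmtDigests = digest(if (length(gmtFiles)) gmtFiles else NULL)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(mappings = mappings, reports = reports,
                 manifest = manifest))
}
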