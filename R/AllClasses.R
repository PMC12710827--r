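#' GEMModel: a genome-scale metabolic model as a knowledge base
#'
#' Holds the gene-reaction-metabolite associations of a genome-scale
#' metabolic model (GEM), used purely as a curated knowledge base: no
#' flux simulation is performed. Reactions carry signed stoichiometry
#' (negative coefficients = consumed, positive = produced), a
#' reversibility flag, and a flattened set of associated gene ids (the
#' Boolean gene-protein-reaction logic is never evaluated; every gene
#' referenced by a reaction's GPR annotation is kept). Each reaction is
#' classified as \code{exchange}, \code{transport}, \code{enzymatic} or
#' \code{uncatalyzed} at load time; exchange reactions and reactions
#' with no genes are never eligible for metabolite-to-gene mapping.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{boundary}.
#' @slot reactions named list of reaction records; each record is a list
#'   with elements \code{id}, \code{stoich} (named numeric, metabolite
#'   id to signed coefficient), \code{reversible}, \code{genes}
#'   (character), \code{subsystem}, \code{kind}.
#' @slot genes data.frame with columns \code{id}, \code{symbol}.
#' @slot metIndex named list: metabolite id -> reaction ids it occurs in.
#' @slot geneIndex named list: gene id -> reaction ids it catalyzes.
#' @slot nameIndex named list: normalized metabolite name -> metabolite
#'   ids (all compartment instances of the species).
#' @slot compartments character vector of declared compartment codes.
#'
#' @seealso \code{\link{loadGEM}}, \code{\link{modelStats}},
#'   \code{\link{classifyReaction}}
#' @export
setClass("GEMModel",
  representation(
    metabolites  = "data.frame",
    reactions    = "list",
    genes        = "data.frame",
    metIndex     = "list",
    geneIndex    = "list",
    nameIndex    = "list",
    compartments = "character"
  )
)

setValidity("GEMModel", function(object) {
  msgs <- character()
  met <- object@metabolites
  gn <- object@genes
  if (nrow(met) > 0 && anyDuplicated(met$id))
    msgs <- c(msgs, "duplicated metabolite ids")
  if (nrow(gn) > 0 && anyDuplicated(gn$id))
    msgs <- c(msgs, "duplicated gene ids")
  if (length(object@reactions) > 0 &&
      anyDuplicated(vapply(object@reactions, `[[`, "", "id")))
    msgs <- c(msgs, "duplicated reaction ids")
  for (rxn in object@reactions) {
    if (length(rxn$stoich) == 0L)
      msgs <- c(msgs, sprintf("reaction '%s' has empty stoichiometry", rxn$id))
    if (any(rxn$stoich == 0))
      msgs <- c(msgs, sprintf("reaction '%s' has zero coefficients", rxn$id))
    bad <- setdiff(names(rxn$stoich), met$id)
    if (length(bad))
      msgs <- c(msgs, sprintf("reaction '%s' references undeclared metabolite(s): %s",
                              rxn$id, paste(bad, collapse = ", ")))
    badg <- setdiff(rxn$genes, gn$id)
    if (length(badg))
      msgs <- c(msgs, sprintf("reaction '%s' references undeclared gene(s): %s",
                              rxn$id, paste(badg, collapse = ", ")))
  }
  # indexes must be exact inverses of the reaction records
  for (m in names(object@metIndex)) {
    for (r in object@metIndex[[m]]) {
      if (!m %in% names(object@reactions[[r]]$stoich))
        msgs <- c(msgs, sprintf("metIndex: '%s' -> '%s' not in stoichiometry", m, r))
    }
  }
  for (g in names(object@geneIndex)) {
    for (r in object@geneIndex[[g]]) {
      if (!g %in% object@reactions[[r]]$genes)
        msgs <- c(msgs, sprintf("geneIndex: '%s' -> '%s' not in gene set", g, r))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MetaboliteSignature: a named list of metabolite names
#'
#' A metabolite signature is a list of metabolite names (RefMet-style
#' nomenclature for real models) produced by an upstream differential
#' analysis, optionally carrying a direction of change. Duplicated
#' names are removed with a warning at construction.
#'
#' @slot label free-text signature label.
#' @slot names character vector of metabolite names, duplicates removed.
#' @slot direction one of \code{"up"}, \code{"down"}, \code{"none"}.
#' @export
setClass("MetaboliteSignature",
  representation(label = "character", names = "character",
                 direction = "character")
)

setValidity("MetaboliteSignature", function(object) {
  if (length(object@names) == 0L) return("signature has no metabolite names")
  if (anyDuplicated(object@names)) return("signature names must be unique")
  if (!object@direction %in% c("up", "down", "none"))
    return("direction must be 'up', 'down' or 'none'")
  TRUE
})

#' ResolvedSignature: a signature matched against a model
#'
#' Records, for each input name, the model metabolite ids it resolved
#' to (all compartment instances when compartment collapsing is on),
#' plus the list of names that matched nothing. \code{S} is the number
#' of resolved unique signature metabolites and is the signature size
#' used by the specificity score.
#'
#' @slot signature the input \linkS4class{MetaboliteSignature}.
#' @slot resolved named list: input name -> character vector of model
#'   metabolite ids.
#' @slot unresolved character vector of unmatched input names.
#' @slot S integer, \code{length(resolved)}.
#' @slot collapsed logical, whether compartment instances were collapsed.
#' @export
setClass("ResolvedSignature",
  representation(signature = "MetaboliteSignature", resolved = "list",
                 unresolved = "character", S = "integer",
                 collapsed = "logical")
)

setValidity("ResolvedSignature", function(object) {
  inn <- object@signature@names
  if (!setequal(c(names(object@resolved), object@unresolved), inn))
    return("resolved + unresolved must partition the input names")
  if (object@S != length(object@resolved))
    return("S must equal the number of resolved names")
  TRUE
})

#' MappingResult: genes mapped from a metabolite signature
#'
#' The outcome of mapping a resolved signature to enzyme-coding genes
#' under one mapping rule, with per-gene specificity scores and sigmoid
#' weights. Genes are ranked by ascending specificity score (smaller =
#' more specific), breaking ties by ascending number of catalyzed
#' reactions and then lexicographic gene id.
#'
#' @slot rule \code{"non-directional"} or \code{"directional"}.
#' @slot mappedGenes data.frame with one row per mapped gene: columns
#'   \code{geneId}, \code{symbol}, \code{nReactions}, \code{metabolites}
#'   (semicolon-joined signature metabolites supporting the gene),
#'   \code{Ai}, \code{ai}, \code{si}, \code{wi}, \code{rank}.
#' @slot resolvedSignature the \linkS4class{ResolvedSignature} used.
#' @slot params list of the mapping/weighting parameters (\code{M},
#'   weight parameters, universe convention, model gene universe).
#' @export
setClass("MappingResult",
  representation(rule = "character", mappedGenes = "data.frame",
                 resolvedSignature = "ResolvedSignature", params = "list")
)

setValidity("MappingResult", function(object) {
  if (!object@rule %in% c("non-directional", "directional"))
    return("rule must be 'non-directional' or 'directional'")
  mg <- object@mappedGenes
  if (nrow(mg)) {
    if (any(mg$ai < 1)) return("every mapped gene must have ai >= 1")
    if (any(mg$si <= 0 | mg$si > 1)) return("si must lie in (0, 1]")
    if (is.unsorted(mg$rank)) return("rows must be ordered by rank")
  }
  TRUE
})

#' GeneSetCollection: named gene sets read from a GMT file
#'
#' @slot name collection label (by default the GMT file stem).
#' @slot sets named list of character vectors of member gene ids
#'   (deduplicated within each set).
#' @slot descriptions named character vector, one per set.
#' @seealso \code{\link{readGMT}}
#' @export
setClass("GeneSetCollection",
  representation(name = "character", sets = "list",
                 descriptions = "character")
)

setValidity("GeneSetCollection", function(object) {
  if (anyDuplicated(names(object@sets))) return("set names must be unique")
  if (length(object@sets) &&
      any(vapply(object@sets, length, 0L) == 0L))
    return("sets must have at least one member")
  TRUE
})

#' ORAReport: one collection's over-representation results
#'
#' Rows are sorted by ascending p-value (stable sort). \code{significant}
#' returns the rows with BH-adjusted p below the report's alpha.
#'
#' @slot collection collection label.
#' @slot rows data.frame with columns \code{setName}, \code{N}, \code{K},
#'   \code{nRaw}, \code{kRaw}, \code{nW}, \code{kW}, \code{p},
#'   \code{pAdj}, \code{hits}.
#' @slot params list: \code{useWeights}, \code{background} size and
#'   provenance, \code{alpha}.
#' @export
setClass("ORAReport",
  representation(collection = "character", rows = "data.frame",
                 params = "list")
)

setValidity("ORAReport", function(object) {
  r <- object@rows
  if (nrow(r)) {
    if (any(r$p <= 0 | r$p > 1)) return("p must lie in (0, 1]")
    if (any(r$pAdj + 1e-12 < r$p)) return("pAdj must be >= p")
    if (any(r$kW > pmin(r$nW, r$K))) return("kW must be <= min(nW, K)")
    if (is.unsorted(r$p)) return("rows must be sorted by p")
  }
  TRUE
})
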