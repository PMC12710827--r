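#' Create a metabolite signature
#'
#' @param names character vector of metabolite names (RefMet-style for
#'   real models). Duplicates are dropped with a warning.
#' @param label free-text label for the signature.
#' @param direction optional direction of change, \code{"up"},
#'   \code{"down"} or \code{"none"}.
#' @return a \linkS4class{MetaboliteSignature}.
#' @export
MetaboliteSignature <- function(names, label = "signature",
                                direction = c("none", "up", "down")) {
  direction <- match.arg(direction)
  names <- as.character(names)
  if (length(names) == 0L)
    stop("a signature needs at least one metabolite name", call. = FALSE)
  if (anyDuplicated(names)) {
    warning(sprintf("signature '%s': %d duplicated name(s) removed",
                    label, sum(duplicated(names))), call. = FALSE)
    names <- unique(names)
  }
  new("MetaboliteSignature", label = label, names = names,
      direction = direction)
}

#' Read a metabolite signature from a text file
#'
#' Accepts either a plain list (one metabolite name per line) or a
#' two-column tab-separated file \code{name<TAB>direction} with
#' direction \code{up} or \code{down}, in which case one signature per
#' direction is returned.
#'
#' @param path input file.
#' @param label signature label; defaults to the file stem.
#' @return a \linkS4class{MetaboliteSignature}, or a named list of them
#'   (\code{up}, \code{down}) for two-column input.
#' @export
readSignature <- function(path, label = NULL) {
  if (!file.exists(path))
    stop(sprintf("signature file '%s' does not exist", path), call. = FALSE)
  label <- label %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop(sprintf("signature file '%s' is empty", path), call. = FALSE)
  if (any(grepl("\t", lines, fixed = TRUE))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(parts, `[[`, "", 1L)
    dir <- tolower(vapply(parts, function(p) p[2] %||% "none", ""))
    bad <- !dir %in% c("up", "down")
    if (any(bad))
      stop(sprintf("signature file '%s': direction must be 'up' or 'down' (line %d)",
                   path, which(bad)[1]), call. = FALSE)
    byDir <- split(nm, dir)
    return(Map(function(x, d) MetaboliteSignature(x,
                 label = paste(label, d, sep = "_"), direction = d),
               byDir, names(byDir)))
  }
  MetaboliteSignature(lines, label = label)
}

#' Resolve a metabolite signature against a model
#'
#' Matches each input name (after normalization: trim, case-fold,
#' collapse internal whitespace) exactly against the model's metabolite
#' names and ids. With compartment collapsing on (the default,
#' appropriate for compartment-agnostic measured metabolomes), all
#' compartment instances of a matched species resolve to the same
#' signature metabolite. Unresolved names are reported, never silently
#' dropped.
#'
#' @param sig a \linkS4class{MetaboliteSignature}.
#' @param model a \linkS4class{GEMModel}.
#' @param collapseCompartments logical, default \code{TRUE}.
#' @param synonyms optional named character vector (or 2-column
#'   data.frame) mapping input names to model names; applied after
#'   normalization, before matching.
#' @return a \linkS4class{ResolvedSignature}.
#' @export
resolveSignature <- function(sig, model, collapseCompartments = TRUE,
                             synonyms = NULL) {
  stopifnot(is(sig, "MetaboliteSignature"), is(model, "GEMModel"))
  stopifnot_scalar_flag(collapseCompartments, "collapseCompartments")
  if (is.data.frame(synonyms))
    synonyms <- setNames(as.character(synonyms[[2]]),
                         as.character(synonyms[[1]]))
  norm <- normalizeMetName(sig@names)
  if (!is.null(synonyms)) {
    syn <- setNames(normalizeMetName(synonyms), normalizeMetName(names(synonyms)))
    hit <- norm %in% names(syn)
    norm[hit] <- unname(syn[norm[hit]])
  }
  idByNorm <- model@nameIndex
  metIds <- model@metabolites$id
  resolved <- list()
  unresolved <- character(0)
  for (i in seq_along(sig@names)) {
    ids <- idByNorm[[norm[i]]]
    if (is.null(ids) && norm[i] %in% normalizeMetName(metIds))
      ids <- metIds[normalizeMetName(metIds) == norm[i]]
    if (is.null(ids) || length(ids) == 0L) {
      unresolved <- c(unresolved, sig@names[i])
    } else {
      resolved[[sig@names[i]]] <- ids
    }
  }
  if (length(unresolved))
    warning(sprintf("signature '%s': %d of %d name(s) not found in model",
                    sig@label, length(unresolved), length(sig@names)),
            call. = FALSE)
  new("ResolvedSignature", signature = sig, resolved = resolved,
      unresolved = unresolved, S = length(resolved),
      collapsed = collapseCompartments)
}

# token under which a metabolite id is counted in the specificity
# universe: its normalized name when collapsing, else the id itself
metTokens <- function(model, ids, collapsed) {
  if (collapsed) {
    normalizeMetName(model@metabolites$name[match(ids, model@metabolites$id)])
  } else ids
}

# rule-filtered metabolite ids of one reaction record: under the
# directional rule only produced metabolites count, except that every
# metabolite of a reversible reaction is treated as both reactant and
# product
ruleMets <- function(rxn, rule) {
  if (rule == "non-directional" || rxn$reversible) names(rxn$stoich)
  else names(rxn$stoich)[rxn$stoich > 0]
}

#' Map a resolved signature to enzyme-coding genes
#'
#' For each resolved signature metabolite, collects the
#' mapping-eligible reactions it participates in (reactions with at
#' least one gene and kind other than exchange), applies the mapping
#' rule, and unions the genes of the retained reactions. Under the
#' non-directional rule any participation counts; under the directional
#' rule only reactions producing the metabolite (positive coefficient),
#' with every metabolite of a reversible reaction treated as both
#' reactant and product. Currency metabolites (ATP, NADH, ...) receive
#' no special handling. Each mapped gene is then scored: \code{Ai} is
#' the number of distinct universe metabolites associated with the gene
#' under the same rule, \code{ai} the overlap with the signature,
#' \code{si} the upper-tail hypergeometric specificity score and
#' \code{wi} its sigmoid weight. Genes are ranked by ascending
#' \code{si}, then ascending number of catalyzed reactions, then gene
#' id.
#'
#' @param rsig a \linkS4class{ResolvedSignature} with \code{S >= 1}
#'   (an \code{S = 0} input yields an empty result with a warning).
#' @param model the \linkS4class{GEMModel} the signature was resolved
#'   against.
#' @param rule \code{"non-directional"} (default) or
#'   \code{"directional"}.
#' @param params sigmoid weight parameters, see
#'   \code{\link{weightParams}}.
#' @param universe \code{"collapsed"} (default; unique
#'   compartment-collapsed metabolites define M) or \code{"species"}
#'   (raw compartmentalized species).
#' @return a \linkS4class{MappingResult}.
#' @export
mapToGenes <- function(rsig, model, rule = c("non-directional", "directional"),
                       params = weightParams(),
                       universe = c("collapsed", "species")) {
  stopifnot(is(rsig, "ResolvedSignature"), is(model, "GEMModel"))
  rule <- match.arg(rule)
  universe <- match.arg(universe)
  collapsed <- universe == "collapsed"
  M <- universeSize(model, universe)

  emptyResult <- function() {
    mg <- data.frame(geneId = character(0), symbol = character(0),
                     nReactions = integer(0), metabolites = character(0),
                     Ai = integer(0), ai = integer(0), si = numeric(0),
                     wi = numeric(0), rank = integer(0),
                     stringsAsFactors = FALSE)
    new("MappingResult", rule = rule, mappedGenes = mg,
        resolvedSignature = rsig,
        params = list(M = M, S = 0L, universe = universe, weights = params,
                      modelGenes = gemGeneIds(model)))
  }
  if (rsig@S == 0L) {
    warning(sprintf("signature '%s': no metabolites resolved; empty mapping",
                    rsig@signature@label), call. = FALSE)
    return(emptyResult())
  }

  eligible <- mappingEligible(model)
  sigIds <- unique(unlist(rsig@resolved, use.names = FALSE))
  sigTok <- unique(metTokens(model, sigIds, collapsed))
  S <- length(sigTok)

  # gene -> supporting signature input names
  support <- list()
  for (nm in names(rsig@resolved)) {
    ids <- rsig@resolved[[nm]]
    rxns <- unique(unlist(model@metIndex[ids], use.names = FALSE))
    rxns <- intersect(rxns, eligible)
    for (r in rxns) {
      rxn <- model@reactions[[r]]
      if (rule == "directional" && !rxn$reversible &&
          !any(rxn$stoich[intersect(ids, names(rxn$stoich))] > 0))
        next
      for (g in rxn$genes)
        support[[g]] <- unique(c(support[[g]], nm))
    }
  }
  genes <- sort(names(support))
  if (length(genes) == 0L) return(emptyResult())

  rows <- lapply(genes, function(g) {
    rxnIds <- model@geneIndex[[g]]
    elig <- intersect(rxnIds, eligible)
    assoc <- unique(unlist(lapply(model@reactions[elig], ruleMets,
                                  rule = rule), use.names = FALSE))
    tok <- unique(metTokens(model, assoc, collapsed))
    Ai <- length(tok)
    ai <- length(intersect(tok, sigTok))
    data.frame(geneId = g,
               symbol = model@genes$symbol[match(g, model@genes$id)],
               nReactions = length(rxnIds),
               metabolites = paste(sort(support[[g]]), collapse = ";"),
               Ai = Ai, ai = ai, stringsAsFactors = FALSE)
  })
  mg <- do.call(rbind, rows)
  mg$si <- specificityScore(M, S, mg$Ai, mg$ai)
  mg$wi <- sigmoidWeight(mg$si, params)
  ord <- order(mg$si, mg$nReactions, mg$geneId, method = "radix")
  mg <- mg[ord, , drop = FALSE]
  mg$rank <- seq_len(nrow(mg))
  rownames(mg) <- NULL

  new("MappingResult", rule = rule, mappedGenes = mg,
      resolvedSignature = rsig,
      params = list(M = M, S = S, universe = universe, weights = params,
                    modelGenes = gemGeneIds(model)))
}

#' Map one or more signatures to ranked gene lists
#'
#' Batch front end running resolve -> map -> score -> rank for each
#' signature independently; a signature that fails to resolve yields an
#' empty flagged result rather than aborting the batch.
#'
#' @param sigs a \linkS4class{MetaboliteSignature} or a list of them.
#' @param model a \linkS4class{GEMModel}.
#' @param rule mapping rule, see \code{\link{mapToGenes}}.
#' @param params sigmoid weight parameters.
#' @param collapseCompartments passed to \code{\link{resolveSignature}}.
#' @param synonyms passed to \code{\link{resolveSignature}}.
#' @param universe passed to \code{\link{mapToGenes}}.
#' @return a named list of \linkS4class{MappingResult}, one per
#'   signature.
#' @export
signatureToGenes <- function(sigs, model,
                             rule = c("non-directional", "directional"),
                             params = weightParams(),
                             collapseCompartments = TRUE, synonyms = NULL,
                             universe = c("collapsed", "species")) {
  rule <- match.arg(rule)
  universe <- match.arg(universe)
  if (is(sigs, "MetaboliteSignature")) sigs <- list(sigs)
  if (length(sigs) == 0L)
    stop("at least one signature is required", call. = FALSE)
  out <- lapply(sigs, function(s) {
    rsig <- resolveSignature(s, model,
                             collapseCompartments = collapseCompartments,
                             synonyms = synonyms)
    mapToGenes(rsig, model, rule = rule, params = params,
               universe = universe)
  })
  names(out) <- vapply(sigs, function(s) s@label, "")
  out
}

#' Extract the mapped gene table
#'
#' @param result a \linkS4class{MappingResult}.
#' @return the ranked mapped-gene data.frame.
#' @export
mappedGenes <- function(result) {
  stopifnot(is(result, "MappingResult"))
  result@mappedGenes
}

#' Write a mapping result as TSV
#'
#' Columns: \code{gene_id}, \code{symbol}, \code{n_reactions},
#' \code{metabolites}, \code{A_i}, \code{a_i}, \code{s_i}, \code{w_i},
#' \code{rank}.
#'
#' @param result a \linkS4class{MappingResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMappingTSV <- function(result, path) {
  mg <- mappedGenes(result)
  out <- data.frame(gene_id = mg$geneId, symbol = mg$symbol,
                    n_reactions = mg$nReactions,
                    metabolites = mg$metabolites,
                    A_i = mg$Ai, a_i = mg$ai,
                    s_i = formatC(mg$si, format = "e", digits = 4),
                    w_i = formatC(mg$wi, format = "e", digits = 4),
                    rank = mg$rank, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
setMethod("show", "MappingResult", function(object) {
  mg <- object@mappedGenes
  cat(sprintf("MappingResult (%s rule): %d gene(s) from signature '%s' (S=%d)\n",
              object@rule, nrow(mg), object@resolvedSignature@signature@label,
              object@resolvedSignature@S))
  if (nrow(mg)) {
    cat("  top genes by specificity:\n")
    print(head(mg[, c("geneId", "Ai", "ai", "si", "wi", "rank")], 5),
          row.names = FALSE)
  }
})
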