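#' Construct a GEMModel from component tables
#'
#' Builds the indexed model from a metabolite table, a list of reaction
#' records and a gene table, classifying every reaction. Used by
#' \code{\link{loadGEM}} and \code{\link{generateGEM}}; call it directly
#' to assemble a model programmatically.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{boundary} (missing columns are filled
#'   with defaults: \code{name = id}, \code{compartment = "c"},
#'   \code{boundary = FALSE}).
#' @param reactions list of reaction records: each a list with
#'   \code{id}, \code{stoich} (named numeric), \code{reversible},
#'   \code{genes} (character, possibly empty), optional
#'   \code{subsystem}.
#' @param genes data.frame with columns \code{id} and optional
#'   \code{symbol}, or a character vector of gene ids.
#' @return a validated \linkS4class{GEMModel}.
#' @export
GEMModel <- function(metabolites, reactions, genes) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- rep("c", nrow(metabolites))
  if (is.null(metabolites$boundary))
    metabolites$boundary <- rep(FALSE, nrow(metabolites))
  metabolites$id <- as.character(metabolites$id)
  metabolites$name <- as.character(metabolites$name)

  if (is.character(genes)) genes <- data.frame(id = genes,
                                               stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$symbol)) genes$symbol <- genes$id
  if (is.null(genes$id)) genes$id <- character(0)

  reactions <- lapply(reactions, function(r) {
    r$genes <- as.character(r$genes %||% character(0))
    r$subsystem <- as.character(r$subsystem %||% NA_character_)
    r$reversible <- isTRUE(r$reversible)
    r$stoich <- unlist(r$stoich)
    storage.mode(r$stoich) <- "double"
    r
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  compartments <- unique(metabolites$compartment)
  compartments <- compartments[!is.na(compartments) & nzchar(compartments)]

  # integrity before indexing so errors name the offending reaction
  for (r in reactions) {
    bad <- setdiff(names(r$stoich), metabolites$id)
    if (length(bad))
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r$id, paste(bad, collapse = ", ")), call. = FALSE)
    badg <- setdiff(r$genes, genes$id)
    if (length(badg))
      stop(sprintf("reaction '%s' references undeclared gene(s): %s",
                   r$id, paste(badg, collapse = ", ")), call. = FALSE)
  }

  metIndex <- lapply(setNames(metabolites$id, metabolites$id), function(m) {
    names(reactions)[vapply(reactions, function(r) m %in% names(r$stoich), NA)]
  })
  geneIndex <- lapply(setNames(genes$id, genes$id), function(g) {
    names(reactions)[vapply(reactions, function(r) g %in% r$genes, NA)]
  })
  nm <- normalizeMetName(metabolites$name)
  nameIndex <- split(metabolites$id, nm)

  model <- new("GEMModel", metabolites = metabolites, reactions = reactions,
               genes = genes, metIndex = metIndex, geneIndex = geneIndex,
               nameIndex = nameIndex, compartments = compartments)
  model@reactions <- lapply(model@reactions, function(r) {
    r$kind <- classifyReaction(r, model)
    r
  })
  validObject(model)
  model
}

#' Load a genome-scale metabolic model
#'
#' Reads a GEM from SBML Level 3 with the fbc extension, or from the
#' package's toy JSON/TSV dialect, into a fully indexed
#' \linkS4class{GEMModel}. Boolean gene-protein-reaction expressions are
#' flattened: every gene referenced by a reaction's association is kept
#' and the AND/OR structure is discarded, because the model is used
#' only as a knowledge base of gene-reaction-metabolite links.
#' Reversibility comes from the reaction's \code{reversible} attribute
#' when present, otherwise from flux bounds (reversible iff lower bound
#' < 0 and upper bound > 0).
#'
#' The toy JSON dialect is a single object with arrays:
#' \itemize{
#'   \item \code{metabolites}: \code{id}, \code{name}, \code{compartment},
#'     \code{boundary}
#'   \item \code{reactions}: \code{id}, \code{stoich} (object mapping
#'     metabolite id to signed coefficient; negative = consumed,
#'     positive = produced), \code{reversible}, \code{genes}, optional
#'     \code{subsystem}
#'   \item \code{genes}: \code{id}, \code{symbol}
#' }
#' The TSV twin has one reaction per row with columns \code{id},
#' \code{stoich} (\code{"m1:-1;m2:1"}), \code{reversible}, \code{genes}
#' (semicolon-joined, may be empty) and optional \code{subsystem};
#' metabolites and genes are inferred from the reaction rows, with the
#' compartment parsed from a trailing \code{[x]} or \code{_x} id suffix
#' when present.
#'
#' @param source path to the model file.
#' @param format one of \code{"sbml-fbc"}, \code{"toy-json"},
#'   \code{"toy-tsv"}; by default guessed from the file extension
#'   (\code{.xml}/\code{.sbml}, \code{.json}, \code{.tsv}).
#' @return a \linkS4class{GEMModel}.
#' @examples
#' path <- tempfile(fileext = ".json")
#' m <- generateGEM(nMetabolites = 8, nReactions = 6, nGenes = 4, seed = 1)
#' writeToyJSON(m, path)
#' modelStats(loadGEM(path))
#' @export
loadGEM <- function(source, format = c("auto", "sbml-fbc", "toy-json",
                                       "toy-tsv")) {
  format <- match.arg(format)
  if (!file.exists(source))
    stop(sprintf("model file '%s' does not exist", source), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- switch(ext,
      xml = , sbml = "sbml-fbc",
      json = "toy-json",
      tsv = , txt = "toy-tsv",
      stop(sprintf("cannot guess model format from extension '.%s'", ext),
           call. = FALSE))
  }
  switch(format,
    "toy-json" = readToyJSON(source),
    "toy-tsv"  = readToyTSV(source),
    "sbml-fbc" = readSBML(source))
}

readToyJSON <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop(sprintf(
                  "failed to parse toy-json '%s': %s", path,
                  conditionMessage(e)), call. = FALSE))
  for (f in c("metabolites", "reactions", "genes"))
    if (is.null(x[[f]]))
      stop(sprintf("toy-json '%s' lacks the '%s' array", path, f),
           call. = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id, compartment = m$compartment %||% "c",
    boundary = isTRUE(m$boundary), stringsAsFactors = FALSE)))
  genes <- do.call(rbind, lapply(x$genes, function(g) data.frame(
    id = g$id, symbol = g$symbol %||% g$id, stringsAsFactors = FALSE)))
  rxns <- lapply(x$reactions, function(r) list(
    id = r$id, stoich = unlist(r$stoich), reversible = isTRUE(r$reversible),
    genes = unlist(r$genes) %||% character(0),
    subsystem = r$subsystem %||% NA_character_))
  GEMModel(mets %||% data.frame(id = character(0)), rxns,
           genes %||% data.frame(id = character(0)))
}

readToyTSV <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "stoich", "reversible", "genes")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("toy-tsv '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(tab$stoich[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(kv, length, 0L) != 2L
    if (any(bad))
      stop(sprintf("toy-tsv '%s' row %d: malformed stoich entry '%s'",
                   path, i, parts[bad][1]), call. = FALSE)
    stoich <- setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                       vapply(kv, `[[`, "", 1L))
    g <- tab$genes[i]
    genes <- if (is.na(g) || !nzchar(g)) character(0)
             else strsplit(g, ";", fixed = TRUE)[[1]]
    list(id = tab$id[i], stoich = stoich,
         reversible = as.logical(tab$reversible[i]), genes = genes,
         subsystem = if ("subsystem" %in% names(tab)) tab$subsystem[i]
                     else NA_character_)
  })
  metIds <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  compGuess <- function(id) {
    m <- regmatches(id, regexec("\\[([A-Za-z0-9]+)\\]$|_([A-Za-z])$", id))[[1]]
    if (length(m)) { cc <- m[m != ""][-1]; if (length(cc)) return(cc[1]) }
    "c"
  }
  mets <- data.frame(id = metIds, name = metIds,
                     compartment = vapply(metIds, compGuess, ""),
                     boundary = FALSE, stringsAsFactors = FALSE)
  geneIds <- unique(unlist(lapply(rxns, `[[`, "genes")))
  GEMModel(mets, rxns, data.frame(id = geneIds %||% character(0),
                                  stringsAsFactors = FALSE))
}

# namespace-agnostic child lookup / attribute access for SBML documents
xmlFindAll <- function(node, localname) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", localname))
}
xmlAttrAny <- function(node, localname) {
  at <- xml2::xml_attrs(node)
  hit <- names(at) == localname |
    endsWith(names(at), paste0(":", localname))
  if (any(hit)) at[[which(hit)[1]]] else NA_character_
}

readSBML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("failed to parse SBML '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  modelNode <- xmlFindAll(doc, "model")
  if (length(modelNode) == 0L)
    stop(sprintf("SBML '%s': no <model> element", path), call. = FALSE)

  # global flux-bound parameters, for reversibility fallback
  params <- xmlFindAll(doc, "parameter")
  paramVal <- setNames(as.numeric(vapply(params, xmlAttrAny, "", "value")),
                       vapply(params, xmlAttrAny, "", "id"))

  spNodes <- xmlFindAll(doc, "species")
  mets <- do.call(rbind, lapply(spNodes, function(s) data.frame(
    id = xmlAttrAny(s, "id"),
    name = { n <- xmlAttrAny(s, "name"); if (is.na(n)) xmlAttrAny(s, "id") else n },
    compartment = xmlAttrAny(s, "compartment"),
    boundary = identical(xmlAttrAny(s, "boundaryCondition"), "true"),
    stringsAsFactors = FALSE)))

  gpNodes <- xmlFindAll(doc, "geneProduct")
  genes <- if (length(gpNodes)) do.call(rbind, lapply(gpNodes, function(g) {
    id <- xmlAttrAny(g, "id")
    lab <- xmlAttrAny(g, "label")
    data.frame(id = id, symbol = if (is.na(lab)) id else lab,
               stringsAsFactors = FALSE)
  })) else data.frame(id = character(0), symbol = character(0),
                      stringsAsFactors = FALSE)

  rxNodes <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- lapply(rxNodes, function(r) {
    id <- xmlAttrAny(r, "id")
    reactants <- xml2::xml_find_all(r,
      "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    products <- xml2::xml_find_all(r,
      "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    coef <- function(nodes, sign) {
      if (length(nodes) == 0L) return(numeric(0))
      st <- as.numeric(vapply(nodes, function(n) {
        v <- xmlAttrAny(n, "stoichiometry"); if (is.na(v)) "1" else v
      }, ""))
      setNames(sign * st, vapply(nodes, xmlAttrAny, "", "species"))
    }
    stoich <- c(coef(reactants, -1), coef(products, +1))
    # a species on both sides keeps the net; drop exact cancellations
    if (anyDuplicated(names(stoich))) {
      stoich <- tapply(stoich, names(stoich), sum)
      stoich <- stoich[stoich != 0]
    }
    revAttr <- xmlAttrAny(r, "reversible")
    reversible <- if (!is.na(revAttr)) identical(revAttr, "true") else {
      lb <- paramVal[xmlAttrAny(r, "lowerFluxBound")]
      ub <- paramVal[xmlAttrAny(r, "upperFluxBound")]
      isTRUE(unname(lb) < 0) && isTRUE(unname(ub) > 0)
    }
    grefs <- xml2::xml_find_all(r, ".//*[local-name()='geneProductRef']")
    gids <- unique(vapply(grefs, xmlAttrAny, "", "geneProduct"))
    list(id = id, stoich = stoich, reversible = reversible,
         genes = gids[!is.na(gids)], subsystem = NA_character_)
  })
  GEMModel(mets %||% data.frame(id = character(0)), rxns, genes)
}

#' Write a model in the toy JSON dialect
#'
#' @param model a \linkS4class{GEMModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeToyJSON <- function(model, path) {
  stopifnot(is(model, "GEMModel"))
  out <- list(
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i) {
      m <- model@metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           boundary = m$boundary)
    }),
    reactions = lapply(unname(model@reactions), function(r) {
      list(id = r$id, stoich = as.list(r$stoich),
           reversible = r$reversible, genes = as.list(r$genes),
           subsystem = if (is.na(r$subsystem)) NULL else r$subsystem)
    }),
    genes = lapply(seq_len(nrow(model@genes)), function(i) {
      g <- model@genes[i, ]
      list(id = g$id, symbol = g$symbol)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Classify a reaction as exchange, transport, enzymatic or uncatalyzed
#'
#' A reaction is \code{exchange} when it involves a boundary-condition
#' species or is single-sided (all coefficients of one sign);
#' \code{transport} when the multiset of compartment-stripped metabolite
#' names is identical on the consumed and produced sides but the
#' compartments differ; \code{uncatalyzed} when it has no genes and is
#' neither of the above; \code{enzymatic} otherwise. Exchange reactions
#' and reactions without genes are excluded from metabolite-to-gene
#' mapping; gene-carrying transporters remain eligible.
#'
#' @param rxn a reaction record (element of \code{gemReactions(model)})
#'   or a reaction id.
#' @param model the owning \linkS4class{GEMModel}.
#' @return one of \code{"exchange"}, \code{"transport"},
#'   \code{"enzymatic"}, \code{"uncatalyzed"}.
#' @export
classifyReaction <- function(rxn, model) {
  if (is.character(rxn)) {
    if (!rxn %in% names(model@reactions))
      stop(sprintf("reaction '%s' not in model", rxn), call. = FALSE)
    rxn <- model@reactions[[rxn]]
  }
  met <- model@metabolites
  ids <- names(rxn$stoich)
  rows <- match(ids, met$id)
  if (any(met$boundary[rows])) return("exchange")
  signs <- sign(rxn$stoich)
  if (all(signs > 0) || all(signs < 0)) return("exchange")
  stripped <- stripCompartment(met$name[rows], model@compartments)
  comp <- met$compartment[rows]
  lhs <- sort(stripped[signs < 0]); rhs <- sort(stripped[signs > 0])
  if (identical(lhs, rhs) &&
      !identical(sort(comp[signs < 0]), sort(comp[signs > 0])))
    return("transport")
  if (length(rxn$genes) == 0L) return("uncatalyzed")
  "enzymatic"
}

#' Model summary counts
#'
#' @param model a \linkS4class{GEMModel}.
#' @return named integer vector: \code{nMetabolites}, \code{nReactions},
#'   \code{nGenes}, \code{nEligible}. Mapping-eligible reactions are
#'   those with at least one associated gene whose kind is not
#'   \code{exchange}.
#' @export
modelStats <- function(model) {
  stopifnot(is(model, "GEMModel"))
  c(nMetabolites = nrow(model@metabolites),
    nReactions = length(model@reactions),
    nGenes = nrow(model@genes),
    nEligible = length(mappingEligible(model)))
}

#' Ids of mapping-eligible reactions
#'
#' @param model a \linkS4class{GEMModel}.
#' @return character vector of reaction ids with non-empty gene sets
#'   and kind other than \code{exchange}.
#' @export
mappingEligible <- function(model) {
  keep <- vapply(model@reactions, function(r)
    length(r$genes) > 0L && r$kind != "exchange", NA)
  names(model@reactions)[keep]
}

#' @rdname accessors
#' @export
gemMetabolites <- function(model) model@metabolites

#' @rdname accessors
#' @export
gemReactions <- function(model) model@reactions

#' Accessors for GEMModel components
#'
#' \code{gemMetabolites}, \code{gemReactions} and \code{gemGenes} return
#' the metabolite table, the reaction record list and the gene table of
#' a \linkS4class{GEMModel}; \code{gemGeneIds} the character vector of
#' gene ids (the default ORA background).
#'
#' @param model a \linkS4class{GEMModel}.
#' @name accessors
#' @export
gemGenes <- function(model) model@genes

#' @rdname accessors
#' @export
gemGeneIds <- function(model) model@genes$id

# number of metabolites in the specificity universe under a convention
universeSize <- function(model, universe = c("collapsed", "species")) {
  universe <- match.arg(universe)
  if (universe == "species") nrow(model@metabolites)
  else length(model@nameIndex)
}

#' @export
setMethod("show", "GEMModel", function(object) {
  st <- modelStats(object)
  kinds <- table(vapply(object@reactions, `[[`, "", "kind"))
  cat("GEMModel:", st["nMetabolites"], "metabolites,",
      st["nReactions"], "reactions,", st["nGenes"], "genes\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
  cat("  reaction kinds:",
      paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  cat("  mapping-eligible reactions:", st["nEligible"], "\n")
})
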