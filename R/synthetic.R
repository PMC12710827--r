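#' Generate a seeded toy genome-scale metabolic model
#'
#' Builds a random but reproducible toy GEM for testing the mapping and
#' scoring machinery: no mass balance or thermodynamics, just the
#' combinatorial gene-reaction-metabolite structure. Non-exchange
#' reactions draw 1-3 reactants and 1-3 products (disjoint, unit
#' coefficients); exchange reactions are single-sided and carry no
#' genes. Every metabolite participates in at least one reaction and
#' every gene is attached to at least one non-exchange reaction, with
#' 1-3 genes per reaction. \code{promiscuity} sets the target mean
#' number of reaction attachments per gene (total gene slots =
#' \code{round(promiscuity * nGenes)}, clamped so each reaction keeps
#' 1-3 genes); higher values give genes larger metabolite
#' neighborhoods and hence less specific signature associations. All
#' sampling consumes a single RNG stream seeded from \code{seed}
#' (topology first, then reversibility, then gene attachment), so a
#' given spec is bit-reproducible.
#'
#' @param nMetabolites,nReactions,nGenes counts (each >= 1).
#' @param reversibleFraction fraction of non-exchange reactions marked
#'   reversible.
#' @param exchangeFraction fraction of reactions that are single-sided
#'   boundary exchanges.
#' @param promiscuity target mean reactions per gene (>= 1).
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{GEMModel} with metabolites
#'   \code{MET0001...}, reactions \code{RXN0001...}, genes
#'   \code{G0001...}.
#' @examples
#' m <- generateGEM(nMetabolites = 30, nReactions = 40, nGenes = 15, seed = 1)
#' modelStats(m)
#' @export
generateGEM <- function(nMetabolites = 30, nReactions = 40, nGenes = 15,
                        reversibleFraction = 0.25, exchangeFraction = 0.1,
                        promiscuity = 1.5, seed = 1) {
  if (nMetabolites < 1 || nReactions < 1 || nGenes < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (reversibleFraction < 0 || reversibleFraction > 1 ||
      exchangeFraction < 0 || exchangeFraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (promiscuity < 1)
    stop("'promiscuity' must be >= 1", call. = FALSE)
  nExchange <- round(exchangeFraction * nReactions)
  nEnz <- nReactions - nExchange
  if (nExchange > nMetabolites)
    stop("more exchange reactions than metabolites", call. = FALSE)
  if (nEnz < 1)
    stop("at least one non-exchange reaction is required", call. = FALSE)
  if (nMetabolites < 2)
    stop("non-exchange reactions need >= 2 metabolites", call. = FALSE)

  metIds <- sprintf("MET%04d", seq_len(nMetabolites))
  geneIds <- sprintf("G%04d", seq_len(nGenes))

  withSeed(seed, {
    # topology: cycle through a shuffled metabolite order so every
    # metabolite is used at least once before any is reused
    pool <- sample(metIds)
    cursor <- 0L
    draw <- function(k, exclude = character(0)) {
      out <- character(0)
      guard <- 0L
      while (length(out) < k && guard < 10L * nMetabolites) {
        cursor <<- cursor %% nMetabolites + 1L
        cand <- pool[cursor]
        if (!cand %in% exclude && !cand %in% out) out <- c(out, cand)
        guard <- guard + 1L
      }
      if (length(out) < k) out <- setdiff(metIds, exclude)[seq_len(k)]
      out
    }
    rxns <- vector("list", nReactions)
    for (i in seq_len(nEnz)) {
      nr <- sample(1:3, 1)
      np <- sample(1:3, 1)
      np <- min(np, nMetabolites - nr)
      reac <- draw(nr)
      prod <- draw(np, exclude = reac)
      rxns[[i]] <- list(id = sprintf("RXN%04d", i),
                        stoich = c(setNames(rep(-1, length(reac)), reac),
                                   setNames(rep(+1, length(prod)), prod)),
                        reversible = FALSE, genes = character(0))
    }
    for (i in seq_len(nExchange)) {
      m <- draw(1)
      rxns[[nEnz + i]] <- list(id = sprintf("RXN%04d", nEnz + i),
                               stoich = setNames(-1, m),
                               reversible = FALSE, genes = character(0))
    }
    # reversibility of the non-exchange reactions
    rev <- runif(nEnz) < reversibleFraction
    for (i in seq_len(nEnz)) rxns[[i]]$reversible <- rev[i]

    # gene attachment: total slots target promiscuity * nGenes, each
    # non-exchange reaction gets 1-3 slots, every gene appears >= once
    slots <- max(nEnz, min(3L * nEnz, round(promiscuity * nGenes),
                           na.rm = TRUE))
    slots <- max(slots, nGenes)
    perRxn <- rep(1L, nEnz)
    extra <- slots - nEnz
    while (extra > 0L) {
      i <- sample(which(perRxn < 3L), 1)
      perRxn[i] <- perRxn[i] + 1L
      extra <- extra - 1L
      if (!any(perRxn < 3L)) break
    }
    slotGenes <- c(sample(geneIds),
                   sample(geneIds, max(0L, sum(perRxn) - nGenes),
                          replace = TRUE))
    slotGenes <- sample(slotGenes)  # shuffle coverage slots into place
    pos <- 1L
    for (i in seq_len(nEnz)) {
      g <- unique(slotGenes[pos:(pos + perRxn[i] - 1L)])
      rxns[[i]]$genes <- g
      pos <- pos + perRxn[i]
    }
    # any gene that lost all its slots to within-reaction dedup gets
    # re-attached to a random non-exchange reaction with spare room
    used <- unique(unlist(lapply(rxns[seq_len(nEnz)], `[[`, "genes")))
    for (g in setdiff(geneIds, used)) {
      room <- which(vapply(rxns[seq_len(nEnz)], function(r)
        length(r$genes) < 3L, NA))
      i <- if (length(room)) room[sample.int(length(room), 1)]
           else sample.int(nEnz, 1)
      rxns[[i]]$genes <- unique(c(rxns[[i]]$genes, g))
    }

    mets <- data.frame(id = metIds, name = metIds, compartment = "c",
                       boundary = FALSE, stringsAsFactors = FALSE)
    GEMModel(mets, rxns, data.frame(id = geneIds, symbol = geneIds,
                                    stringsAsFactors = FALSE))
  })
}

#' Plant a metabolite signature around a target gene
#'
#' Samples a fraction of the target gene's metabolite neighborhood
#' (its associated metabolites over mapping-eligible reactions, under
#' the non-directional rule) and adds random non-target metabolites as
#' noise, yielding a signature with known ground truth for recovery
#' tests: a specific target (small neighborhood) should attain the
#' best (smallest) specificity score among all mapped genes.
#'
#' @param model a \linkS4class{GEMModel}.
#' @param targetGene gene id whose neighborhood seeds the signature.
#' @param coverage fraction of the target's metabolites to include,
#'   in (0, 1].
#' @param noise count of random non-target metabolites added.
#' @param seed integer RNG seed.
#' @return list with elements \code{signature} (a
#'   \linkS4class{MetaboliteSignature}) and \code{truth} (list:
#'   \code{targetGene}, \code{targetMetabolites}, \code{sampled},
#'   \code{noise}, \code{recoverable} — \code{FALSE} when the coverage
#'   sample came out empty and the signature is noise-only).
#' @export
plantSignature <- function(model, targetGene, coverage = 1, noise = 0,
                           seed = 1) {
  stopifnot(is(model, "GEMModel"))
  if (!targetGene %in% model@genes$id)
    stop(sprintf("gene '%s' not in model", targetGene), call. = FALSE)
  if (coverage <= 0 || coverage > 1)
    stop("'coverage' must lie in (0, 1]", call. = FALSE)
  eligible <- mappingEligible(model)
  rxns <- intersect(model@geneIndex[[targetGene]], eligible)
  hood <- unique(unlist(lapply(model@reactions[rxns], function(r)
    names(r$stoich)), use.names = FALSE))
  hoodNames <- unique(model@metabolites$name[match(hood, model@metabolites$id)])
  if (length(hoodNames) == 0L)
    stop(sprintf("gene '%s' has no associated metabolites", targetGene),
         call. = FALSE)
  withSeed(seed, {
    k <- round(coverage * length(hoodNames))
    sampled <- if (k >= 1L) sort(sample(hoodNames, k)) else character(0)
    others <- setdiff(unique(model@metabolites$name), hoodNames)
    noiseNames <- if (noise > 0L && length(others))
      sort(sample(others, min(noise, length(others)))) else character(0)
    nm <- c(sampled, noiseNames)
    if (length(nm) == 0L)
      stop("planted signature is empty (coverage sample and noise both empty)",
           call. = FALSE)
    sig <- MetaboliteSignature(nm, label = sprintf("planted_%s", targetGene))
    list(signature = sig,
         truth = list(targetGene = targetGene,
                      targetMetabolites = hoodNames, sampled = sampled,
                      noise = noiseNames,
                      recoverable = length(sampled) > 0L))
  })
}
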