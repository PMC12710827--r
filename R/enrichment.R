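#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then tab-separated member ids.
#' Duplicate members within a set are removed.
#'
#' @param path GMT file.
#' @param name collection label; defaults to the file stem.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, name = NULL) {
  if (!file.exists(path))
    stop(sprintf("GMT file '%s' does not exist", path), call. = FALSE)
  name <- name %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("GMT file '%s' is empty", path), call. = FALSE)
    return(new("GeneSetCollection", name = name, sets = list(),
               descriptions = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3L
  if (any(short))
    stop(sprintf("GMT file '%s': line %d has fewer than 3 fields",
                 path, which(short)[1]), call. = FALSE)
  snames <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(snames))
    stop(sprintf("GMT file '%s': duplicated set name '%s'",
                 path, snames[duplicated(snames)][1]), call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- snames
  descriptions <- setNames(vapply(parts, `[[`, "", 2L), snames)
  new("GeneSetCollection", name = name, sets = sets,
      descriptions = descriptions)
}

#' Upper-tail hypergeometric probability
#'
#' \deqn{P(X \ge k) = \sum_{j = k}^{\min(n, K)}
#'   \frac{\binom{K}{j}\binom{N - K}{n - j}}{\binom{N}{n}}}
#' for a draw of \code{n} genes from a background of \code{N} of which
#' \code{K} belong to the set, observing \code{k} members. Evaluated
#' through the hypergeometric survival function (log-space internally).
#'
#' @param N background size.
#' @param K set members within the background.
#' @param n drawn genes.
#' @param k observed members among the drawn genes.
#' @return probability in (0, 1]; \code{k = 0} gives 1 exactly.
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  if (any(N < 0 | K < 0 | K > N)) stop("require 0 <= K <= N", call. = FALSE)
  if (any(n < 0 | n > N)) stop("require 0 <= n <= N", call. = FALSE)
  if (any(k < 0 | k > n)) stop("require 0 <= k <= n", call. = FALSE)
  ifelse(k == 0, 1,
         phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Weight-adjusted query and overlap counts
#'
#' Continuous weighted counts are rounded half-up to integers:
#' \code{nW = floor(1/2 + sum(w))} over the mapped genes in the
#' background, and \code{kW = floor(1/2 + sum(w))} over the mapped
#' genes that are also set members. After rounding, \code{kW} is
#' clamped to \code{min(nW, K)} so the counts remain a valid
#' hypergeometric configuration. Only the query-side counts are
#' weighted; the background \code{N} and set size \code{K} never are.
#'
#' @param weights named numeric vector, gene id -> weight in [0, 1].
#' @param members character vector of set member gene ids.
#' @param background character vector of background gene ids; all
#'   weighted genes must belong to it.
#' @return named integer vector \code{c(nW, kW)}.
#' @export
weightedCounts <- function(weights, members, background) {
  if (length(weights) && is.null(names(weights)))
    stop("'weights' must be named by gene id", call. = FALSE)
  out <- setdiff(names(weights), background)
  if (length(out))
    stop(sprintf("weighted gene(s) outside background: %s",
                 paste(head(out, 3), collapse = ", ")), call. = FALSE)
  K <- length(intersect(members, background))
  nW <- floor(0.5 + sum(weights))
  kW <- floor(0.5 + sum(weights[names(weights) %in% members]))
  kW <- min(kW, nW, K)
  c(nW = as.integer(nW), kW = as.integer(kW))
}

#' Specificity-weighted over-representation analysis
#'
#' Tests each gene set of one or more collections for over-representation
#' of the mapped genes, using the sigmoid specificity weights: the query
#' size \code{n} and overlap \code{k} of the classical hypergeometric
#' test are replaced by the rounded weighted counts \code{nW}, \code{kW}
#' (see \code{\link{weightedCounts}}), which down-weights promiscuous
#' genes with low signature specificity. The background \code{N} and
#' per-set \code{K} are plain gene counts (never weighted). P-values are
#' Benjamini-Hochberg adjusted within each collection separately.
#' Degenerate rows (no set member in the background, or a weighted
#' query count of zero) are kept with \code{p = 1} so row counts are
#' stable for downstream pathway-overlap tests.
#'
#' @param mapping a \linkS4class{MappingResult}.
#' @param collections a \linkS4class{GeneSetCollection} or a list of
#'   them.
#' @param background character vector of background gene ids; defaults
#'   to all enzyme-coding genes of the model the mapping was computed
#'   on. Mapped genes outside the background are dropped with a
#'   warning.
#' @param useWeights logical; \code{FALSE} reduces the test to the
#'   classical unweighted ORA.
#' @param alpha significance threshold on the adjusted p-value
#'   (strict: \code{pAdj < alpha}).
#' @return a named list of \linkS4class{ORAReport}, one per collection
#'   (a single report if one collection was given).
#' @export
runORA <- function(mapping, collections, background = NULL,
                   useWeights = TRUE, alpha = 0.05) {
  stopifnot(is(mapping, "MappingResult"))
  stopifnot_scalar_flag(useWeights, "useWeights")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  single <- is(collections, "GeneSetCollection")
  if (single) collections <- list(collections)
  background <- background %||% mapping@params$modelGenes
  background <- unique(as.character(background))
  if (length(background) == 0L)
    stop("background is empty", call. = FALSE)

  mg <- mappedGenes(mapping)
  drop <- setdiff(mg$geneId, background)
  if (length(drop)) {
    warning(sprintf("%d mapped gene(s) outside the background dropped",
                    length(drop)), call. = FALSE)
    mg <- mg[mg$geneId %in% background, , drop = FALSE]
  }
  w <- if (useWeights) setNames(mg$wi, mg$geneId)
       else setNames(rep(1, nrow(mg)), mg$geneId)
  N <- length(background)

  reports <- lapply(collections, function(coll) {
    rows <- lapply(names(coll@sets), function(sn) {
      members <- intersect(coll@sets[[sn]], background)
      K <- length(members)
      hits <- intersect(names(w), members)
      wc <- weightedCounts(w, members, background)
      p <- if (K == 0L || wc["nW"] == 0L) 1
           else hypergeomUpperTail(N, K, wc["nW"], wc["kW"])
      data.frame(setName = sn, N = N, K = K,
                 nRaw = length(w), kRaw = length(hits),
                 nW = wc["nW"], kW = wc["kW"], p = unname(p),
                 hits = paste(sort(hits), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    rows <- if (length(rows)) do.call(rbind, rows) else
      data.frame(setName = character(0), N = integer(0), K = integer(0),
                 nRaw = integer(0), kRaw = integer(0), nW = integer(0),
                 kW = integer(0), p = numeric(0), hits = character(0),
                 stringsAsFactors = FALSE)
    rows$pAdj <- p.adjust(rows$p, method = "BH")
    ord <- order(rows$p, rows$setName, method = "radix")
    rows <- rows[ord, c("setName", "N", "K", "nRaw", "kRaw", "nW", "kW",
                        "p", "pAdj", "hits"), drop = FALSE]
    rownames(rows) <- NULL
    new("ORAReport", collection = coll@name, rows = rows,
        params = list(useWeights = useWeights, alpha = alpha,
                      backgroundSize = N))
  })
  names(reports) <- vapply(collections, function(x) x@name, "")
  if (single) reports[[1]] else reports
}

#' Rows of an ORA report
#'
#' @param report an \linkS4class{ORAReport}.
#' @param onlySignificant return only rows with \code{pAdj} strictly
#'   below the report's alpha.
#' @return data.frame of enrichment rows.
#' @export
oraRows <- function(report, onlySignificant = FALSE) {
  stopifnot(is(report, "ORAReport"))
  r <- report@rows
  if (onlySignificant) r[r$pAdj < report@params$alpha, , drop = FALSE]
  else r
}

#' Names of significantly enriched sets
#'
#' @param report an \linkS4class{ORAReport}.
#' @return character vector of set names with \code{pAdj < alpha}.
#' @export
significantSets <- function(report) {
  oraRows(report, onlySignificant = TRUE)$setName
}

#' Write an ORA report as TSV
#'
#' @param report an \linkS4class{ORAReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeORATSV <- function(report, path) {
  r <- oraRows(report)
  out <- data.frame(set_name = r$setName, N = r$N, K = r$K,
                    n_raw = r$nRaw, k_raw = r$kRaw,
                    n_w = r$nW, k_w = r$kW,
                    p = formatC(r$p, format = "e", digits = 4),
                    p_adj = formatC(r$pAdj, format = "e", digits = 4),
                    hits = r$hits, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
setMethod("show", "ORAReport", function(object) {
  r <- object@rows
  sig <- sum(r$pAdj < object@params$alpha)
  cat(sprintf("ORAReport '%s': %d set(s), %d significant at pAdj < %g (%s)\n",
              object@collection, nrow(r), sig, object@params$alpha,
              if (object@params$useWeights) "weighted" else "unweighted"))
  if (nrow(r))
    print(head(r[, c("setName", "K", "nW", "kW", "p", "pAdj")], 5),
          row.names = FALSE)
})
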