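#' Single-molecule concordance test
#'
#' Tests whether GEM-mapped enzyme-coding genes overlap a paired
#' differential-expression signature more than expected by chance. The
#' background is the intersection of the model's enzyme-coding genes
#' and the genes/proteins actually measured in the paired omics layer;
#' both input sets are restricted to that background before the
#' one-sided (upper-tail) hypergeometric test. When up- and
#' down-regulated signatures were mapped separately, pass the union of
#' their mapped genes (and the union of the up/down DE sets).
#'
#' @param mapped character vector of mapped gene ids.
#' @param de character vector of differentially expressed gene/protein
#'   ids from the paired layer.
#' @param gemGenes character vector of the model's enzyme-coding gene
#'   ids.
#' @param measured character vector of gene/protein ids measured in the
#'   paired layer.
#' @return list of class \code{"overlapTest"}: \code{nA}, \code{nB}
#'   (restricted set sizes), \code{overlap}, \code{NBg} (background
#'   size) and \code{p}.
#' @export
singleMoleculeOverlap <- function(mapped, de, gemGenes, measured) {
  bg <- intersect(unique(gemGenes), unique(measured))
  if (length(bg) == 0L)
    stop("empty background: no measured gene is in the model", call. = FALSE)
  a <- intersect(unique(mapped), bg)
  b <- intersect(unique(de), bg)
  ov <- length(intersect(a, b))
  p <- hypergeomUpperTail(length(bg), length(b), length(a), ov)
  structure(list(nA = length(a), nB = length(b), overlap = ov,
                 NBg = length(bg), p = p), class = "overlapTest")
}

#' Pathway-level concordance test
#'
#' Upper-tail hypergeometric test on two sets of enriched pathway names
#' over an eligible-pathway background: the pathways sufficiently
#' represented in both gene universes. Enriched names outside the
#' eligible background are dropped with a warning.
#'
#' @param enrichedA,enrichedB character vectors of enriched set names
#'   from the two sides (e.g. GEM-mapped genes vs. the paired omics
#'   signature).
#' @param eligible character vector of eligible pathway names (the
#'   background).
#' @return list of class \code{"overlapTest"} as in
#'   \code{\link{singleMoleculeOverlap}}.
#' @export
pathwayOverlap <- function(enrichedA, enrichedB, eligible) {
  eligible <- unique(eligible)
  if (length(eligible) == 0L)
    stop("empty eligible-pathway background", call. = FALSE)
  dropN <- length(setdiff(enrichedA, eligible)) +
    length(setdiff(enrichedB, eligible))
  if (dropN > 0)
    warning(sprintf("%d enriched pathway name(s) outside the background dropped",
                    dropN), call. = FALSE)
  a <- intersect(unique(enrichedA), eligible)
  b <- intersect(unique(enrichedB), eligible)
  ov <- length(intersect(a, b))
  p <- hypergeomUpperTail(length(eligible), length(b), length(a), ov)
  structure(list(nA = length(a), nB = length(b), overlap = ov,
                 NBg = length(eligible), p = p), class = "overlapTest")
}

#' @export
print.overlapTest <- function(x, ...) {
  cat(sprintf("overlap test: |A|=%d, |B|=%d, overlap=%d, background=%d, p=%.4g\n",
              x$nA, x$nB, x$overlap, x$NBg, x$p))
  invisible(x)
}

#' Which pathways are sufficiently represented in a gene universe
#'
#' A set is eligible for the pathway-level concordance background when
#' at least \code{minGenes} of its members lie in the given gene
#' universe. Apply once per side and intersect the results to get the
#' background for \code{\link{pathwayOverlap}}.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param genes character vector: the gene universe of one side.
#' @param minGenes minimum members present (default 5).
#' @return character vector of eligible set names.
#' @export
eligibleSets <- function(collection, genes, minGenes = 5) {
  stopifnot(is(collection, "GeneSetCollection"))
  keep <- vapply(collection@sets, function(m)
    length(intersect(m, genes)) >= minGenes, NA)
  names(collection@sets)[keep]
}

#' Kolmogorov-Smirnov uniformity test for p-value collections
#'
#' Tests whether a collection of p-values is skewed toward zero
#' relative to Uniform(0, 1). The default one-sided alternative uses
#' \eqn{D^+ = \max_i (i/n - x_{(i)})} over the sorted sample; the
#' two-sided alternative uses \eqn{D = \max(D^+, D^-)} with
#' \eqn{D^- = \max_i (x_{(i)} - (i-1)/n)}. The statistic is computed by
#' a sorted scan; the p-value comes from the standard KS sampling
#' distribution as implemented in \code{stats::ks.test} (exact for
#' small samples where available, asymptotic otherwise; ties warnings
#' are suppressed since p-value collections routinely contain ties).
#'
#' @param pvals numeric vector of probabilities in [0, 1].
#' @param alternative \code{"skew-to-zero"} (default) or
#'   \code{"two-sided"}.
#' @return list of class \code{"ksUniform"}: \code{n}, \code{D},
#'   \code{p}, \code{alternative}.
#' @examples
#' ksUniform(runif(50))$D          # small for uniform input
#' ksUniform(rbeta(50, 0.2, 1))$D  # large for zero-skewed input
#' @export
ksUniform <- function(pvals, alternative = c("skew-to-zero", "two-sided")) {
  alternative <- match.arg(alternative)
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0L)
    stop("at least one p-value is required", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(pvals)
  x <- sort(pvals)
  dPlus <- max(seq_len(n) / n - x)
  dMinus <- max(x - (seq_len(n) - 1) / n)
  D <- if (alternative == "skew-to-zero") dPlus else max(dPlus, dMinus)
  ksAlt <- if (alternative == "skew-to-zero") "greater" else "two.sided"
  p <- suppressWarnings(
    stats::ks.test(pvals, "punif", alternative = ksAlt)$p.value)
  structure(list(n = n, D = D, p = p, alternative = alternative),
            class = "ksUniform")
}

#' @export
print.ksUniform <- function(x, ...) {
  cat(sprintf("KS uniformity test (%s): n=%d, D=%.4f, p=%.4g\n",
              x$alternative, x$n, x$D, x$p))
  invisible(x)
}

#' Count significant comparisons in a p-value matrix
#'
#' Rows are comparisons (datasets/phenotypes), columns are p-values
#' under different conditions (e.g. mapping rules or gene-set
#' collections). Significance is strict (\code{p < alpha}). In
#' \code{"any-column"} mode (the default), a row counts as significant
#' when its minimum over columns is below alpha; \code{"per-column"}
#' returns one count per column.
#'
#' @param pTable numeric matrix or data.frame of p-values (non-numeric
#'   columns of a data.frame are dropped).
#' @param alpha significance level in (0, 1).
#' @param mode \code{"any-column"} or \code{"per-column"}.
#' @return an integer count, or a named integer vector in per-column
#'   mode.
#' @export
countSignificant <- function(pTable, alpha = 0.05,
                             mode = c("any-column", "per-column")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (is.data.frame(pTable))
    pTable <- as.matrix(pTable[vapply(pTable, is.numeric, NA)])
  if (length(pTable) == 0L || nrow(pTable) == 0L)
    return(if (mode == "any-column") 0L else
           setNames(integer(ncol(pTable) %||% 0L), colnames(pTable)))
  if (mode == "any-column") {
    sum(apply(pTable, 1L, min, na.rm = TRUE) < alpha)
  } else {
    apply(pTable, 2L, function(col) sum(col < alpha, na.rm = TRUE))
  }
}

#' Bundled paired-omics benchmark tables
#'
#' Ships the concordance statistics of an eleven-comparison benchmark
#' across ten public paired metabolomics-proteomics/transcriptomics
#' studies (EMT, serine starvation, NECS age and extreme longevity,
#' M005 kidney/liver/gastrocnemius/plasma, ROSMAP, COVID urine and
#' serum). The \code{"single-molecule"} table holds, per comparison,
#' the mapped-gene vs. DE-gene overlap test under the non-directional
#' (\code{p_nd}) and directional (\code{p_d}) mapping rules; the
#' \code{"pathway"} table holds the enriched-pathway overlap tests per
#' gene-set collection (HALLMARK, KEGG, REACTOME, GOBP, GOMF). These
#' drive the evaluation-statistics examples and regression tests
#' without any download.
#'
#' @param level \code{"single-molecule"} or \code{"pathway"}.
#' @return data.frame with the columns described above.
#' @examples
#' tab <- evaluationTable("single-molecule")
#' ksUniform(tab$p_nd)
#' countSignificant(tab[, c("p_nd", "p_d")])
#' @export
evaluationTable <- function(level = c("single-molecule", "pathway")) {
  level <- match.arg(level)
  fname <- switch(level, "single-molecule" = "single_molecule_eval.tsv",
                  "pathway" = "pathway_eval.tsv")
  path <- system.file("extdata", fname, package = "gemsig", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
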