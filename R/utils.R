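#' @importFrom methods new is slot validObject slotNames
#' @importFrom stats phyper p.adjust ks.test rpois runif
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a metabolite name for matching
#'
#' Trims leading/trailing whitespace, case-folds, and collapses internal
#' runs of whitespace to a single space. Signature names and model
#' metabolite names are both passed through this before comparison; no
#' fuzzy or synonym matching is attempted here.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
normalizeMetName <- function(x) {
  x <- trimws(as.character(x))
  x <- tolower(x)
  gsub("[[:space:]]+", " ", x)
}

# Strip a trailing compartment code from a metabolite name or id.
# Recognizes "name[c]" and "name_c" forms where "c" is one of the model's
# declared compartment codes; anything else is returned unchanged.
stripCompartment <- function(x, compartments) {
  if (length(compartments) == 0L) return(x)
  codes <- paste(vapply(compartments, function(cc) {
    gsub("([][{}()*+?.\\^$|])", "\\\\\\1", cc)
  }, character(1)), collapse = "|")
  x <- sub(paste0("\\[(", codes, ")\\]$"), "", x)
  sub(paste0("_(", codes, ")$"), "", x)
}

# Evaluate `expr` with the RNG seeded from `seed`, restoring the caller's
# RNG state afterwards so package functions never perturb user sessions.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", what), call. = FALSE)
  invisible(x)
}
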