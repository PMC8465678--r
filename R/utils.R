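#' @useDynLib mdlinker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict runif setNames
#' @importFrom utils read.delim write.table head
#' @importFrom graphics boxplot
NULL

#' The five association evidence types
#'
#' Fixed, ordered vocabulary of evidence categories linking an miRNA to a
#' disease: genetic evidence, epigenetic evidence, circulating-miRNA assays,
#' miRNA-target interaction and tissue expression. The order is the canonical
#' tie-break order used wherever type scores are ranked.
#'
#' @return Character vector of length 5.
#' @export
association_types <- function() {
  c("genetics", "epigenetics", "circulating", "target", "tissue")
}

#' Normalize an entity name
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal runs
#' of whitespace to a single space. Applied identically to miRNA and disease
#' names in every reader so that entities match across input files.
#'
#' @param x character vector of raw names.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Default synonym table for evidence-category strings
#'
#' Maps the category dialects found in association dumps onto the five
#' canonical types. Pass a modified copy to [read_associations()] to accept
#' additional spellings.
#'
#' @return Named character vector: names are accepted (normalized) input
#'   strings, values are canonical types.
#' @export
type_synonyms <- function() {
  c(
    "genetics" = "genetics",
    "genetic" = "genetics",
    "epigenetics" = "epigenetics",
    "epigenetic" = "epigenetics",
    "circulating" = "circulating",
    "circulation" = "circulating",
    "circulating mirnas" = "circulating",
    "circulating mirna" = "circulating",
    "target" = "target",
    "mirna-target" = "target",
    "mirna-target interaction" = "target",
    "mirna-target interactions" = "target",
    "target interaction" = "target",
    "tissue" = "tissue",
    "tissue expression" = "tissue",
    "mirna tissue expression" = "tissue"
  )
}

# Derive a stream-specific 31-bit seed from a master seed; keeps every source
# of randomness a pure function of (master seed, stream label).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
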