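# internal helpers shared across stages

#' Stable 31-bit string hash (polynomial rolling hash)
#'
#' Used to derive per-pair permutation sub-seeds that do not depend on the
#' order in which pairs are evaluated.
#' @noRd
stable_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Sub-seed for one unordered gene pair
#' @noRd
pair_seed <- function(seed, gene_a, gene_b) {
  h <- stable_hash(paste(gene_a, gene_b, sep = "\r"))
  as.integer(bitwXor(as.integer(seed %% 2147483647L), h) %% 2147483647L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a genes-by-samples expression matrix
#'
#' The pipeline's substrate is a plain numeric matrix on log2 scale with
#' gene ids as row names and sample ids as column names. Missing values are
#' tolerated (pairwise complete-case handling downstream); infinities are not.
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @param allow_na allow missing entries (default TRUE).
#' @return the validated matrix, invisibly.
#' @export
validate_expression_matrix <- function(m, allow_na = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (any(is.infinite(m))) stop("non-finite expression values")
  if (!allow_na && anyNA(m)) stop("missing values not allowed here")
  invisible(m)
}

#' Canonical undirected order for a pair of gene ids
#' @noRd
canonical_pair <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' md5 checksums for a set of files
#' @noRd
file_checksums <- function(paths) {
  unname(tools::md5sum(paths))
}
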