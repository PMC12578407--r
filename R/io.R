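# Readers and writers for the pipeline's plain-text interchange formats:
# TSV expression matrices (first column = gene id, header = sample ids),
# the GCT dialect (2-line header, Name/Description columns), GMT gene-set
# collections and the tri-state candidate-annotation table.

#' Write an expression matrix as TSV
#'
#' @param mat genes-by-samples matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV expression matrix
#'
#' First column gene ids, remaining columns one sample each; all cells
#' numeric. Duplicate gene ids are an error naming the offenders.
#'
#' @param path input file.
#' @return numeric genes-by-samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed expression TSV: need gene column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  body <- df[, -1, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric cells in columns: ",
                      paste(names(body)[!num], collapse = ", "))
  mat <- as.matrix(body)
  rownames(mat) <- genes
  validate_expression_matrix(mat)
  mat
}

#' Read a GCT expression matrix
#'
#' GCT dialect: line 1 version tag, line 2 declared `n_genes n_samples`,
#' then a header with Name and Description columns. Declared dimensions
#' must match the body.
#'
#' @param path input file.
#' @return numeric genes-by-samples matrix; descriptions kept in the
#'   `"description"` attribute.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GCT: fewer than 3 lines")
  dims <- strsplit(trimws(lines[2]), "\t| +")[[1]]
  dims <- suppressWarnings(as.integer(dims))
  if (length(dims) < 2 || anyNA(dims[1:2])) stop("malformed GCT dimension line")
  df <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed GCT header: need Name, Description, samples")
  if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2]) {
    stop("GCT declared dimensions (", dims[1], " x ", dims[2],
         ") do not match body (", nrow(df), " x ", ncol(df) - 2L, ")")
  }
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in GCT body")
  rownames(mat) <- genes
  attr(mat, "description") <- as.character(df[[2]])
  validate_expression_matrix(mat)
  mat
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then members. Set
#' order is preserved; duplicated members within a set are removed with a
#' warning.
#'
#' @param path input file.
#' @return list of `list(name, description, genes)`; empty file gives an
#'   empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  out <- vector("list", length(lines))
  n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    dup <- duplicated(genes)
    n_dup <- n_dup + sum(dup)
    out[[i]] <- list(name = f[1], description = f[2], genes = genes[!dup])
  }
  if (n_dup > 0) warning(n_dup, " duplicated member(s) removed across sets")
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write a GMT gene-set collection
#'
#' @param sets list of `list(name, description, genes)`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description %||% "", s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a signature from a two-set GMT
#'
#' The poor-prognosis set is recognized by a name containing "POOR"
#' (case-insensitive), the good-prognosis set by "GOOD"; otherwise the
#' first set is taken as poor and the second as good.
#'
#' @param path GMT file with exactly two sets.
#' @param name signature label (default: file base name).
#' @return a [signature_definition()].
#' @export
read_signature_gmt <- function(path, name = NULL) {
  sets <- read_gmt(path)
  if (length(sets) != 2) stop("signature GMT must contain exactly 2 sets")
  nms <- toupper(vapply(sets, `[[`, "", "name"))
  poor_i <- grep("POOR", nms)
  good_i <- grep("GOOD", nms)
  if (length(poor_i) != 1 || length(good_i) != 1) { poor_i <- 1; good_i <- 2 }
  signature_definition(
    name %||% sub("\\.gmt$", "", basename(path)),
    poor_genes = sets[[poor_i]]$genes,
    good_genes = sets[[good_i]]$genes
  )
}

#' Read a tri-state candidate annotation table
#'
#' TSV with columns `gene`, `liver_expression_high`,
#' `liver_disease_association`, `druggable` and optional `evidence_note`.
#' Flag cells are `true`/`false`/`unknown` (case-insensitive; empty = NA =
#' unknown). Unknown is distinct from false.
#'
#' @param path input file.
#' @return data.frame with logical (NA-able) flag columns, one row per gene.
#' @export
read_annotations_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("gene", "liver_expression_high", "liver_disease_association", "druggable")
  if (!all(need %in% names(df))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stop("duplicate annotation rows for a gene")
  parse_flag <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes")] <- TRUE
    out[x %in% c("false", "f", "0", "no")] <- FALSE
    out
  }
  for (cl in need[-1]) df[[cl]] <- parse_flag(df[[cl]])
  df
}
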