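#' Construct an expression dataset
#'
#' Bundles an N x P expression matrix `E` (rows are experiments, columns are
#' genes) with an aligned binary perturbation matrix `K` recording which gene
#' was knocked out in which experiment (`K[i, j] = 1` means gene j was
#' externally perturbed in experiment i; all zeros when nothing is known), and
#' an optional set of transcription factors eligible as regulators.
#'
#' @param expression numeric matrix, N experiments x P genes. Column names are
#'   used as gene identifiers; if absent, `gene_ids` must be given.
#' @param perturbation binary matrix of the same shape as `expression`, or
#'   `NULL` for all zeros (no knockout information).
#' @param gene_ids character vector of P unique gene identifiers.
#' @param tf_ids subset of `gene_ids` eligible as regulators; defaults to all
#'   genes.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `expression`, `perturbation`, `gene_ids`, `tf_ids` and a `normalized`
#'   flag.
#' @seealso [read_expression()], [normalize_expression()], [attach_knockouts()]
#' @export
expression_dataset <- function(expression, perturbation = NULL,
                               gene_ids = colnames(expression),
                               tf_ids = gene_ids) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (is.null(gene_ids))
    .stopf("gene identifiers are required (column names or gene_ids=)")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(expression))
    .stopf("gene_ids has length %d but expression has %d columns",
           length(gene_ids), ncol(expression))
  if (anyDuplicated(gene_ids))
    .stopf("duplicate gene identifier: %s",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (is.null(perturbation)) {
    perturbation <- matrix(0, nrow(expression), ncol(expression))
  } else {
    perturbation <- as.matrix(perturbation)
    storage.mode(perturbation) <- "double"
  }
  if (!identical(dim(perturbation), dim(expression)))
    .stopf("perturbation matrix must have the same shape as expression")
  if (!all(perturbation %in% c(0, 1)))
    .stopf("perturbation entries must be 0 or 1")
  tf_ids <- as.character(tf_ids)
  if (!all(tf_ids %in% gene_ids))
    .stopf("unknown transcription factor id: %s",
           paste(setdiff(tf_ids, gene_ids), collapse = ", "))
  dimnames(expression) <- list(NULL, gene_ids)
  dimnames(perturbation) <- list(NULL, gene_ids)
  structure(
    list(expression = expression, perturbation = perturbation,
         gene_ids = gene_ids, tf_ids = tf_ids, normalized = FALSE),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d experiments x %d genes (%d TFs)%s\n",
              nrow(x$expression), length(x$gene_ids), length(x$tf_ids),
              if (x$normalized) ", normalized" else ""))
  nko <- sum(rowSums(x$perturbation) > 0)
  cat(sprintf("  knockout experiments: %d\n", nko))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$expression)

# Split a tab-delimited text file into a validated list of fields, erroring
# with the offending line / cell named. Used by all the TSV readers because
# base read.delim cannot report which row is ragged.
.read_tsv_fields <- function(path, expect_header = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) .stopf("file '%s' is empty", path)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read an expression matrix in the DREAM tab-separated dialect
#'
#' The file has one header row of gene identifiers and one numeric row per
#' experiment, tab-separated. The perturbation matrix is all zeros unless
#' attached afterwards (see [attach_knockouts()] and [read_knockouts()]).
#'
#' @param path path to the TSV file.
#' @param tf_ids optional regulator subset (e.g. a DREAM5 TF list).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, tf_ids = NULL) {
  fields <- .read_tsv_fields(path)
  header <- fields[[1]]
  p <- length(header)
  rows <- fields[-1]
  if (length(rows) < 1) .stopf("'%s' has a header but no data rows", path)
  mat <- matrix(NA_real_, length(rows), p)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != p)
      .stopf("line %d of '%s' has %d fields, expected %d",
             i + 1L, path, length(rows[[i]]), p)
    vals <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      .stopf("non-numeric value '%s' at line %d, column %d ('%s') of '%s'",
             rows[[i]][j], i + 1L, j, header[j], path)
    }
    mat[i, ] <- vals
  }
  colnames(mat) <- header
  if (is.null(tf_ids)) tf_ids <- header
  expression_dataset(mat, gene_ids = header, tf_ids = tf_ids)
}

#' Write an expression matrix in the DREAM tab-separated dialect
#'
#' @param dataset an [expression_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dataset$gene_ids, collapse = "\t"), con)
  for (i in seq_len(nrow(dataset$expression)))
    writeLines(paste(sprintf("%.17g", dataset$expression[i, ]),
                     collapse = "\t"), con)
  invisible(path)
}

#' Attach knockout annotations to a dataset
#'
#' Rebuilds the binary perturbation matrix `K` from a list of
#' (experiment index, gene id) pairs: `K` gets a 1 exactly at the listed
#' cells and 0 elsewhere. Duplicate pairs collapse to a single 1. An empty
#' list yields an all-zero `K` (no knockout information).
#'
#' @param dataset an [expression_dataset()].
#' @param knockouts data frame or two-column structure with an experiment
#'   index (1-based row of `E`) and a gene identifier; or an empty list.
#' @return The dataset with its perturbation matrix replaced.
#' @export
attach_knockouts <- function(dataset, knockouts) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  K <- matrix(0, nrow(dataset$expression), ncol(dataset$expression),
              dimnames = dimnames(dataset$perturbation))
  if (length(knockouts)) {
    ko <- as.data.frame(knockouts)
    idx <- as.integer(ko[[1]])
    genes <- as.character(ko[[2]])
    if (any(idx < 1 | idx > nrow(K)))
      .stopf("experiment index out of range: %s",
             paste(idx[idx < 1 | idx > nrow(K)], collapse = ", "))
    bad <- setdiff(genes, dataset$gene_ids)
    if (length(bad)) .stopf("unknown gene id: %s", paste(bad, collapse = ", "))
    K[cbind(idx, match(genes, dataset$gene_ids))] <- 1
  }
  dataset$perturbation <- K
  dataset
}

#' Read knockout annotations
#'
#' Two dialects are accepted: a full N x P binary matrix with the same header
#' as the expression file, or two-column metadata lines
#' `experiment_index<TAB>gene_id` (no header needed when every first field is
#' an integer).
#'
#' @param path path to the TSV file.
#' @param dataset the [expression_dataset()] the annotations refer to.
#' @return The dataset with its perturbation matrix filled in.
#' @export
read_knockouts <- function(path, dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  fields <- .read_tsv_fields(path)
  first <- fields[[1]]
  if (length(first) == 2 &&
      !anyNA(suppressWarnings(as.integer(vapply(fields, `[`, "", 1L))))) {
    ko <- data.frame(
      experiment = as.integer(vapply(fields, `[`, "", 1L)),
      gene = vapply(fields, `[`, "", 2L)
    )
    return(attach_knockouts(dataset, ko))
  }
  # full-matrix dialect: header of gene ids then 0/1 rows
  if (!setequal(first, dataset$gene_ids))
    .stopf("knockout matrix header does not match the dataset's genes")
  p <- length(first)
  rows <- fields[-1]
  if (length(rows) != nrow(dataset$expression))
    .stopf("knockout matrix has %d rows, expression has %d",
           length(rows), nrow(dataset$expression))
  K <- matrix(0, length(rows), p)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != p)
      .stopf("line %d of '%s' has %d fields, expected %d",
             i + 1L, path, length(rows[[i]]), p)
    K[i, ] <- as.numeric(rows[[i]])
  }
  colnames(K) <- first
  K <- K[, dataset$gene_ids, drop = FALSE]
  dataset$perturbation <- K
  dimnames(dataset$perturbation) <- dimnames(dataset$expression)
  expression_dataset(dataset$expression, dataset$perturbation,
                     dataset$gene_ids, dataset$tf_ids)
}

#' Normalize expression to zero mean and unit standard deviation
#'
#' Each gene column is centred on its mean and scaled by its sample standard
#' deviation (denominator N-1). Zero-variance columns map to all zeros: a
#' constant gene carries no regulatory signal and can never be selected as a
#' regulator. The transform is idempotent.
#'
#' @param dataset an [expression_dataset()].
#' @return The dataset with normalized expression and `normalized = TRUE`.
#' @export
normalize_expression <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  E <- dataset$expression
  if (nrow(E) < 2) .stopf("normalization needs at least 2 experiments")
  mu <- colMeans(E)
  sdev <- apply(E, 2L, sd)
  E <- sweep(E, 2L, mu, "-")
  pos <- sdev > 0
  E[, pos] <- sweep(E[, pos, drop = FALSE], 2L, sdev[pos], "/")
  E[, !pos] <- 0
  dataset$expression <- E
  dataset$normalized <- TRUE
  dataset
}
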