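#' Construct a score matrix
#'
#' A P x P weighted adjacency matrix: entry (i, j) is the evidence that gene i
#' regulates gene j. Rows are regulators, columns are targets. The diagonal is
#' structurally zero (no self-regulation) and rows of genes outside the
#' regulator set are structurally zero.
#'
#' @param scores nonnegative P x P numeric matrix.
#' @param gene_ids character vector of P gene identifiers (defaults to the
#'   matrix dimnames).
#' @param tf_ids regulator subset; rows outside it must be all zero.
#' @param stage label of the refinement stage: `"V"` (raw importance),
#'   `"V1"` (variance-refined) or `"V2"` (knockout-refined).
#' @return An object of class `ScoreMatrix`.
#' @export
score_matrix <- function(scores, gene_ids = rownames(scores),
                         tf_ids = gene_ids, stage = c("V", "V1", "V2")) {
  stage <- match.arg(stage)
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) .stopf("score matrix must be square")
  if (is.null(gene_ids)) .stopf("gene identifiers are required")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) .stopf("duplicate gene identifier")
  if (length(gene_ids) != nrow(scores))
    .stopf("gene_ids length does not match matrix dimension")
  if (any(!is.finite(scores))) .stopf("scores must be finite")
  if (any(scores < 0)) .stopf("scores must be nonnegative")
  if (any(diag(scores) != 0)) .stopf("diagonal entries must be exactly 0")
  nontf <- setdiff(gene_ids, tf_ids)
  if (length(nontf) && any(scores[match(nontf, gene_ids), ] != 0))
    .stopf("rows of genes outside tf_ids must be all zero")
  dimnames(scores) <- list(gene_ids, gene_ids)
  structure(list(scores = scores, gene_ids = gene_ids,
                 tf_ids = as.character(tf_ids), stage = stage),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix (stage %s): %d genes, %d eligible regulators\n",
              x$stage, length(x$gene_ids), length(x$tf_ids)))
  cat(sprintf("  nonzero scores: %d of %d off-diagonal cells\n",
              sum(x$scores != 0),
              length(x$gene_ids) * (length(x$gene_ids) - 1L)))
  invisible(x)
}

#' Rank the edges of a score matrix
#'
#' Flattens a [score_matrix()] into a ranked edge list: ordered
#' (regulator, target, score) triples, self-pairs excluded, sorted by
#' descending score with ties broken by (regulator index, target index)
#' ascending so the output is bit-reproducible.
#'
#' @param matrix a [score_matrix()].
#' @param top_k keep the first `top_k` edges, or `Inf` for all.
#' @return A data frame with columns `regulator`, `target`, `score`.
#' @export
ranked_edges <- function(matrix, top_k = Inf) {
  stopifnot(inherits(matrix, "ScoreMatrix"))
  if (!is.infinite(top_k)) {
    top_k <- as.numeric(top_k)
    if (length(top_k) != 1 || is.na(top_k) || top_k <= 0 ||
        top_k != floor(top_k))
      .stopf("top_k must be a positive integer or Inf")
  }
  p <- length(matrix$gene_ids)
  reg <- rep(seq_len(p), times = p)
  tgt <- rep(seq_len(p), each = p)
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  sc <- matrix$scores[cbind(reg, tgt)]
  ord <- order(-sc, reg, tgt)
  out <- data.frame(regulator = matrix$gene_ids[reg[ord]],
                    target = matrix$gene_ids[tgt[ord]],
                    score = sc[ord], stringsAsFactors = FALSE)
  head(out, n = if (is.infinite(top_k)) nrow(out) else top_k)
}

#' Write a ranked edge list in the DREAM submission dialect
#'
#' Writes `regulator<TAB>target<TAB>score` lines in descending score order
#' (deterministic tie-break, see [ranked_edges()]).
#'
#' @inheritParams ranked_edges
#' @param path output file path.
#' @return The ranked edge data frame, invisibly.
#' @export
write_ranked_edges <- function(matrix, path, top_k = Inf) {
  edges <- ranked_edges(matrix, top_k)
  lines <- sprintf("%s\t%s\t%.17g", edges$regulator, edges$target, edges$score)
  writeLines(lines, path)
  invisible(edges)
}

#' Read a ranked edge list
#'
#' @param path three-column TSV `regulator<TAB>target<TAB>score`, no header.
#' @return A data frame with columns `regulator`, `target`, `score`.
#' @export
read_ranked_edges <- function(path) {
  fields <- .read_tsv_fields(path)
  for (i in seq_along(fields))
    if (length(fields[[i]]) != 3)
      .stopf("line %d of '%s' has %d fields, expected 3",
             i, path, length(fields[[i]]))
  data.frame(regulator = vapply(fields, `[`, "", 1L),
             target = vapply(fields, `[`, "", 2L),
             score = as.numeric(vapply(fields, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Read a gold-standard edge list
#'
#' DREAM gold standards are three-column TSVs `regulator<TAB>target<TAB>label`
#' with label 1 for a confirmed edge and 0 for a confirmed non-edge; a
#' two-column file lists confirmed edges only (label 1 implied).
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `regulator`, `target`, `label`.
#' @export
read_gold_standard <- function(path) {
  fields <- .read_tsv_fields(path)
  n <- vapply(fields, length, 0L)
  if (!all(n %in% 2:3))
    .stopf("gold standard lines must have 2 or 3 fields (line %d has %d)",
           which(!n %in% 2:3)[1], n[!n %in% 2:3][1])
  data.frame(
    regulator = vapply(fields, `[`, "", 1L),
    target = vapply(fields, `[`, "", 2L),
    label = vapply(fields, function(f)
      if (length(f) == 3) as.numeric(f[3]) else 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Write a gold-standard edge list
#'
#' @param gold data frame with columns `regulator`, `target`, `label`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  writeLines(sprintf("%s\t%s\t%d", gold$regulator, gold$target,
                     as.integer(gold$label)), path)
  invisible(path)
}
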