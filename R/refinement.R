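#' Row-variance refinement of a score matrix
#'
#' Multiplies every row of the raw adjacency matrix by the variance of that
#' row. Rows of V hold one regulator's scores across all its potential
#' targets, computed independently in different subproblems; a regulator that
#' truly drives many targets (a hub) produces an elevated row variance, while
#' a regulator picked up only as diffuse noise produces a flat row. The
#' transform therefore up-weights rows with a strong direct-regulation
#' signature. Within a row it is a multiplication by a nonnegative constant,
#' so the ranking of targets within each row is preserved.
#'
#' The row variance is the sample variance over all off-diagonal entries of
#' the row (the structurally-zero diagonal cell is excluded; for a 2-gene
#' network a row has a single usable entry and its variance is taken as 0).
#'
#' @param V a [score_matrix()].
#' @return A [score_matrix()] at stage `"V1"`.
#' @export
variance_rescale <- function(V) {
  stopifnot(inherits(V, "ScoreMatrix"))
  s <- V$scores
  p <- nrow(s)
  v1 <- s
  for (i in seq_len(p)) {
    offdiag <- s[i, -i]
    s2 <- if (length(offdiag) > 1) var(offdiag) else 0
    v1[i, ] <- s2 * s[i, ]
  }
  diag(v1) <- 0
  score_matrix(v1, V$gene_ids, V$tf_ids, stage = "V1")
}

#' Knockout z-score refinement of a score matrix
#'
#' When knockout expression profiles are available, the score of a candidate
#' edge i -> j is rescaled by how strongly target j responded to the knockout
#' of regulator i. Over the knockout experiments (rows of E in which any gene
#' is perturbed), let alpha(i) be the experiments in which gene i itself was
#' knocked out and beta(i) the remaining knockout experiments. The edge score
#' becomes
#' \deqn{v^2_{ij} = \left| \frac{\bar e_{\alpha(i),j} - \bar e_{\beta(i),j}}
#'   {\sigma_j} \right| \cdot v^1_{ij},}
#' where \eqn{\sigma_j} is the (population) standard deviation of gene j's
#' expression over all knockout experiments: the multiplier counts how many
#' standard deviations gene j's typical expression shifted when its putative
#' regulator was removed. Rows of regulators that were never knocked out pass
#' through unchanged, as do rows with no comparison experiments
#' (empty beta). A target with constant expression across the knockouts has
#' no signal: its multiplier is defined as 0. If the perturbation matrix is
#' all zero the whole step is the identity.
#'
#' @param V1 a [score_matrix()] (typically variance-refined).
#' @param dataset the normalized [expression_dataset()] carrying `E` and `K`.
#' @return A [score_matrix()] at stage `"V2"`.
#' @export
knockout_rescale <- function(V1, dataset) {
  stopifnot(inherits(V1, "ScoreMatrix"), inherits(dataset, "ExpressionDataset"))
  if (!identical(V1$gene_ids, dataset$gene_ids))
    .stopf("score matrix and dataset carry different gene sets")
  s <- V1$scores
  K <- dataset$perturbation
  E <- dataset$expression
  ko_rows <- which(rowSums(K) > 0)
  if (length(ko_rows) == 0)
    return(score_matrix(s, V1$gene_ids, V1$tf_ids, stage = "V2"))

  Eko <- E[ko_rows, , drop = FALSE]
  Kko <- K[ko_rows, , drop = FALSE]
  # population sd of each transcript over all knockout experiments
  mu <- colMeans(Eko)
  sigma <- sqrt(colMeans(sweep(Eko, 2L, mu, "-")^2))

  v2 <- s
  p <- length(V1$gene_ids)
  for (i in seq_len(p)) {
    alpha <- which(Kko[, i] != 0)
    if (length(alpha) == 0) next             # gene i never knocked out
    beta <- which(Kko[, i] == 0)
    if (length(beta) == 0) next              # no comparison experiments
    e_alpha <- colMeans(Eko[alpha, , drop = FALSE])
    e_beta <- colMeans(Eko[beta, , drop = FALSE])
    mult <- numeric(p)
    ok <- sigma > 0
    mult[ok] <- abs(e_alpha[ok] - e_beta[ok]) / sigma[ok]
    v2[i, ] <- mult * s[i, ]
  }
  diag(v2) <- 0
  score_matrix(v2, V1$gene_ids, V1$tf_ids, stage = "V2")
}
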