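#' Build the gene-selection subproblem for one target gene
#'
#' Extracts the target vector `Y_k` and candidate-TF matrix `X_-k` for gene k:
#' columns are the eligible transcription factors excluding the target itself
#' (no self-regulation), and rows are all experiments except those in which
#' the target was itself perturbed (its expression there reflects the external
#' perturbation, not its regulators). Candidate columns are ordered
#' lexicographically by gene id so the subproblem is independent of the
#' dataset's gene order.
#'
#' @param dataset an [expression_dataset()].
#' @param target_gene gene identifier.
#' @return A list with `target_gene`, `y` (target expression over valid
#'   experiments), `x` (matrix of candidate TF expression over the same
#'   experiments), `tf_index` (map from columns of `x` to positions in
#'   `dataset$gene_ids`) and `rows` (the valid experiment indices).
#' @export
build_subproblem <- function(dataset, target_gene) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  k <- match(target_gene, dataset$gene_ids)
  if (is.na(k)) .stopf("unknown target gene '%s'", target_gene)
  rows <- which(dataset$perturbation[, k] == 0)
  if (length(rows) == 0)
    .stopf("gene '%s' is perturbed in every experiment; no valid rows remain",
           target_gene)
  tfs <- .csort(setdiff(dataset$tf_ids, target_gene))
  list(target_gene = target_gene,
       y = dataset$expression[rows, k],
       x = dataset$expression[rows, tfs, drop = FALSE],
       tf_index = match(tfs, dataset$gene_ids),
       rows = rows)
}

#' Infer a gene regulatory network
#'
#' Runs the full inference pipeline: the dataset is normalized to zero mean
#' and unit variance per gene, the P independent gene-selection subproblems
#' are solved by [boost_gene()], and their importance vectors are bound
#' column-wise into the raw adjacency matrix V (rows = regulators, columns =
#' targets). V is then refined by [variance_rescale()] and, when the
#' perturbation matrix contains any knockouts, by [knockout_rescale()].
#'
#' Each gene's boosting run uses an RNG stream derived from `config$seed` and
#' the gene's identifier, so results are identical whether genes are processed
#' serially or in parallel, and are invariant (up to the same permutation)
#' under reordering of the dataset's genes.
#'
#' @param dataset an [expression_dataset()].
#' @param config a [boosting_config()]; its `seed` drives all randomness.
#' @param var_refine apply the row-variance refinement (default `TRUE`).
#' @param ko_refine apply the knockout z-score refinement when knockout
#'   profiles are available (default `TRUE`; a no-op when `K` is all zero).
#' @param threads number of worker processes for the per-gene subproblems.
#' @return A [score_matrix()] at stage `"V"`, `"V1"` or `"V2"` depending on
#'   the refinements applied.
#' @export
infer_network <- function(dataset, config = boosting_config(),
                          var_refine = TRUE, ko_refine = TRUE, threads = 1L) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(config, "BoostingConfig"))
  if (!isTRUE(dataset$normalized)) dataset <- normalize_expression(dataset)
  genes <- dataset$gene_ids
  p <- length(genes)
  master <- if (is.null(config$seed)) 0L else config$seed

  fit_column <- function(k) {
    col <- numeric(p)
    sp <- build_subproblem(dataset, genes[k])
    if (ncol(sp$x) == 0) return(col)  # no candidate regulators
    cfg <- config
    cfg$seed <- .derive_seed(master, "gene", genes[k])
    model <- tryCatch(
      boost_gene(sp$y, sp$x, cfg),
      error = function(e) .stopf("target gene '%s': %s",
                                 genes[k], conditionMessage(e))
    )
    col[sp$tf_index] <- model$importance
    col
  }

  cols <- if (threads > 1L) {
    parallel::mclapply(seq_len(p), fit_column, mc.cores = threads)
  } else {
    lapply(seq_len(p), fit_column)
  }
  V <- matrix(unlist(cols), nrow = p, ncol = p,
              dimnames = list(genes, genes))
  diag(V) <- 0
  out <- score_matrix(V, genes, dataset$tf_ids, stage = "V")
  if (var_refine) out <- variance_rescale(out)
  if (ko_refine && any(dataset$perturbation != 0))
    out <- knockout_rescale(out, dataset)
  out
}

#' Cross-validated grid search over the sampling rates
#'
#' For every (s_s, s_f) pair on the grid, computes the mean held-out squared
#' prediction error of [boost_gene()] under k-fold cross-validation, averaged
#' over all observations across all gene-selection subproblems, and reports
#' the pair attaining the minimum. This tunes the sampling rates without ever
#' looking at a gold-standard network. Fold assignment is deterministic given
#' `seed` and depends on gene identifiers, not gene order.
#'
#' @param dataset an [expression_dataset()].
#' @param ss_grid,sf_grid numeric vectors of candidate sampling rates; the
#'   default grid is `{0.1, 0.3, 0.5, 0.7, 1}` for both.
#' @param T,nu boosting iterations and shrinkage held fixed during the search.
#' @param folds number of cross-validation folds (experiments are folded,
#'   genes are not).
#' @param seed integer seed for fold assignment and boosting.
#' @param threads worker processes across grid points.
#' @return An object of class `TuningResult`: `grid` (data frame with columns
#'   `s_s`, `s_f`, `loss`) and `best` (row of `grid` attaining minimal loss;
#'   ties go to the earliest grid point).
#' @export
grid_search_parameters <- function(dataset,
                                   ss_grid = c(0.1, 0.3, 0.5, 0.7, 1),
                                   sf_grid = c(0.1, 0.3, 0.5, 0.7, 1),
                                   T = 5000, nu = 0.001, folds = 5,
                                   seed = 1L, threads = 1L) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (nrow(dataset$expression) < folds)
    .stopf("%d folds but only %d experiments", folds, nrow(dataset$expression))
  if (!isTRUE(dataset$normalized)) dataset <- normalize_expression(dataset)
  genes <- dataset$gene_ids

  subproblems <- lapply(genes, function(g) {
    sp <- build_subproblem(dataset, g)
    if (ncol(sp$x) == 0) return(NULL)
    if (length(sp$y) < folds) return(NULL)  # too few valid rows to fold
    set.seed(.derive_seed(seed, "folds", g))
    sp$fold <- sample(rep_len(seq_len(folds), length(sp$y)))
    sp
  })
  subproblems <- Filter(Negate(is.null), subproblems)
  if (!length(subproblems)) .stopf("no foldable gene subproblem")

  grid <- expand.grid(s_s = ss_grid, s_f = sf_grid,
                      KEEP.OUT.ATTRS = FALSE)
  point_loss <- function(i) {
    ss <- grid$s_s[i]; sf <- grid$s_f[i]
    se <- 0; nobs <- 0
    for (sp in subproblems) {
      for (fd in seq_len(folds)) {
        test <- sp$fold == fd
        cfg <- boosting_config(
          T = T, nu = nu, s_s = ss, s_f = sf,
          seed = .derive_seed(seed, "cv", sp$target_gene, ss, sf, fd)
        )
        model <- boost_gene(sp$y[!test], sp$x[!test, , drop = FALSE], cfg)
        pred <- predict(model, sp$x[test, , drop = FALSE])
        se <- se + sum((sp$y[test] - pred)^2)
        nobs <- nobs + sum(test)
      }
    }
    se / nobs
  }
  losses <- if (threads > 1L) {
    unlist(parallel::mclapply(seq_len(nrow(grid)), point_loss,
                              mc.cores = threads))
  } else {
    vapply(seq_len(nrow(grid)), point_loss, 0)
  }
  grid$loss <- losses
  structure(list(grid = grid, best = grid[which.min(grid$loss), ]),
            class = "TuningResult")
}

#' @export
print.TuningResult <- function(x, ...) {
  cat(sprintf(
    "TuningResult: %d grid points; best (s_s = %g, s_f = %g), CV loss %.6g\n",
    nrow(x$grid), x$best$s_s, x$best$s_f, x$best$loss))
  invisible(x)
}

#' Stability of the inferred network across independent runs
#'
#' Re-runs [infer_network()] `runs` times with independently derived seeds and
#' computes the Spearman rank correlation between every pair of resulting
#' score matrices (on their off-diagonal entries). A high minimum correlation
#' means the randomized algorithm finds essentially the same network on every
#' execution.
#'
#' @param dataset an [expression_dataset()].
#' @param config a [boosting_config()]; `config$seed` seeds the whole
#'   experiment and per-run seeds are derived from it.
#' @param runs number of independent inference runs (>= 2).
#' @param ... passed on to [infer_network()] (e.g. refinement flags,
#'   `threads`).
#' @return The minimum pairwise Spearman correlation, with the full matrix of
#'   pairwise correlations in attribute `"pairwise"`.
#' @export
stability_check <- function(dataset, config = boosting_config(), runs = 10,
                            ...) {
  if (runs < 2) .stopf("stability_check needs at least 2 runs")
  master <- if (is.null(config$seed)) 0L else config$seed
  vecs <- lapply(seq_len(runs), function(r) {
    cfg <- config
    cfg$seed <- .derive_seed(master, "stability-run", r)
    v <- infer_network(dataset, cfg, ...)
    s <- v$scores
    s[row(s) != col(s)]
  })
  if (any(vapply(vecs, function(v) sd(v) == 0, TRUE)))
    .stopf("degenerate (constant) score matrix; correlation undefined")
  rho <- diag(1, runs)
  for (a in seq_len(runs - 1)) {
    for (b in seq((a + 1), runs)) {
      rho[a, b] <- rho[b, a] <- cor(vecs[[a]], vecs[[b]], method = "spearman")
    }
  }
  structure(min(rho), pairwise = rho)
}
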