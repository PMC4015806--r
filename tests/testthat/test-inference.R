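test_that("build_subproblem excludes the target column and its perturbed rows", {
  ds <- toy_dataset(n = 4, genes = c("G1", "G2", "G3", "G4"))
  sp <- build_subproblem(ds, "G2")
  expect_equal(ncol(sp$x), 3L)
  expect_equal(nrow(sp$x), 4L)
  expect_false("G2" %in% colnames(sp$x))
  expect_equal(sp$tf_index, match(colnames(sp$x), ds$gene_ids))

  # a knockout of the target drops that experiment from Y and X
  ko <- attach_knockouts(ds, data.frame(experiment = 1, gene = "G2"))
  sp_ko <- build_subproblem(ko, "G2")
  expect_equal(nrow(sp_ko$x), 3L)
  expect_equal(sp_ko$y, ds$expression[2:4, "G2"])
  # other genes' subproblems keep all rows
  expect_equal(nrow(build_subproblem(ko, "G1")$x), 4L)

  # no candidate TFs left: empty feature matrix, not an error
  solo <- expression_dataset(ds$expression, gene_ids = ds$gene_ids,
                             tf_ids = "G1")
  expect_equal(ncol(build_subproblem(solo, "G1")$x), 0L)

  expect_error(build_subproblem(ds, "G9"), "unknown target")
})

test_that("a gene perturbed in every experiment is rejected by name", {
  ds <- toy_dataset(n = 3, genes = c("G1", "G2"))
  ds <- attach_knockouts(ds, data.frame(experiment = 1:3,
                                        gene = rep("G1", 3)))
  expect_error(build_subproblem(ds, "G1"), "G1")
})

test_that("T = 0 inference yields an all-zero matrix", {
  ds <- toy_dataset()
  v <- infer_network(ds, boosting_config(T = 0, seed = 1))
  expect_true(all(v$scores == 0))
  expect_equal(dim(v$scores), c(4L, 4L))
})

test_that("a strong driver gene tops its target's column", {
  set.seed(2)
  n <- 60
  g1 <- rnorm(n)
  g3 <- rnorm(n)
  g2 <- 2 * g1 + rnorm(n, sd = 0.1)
  ds <- expression_dataset(cbind(G1 = g1, G2 = g2, G3 = g3))
  v <- infer_network(ds, boosting_config(T = 100, nu = 0.05, seed = 3),
                     var_refine = FALSE)
  expect_equal(which.max(v$scores[, "G2"]), c(G1 = 1L))
})

test_that("inference is deterministic and invariant to gene permutation", {
  ds <- toy_dataset(n = 15)
  cfg <- boosting_config(T = 40, seed = 21)
  v1 <- infer_network(ds, cfg)
  v2 <- infer_network(ds, cfg)
  expect_identical(v1$scores, v2$scores)

  perm <- c(3, 1, 4, 2)
  dsp <- expression_dataset(ds$expression[, perm],
                            ds$perturbation[, perm],
                            ds$gene_ids[perm], ds$tf_ids)
  vp <- infer_network(dsp, cfg)
  expect_equal(vp$scores[ds$gene_ids, ds$gene_ids], v1$scores)
})

test_that("serial and parallel runs agree bit-for-bit", {
  ds <- toy_dataset(n = 12)
  cfg <- boosting_config(T = 25, seed = 8)
  expect_identical(infer_network(ds, cfg, threads = 2L)$scores,
                   infer_network(ds, cfg, threads = 1L)$scores)
})

test_that("each column depends only on its own subproblem", {
  ds <- toy_dataset(n = 15)
  cfg <- boosting_config(T = 40, seed = 21)
  v <- infer_network(ds, cfg, var_refine = FALSE)
  sp <- build_subproblem(normalize_expression(ds), "G3")
  cfg_g <- cfg
  cfg_g$seed <- ennet:::.derive_seed(cfg$seed, "gene", "G3")
  model <- boost_gene(sp$y, sp$x, cfg_g)
  col <- numeric(4)
  col[sp$tf_index] <- model$importance
  expect_equal(unname(v$scores[, "G3"]), col)
})

test_that("non-TF rows are structurally zero when a TF list is supplied", {
  ds <- toy_dataset(n = 20)
  ds$tf_ids <- c("G1", "G2")
  v <- infer_network(ds, boosting_config(T = 30, seed = 4))
  expect_true(all(v$scores[c("G3", "G4"), ] == 0))
})

test_that("grid search returns per-point CV losses with the minimum flagged", {
  ds <- toy_dataset(n = 20)
  tr <- grid_search_parameters(ds, ss_grid = 1, sf_grid = c(0.3, 1),
                               T = 20, nu = 0.1, folds = 4, seed = 2)
  expect_equal(nrow(tr$grid), 2L)
  expect_true(all(tr$grid$loss >= 0))
  expect_equal(tr$best$loss, min(tr$grid$loss))

  one <- grid_search_parameters(ds, ss_grid = 1, sf_grid = 0.5,
                                T = 10, nu = 0.1, folds = 4, seed = 2)
  expect_equal(nrow(one$grid), 1L)
  expect_equal(unlist(one$best[c("s_s", "s_f")]), c(s_s = 1, s_f = 0.5))

  expect_error(grid_search_parameters(toy_dataset(n = 3), folds = 5), "folds")
})

test_that("CV losses are invariant to gene column order", {
  ds <- toy_dataset(n = 16)
  perm <- c(2, 4, 1, 3)
  dsp <- expression_dataset(ds$expression[, perm], ds$perturbation[, perm],
                            ds$gene_ids[perm], ds$tf_ids)
  a <- grid_search_parameters(ds, ss_grid = 1, sf_grid = 0.5,
                              T = 15, nu = 0.1, folds = 4, seed = 6)
  b <- grid_search_parameters(dsp, ss_grid = 1, sf_grid = 0.5,
                              T = 15, nu = 0.1, folds = 4, seed = 6)
  expect_equal(a$grid$loss, b$grid$loss)
})

test_that("ample sampling beats starved sampling on clean linear data", {
  set.seed(31)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, sprintf("G%d", 1:5)))
  x[, 5] <- x[, 1] - x[, 2] + x[, 3] - x[, 4]  # noiseless linear target
  ds <- expression_dataset(x)
  tr <- grid_search_parameters(ds, ss_grid = c(0.1, 1), sf_grid = c(0.1, 0.3),
                               T = 150, nu = 0.1, folds = 5, seed = 3)
  loss_rich <- tr$grid$loss[tr$grid$s_s == 1 & tr$grid$s_f == 0.3]
  loss_starved <- tr$grid$loss[tr$grid$s_s == 0.1 & tr$grid$s_f == 0.1]
  expect_lt(loss_rich, loss_starved)
})

test_that("identical seeds give perfectly correlated runs; stability errors on degenerate output", {
  ds <- toy_dataset(n = 15)
  cfg <- boosting_config(T = 30, seed = 5)
  a <- infer_network(ds, cfg)
  b <- infer_network(ds, cfg)
  off <- row(a$scores) != col(a$scores)
  expect_equal(cor(a$scores[off], b$scores[off], method = "spearman"), 1)

  expect_error(stability_check(ds, boosting_config(T = 0, seed = 1), runs = 2),
               "degenerate")
  expect_error(stability_check(ds, cfg, runs = 1), "at least 2")
})
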