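test_that("reading a minimal DREAM expression file preserves shape and order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2", "0.1\t0.2", "0.3\t0.4"), path)
  ds <- read_expression(path)
  expect_identical(ds$gene_ids, c("G1", "G2"))
  expect_equal(dim(ds), c(2L, 2L))
  expect_equal(ds$expression[, "G1"], c(0.1, 0.3))
  expect_true(all(ds$perturbation == 0))
})

test_that("malformed expression files fail with the offending line or cell named", {
  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2\tG3", "1\t2\t3", "4\t5"), ragged)
  expect_error(read_expression(ragged), "line 3")

  alpha <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2", "1\toops"), alpha)
  expect_error(read_expression(alpha), "oops")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG1", "1\t2"), dup)
  expect_error(read_expression(dup), "duplicate")
})

test_that("write-then-read round-trips expression to full float precision", {
  set.seed(7)
  ds <- toy_dataset(n = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, path)
  back <- read_expression(path)
  expect_identical(back$expression, ds$expression)
  expect_identical(back$gene_ids, ds$gene_ids)
})

test_that("attach_knockouts builds K exactly from (experiment, gene) pairs", {
  ds <- toy_dataset(n = 2, genes = c("G1", "G2"))
  # no knockout information: K stays all zero
  expect_true(all(attach_knockouts(ds, list())$perturbation == 0))

  ko <- attach_knockouts(ds, data.frame(experiment = 1, gene = "G2"))
  expect_equal(unname(ko$perturbation), rbind(c(0, 1), c(0, 0)))

  # duplicates collapse to a single 1
  dup <- attach_knockouts(ds, data.frame(experiment = c(1, 1), gene = c("G2", "G2")))
  expect_identical(dup$perturbation, ko$perturbation)

  expect_error(attach_knockouts(ds, data.frame(experiment = 1, gene = "G9")),
               "unknown gene")
  expect_error(attach_knockouts(ds, data.frame(experiment = 5, gene = "G1")),
               "out of range")
})

test_that("read_knockouts accepts both the matrix and the metadata dialect", {
  ds <- toy_dataset(n = 3, genes = c("G1", "G2"))

  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tG2", "3\tG1"), meta)
  ds_meta <- read_knockouts(meta, ds)
  expect_equal(unname(ds_meta$perturbation),
               rbind(c(0, 1), c(0, 0), c(1, 0)))

  full <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2", "0\t1", "0\t0", "1\t0"), full)
  ds_full <- read_knockouts(full, ds)
  expect_identical(ds_full$perturbation, ds_meta$perturbation)
})

test_that("normalization centres and scales each gene, zeroing constant columns", {
  E <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  ds <- normalize_expression(expression_dataset(E))
  expect_equal(ds$expression[, "a"], c(-1, 0, 1))
  expect_equal(ds$expression[, "b"], c(0, 0, 0))

  # idempotence
  twice <- normalize_expression(ds)
  expect_equal(twice$expression, ds$expression, tolerance = 1e-12)

  # every non-constant column has mean 0, sample sd 1
  ds2 <- normalize_expression(toy_dataset(n = 9))
  expect_lt(max(abs(colMeans(ds2$expression))), 1e-9)
  expect_lt(max(abs(apply(ds2$expression, 2, sd) - 1)), 1e-9)

  expect_error(normalize_expression(toy_dataset(n = 1)), "at least 2")
})

test_that("ranked edge output is sorted, tie-broken, and storage-order invariant", {
  s <- rbind(c(0, 3), c(1, 0))
  v <- score_matrix(s, c("G1", "G2"))
  edges <- ranked_edges(v)
  expect_equal(edges$regulator, c("G1", "G2"))
  expect_equal(edges$target, c("G2", "G1"))
  expect_equal(edges$score, c(3, 1))

  # all-zero matrix: P*(P-1) lines in (regulator, target) tie-break order
  z <- score_matrix(matrix(0, 3, 3), c("A", "B", "C"))
  ez <- ranked_edges(z)
  expect_equal(nrow(ez), 6L)
  expect_equal(ez$regulator, c("A", "A", "B", "B", "C", "C"))
  expect_equal(ez$target, c("B", "C", "A", "C", "A", "B"))

  # writing is a pure function of the scores: permuting genes and permuting
  # the matrix identically gives the same file content up to the same edges
  set.seed(11)
  v5 <- random_score_matrix(p = 5, seed = 3)
  perm <- sample(5)
  vperm <- score_matrix(v5$scores[perm, perm], v5$gene_ids[perm])
  e1 <- ranked_edges(v5)
  e2 <- ranked_edges(vperm)
  key <- function(e) paste(e$regulator, e$target, e$score)
  expect_setequal(key(e1), key(e2))

  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_ranked_edges(v5, path, top_k = 4)
  expect_equal(nrow(read_ranked_edges(path)), 4L)
  expect_equal(read_ranked_edges(path)$score, out$score)
  expect_error(ranked_edges(v5, top_k = 0), "positive")
})

test_that("score_matrix enforces its structural invariants", {
  expect_error(score_matrix(rbind(c(1, 2), c(3, 0)), c("A", "B")), "diagonal")
  expect_error(score_matrix(rbind(c(0, -1), c(2, 0)), c("A", "B")),
               "nonnegative")
  s <- rbind(c(0, 2), c(1, 0))
  expect_error(score_matrix(s, c("A", "B"), tf_ids = "A"), "tf_ids")
  ok <- score_matrix(rbind(c(0, 2), c(0, 0)), c("A", "B"), tf_ids = "A")
  expect_s3_class(ok, "ScoreMatrix")
})

test_that("gold standards round-trip and default omitted labels to 1", {
  gold <- data.frame(regulator = c("G1", "G2"), target = c("G2", "G3"),
                     label = c(1, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gold_standard(gold, path)
  expect_equal(read_gold_standard(path), gold)

  two_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\tG2", "G2\tG3"), two_col)
  expect_equal(read_gold_standard(two_col)$label, c(1, 1))
})
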