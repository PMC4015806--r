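#' Specification of a synthetic benchmark
#'
#' Describes a sparse, acyclic, directed regulatory network and the experiment
#' plan of the expression compendium simulated from it. The defaults define
#' the bundled 20-gene benchmark used throughout the test suite: every gene is
#' TF-eligible, edges connect roughly 10% of the admissible ordered pairs,
#' regulatory effects are five times the noise scale, and the 100 experiments
#' comprise 30 wild-type rows, one knockout row per gene and 50 multifactorial
#' rows.
#'
#' @param p number of genes (>= 2).
#' @param tf_fraction fraction of genes designated transcription factors (only
#'   TFs may be edge sources).
#' @param edge_density probability that an admissible TF -> gene pair carries
#'   an edge.
#' @param effect_size scale of the regulatory coefficients; edge weights are
#'   drawn as `sign * effect_size * U(0.5, 1.5)`.
#' @param noise_sd standard deviation of the additive noise on every regulated
#'   gene.
#' @param n_wt number of wild-type experiments.
#' @param ko genes to knock out, one experiment each: `"all"`, an integer
#'   count (a random subset of that size), a character vector of gene ids, or
#'   `0` for none.
#' @param n_mf number of multifactorial experiments (every gene receives an
#'   additional unknown perturbation; the perturbation matrix stays 0 there).
#' @param seed integer RNG seed.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(p = 20, tf_fraction = 1, edge_density = 0.1,
                           effect_size = 1, noise_sd = 0.2,
                           n_wt = 30, ko = "all", n_mf = 50, seed = 1L) {
  if (p < 2) .stopf("p must be at least 2")
  if (edge_density <= 0 || edge_density >= 1)
    .stopf("edge_density must lie in (0, 1)")
  if (noise_sd < 0) .stopf("noise_sd must be nonnegative")
  if (tf_fraction <= 0 || tf_fraction > 1)
    .stopf("tf_fraction must lie in (0, 1]")
  structure(list(p = as.integer(p), tf_fraction = tf_fraction,
                 edge_density = edge_density, effect_size = effect_size,
                 noise_sd = noise_sd, n_wt = as.integer(n_wt), ko = ko,
                 n_mf = as.integer(n_mf), seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Sample a gold-standard regulatory network
#'
#' Draws a random acyclic directed network: genes are placed in a random
#' topological order, and each admissible pair (TF source before target in
#' that order, no self-edges) carries an edge with probability
#' `spec$edge_density`. Edge weights are signed regulatory coefficients of
#' magnitude about `spec$effect_size`.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `SyntheticNetwork`: list with `edges` (data
#'   frame `regulator`, `target`, `weight`), `gene_ids`, `tf_ids` and
#'   `topo_order` (gene ids in topological order).
#' @export
sample_network <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(.derive_seed(spec$seed, "network"))
  p <- spec$p
  gene_ids <- sprintf("G%0*d", nchar(p), seq_len(p))
  n_tf <- ceiling(spec$tf_fraction * p)
  if (n_tf < 1) .stopf("no gene designated as a transcription factor")
  tf_ids <- .csort(sample(gene_ids, n_tf))
  topo <- sample(gene_ids)
  pos <- match(gene_ids, topo)

  src <- rep(gene_ids, times = p)
  tgt <- rep(gene_ids, each = p)
  admissible <- src %in% tf_ids & pos[match(src, gene_ids)] <
    pos[match(tgt, gene_ids)]
  src <- src[admissible]; tgt <- tgt[admissible]
  pick <- runif(length(src)) < spec$edge_density
  if (!any(pick))
    .stopf("edge_density %g produced an empty network; increase it",
           spec$edge_density)
  w <- sample(c(-1, 1), sum(pick), replace = TRUE) *
    spec$effect_size * runif(sum(pick), 0.5, 1.5)
  edges <- data.frame(regulator = src[pick], target = tgt[pick], weight = w,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, gene_ids = gene_ids, tf_ids = tf_ids,
                 topo_order = topo),
            class = "SyntheticNetwork")
}

#' @export
print.SyntheticNetwork <- function(x, ...) {
  cat(sprintf("SyntheticNetwork: %d genes (%d TFs), %d edges\n",
              length(x$gene_ids), length(x$tf_ids), nrow(x$edges)))
  invisible(x)
}

#' Simulate steady-state expression from a synthetic network
#'
#' Generates the expression compendium by a single topological pass per
#' experiment: genes with no regulators draw a standard-normal baseline;
#' regulated genes take the weighted sum of their regulators' values plus
#' `N(0, noise_sd)` noise. Knockout rows clamp the knocked gene to its minimal
#' wild-type expression (approximating a null allele) before propagating
#' downstream, and record a 1 in the perturbation matrix. Multifactorial rows
#' add an independent `N(0, 1)` perturbation to every gene's equation and
#' leave the perturbation matrix at 0 (the perturbations are "unknown").
#'
#' Wild-type rows come first, then knockout rows (one per knocked gene, in
#' `ko` order), then multifactorial rows.
#'
#' @param network a [sample_network()] result.
#' @param spec the [synthetic_spec()] used to build it.
#' @return An [expression_dataset()] with the matching perturbation matrix.
#' @export
simulate_expression <- function(network, spec) {
  stopifnot(inherits(network, "SyntheticNetwork"),
            inherits(spec, "SyntheticSpec"))
  set.seed(.derive_seed(spec$seed, "expression"))
  genes <- network$gene_ids
  p <- length(genes)
  topo <- network$topo_order
  parents <- lapply(genes, function(g) {
    e <- network$edges[network$edges$target == g, , drop = FALSE]
    list(reg = match(e$regulator, genes), w = e$weight)
  })
  if (anyNA(match(network$edges$regulator, genes)))
    .stopf("edge names a gene absent from the network")

  ko_genes <- spec$ko
  if (identical(ko_genes, "all")) {
    ko_genes <- genes
  } else if (is.numeric(ko_genes)) {
    ko_genes <- if (ko_genes >= 1) sort(sample(genes, ko_genes)) else character()
  }
  if (!all(ko_genes %in% genes))
    .stopf("unknown knockout gene: %s",
           paste(setdiff(ko_genes, genes), collapse = ", "))

  n <- spec$n_wt + length(ko_genes) + spec$n_mf
  if (n < 2) .stopf("experiment plan yields fewer than 2 experiments")
  E <- matrix(0, n, p, dimnames = list(NULL, genes))
  K <- matrix(0, n, p, dimnames = list(NULL, genes))
  topo_idx <- match(topo, genes)

  has_parents <- vapply(parents, function(pa) length(pa$reg) > 0, TRUE)

  simulate_row <- function(clamp_gene = NA_integer_, clamp_value = 0,
                           multifactorial = FALSE) {
    val <- numeric(p)
    # multifactorial rows shift every gene's basal activation by a random
    # amount; the shift is added to the gene's value before its children read
    # it, so it propagates downstream like a genuine perturbation
    shift <- if (multifactorial) rnorm(p) else numeric(p)
    for (j in topo_idx) {
      if (!is.na(clamp_gene) && j == clamp_gene) {
        val[j] <- clamp_value
        next
      }
      pa <- parents[[j]]
      val[j] <- if (!has_parents[j]) rnorm(1) else
        sum(pa$w * val[pa$reg]) + rnorm(1, sd = spec$noise_sd)
      val[j] <- val[j] + shift[j]
    }
    val
  }

  row <- 0L
  for (i in seq_len(spec$n_wt)) E[row <- row + 1L, ] <- simulate_row()
  wt_min <- if (spec$n_wt > 0)
    apply(E[seq_len(spec$n_wt), , drop = FALSE], 2L, min)
  else rep(-3, p)  # no wild-type reference: clamp well below baseline
  for (g in ko_genes) {
    j <- match(g, genes)
    row <- row + 1L
    E[row, ] <- simulate_row(clamp_gene = j, clamp_value = wt_min[j])
    K[row, j] <- 1
  }
  for (i in seq_len(spec$n_mf))
    E[row <- row + 1L, ] <- simulate_row(multifactorial = TRUE)

  expression_dataset(E, K, genes, network$tf_ids)
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: samples a gold-standard network and simulates its
#' expression compendium in one call.
#'
#' @param spec a [synthetic_spec()]; the defaults give the bundled 20-gene /
#'   100-experiment benchmark.
#' @return A list with `network` ([sample_network()]), `dataset`
#'   ([simulate_expression()]) and `gold` (data frame `regulator`, `target`,
#'   `label = 1` for every true edge).
#' @export
simulate_benchmark <- function(spec = synthetic_spec()) {
  network <- sample_network(spec)
  dataset <- simulate_expression(network, spec)
  gold <- data.frame(regulator = network$edges$regulator,
                     target = network$edges$target,
                     label = 1, stringsAsFactors = FALSE)
  list(network = network, dataset = dataset, gold = gold)
}
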