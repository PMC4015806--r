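# Independent brute-force oracles, kept deliberately naive.

# Enumerate every (column, midpoint) split and evaluate the least-squares
# improvement w1*w2/(w1+w2) * (g1-g2)^2 directly. Returns the maximal
# improvement and the (first) split attaining it under the (column, threshold)
# ascending tie-break.
oracle_best_stump <- function(x, r) {
  x <- as.matrix(x)
  best <- list(improvement = -Inf, feature = NA, threshold = NA)
  for (q in seq_len(ncol(x))) {
    v <- sort(unique(x[, q]))
    if (length(v) < 2) next
    for (m in (v[-length(v)] + v[-1]) / 2) {
      left <- x[, q] <= m
      w1 <- sum(left); w2 <- sum(!left)
      g1 <- mean(r[left]); g2 <- mean(r[!left])
      imp <- w1 * w2 / (w1 + w2) * (g1 - g2)^2
      if (imp > best$improvement)
        best <- list(improvement = imp, feature = q, threshold = m,
                     gamma_left = g1, gamma_right = g2)
    }
  }
  if (!is.finite(best$improvement)) best$improvement <- 0
  best
}

# Probability that a random positive outscores a random negative, ties 1/2.
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Cell-by-cell evaluation of the knockout z-score update.
oracle_knockout_rescale <- function(v1, E, K) {
  p <- ncol(v1)
  ko <- which(rowSums(K) > 0)
  if (!length(ko)) return(v1)
  out <- v1
  sigma <- apply(E[ko, , drop = FALSE], 2, function(col)
    sqrt(mean((col - mean(col))^2)))
  for (i in seq_len(p)) {
    a <- ko[K[ko, i] != 0]
    b <- ko[K[ko, i] == 0]
    if (!length(a) || !length(b)) next
    for (j in seq_len(p)) {
      m <- if (sigma[j] > 0)
        abs(mean(E[a, j]) - mean(E[b, j])) / sigma[j] else 0
      out[i, j] <- m * v1[i, j]
    }
  }
  diag(out) <- 0
  out
}

# Tiny deterministic dataset used across files.
toy_dataset <- function(n = 8, genes = c("G1", "G2", "G3", "G4"), seed = 42) {
  set.seed(seed)
  E <- matrix(rnorm(n * length(genes)), n, length(genes),
              dimnames = list(NULL, genes))
  expression_dataset(E)
}

random_score_matrix <- function(p = 5, seed = 1) {
  set.seed(seed)
  s <- matrix(abs(rnorm(p * p)), p, p)
  diag(s) <- 0
  score_matrix(s, sprintf("G%d", seq_len(p)))
}
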