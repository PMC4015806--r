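#' Evaluate a ranked network against a gold standard
#'
#' Scores a predicted network DREAM-style: the area under the
#' precision-recall curve (AUPR, step-wise integration over distinct score
#' thresholds) and the area under the ROC curve (AUROC, trapezoidal, i.e. the
#' midrank / Mann-Whitney handling of tied scores). Self-pairs are never
#' scored.
#'
#' Gold standards come in two dialects: files that list both confirmed edges
#' (label 1) and confirmed non-edges (label 0), and files that list confirmed
#' edges only. With `negatives = "listed"` only pairs present in the gold
#' standard are scored; with `negatives = "complement"` every ordered non-self
#' pair of genes absent from the gold standard counts as a negative. The
#' default `"auto"` uses `"listed"` when the gold standard contains any
#' explicit 0 labels and `"complement"` otherwise.
#'
#' @param x a [score_matrix()], or a ranked edge data frame with columns
#'   `regulator`, `target`, `score` (pairs absent from an edge list score 0).
#' @param gold data frame with columns `regulator`, `target` and optionally
#'   `label` (0/1; missing label means 1), as from [read_gold_standard()].
#' @param negatives `"auto"`, `"listed"` or `"complement"` (see Details).
#' @param gene_ids universe of genes for `"complement"` negatives; defaults to
#'   the score matrix's genes or to the genes seen in `x` and `gold`.
#' @return An object of class `EvaluationReport`: list with `aupr`, `auroc`,
#'   `n_positives`, `n_negatives`.
#' @export
evaluate_ranking <- function(x, gold,
                             negatives = c("auto", "listed", "complement"),
                             gene_ids = NULL) {
  negatives <- match.arg(negatives)
  if (!all(c("regulator", "target") %in% names(gold)))
    .stopf("gold standard needs 'regulator' and 'target' columns")
  label <- if ("label" %in% names(gold)) as.numeric(gold$label) else
    rep(1, nrow(gold))
  if (!all(label %in% c(0, 1))) .stopf("gold labels must be 0 or 1")
  gold_key <- paste(gold$regulator, gold$target, sep = "\r")
  if (anyDuplicated(gold_key)) .stopf("duplicate pair in gold standard")
  self <- gold$regulator == gold$target
  gold <- gold[!self, , drop = FALSE]; label <- label[!self]
  gold_key <- gold_key[!self]

  if (negatives == "auto")
    negatives <- if (any(label == 0)) "listed" else "complement"

  if (inherits(x, "ScoreMatrix")) {
    if (is.null(gene_ids)) gene_ids <- x$gene_ids
    lookup <- function(r, t) x$scores[cbind(match(r, x$gene_ids),
                                            match(t, x$gene_ids))]
  } else {
    if (!all(c("regulator", "target", "score") %in% names(x)))
      .stopf("edge list needs 'regulator', 'target' and 'score' columns")
    if (is.null(gene_ids))
      gene_ids <- unique(c(x$regulator, x$target, gold$regulator, gold$target))
    key <- paste(x$regulator, x$target, sep = "\r")
    lookup <- function(r, t) {
      s <- x$score[match(paste(r, t, sep = "\r"), key)]
      s[is.na(s)] <- 0  # pairs missing from the ranking score below everything listed
      s
    }
  }

  bad <- setdiff(c(gold$regulator, gold$target), gene_ids)
  if (length(bad))
    .stopf("gold standard names genes absent from the prediction: %s",
           paste(unique(bad), collapse = ", "))

  if (negatives == "listed") {
    reg <- gold$regulator; tgt <- gold$target; y <- label
  } else {
    p <- length(gene_ids)
    reg_i <- rep(seq_len(p), times = p)
    tgt_i <- rep(seq_len(p), each = p)
    keep <- reg_i != tgt_i
    reg <- gene_ids[reg_i[keep]]; tgt <- gene_ids[tgt_i[keep]]
    y <- numeric(length(reg))
    pos_key <- gold_key[label == 1]
    y[paste(reg, tgt, sep = "\r") %in% pos_key] <- 1
    # explicitly labelled non-edges stay negatives; unlabelled pairs too
  }
  scores <- lookup(reg, tgt)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0) .stopf("gold standard contains no positive edge")
  if (n_neg == 0) .stopf("gold standard contains no negative pair")

  structure(list(aupr = .aupr(scores, y), auroc = .auroc(scores, y),
                 n_positives = n_pos, n_negatives = n_neg),
            class = "EvaluationReport")
}

# Midrank (Mann-Whitney) AUROC: equals the trapezoidal area under the ROC
# curve when tied scores are swept together.
.auroc <- function(scores, y) {
  r <- rank(scores)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Step-wise AUPR: sweep distinct score thresholds from high to low, and sum
# precision * gain-in-recall at each threshold (ties enter as one block).
.aupr <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  block_end <- which(diff(s) != 0)
  block_end <- c(block_end, length(s))
  tp <- cumsum(yy)[block_end]
  n <- block_end
  recall <- tp / sum(y == 1)
  precision <- tp / n
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: AUPR %.4f, AUROC %.4f (%d positives, %d negatives)\n",
              x$aupr, x$auroc, x$n_positives, x$n_negatives))
  invisible(x)
}

#' DREAM Overall Score from per-network p-values
#'
#' Combines AUPR and AUROC p-values of the networks of one challenge:
#' \deqn{\mathrm{Overall\ Score} = -\tfrac{1}{2}
#'   \log_{10}(\bar p_{\mathrm{AUPR}} \cdot \bar p_{\mathrm{AUROC}}),}
#' where each \eqn{\bar p} is the geometric mean across networks. The
#' p-values come from the challenge organizers' empirical null ensembles and
#' are supplied by the caller; they are not computed here.
#'
#' @param p_aupr,p_auroc numeric vectors of p-values in (0, 1], one per
#'   network.
#' @return The overall score (a nonnegative real; larger is better).
#' @export
overall_score <- function(p_aupr, p_auroc) {
  for (p in list(p_aupr, p_auroc)) {
    if (!length(p) || any(is.na(p)) || any(p <= 0) || any(p > 1))
      .stopf("p-values must lie in (0, 1]")
  }
  geomean_log10 <- function(p) mean(log10(p))
  -0.5 * (geomean_log10(p_aupr) + geomean_log10(p_auroc))
}
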