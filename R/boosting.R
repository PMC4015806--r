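#' Boosting configuration
#'
#' Hyperparameters of the per-gene gradient boosting. The defaults are the
#' ones used throughout the DREAM benchmarks: `s_s = 1` (a bootstrap sample of
#' the same size as the training set at every iteration, leaving about 0.37 of
#' the rows out of bag), `s_f = 0.3` (each stump sees 30% of the candidate
#' TFs, Random-Forest style), `T = 5000` iterations and shrinkage
#' `nu = 0.001`. Smaller `nu` needs proportionally larger `T`.
#'
#' @param T number of boosting iterations (>= 0).
#' @param nu shrinkage factor in (0, 1], scaling each stump's contribution.
#' @param s_s observation sampling rate in (0, 1]: each iteration draws a
#'   bootstrap sample (with replacement) of `ceiling(s_s * N)` rows.
#' @param s_f TF sampling rate in (0, 1]: each iteration draws
#'   `ceiling(s_f * Q)` candidate TF columns without replacement.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param bag set `FALSE` to disable row resampling entirely (every iteration
#'   uses all rows); with `s_f = 1` this makes boosting fully deterministic
#'   and its training loss provably non-increasing.
#' @return An object of class `BoostingConfig`.
#' @export
boosting_config <- function(T = 5000, nu = 0.001, s_s = 1, s_f = 0.3,
                            seed = NULL, bag = TRUE) {
  if (length(T) != 1 || is.na(T) || T < 0 || T != floor(T))
    .stopf("T must be a nonnegative integer")
  for (nm in c("nu", "s_s", "s_f")) {
    v <- get(nm)
    if (length(v) != 1 || is.na(v) || v <= 0 || v > 1)
      .stopf("%s must lie in (0, 1]", nm)
  }
  structure(list(T = as.integer(T), nu = nu, s_s = s_s, s_f = s_f,
                 seed = if (!is.null(seed)) as.integer(seed),
                 bag = isTRUE(bag)),
            class = "BoostingConfig")
}

#' Fit a single regression stump
#'
#' Exhaustively searches every candidate split of every column: candidate
#' thresholds are the midpoints between consecutive distinct sorted values,
#' and the split maximising the least-squares improvement
#' \deqn{i^2 = \frac{w_1 w_2}{w_1 + w_2} (\gamma_1 - \gamma_2)^2}
#' is returned, where \eqn{w_1, w_2} count the observations falling left
#' (x <= threshold) and right of the split and \eqn{\gamma_1, \gamma_2} are
#' the residual means in the two regions. Ties are broken by lowest column
#' index, then lowest threshold. When every column is constant no split
#' exists: a degenerate stump is returned (`degenerate = TRUE`,
#' improvement 0, both response values equal to the residual mean).
#'
#' @param x_columns numeric matrix, M observations x Q candidate TF columns.
#' @param residuals numeric vector of length M (pseudo-residuals).
#' @return An object of class `StumpModel`: list with `feature` (column index,
#'   `NA` if degenerate), `threshold`, `gamma_left`, `gamma_right`,
#'   `improvement`, `degenerate`.
#' @export
fit_stump <- function(x_columns, residuals) {
  x_columns <- as.matrix(x_columns)
  if (nrow(x_columns) < 2) .stopf("fit_stump needs at least 2 observations")
  if (ncol(x_columns) < 1) .stopf("fit_stump needs at least 1 column")
  if (length(residuals) != nrow(x_columns))
    .stopf("residuals length must match rows of x_columns")
  st <- .cpp_best_stump(x_columns, as.numeric(residuals))
  degenerate <- st$feature == 0L
  structure(list(feature = if (degenerate) NA_integer_ else st$feature,
                 threshold = st$threshold,
                 gamma_left = st$gamma_left,
                 gamma_right = st$gamma_right,
                 improvement = st$improvement,
                 degenerate = degenerate),
            class = "StumpModel")
}

#' Gradient boosting of regression stumps for one target gene
#'
#' Fits the expression of one target gene as a function of candidate TF
#' expression by gradient boosting under squared-error loss. The model starts
#' at the constant `f0 = mean(target)`. Each iteration recomputes the
#' pseudo-residuals `y - f` on all rows (under squared error these are the
#' ordinary residuals), draws a bootstrap row sample of size
#' `ceiling(s_s * N)` and a without-replacement column sample of
#' `ceiling(s_f * Q)` TFs, fits the best regression stump to the sampled
#' residuals, and adds `nu` times the stump to the model. The raw (unscaled)
#' least-squares improvement of the winning TF is accumulated into that TF's
#' importance score; a TF never selected keeps importance exactly 0.
#'
#' @param target numeric vector of length N: the target gene's expression.
#' @param tf_matrix numeric N x Q matrix of candidate TF expression.
#' @param config a [boosting_config()].
#' @return An object of class `BoostedGeneModel`: list with `intercept`,
#'   `stumps` (one per iteration), `importance` (length Q), `nu`, `fitted`
#'   (final training predictions), `train_loss` (mean squared training error
#'   after each iteration) and `oob_fraction` (per-iteration fraction of rows
#'   absent from the bootstrap sample; `NA` when `bag = FALSE`).
#' @export
boost_gene <- function(target, tf_matrix, config = boosting_config()) {
  stopifnot(inherits(config, "BoostingConfig"))
  tf_matrix <- as.matrix(tf_matrix)
  n <- length(target)
  q <- ncol(tf_matrix)
  if (n < 2) .stopf("boost_gene needs at least 2 observations")
  if (q < 1) .stopf("boost_gene needs at least 1 candidate TF")
  if (nrow(tf_matrix) != n)
    .stopf("tf_matrix has %d rows but target has length %d", nrow(tf_matrix), n)
  if (!is.null(config$seed)) set.seed(config$seed)

  f0 <- mean(target)
  f <- rep(f0, n)
  importance <- numeric(q)
  stumps <- vector("list", config$T)
  train_loss <- numeric(config$T)
  oob <- rep(NA_real_, config$T)
  n_row <- ceiling(config$s_s * n)
  n_col <- ceiling(config$s_f * q)

  for (t in seq_len(config$T)) {
    r <- target - f
    if (config$bag) {
      rows <- sample.int(n, n_row, replace = TRUE)
      oob[t] <- 1 - length(unique(rows)) / n
    } else {
      rows <- seq_len(n)
    }
    cols <- if (n_col < q) sort(sample.int(q, n_col)) else seq_len(q)
    st <- .cpp_best_stump(tf_matrix[rows, cols, drop = FALSE], r[rows])
    if (st$feature > 0L) {
      j <- cols[st$feature]
      importance[j] <- importance[j] + st$improvement
      h <- ifelse(tf_matrix[, j] <= st$threshold,
                  st$gamma_left, st$gamma_right)
      stumps[[t]] <- list(feature = j, threshold = st$threshold,
                          gamma_left = st$gamma_left,
                          gamma_right = st$gamma_right,
                          improvement = st$improvement)
    } else {
      # all sampled columns constant: no split; shift by the residual mean
      h <- rep(st$gamma_left, n)
      stumps[[t]] <- list(feature = NA_integer_, threshold = NA_real_,
                          gamma_left = st$gamma_left,
                          gamma_right = st$gamma_left,
                          improvement = 0)
    }
    f <- f + config$nu * h
    train_loss[t] <- mean((target - f)^2)
  }

  structure(list(intercept = f0, stumps = stumps, importance = importance,
                 nu = config$nu, n_features = q, fitted = f,
                 train_loss = train_loss, oob_fraction = oob),
            class = "BoostedGeneModel")
}

#' @export
print.BoostedGeneModel <- function(x, ...) {
  cat(sprintf("BoostedGeneModel: %d stumps over %d candidate TFs, nu = %g\n",
              length(x$stumps), x$n_features, x$nu))
  sel <- sum(x$importance > 0)
  cat(sprintf("  TFs with nonzero importance: %d\n", sel))
  invisible(x)
}

#' Predict from a boosted gene model
#'
#' Evaluates `f0 + nu * sum_t h_t(x)` row-wise: each stump contributes its
#' left response where its feature is <= its threshold and its right response
#' elsewhere.
#'
#' @param object a [boost_gene()] model.
#' @param newdata numeric matrix with the training number of TF columns.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.BoostedGeneModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    .stopf("newdata has %d columns but the model was trained on %d",
           ncol(newdata), object$n_features)
  out <- rep(object$intercept, nrow(newdata))
  for (st in object$stumps) {
    if (is.na(st$feature)) {
      out <- out + object$nu * st$gamma_left
    } else {
      out <- out + object$nu * ifelse(newdata[, st$feature] <= st$threshold,
                                      st$gamma_left, st$gamma_right)
    }
  }
  out
}
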