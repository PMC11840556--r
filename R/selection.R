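#' Hyperparameter grid
#'
#' The default grid follows the method's search space: 100 penalty
#' strengths lambda uniform in log10 over \[-4, 3\], the 21-point mixing
#' grid gamma in \{0, 0.05, ..., 1\}, and L in \{0, 1, 2, 3\} hidden
#' layers. The hidden-unit count k is not searched; it defaults to the
#' number of labeled species (set at fit time when `k = NULL`).
#'
#' @param lambdas penalty strengths (ascending).
#' @param gammas L1/L2 mixing values in \[0, 1\].
#' @param layers hidden-layer counts, subset of 0:3.
#' @param k hidden units per hidden layer, or `NULL` for "number of
#'   labeled species".
#' @return a `gap_grid` list.
#' @export
gap_grid <- function(lambdas = 10^seq(-4, 3, length.out = 100),
                     gammas = seq(0, 1, by = 0.05),
                     layers = 0:3, k = NULL) {
  if (any(lambdas < 0)) stop_input("lambdas must be >= 0")
  if (any(gammas < 0 | gammas > 1)) stop_input("gammas must be in [0, 1]")
  if (!all(layers %in% 0:3)) stop_input("layers must be a subset of 0:3")
  structure(list(lambdas = sort(lambdas), gammas = sort(gammas),
                 layers = sort(unique(as.integer(layers))), k = k),
            class = "gap_grid")
}

#' Reduced grid for screens and benchmarks
#'
#' A deliberately smaller, clearly non-default search space (10 lambdas x
#' 5 gammas x L in \{0, 1\}, k = 4) used by the simulation benchmark and
#' useful for quick scans; the default full grid remains [gap_grid()].
#'
#' @return a `gap_grid`.
#' @export
reduced_grid <- function() {
  gap_grid(lambdas = 10^seq(-4, 3, length.out = 10),
           gammas = seq(0, 1, by = 0.25), layers = 0:1, k = 4L)
}

#' Cross-validation fold assignment
#'
#' `mode = "nfold"` gives leave-one-out folds (each labeled species its
#' own fold), the method's default for small n; `mode = "kfold"` gives a
#' seeded partition into k near-equal folds.
#'
#' @param n_labeled number of labeled species.
#' @param mode `"nfold"` (leave-one-out) or `"kfold"`.
#' @param k folds for `kfold`.
#' @param seed seed for the `kfold` shuffle.
#' @return integer vector of fold ids (1-based), length `n_labeled`.
#' @export
make_folds <- function(n_labeled, mode = c("nfold", "kfold"), k = 5L,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (n_labeled < 2L) stop_input("need at least 2 labeled species")
  if (mode == "nfold") return(seq_len(n_labeled))
  if (k > n_labeled) stop_input("k exceeds the number of labeled species")
  perm <- sample_seeded(n_labeled, seed)
  fold <- integer(n_labeled)
  fold[perm] <- rep_len(seq_len(k), n_labeled)
  fold
}

# seeded permutation that leaves the caller's RNG state untouched
sample_seeded <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Cross-validation error of one configuration
#'
#' For each fold, trains on the complement and predicts the held-out
#' species; the error is the number of misclassified species divided by
#' the number of labeled species. A fold whose training portion contains a
#' single class is kept with a warning (the network then predicts that
#' class throughout).
#'
#' @param features matrix or `gap_features` of labeled rows.
#' @param labels `yes`/`no` labels, one per row.
#' @param spec a [network_spec()].
#' @param config a [training_config()]; `config$seed` seeds each fold's
#'   initialization reproducibly.
#' @param folds integer fold ids from [make_folds()].
#' @return a `cv_result`: `cv_error`, `predicted` (per-species labels),
#'   `prob_yes`, `folds`.
#' @export
cv_error <- function(features, labels, spec, config = training_config(),
                     folds = make_folds(length(labels))) {
  X <- if (inherits(features, "gap_features")) features$values else as.matrix(features)
  y <- factor(as.character(labels), levels = c("no", "yes"))
  if (anyNA(y)) stop_input("labels must be 'yes' or 'no'")
  single <- vapply(seq_len(max(folds)), function(f)
    length(unique(y[folds != f])) < 2L, logical(1L))
  if (any(single))
    warning("fold(s) with single-class training portion: ",
            paste(which(single), collapse = ", "), call. = FALSE)
  prob <- cv_grid_probs(X, label_onehot(y), folds, spec$L, spec$k,
                        config$lambda, config$gamma, config)
  pred <- proba_to_label(prob[, 1L])
  structure(list(cv_error = mean(pred != y), predicted = stats::setNames(pred, rownames(X)),
                 prob_yes = stats::setNames(prob[, 1L], rownames(X)),
                 folds = folds, lambda = config$lambda, gamma = config$gamma,
                 L = spec$L),
            class = "cv_result")
}

# held-out P(yes) for every (lambda, gamma) cell at fixed L; n x C matrix
cv_grid_probs <- function(X, Y, folds, L, k, lambdas, gammas, config) {
  C <- length(lambdas)
  stopifnot(length(gammas) == C)
  F <- max(folds)
  # seeds keyed by hyperparameter *values*, so re-evaluating a single cell
  # reproduces its grid result exactly
  seeds <- matrix(0, C, F)
  for (ci in seq_len(C)) {
    key <- derive_seed(config$seed, "cell", L,
                       format(lambdas[ci], digits = 12),
                       format(gammas[ci], digits = 12))
    for (f in seq_len(F)) seeds[ci, f] <- derive_seed(key, "fold", f)
  }
  shuffle_seeds <- vapply(seq_len(F), function(f)
    as.numeric(derive_seed(config$seed, "shuffle", L, f)), numeric(1L))
  .cpp_cv_grid(X, Y, as.integer(folds), L, k, lambdas, gammas, seeds,
               config$epochs, config$learning_rate, config$beta1,
               config$beta2, config$batch_size, shuffle_seeds)
}

#' Grid search with cross-validation
#'
#' Evaluates the cross-validation error of every (L, lambda, gamma) cell,
#' selects the minimum, and breaks ties by the simplest adequate model:
#' minimal L first, then maximal lambda, then minimal gamma (the most
#' regularized among equals). The chosen configuration is refit on all
#' labeled rows.
#'
#' @param features matrix or `gap_features` of labeled rows.
#' @param labels `yes`/`no` labels.
#' @param grid a [gap_grid()].
#' @param cv `"nfold"` or `"kfold"`.
#' @param k_folds folds when `cv = "kfold"`.
#' @param seed master seed; per-cell seeds are derived from it so results
#'   are independent of evaluation order.
#' @param config base [training_config()] (its lambda/gamma are ignored).
#' @return a `selection_result`: `results` (data.frame of all cells),
#'   `chosen` (row of the winning cell), `classifier` (refit
#'   `trained_network`), `cv_predictions` for the chosen cell, `folds`.
#' @export
grid_search <- function(features, labels, grid = gap_grid(),
                        cv = c("nfold", "kfold"), k_folds = 5L, seed = 1L,
                        config = training_config()) {
  cv <- match.arg(cv)
  X <- if (inherits(features, "gap_features")) features$values else as.matrix(features)
  y <- factor(as.character(labels), levels = c("no", "yes"))
  n <- length(y)
  folds <- make_folds(n, mode = cv, k = k_folds,
                      seed = derive_seed(seed, "folds"))
  k <- grid$k %||% n
  cells <- expand.grid(gamma = grid$gammas, lambda = grid$lambdas,
                       KEEP.OUT.ATTRS = FALSE)
  C <- nrow(cells)
  Y <- label_onehot(y)
  res <- vector("list", length(grid$layers))
  probs <- vector("list", length(grid$layers))
  config$seed <- derive_seed(seed, "train")
  for (li in seq_along(grid$layers)) {
    L <- grid$layers[li]
    P <- cv_grid_probs(X, Y, folds, L, k, cells$lambda, cells$gamma, config)
    pred <- P > 0.5
    err <- colMeans(pred != (as.integer(y) - 1L))
    res[[li]] <- data.frame(L = L, lambda = cells$lambda,
                            gamma = cells$gamma, cv_error = err)
    probs[[li]] <- P
  }
  results <- do.call(rbind, res)
  best <- which(results$cv_error == min(results$cv_error))
  best <- best[order(results$L[best], -results$lambda[best],
                     results$gamma[best])][1L]
  chosen <- results[best, , drop = FALSE]
  li <- match(chosen$L, grid$layers)
  ci <- best - (li - 1L) * C
  prob_best <- probs[[li]][, ci]
  refit_config <- config
  refit_config$lambda <- chosen$lambda
  refit_config$gamma <- chosen$gamma
  refit_config$seed <- derive_seed(seed, "refit")
  spec <- network_spec(ncol(X), L = chosen$L, k = k)
  clf <- train_network(X, y, spec, refit_config)
  structure(list(results = results, chosen = chosen, classifier = clf,
                 cv_predictions = stats::setNames(proba_to_label(prob_best),
                                                  rownames(X)),
                 cv_prob_yes = stats::setNames(prob_best, rownames(X)),
                 folds = folds, k = k, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Grid search over", nrow(x$results), "cells\n")
  cat(sprintf("chosen: L = %d, lambda = %.4g, gamma = %.3g, CV error = %.4g\n",
              x$chosen$L, x$chosen$lambda, x$chosen$gamma, x$chosen$cv_error))
  invisible(x)
}
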