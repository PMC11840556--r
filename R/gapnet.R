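#' Fit a gap-pattern phenotype classifier
#'
#' The main entry point. Takes a multi-species alignment of one genomic
#' region, a phenotype label per species (`yes` / `no` / `unknown`) and an
#' optional rooted species tree, and fits an elastic-net-penalized dense
#' feed-forward classifier to predict the phenotype from the alignment's
#' gap pattern:
#'
#' 1. the alignment is one-hot encoded (1 = nucleotide, 0 = gap),
#'    invariant columns are removed and the rest centered (statistics
#'    computed over all species, labeled and unknown, so unknown species
#'    can be scored consistently);
#' 2. the centered matrix is reduced to the m principal components
#'    capturing at least `var_threshold` of the variance;
#' 3. when a tree is given, binary clade-membership features (one per
#'    non-root internal node) are appended;
#' 4. an (L, lambda, gamma) grid is searched by cross-validation
#'    (leave-one-out by default) and the simplest adequate model — the
#'    minimum-error cell with the fewest hidden layers — is refit on all
#'    labeled species.
#'
#' @param alignment a `gap_alignment` (see [read_alignment()]) or a path
#'   to an aligned FASTA file.
#' @param labels named phenotype factor from [read_labels()] /
#'   [make_labels()], or a path to a labels TSV. Species with label
#'   `unknown` take no part in training but are encoded, projected and
#'   predicted.
#' @param tree optional rooted species tree ([ape::phylo], Newick string
#'   or file); adds clade features.
#' @param grid hyperparameter [gap_grid()].
#' @param cv `"nfold"` (leave-one-out, default) or `"kfold"`.
#' @param k_folds folds when `cv = "kfold"`.
#' @param var_threshold PCA explained-variance threshold (default 0.95).
#' @param seed master seed for all randomness in the fit.
#' @param config base [training_config()].
#' @return an object of class `gapnet` with, among others: `selection`
#'   (all grid-cell CV errors), `cv_error` (the chosen cell's error),
#'   `classifier`, `pca`, `tree_features`, per-species CV predictions and
#'   predictions for unknown-status species. Supports `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `simulate` and `plot`.
#' @seealso [importance()], [scan_regions()], [predict.gapnet()]
#' @examples
#' aln <- new_alignment(
#'   c("sp1", "sp2", "sp3", "sp4", "sp5", "sp6"),
#'   c("ACGTACGT", "ACGTAC--", "ACG--C--", "A-GTACGT", "A-G--CGT", "ACGTACGT"))
#' lab <- make_labels(paste0("sp", 1:6),
#'                    c("yes", "yes", "no", "yes", "no", "unknown"))
#' fit <- gapnet(aln, lab, grid = gap_grid(lambdas = c(1e-4, 1), gammas = 0.5,
#'                                         layers = 0), seed = 7)
#' fit$cv_error
#' predict(fit)
#' @export
gapnet <- function(alignment, labels, tree = NULL, grid = gap_grid(),
                   cv = c("nfold", "kfold"), k_folds = 5L,
                   var_threshold = 0.95, seed = 1L,
                   config = training_config()) {
  cl <- match.call()
  cv <- match.arg(cv)
  if (is.character(alignment)) alignment <- read_alignment(alignment)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  stopifnot(inherits(alignment, "gap_alignment"))
  if (is.null(names(labels))) stop_input("labels must be named by species")

  missing <- setdiff(names(labels), alignment$species)
  if (length(missing))
    stop_input("label table species absent from alignment: ",
               paste(missing, collapse = ", "))
  lab <- factor(rep("unknown", length(alignment$species)),
                levels = c("no", "yes", "unknown"))
  names(lab) <- alignment$species
  lab[names(labels)] <- as.character(labels)
  labeled <- which(lab %in% c("no", "yes"))
  if (sum(lab == "yes") < 2L || sum(lab == "no") < 2L)
    stop_input("need at least 2 species labeled 'yes' and 2 labeled 'no'")

  gm <- encode_alignment(alignment)
  pc <- pca_reduce(gm, var_threshold = var_threshold)
  tf <- if (!is.null(tree)) encode_tree_features(tree, alignment$species)
  feats <- assemble_features(pc, tf)

  sel <- grid_search(feats$values[labeled, , drop = FALSE],
                     droplevels(lab[labeled]), grid = grid, cv = cv,
                     k_folds = k_folds, seed = seed, config = config)

  fit <- structure(list(
    call = cl, region_id = alignment$region_id,
    species = alignment$species, labels = lab, labeled = labeled,
    gap_matrix = gm, pca = pc, tree_features = tf, features = feats,
    selection = sel, chosen = sel$chosen, cv_error = sel$chosen$cv_error,
    classifier = sel$classifier,
    cv_predictions = sel$cv_predictions, cv_prob_yes = sel$cv_prob_yes,
    var_threshold = var_threshold, seed = seed, cv_mode = cv),
    class = "gapnet")
  fit
}

#' @export
print.gapnet <- function(x, ...) {
  cat("Gap-pattern phenotype classifier ('", x$region_id, "')\n", sep = "")
  n_lab <- length(x$labeled)
  cat(sprintf("  %d species (%d labeled, %d unknown); %d variable positions, m = %d PCs (%.1f%% var)%s\n",
              length(x$species), n_lab, length(x$species) - n_lab,
              ncol(x$gap_matrix$values), x$pca$m,
              100 * x$pca$explained_fraction,
              if (!is.null(x$tree_features))
                paste0(" + ", x$tree_features$t, " clade features") else ""))
  cat(sprintf("  chosen model: L = %d hidden layers, lambda = %.4g, gamma = %.3g\n",
              x$chosen$L, x$chosen$lambda, x$chosen$gamma))
  cat(sprintf("  cross-validation error: %.4g (%d of %d misclassified)\n",
              x$cv_error, round(x$cv_error * n_lab), n_lab))
  invisible(x)
}

#' @export
summary.gapnet <- function(object, ...) {
  res <- object$selection$results
  structure(list(fit = object,
                 best_by_L = do.call(rbind, lapply(split(res, res$L), function(d)
                   d[which.min(d$cv_error), ])),
                 n_cells = nrow(res)),
            class = "summary.gapnet")
}

#' @export
print.summary.gapnet <- function(x, ...) {
  print(x$fit)
  cat("\nBest cell per hidden-layer count (", x$n_cells, " cells searched):\n",
      sep = "")
  print(x$best_by_L, row.names = FALSE)
  unk <- predict(x$fit)
  if (length(unk)) {
    cat("\nPredicted phenotype for unknown-status species:\n")
    print(unk)
  }
  invisible(x)
}

#' Reconstructed per-position coefficients
#'
#' Maps the classifier's first-layer weights back from PC space to
#' alignment positions: the weight block attached to the m PC inputs is
#' premultiplied by the loading matrix, giving one coefficient vector per
#' retained alignment position (columns of width 2 for `L = 0`, k for
#' deeper models). Clade-feature weights have no alignment position and
#' are excluded.
#'
#' @param object a `gapnet` fit.
#' @param ... unused.
#' @return p x d coefficient matrix with `position_index` rownames.
#' @export
coef.gapnet <- function(object, ...) {
  reconstruct_position_weights(object)
}

#' Predict phenotype for species
#'
#' With `newdata = NULL`, returns predictions for the unknown-status
#' species of the fitted alignment (their rows were encoded and projected
#' during the fit). `newdata` may also be a `gap_alignment` (same
#' alignment coordinates: rows are re-encoded with the stored position
#' index and column means, projected onto the stored loadings, and clade
#' features are looked up when the model uses them — such species must
#' appear in the fitted tree), or a bare feature matrix.
#'
#' @param object a `gapnet` fit.
#' @param newdata `NULL`, a `gap_alignment`, or a feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param species optional subset of species to predict (for `NULL` /
#'   alignment newdata).
#' @param ... unused.
#' @return named factor of labels, or matrix of class probabilities.
#' @export
predict.gapnet <- function(object, newdata = NULL,
                           type = c("class", "prob"), species = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$features))
      stop_input("this fit carries no stored features (loaded from file?); supply newdata")
    rows <- object$features$values
    species <- species %||% object$species[object$labels == "unknown"]
    rows <- rows[match(species, object$species), , drop = FALSE]
    rownames(rows) <- species
  } else if (inherits(newdata, "gap_alignment")) {
    rows <- features_for_alignment(object, newdata, species)
  } else {
    rows <- as.matrix(newdata)
  }
  P <- predict_proba(object$classifier, rows)
  if (type == "prob") return(P)
  stats::setNames(proba_to_label(P[, "yes"]), rownames(rows))
}

# encode arbitrary alignment rows with the stored preprocessing
features_for_alignment <- function(object, aln, species = NULL) {
  stopifnot(inherits(aln, "gap_alignment"))
  species <- species %||% aln$species
  idx <- match(species, aln$species)
  if (anyNA(idx))
    stop_input("species not in alignment: ",
               paste(species[is.na(idx)], collapse = ", "))
  if (ncol(aln$seq) < max(object$pca$position_index))
    stop_input("alignment has fewer columns than the fitted region")
  x <- (aln$seq[idx, object$pca$position_index, drop = FALSE] != "-") * 1
  x <- sweep(x, 2L, object$pca$column_means)
  z <- x %*% object$pca$loadings
  rownames(z) <- species
  if (!is.null(object$tree_features)) {
    tfv <- object$tree_features$values
    miss <- setdiff(species, rownames(tfv))
    if (length(miss))
      stop_input("model uses tree features but species are not in the fitted tree: ",
                 paste(miss, collapse = ", "))
    z <- cbind(z, tfv[species, , drop = FALSE])
  }
  z
}

#' Cross-validation residuals
#'
#' Response residuals `y - p_hat` for the labeled species, where `p_hat`
#' is the held-out probability of class `yes` from the chosen model's
#' cross-validation and `y` is 1 for `yes`, 0 for `no`.
#'
#' @param object a `gapnet` fit.
#' @param ... unused.
#' @return named numeric vector.
#' @export
residuals.gapnet <- function(object, ...) {
  y <- as.integer(object$labels[object$labeled] == "yes")
  r <- y - object$cv_prob_yes
  stats::setNames(r, object$species[object$labeled])
}

#' Simulate phenotype labels from the fitted classifier
#'
#' Parametric bootstrap: draws labels for the labeled species from the
#' fitted class probabilities.
#'
#' @param object a `gapnet` fit.
#' @param nsim number of label sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame of factors, one column per simulation.
#' @export
simulate.gapnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rows <- object$features$values[object$labeled, , drop = FALSE]
  p <- predict_proba(object$classifier, rows)[, "yes"]
  out <- as.data.frame(replicate(nsim, factor(
    ifelse(stats::runif(length(p)) < p, "yes", "no"),
    levels = c("no", "yes")), simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$species[object$labeled]
  out
}

#' Plot the cross-validation error profile
#'
#' One panel per hidden-layer count L: CV error against log10(lambda),
#' one line per gamma. The chosen cell is marked.
#'
#' @param x a `gapnet` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gapnet <- function(x, ...) {
  res <- x$selection$results
  Ls <- sort(unique(res$L))
  op <- graphics::par(mfrow = c(1, length(Ls)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (L in Ls) {
    d <- res[res$L == L, ]
    wide <- stats::reshape(d[c("lambda", "gamma", "cv_error")],
                           idvar = "lambda", timevar = "gamma",
                           direction = "wide")
    graphics::matplot(log10(wide$lambda), as.matrix(wide[-1L]), type = "l",
                      lty = 1, xlab = expression(log[10](lambda)),
                      ylab = "CV error", main = paste0("L = ", L), ...)
    if (x$chosen$L == L)
      graphics::points(log10(x$chosen$lambda), x$chosen$cv_error, pch = 19)
  }
  invisible(x)
}
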