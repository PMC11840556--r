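#' Save a fitted classifier to a self-describing JSON file
#'
#' Stores the chosen architecture and weights together with every
#' preprocessing handle (retained positions, column means, PCA loadings,
#' clade features) so that [read_gapnet()] + [predict.gapnet()] work from
#' the file alone, without refitting. Grid-search results and CV
#' predictions are included for reporting.
#'
#' @param fit a [gapnet()] fit.
#' @param path output file.
#' @export
write_gapnet <- function(fit, path) {
  stopifnot(inherits(fit, "gapnet"))
  obj <- list(
    format = "gapnet-model", version = 1L,
    region_id = fit$region_id, species = fit$species,
    labels = as.character(fit$labels),
    chosen = as.list(fit$chosen),
    cv_error = fit$cv_error,
    cv_mode = fit$cv_mode, seed = fit$seed,
    var_threshold = fit$var_threshold,
    spec = unclass(fit$classifier$spec),
    config = unclass(fit$classifier$config),
    weights = list(W = lapply(fit$classifier$weights$W, mat_out),
                   b = lapply(fit$classifier$weights$b, mat_out)),
    pca = list(m = fit$pca$m,
               explained_fraction = fit$pca$explained_fraction,
               position_index = fit$pca$position_index,
               column_means = fit$pca$column_means,
               loadings = mat_out(fit$pca$loadings)),
    tree_features = if (!is.null(fit$tree_features))
      list(clade_ids = fit$tree_features$clade_ids,
           values = mat_out(fit$tree_features$values),
           species = rownames(fit$tree_features$values)),
    selection = as.list(fit$selection$results),
    cv_predictions = as.character(fit$cv_predictions))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a classifier saved by [write_gapnet()]
#'
#' Rebuilds a prediction-capable object of class `gapnet` (without the
#' encoded training matrix; refit-dependent components such as residuals
#' are unavailable).
#'
#' @param path JSON file written by [write_gapnet()].
#' @return a `gapnet` object usable with [predict.gapnet()],
#'   [coef.gapnet()] and [importance()].
#' @export
read_gapnet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "gapnet-model"))
    stop_input("not a gapnet model file: ", path)
  spec <- structure(obj$spec, class = "network_spec")
  config <- structure(obj$config, class = "training_config")
  weights <- list(W = lapply(obj$weights$W, mat_in),
                  b = lapply(obj$weights$b, mat_in))
  clf <- structure(list(spec = spec, config = config, weights = weights,
                        class_order = c("no", "yes")),
                  class = "trained_network")
  loadings <- mat_in(obj$pca$loadings)
  colnames(loadings) <- paste0("PC", seq_len(obj$pca$m))
  pca <- structure(list(m = obj$pca$m,
                        explained_fraction = obj$pca$explained_fraction,
                        position_index = as.integer(obj$pca$position_index),
                        column_means = as.numeric(obj$pca$column_means),
                        loadings = loadings, species = obj$species),
                   class = "gap_pca")
  tf <- NULL
  if (length(obj$tree_features$clade_ids)) {
    vals <- mat_in(obj$tree_features$values)
    dimnames(vals) <- list(obj$tree_features$species,
                           obj$tree_features$clade_ids)
    tf <- structure(list(values = vals,
                         clade_ids = obj$tree_features$clade_ids,
                         t = ncol(vals), c = ncol(vals) + 1L),
                    class = "gap_treefeatures")
  }
  labels <- factor(obj$labels, levels = c("no", "yes", "unknown"))
  names(labels) <- obj$species
  structure(list(call = NULL, region_id = obj$region_id,
                 species = obj$species, labels = labels,
                 labeled = which(labels != "unknown"),
                 gap_matrix = NULL, pca = pca, tree_features = tf,
                 features = NULL,
                 selection = list(results = as.data.frame(obj$selection)),
                 chosen = as.data.frame(obj$chosen),
                 cv_error = obj$cv_error, classifier = clf,
                 cv_predictions = obj$cv_predictions,
                 var_threshold = obj$var_threshold, seed = obj$seed,
                 cv_mode = obj$cv_mode),
            class = "gapnet")
}

# matrices travel through JSON as {nrow, ncol, data} with column-major data,
# so single-row / single-column shapes survive the round trip
mat_out <- function(m) list(nrow = nrow(m), ncol = ncol(m),
                            data = as.numeric(m))
mat_in <- function(o) matrix(as.numeric(o$data), nrow = o$nrow, ncol = o$ncol)
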