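#' Predict phenotype for unknown-status species
#'
#' Thin wrapper over [predict.gapnet()] that returns a tidy table for the
#' species whose label was `unknown` at fit time (or any species subset).
#'
#' @param fit a [gapnet()] fit.
#' @param species species to predict; defaults to all unknown-status
#'   species of the fit.
#' @return data.frame with `species`, `label`, `prob_yes`.
#' @export
predict_unknown <- function(fit, species = NULL) {
  stopifnot(inherits(fit, "gapnet"))
  species <- species %||% fit$species[fit$labels == "unknown"]
  if (length(species) == 0L)
    return(data.frame(species = character(0), label = character(0),
                      prob_yes = numeric(0)))
  P <- predict(fit, type = "prob", species = species)
  data.frame(species = species,
             label = as.character(proba_to_label(P[, "yes"])),
             prob_yes = unname(P[, "yes"]))
}

#' Screen genomic regions for phenotype association
#'
#' Runs the full selection pipeline independently on each region and
#' flags as candidates those whose minimum cross-validation error is at
#' or below `threshold` (default 0.1) — or, with `rule = "min"`, the
#' region(s) attaining the overall minimum error, the rule used for
#' genome-wide screens. Per-region seeds are derived from the master seed
#' and the region id, so results do not depend on the order in which
#' regions are scanned. Regions that fail (e.g. no variable columns, or
#' missing labeled species) are recorded with `failed = TRUE` and
#' excluded from the candidate set.
#'
#' @param regions a named list of `gap_alignment` objects, or a directory
#'   of FASTA files (each file one region).
#' @param labels phenotype labels (named factor or TSV path), shared
#'   across regions.
#' @param tree optional rooted species tree; adds clade features in every
#'   region model.
#' @param threshold candidate cutoff on the minimum CV error.
#' @param rule `"threshold"` (default) or `"min"`.
#' @param grid hyperparameter [gap_grid()]; screens typically use
#'   [reduced_grid()].
#' @param cv,k_folds,var_threshold,config as in [gapnet()].
#' @param seed master seed.
#' @return a `gapnet_scan` data.frame: `region_id`, `min_cv_error`, `L`,
#'   `lambda`, `gamma`, `candidate`, `failed`.
#' @export
scan_regions <- function(regions, labels, tree = NULL, threshold = 0.1,
                         rule = c("threshold", "min"), grid = reduced_grid(),
                         cv = "nfold", k_folds = 5L, var_threshold = 0.95,
                         seed = 1L, config = training_config()) {
  rule <- match.arg(rule)
  if (is.character(regions) && length(regions) == 1L && dir.exists(regions)) {
    files <- list.files(regions, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    regions <- lapply(files, read_alignment)
    names(regions) <- vapply(regions, `[[`, "", "region_id")
  }
  if (is.null(names(regions)))
    names(regions) <- paste0("region", seq_along(regions))
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)

  rows <- lapply(names(regions), function(id) {
    fit <- tryCatch(
      gapnet(regions[[id]], labels, tree = tree, grid = grid, cv = cv,
             k_folds = k_folds, var_threshold = var_threshold,
             seed = derive_seed(seed, id), config = config),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(region_id = id, min_cv_error = NA_real_,
                        L = NA_integer_, lambda = NA_real_, gamma = NA_real_,
                        candidate = FALSE, failed = TRUE,
                        message = conditionMessage(fit)))
    data.frame(region_id = id, min_cv_error = fit$cv_error,
               L = fit$chosen$L, lambda = fit$chosen$lambda,
               gamma = fit$chosen$gamma, candidate = FALSE, failed = FALSE,
               message = "")
  })
  out <- do.call(rbind, rows)
  ok <- !out$failed
  if (rule == "threshold") {
    out$candidate <- ok & out$min_cv_error <= threshold
  } else if (any(ok)) {
    out$candidate <- ok & out$min_cv_error == min(out$min_cv_error[ok])
  }
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- rule
  class(out) <- c("gapnet_scan", "data.frame")
  out
}

#' @export
print.gapnet_scan <- function(x, ...) {
  cat("Region scan: ", nrow(x), " regions, ", sum(x$candidate),
      " candidate(s) (rule = ", attr(x, "rule"), ", threshold = ",
      attr(x, "threshold"), ", ", sum(x$failed), " failed)\n", sep = "")
  print(utils::head(as.data.frame(x)[order(x$min_cv_error),
    c("region_id", "min_cv_error", "L", "lambda", "gamma", "candidate")],
    10L), row.names = FALSE)
  invisible(x)
}

#' Benchmark metrics over scanned regions
#'
#' Summarizes a scan against ground truth: the true positive rate is the
#' fraction of truly trait-associated regions called at the threshold,
#' evaluated on runs where the trait was simulated on each region's own
#' gene tree; the false positive rate is the fraction of regions called
#' when traits are replaced by random labels unrelated to the alignments.
#'
#' @param results a `gapnet_scan` (regions scanned with their associated
#'   traits).
#' @param truth logical vector, `TRUE` for regions whose trait is truly
#'   associated, aligned with `results` rows.
#' @param null_results optional `gapnet_scan` of the same regions scanned
#'   with randomized traits, from which the FPR is computed.
#' @return a `benchmark_metrics` list: `tpr`, `fpr`, `mean_cv_error`,
#'   `n_regions`, `threshold`.
#' @export
benchmark_metrics <- function(results, truth, null_results = NULL) {
  stopifnot(nrow(results) == length(truth))
  ok <- !results$failed
  assoc <- truth & ok
  if (!any(assoc)) stop_input("no associated regions: TPR undefined")
  tpr <- sum(results$candidate[assoc]) / sum(assoc)
  fpr <- if (!is.null(null_results)) {
    okn <- !null_results$failed
    sum(null_results$candidate[okn]) / sum(okn)
  } else NA_real_
  structure(list(tpr = tpr, fpr = fpr,
                 mean_cv_error = mean(results$min_cv_error[assoc]),
                 n_regions = sum(ok), threshold = attr(results, "threshold")),
            class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat(sprintf("Benchmark over %d regions (threshold %.3g):\n", x$n_regions,
              x$threshold))
  cat(sprintf("  mean CV error %.4g | TPR %.3f | FPR %s\n", x$mean_cv_error,
              x$tpr, if (is.na(x$fpr)) "NA" else sprintf("%.3f", x$fpr)))
  invisible(x)
}
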