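#' Position-importance testing
#'
#' Which alignment positions drive the classifier? The first-layer weights
#' attached to the m PC inputs are mapped back to alignment positions
#' through the PCA loadings ([reconstruct_position_weights()]), giving a
#' coefficient vector per position. Each vector is then compared with the
#' mean coefficient across positions via its squared Mahalanobis distance,
#' which under the null follows a Hotelling T-squared distribution; the
#' corresponding F statistic yields a p-value per position, adjusted by
#' Benjamini-Hochberg across positions.
#'
#' @param fit a [gapnet()] fit (or anything accepted by
#'   [reconstruct_position_weights()]).
#' @param alpha significance level applied to the adjusted p-values.
#' @param ... unused.
#' @return a `gapnet_importance` data.frame with one row per retained
#'   alignment position: `position` (original 1-based column),
#'   `coef_norm`, `T2`, `F`, `df1`, `df2`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
importance <- function(fit, alpha = 0.05, ...) UseMethod("importance")

#' @details
#' For an `L = 0` (softmax-regression) model the two reconstructed
#' coefficient columns are tested through their difference
#' (yes-minus-no logit weight, d = 1): a softmax output layer is
#' invariant to adding a constant to both logits, so the sum of the two
#' columns is unidentifiable and its across-position variation is
#' optimization noise that would otherwise dominate the Mahalanobis
#' metric. For deeper models the k first-layer columns are identifiable
#' and are tested jointly (d = k).
#'
#' @rdname importance
#' @export
importance.gapnet <- function(fit, alpha = 0.05, ...) {
  W <- reconstruct_position_weights(fit)
  if (fit$chosen$L == 0)
    W <- W[, 2L, drop = FALSE] - W[, 1L, drop = FALSE]
  ht <- mahalanobis_pvalues(W)
  p_adj <- bh_adjust(ht$p_raw)
  out <- data.frame(position = fit$pca$position_index,
                    coef_norm = sqrt(rowSums(W^2)),
                    T2 = ht$T2, F = ht$F, df1 = ht$df1, df2 = ht$df2,
                    p_raw = ht$p_raw, p_adjusted = p_adj,
                    significant = p_adj < alpha)
  attr(out, "alpha") <- alpha
  attr(out, "region_id") <- fit$region_id
  class(out) <- c("gapnet_importance", "data.frame")
  out
}

#' @export
print.gapnet_importance <- function(x, ...) {
  cat("Position importance (", nrow(x), " positions, alpha = ",
      attr(x, "alpha"), "): ", sum(x$significant),
      " significant after BH adjustment\n", sep = "")
  if (sum(x$significant))
    print(utils::head(as.data.frame(x)[order(x$p_adjusted), ], 10L),
          row.names = FALSE)
  invisible(x)
}

#' Manhattan-style plot of position importance
#'
#' -log10 adjusted p-value against alignment position; the dashed line is
#' the significance cutoff. Supplying an exon map (data.frame with
#' columns `name`, `start`, `end`; 1-based, inclusive) colors points by
#' exon.
#'
#' @param x a `gapnet_importance`.
#' @param exon_map optional exon annotation.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gapnet_importance <- function(x, exon_map = NULL, ...) {
  alpha <- attr(x, "alpha")
  col <- "grey30"
  if (!is.null(exon_map)) {
    grp <- rep(NA_integer_, nrow(x))
    for (i in seq_len(nrow(exon_map)))
      grp[x$position >= exon_map$start[i] & x$position <= exon_map$end[i]] <- i
    col <- ifelse(is.na(grp), "grey70", grp)
  }
  graphics::plot(x$position, -log10(pmax(x$p_adjusted, 1e-300)), pch = 20,
                 col = col, xlab = "alignment position",
                 ylab = expression(-log[10] ~ "adjusted p"), ...)
  graphics::abline(h = -log10(alpha), lty = 2, col = "grey50")
  invisible(x)
}

#' Map classifier weights back to alignment positions
#'
#' Multiplies the p x m loading matrix by the first-layer weight block
#' attached to the PC inputs, yielding a p x d coefficient matrix (d = 2
#' output classes for `L = 0`; d = k hidden units for deeper models).
#' Rows of the first layer that correspond to clade features are excluded
#' — they carry no alignment position.
#'
#' @param clf a `gapnet` fit, or a `trained_network` together with
#'   `loadings`.
#' @param loadings p x m loading matrix (taken from the fit when omitted).
#' @return p x d numeric matrix, rownames = original alignment columns.
#' @export
reconstruct_position_weights <- function(clf, loadings = NULL) {
  if (inherits(clf, "gapnet")) {
    loadings <- loadings %||% clf$pca$loadings
    net <- clf$classifier
    m <- clf$pca$m
    pos <- clf$pca$position_index
  } else if (inherits(clf, "trained_network")) {
    if (is.null(loadings))
      stop_input("supply the loading matrix along with a trained_network")
    net <- clf
    m <- ncol(loadings)
    pos <- rownames(loadings) %||% seq_len(nrow(loadings))
  } else stop_input("unsupported classifier object")
  W1 <- net$weights$W[[1L]]
  if (nrow(W1) < m)
    stop_input("classifier was not trained on PC features")
  W_pc <- W1[seq_len(m), , drop = FALSE] # tree-feature rows excluded
  out <- loadings %*% W_pc
  rownames(out) <- pos
  out
}

#' Hotelling T-squared p-values for coefficient vectors
#'
#' For each row w_j of the p x d coefficient matrix, computes the squared
#' Mahalanobis distance `T2_j = (w_j - wbar)' S^-1 (w_j - wbar)` to the
#' mean coefficient, with S the sample covariance (denominator p - 1)
#' across positions. Under one-sample Hotelling theory
#' `F_j = (p - d) / (d (p - 1)) * T2_j` follows an F distribution with d
#' and p - d degrees of freedom, giving an upper-tail p-value (the F
#' upper tail is inherently one-sided; no doubling). A rank-deficient S
#' falls back to the Moore-Penrose pseudo-inverse with a warning, with d
#' replaced by the rank.
#'
#' @param coefficients p x d matrix from
#'   [reconstruct_position_weights()].
#' @return list with `T2`, `F`, `p_raw`, `df1`, `df2` (each length p).
#' @export
mahalanobis_pvalues <- function(coefficients) {
  W <- as.matrix(coefficients)
  p <- nrow(W); d <- ncol(W)
  if (p <= d + 1) stop_input("need more positions than coefficient dimensions")
  ctr <- sweep(W, 2L, colMeans(W))
  S <- crossprod(ctr) / (p - 1)
  ei <- eigen(S, symmetric = TRUE)
  tol <- max(ei$values, 0) * d * .Machine$double.eps
  rank <- sum(ei$values > tol)
  if (rank < d) {
    warning("singular coefficient covariance; using pseudo-inverse (rank ",
            rank, " of ", d, ")", call. = FALSE)
  }
  if (rank == 0L) {
    T2 <- rep(0, p)
    df1 <- d
  } else {
    U <- ei$vectors[, seq_len(rank), drop = FALSE]
    inv <- U %*% (t(U) / ei$values[seq_len(rank)])
    T2 <- rowSums((ctr %*% inv) * ctr)
    df1 <- rank
  }
  df2 <- p - df1
  Fstat <- (p - df1) / (df1 * (p - 1)) * T2
  p_raw <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(T2 = T2, F = Fstat, p_raw = p_raw, df1 = df1, df2 = df2)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (capped at 1, monotone over ranks).
#'
#' @param p_raw numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_raw) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Significant positions after adjustment
#'
#' @param result a `gapnet_importance` (or data.frame with columns
#'   `position`, `p_adjusted`).
#' @param alpha significance level.
#' @return integer vector of original alignment columns with
#'   `p_adjusted < alpha`.
#' @export
significant_positions <- function(result, alpha = 0.05) {
  if (nrow(result) == 0L) return(integer(0))
  sort(result$position[result$p_adjusted < alpha])
}

#' Export an importance table as TSV
#'
#' Optionally aggregates per exon given a 1-based inclusive exon map
#' (`name`, `start`, `end`): minimum adjusted p and count of significant
#' positions per exon.
#'
#' @param x a `gapnet_importance`.
#' @param path output TSV.
#' @param exon_map optional exon annotation data.frame.
#' @export
write_importance <- function(x, path, exon_map = NULL) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exon_map)) {
    agg <- do.call(rbind, lapply(seq_len(nrow(exon_map)), function(i) {
      sel <- x$position >= exon_map$start[i] & x$position <= exon_map$end[i]
      data.frame(exon = exon_map$name[i], n_positions = sum(sel),
                 min_p_adjusted = if (any(sel)) min(x$p_adjusted[sel]) else NA,
                 n_significant = sum(x$significant[sel]))
    }))
    utils::write.table(agg, paste0(path, ".exons"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
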