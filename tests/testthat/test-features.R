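centered_gm <- function(mat) {
  aln <- new_alignment(paste0("s", seq_len(nrow(mat))),
                       apply(ifelse(mat == 1, "A", "-"), 1, paste,
                             collapse = ""))
  center_columns(filter_invariant(one_hot_gaps(aln)))
}

test_that("PCA keeps the smallest m reaching the variance threshold", {
  # rank-1 pattern: one component explains everything
  gm <- centered_gm(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 0, 1)))
  pc <- pca_reduce(gm)
  expect_equal(pc$m, 1L)
  expect_equal(pc$explained_fraction, 1.0, tolerance = 1e-12)

  expect_error(pca_reduce(gm, var_threshold = 0), "var_threshold")
  expect_error(pca_reduce(gm, var_threshold = 1.2), "var_threshold")
})

test_that("PCA agrees with a brute-force eigendecomposition", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rbinom(6 * 5, 1, 0.5), 6, 5)
    gm <- tryCatch(centered_gm(X), error = function(e) NULL)
    if (is.null(gm)) next
    pc <- pca_reduce(gm, var_threshold = 0.95)
    # oracle: eigendecomposition of the covariance computed directly
    C <- crossprod(gm$values) / (nrow(gm$values) - 1)
    ei <- eigen(C, symmetric = TRUE)
    ev <- pmax(ei$values, 0)
    m_oracle <- unname(which(cumsum(ev) / sum(ev) >= 0.95)[1])
    m_oracle <- min(m_oracle, ncol(gm$values) - 1, nrow(gm$values) - 1)
    expect_equal(pc$m, m_oracle)
    for (j in seq_len(pc$m)) {
      s_oracle <- gm$values %*% ei$vectors[, j]
      # equal up to sign
      expect_equal(abs(unname(pc$scores[, j])), abs(unname(drop(s_oracle))),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
    expect_true(pc$m < ncol(gm$values))  # m < p always
  }
})

test_that("PCA is deterministic with a fixed sign convention", {
  gm <- centered_gm(matrix(rbinom(80, 1, 0.5), 8, 10))
  pc1 <- pca_reduce(gm); pc2 <- pca_reduce(gm)
  expect_identical(pc1$loadings, pc2$loadings)
  for (j in seq_len(pc1$m)) {
    i <- which.max(abs(pc1$loadings[, j]))
    expect_gt(pc1$loadings[i, j], 0)
  }
  # loadings orthonormal
  expect_equal(crossprod(pc1$loadings), diag(pc1$m), tolerance = 1e-10,
               ignore_attr = TRUE)
  # reconstruction error bounded by the unexplained variance
  rec <- pc1$scores %*% t(pc1$loadings)
  rel <- norm(gm$values - rec, "F")^2 / norm(gm$values, "F")^2
  expect_lte(rel, 1 - pc1$explained_fraction + 1e-8)
})

test_that("row projection reproduces training scores and centers correctly", {
  gm <- centered_gm(matrix(rbinom(60, 1, 0.4), 6, 10))
  pc <- pca_reduce(gm)
  expect_equal(project_rows(pc, gm), pc$scores, tolerance = 1e-12)
  # the centering mean projects to zero
  expect_equal(drop(project_rows(pc, matrix(0, 1, nrow(pc$loadings)))),
               rep(0, pc$m), ignore_attr = TRUE)
  # held-out row: manual dot products
  new_row <- matrix(rbinom(nrow(pc$loadings), 1, 0.5), 1)
  ctr <- new_row - pc$column_means
  expect_equal(drop(project_rows(pc, ctr)),
               drop(ctr %*% pc$loadings), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(project_rows(pc, matrix(0, 1, 3)), "mismatch")
})

test_that("clade features encode non-root internal nodes", {
  tf <- encode_tree_features("((A,B),C);", c("A", "B", "C"))
  expect_equal(tf$c, 2L)
  expect_equal(tf$t, 1L)
  expect_equal(unname(tf$values[, 1]), c(1L, 1L, 0L))

  # caterpillar: nested clades checked against manual enumeration
  cat5 <- "((((A,B),C),D),E);"
  tf5 <- encode_tree_features(cat5, LETTERS[1:5])
  expect_equal(tf5$t, 3L)
  memb <- lapply(seq_len(3), function(j)
    sort(LETTERS[1:5][tf5$values[, j] == 1]))
  expect_setequal(vapply(memb, paste, "", collapse = ""),
                  c("ABCD", "ABC", "AB"))
  # nested clades satisfy subset relations; no column is all ones
  expect_true(all(colSums(tf5$values) < 5))
  expect_true(all(colSums(tf5$values) >= 1))

  # a fully resolved rooted tree with 59 tips has 58 internal nodes,
  # hence 57 informative clade features after removing the root
  big <- ape::rtree(59)
  tf59 <- encode_tree_features(big, big$tip.label)
  expect_equal(tf59$c, 58L)
  expect_equal(tf59$t, 57L)

  expect_error(encode_tree_features("((A,B),C);", c("A", "Z")), "not in tree")
  unrooted <- ape::unroot(ape::rtree(5))
  expect_error(encode_tree_features(unrooted, unrooted$tip.label), "rooted")
})

test_that("feature assembly concatenates PC and clade features", {
  gm <- centered_gm(matrix(rbinom(60, 1, 0.4), 6, 10))
  pc <- pca_reduce(gm)
  f1 <- assemble_features(pc)
  expect_equal(ncol(f1$values), pc$m)
  expect_false(f1$includes_tree)

  tree <- ape::rtree(6, tip.label = rownames(pc$scores))
  tf <- encode_tree_features(tree, rownames(pc$scores))
  f2 <- assemble_features(pc, tf)
  expect_equal(ncol(f2$values), pc$m + tf$t)
  expect_equal(f2$feature_names,
               c(paste0("PC", seq_len(pc$m)), tf$clade_ids))

  tf_bad <- tf
  rownames(tf_bad$values) <- rev(rownames(tf$values))
  expect_error(assemble_features(pc, tf_bad), "row order")
})
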