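# clearly separable 6-row feature set for leave-one-out checks
loo_toy <- function() {
  X <- rbind(c(3, 0), c(2.5, 0.4), c(2.8, -0.2),
             c(-3, 0), c(-2.6, 0.3), c(-2.9, -0.1))
  rownames(X) <- paste0("s", 1:6)
  list(X = X, y = c("yes", "yes", "yes", "no", "no", "no"))
}

test_that("fold construction covers both modes", {
  expect_equal(make_folds(34, "nfold"), 1:34)
  f10 <- make_folds(10, "kfold", k = 5, seed = 3)
  expect_equal(sort(unique(f10)), 1:5)
  expect_true(all(table(f10) == 2))
  # a seeded k-fold assignment is a true partition
  f <- make_folds(23, "kfold", k = 5, seed = 9)
  expect_equal(length(f), 23L)
  expect_equal(sort(unlist(lapply(1:5, function(k) which(f == k)))), 1:23)
  expect_error(make_folds(3, "kfold", k = 5), "exceeds")
  expect_error(make_folds(1), "at least 2")
})

test_that("cross-validation error counts misclassified species", {
  d <- loo_toy()
  cv <- cv_error(d$X, d$y, network_spec(2, L = 0),
                 training_config(lambda = 1e-4, epochs = 300, seed = 1),
                 folds = make_folds(6))
  expect_equal(cv$cv_error, 0)
  # per-fold convex refits agree with the leave-one-out predictions
  for (i in 1:6) {
    or <- suppressWarnings(
      glm((d$y[-i] == "yes") ~ d$X[-i, ], family = binomial()))
    pred <- drop(c(1, d$X[i, ]) %*% coef(or)) > 0
    expect_equal(unname(cv$predicted[i] == "yes"), pred)
  }
  # reported per-species predictions reproduce the counted error exactly
  expect_equal(cv$cv_error, mean(cv$predicted != d$y))
  # 2 of 34 misclassified gives 0.0588...
  expect_equal(2 / 34, 0.058823529, tolerance = 1e-8)
})

test_that("grid search picks the minimum and prefers the simplest model", {
  d <- loo_toy()
  cfg <- training_config(epochs = 300)
  # single-cell grid returns that cell
  g1 <- gap_grid(lambdas = 0.01, gammas = 0.5, layers = 0L)
  sel1 <- grid_search(d$X, d$y, g1, seed = 2, config = cfg)
  expect_equal(nrow(sel1$results), 1L)
  expect_equal(sel1$chosen$lambda, 0.01)

  # L=0 and L=1 both reach zero error on separable data: pick L=0
  g2 <- gap_grid(lambdas = c(1e-4), gammas = 0, layers = 0:1, k = 2L)
  sel2 <- grid_search(d$X, d$y, g2, seed = 2, config = cfg)
  expect_equal(min(sel2$results$cv_error), 0)
  expect_true(all(sel2$results$cv_error == 0))
  expect_equal(sel2$chosen$L, 0L)

  # chosen error is the grid minimum
  expect_equal(sel2$chosen$cv_error, min(sel2$results$cv_error))
})

test_that("grid cells are reproduced exactly by single-cell re-evaluation", {
  set.seed(5)
  X <- matrix(rnorm(24), 8, 3)
  y <- c(rep("yes", 4), rep("no", 4))
  cfg <- training_config(epochs = 200)
  grid <- gap_grid(lambdas = c(1e-3, 1, 100), gammas = c(0, 0.5, 1),
                   layers = 0:1, k = 2L)
  sel <- grid_search(X, y, grid, seed = 7, config = cfg)
  expect_equal(nrow(sel$results), 18L)
  # brute-force re-evaluation of every cell, one at a time
  cfg2 <- cfg
  cfg2$seed <- derive_seed(7, "train")
  for (r in sample(nrow(sel$results), 6)) {
    row <- sel$results[r, ]
    cfg_cell <- cfg2
    cfg_cell$lambda <- row$lambda
    cfg_cell$gamma <- row$gamma
    cv <- cv_error(X, y, network_spec(3, L = row$L, k = 2L), cfg_cell,
                   folds = make_folds(8))
    expect_equal(cv$cv_error, row$cv_error)
  }
  # tie-break inside equal-error cells: max lambda then min gamma
  best <- sel$results[sel$results$cv_error == min(sel$results$cv_error), ]
  best <- best[best$L == min(best$L), ]
  expect_equal(sel$chosen$lambda, max(best$lambda))
})

test_that("LOOCV error is invariant to species ordering on separated data", {
  d <- loo_toy()
  cfg <- training_config(epochs = 300)
  spec <- network_spec(2, L = 0)
  e1 <- cv_error(d$X, d$y, spec, cfg, make_folds(6))$cv_error
  perm <- c(4, 2, 6, 1, 3, 5)
  e2 <- cv_error(d$X[perm, ], d$y[perm], spec, cfg, make_folds(6))$cv_error
  expect_equal(e1, e2)
})

test_that("single-class training folds are kept with a warning", {
  X <- rbind(c(2, 0), c(-2, 0), c(-2.1, 0.1))
  y <- c("yes", "no", "no")
  expect_warning(
    cv <- cv_error(X, y, network_spec(2, L = 0),
                   training_config(epochs = 100), folds = 1:3),
    "single-class")
  expect_true(cv$cv_error >= 0 && cv$cv_error <= 1)
})
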