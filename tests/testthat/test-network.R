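# toy data used across training tests: linearly separable in 2 features
sep_data <- function() {
  X <- rbind(c(2, 0), c(1.5, 0.5), c(-2, 0), c(-1.5, -0.5))
  rownames(X) <- paste0("s", 1:4)
  list(X = X, y = c("yes", "yes", "no", "no"))
}

test_that("elastic-net penalty matches its definition", {
  expect_equal(elastic_net_penalty(c(1, -2, 3), lambda = 0, gamma = 0.7), 0)
  expect_equal(elastic_net_penalty(c(1, -2), lambda = 2, gamma = 1), 2 * 3)
  set.seed(3)
  w <- rnorm(20)
  expect_equal(elastic_net_penalty(w, lambda = 1.3, gamma = 0.5),
               1.3 * (0.5 * sum(abs(w)) + 0.25 * sum(w^2)))
  expect_error(elastic_net_penalty(w, lambda = -1, gamma = 0), "lambda")
  expect_error(elastic_net_penalty(w, lambda = 1, gamma = 2), "gamma")
})

test_that("unpenalized L=0 training matches a convex logistic oracle", {
  # noisy, non-separable data so the optimum is finite
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  y <- ifelse(runif(20) < plogis(1.5 * X[, 1]), "yes", "no")
  if (length(unique(y)) < 2) y[1:2] <- c("yes", "no")
  cfg <- training_config(lambda = 0, gamma = 0, epochs = 4000, seed = 5)
  net <- train_network(X, y, network_spec(2, L = 0), cfg)
  P <- predict_proba(net, X)
  Y <- cbind(no = as.numeric(y == "no"), yes = as.numeric(y == "yes"))
  loss_net <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
  or <- glm((y == "yes") ~ X, family = binomial())
  loss_glm <- -mean(log(ifelse(y == "yes", fitted(or), 1 - fitted(or))))
  expect_lt(abs(loss_net - loss_glm), 1e-3)
})

test_that("a separable toy set is fit perfectly without penalty", {
  d <- sep_data()
  net <- train_network(d$X, d$y, network_spec(2, L = 0),
                       training_config(lambda = 0, epochs = 500, seed = 2))
  P <- predict_proba(net, d$X)
  expect_equal(unname(ifelse(P[, "yes"] > 0.5, "yes", "no")), d$y)
})

test_that("an overwhelming penalty collapses predictions to the class prior", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3)
  y <- c(rep("yes", 14), rep("no", 6))
  net <- train_network(X, y, network_spec(3, L = 0),
                       training_config(lambda = 1e3, gamma = 0.5,
                                       epochs = 2000, seed = 4))
  P <- predict_proba(net, X)
  # intercept-only oracle: every row predicted at the training prior
  expect_equal(unname(P[, "yes"]), rep(0.7, 20), tolerance = 0.02)
})

test_that("forward pass is a softmax and matches manual computation", {
  # zero-weight network: both classes at exactly one half
  spec <- network_spec(3, L = 0)
  net <- structure(list(spec = spec, config = training_config(),
                        weights = list(W = list(matrix(0, 3, 2)),
                                       b = list(matrix(0, 1, 2))),
                        class_order = c("no", "yes")),
                   class = "trained_network")
  P <- predict_proba(net, matrix(rnorm(9), 3, 3))
  expect_equal(unname(P), matrix(0.5, 3, 2))

  # random small L=1 network against an explicit forward pass
  set.seed(14)
  W1 <- matrix(rnorm(6), 3, 2); b1 <- matrix(rnorm(2), 1)
  W2 <- matrix(rnorm(4), 2, 2); b2 <- matrix(rnorm(2), 1)
  net1 <- structure(list(spec = network_spec(3, L = 1, k = 2),
                         config = training_config(),
                         weights = list(W = list(W1, W2), b = list(b1, b2)),
                         class_order = c("no", "yes")),
                    class = "trained_network")
  X <- matrix(rnorm(15), 5, 3)
  H <- pmax(X %*% W1 + rep(b1, each = 5), 0)
  Z <- H %*% W2 + rep(b2, each = 5)
  Pm <- exp(Z) / rowSums(exp(Z))
  expect_equal(unname(predict_proba(net1, X)), unname(Pm), tolerance = 1e-6)
  expect_equal(rowSums(predict_proba(net1, X)), rep(1, 5), tolerance = 1e-9)
})

test_that("total absolute weight shrinks as lambda grows", {
  set.seed(31)
  X <- matrix(rnorm(60), 20, 3)
  y <- ifelse(X[, 1] + rnorm(20, sd = 0.5) > 0, "yes", "no")
  if (length(unique(y)) < 2) y[1:2] <- c("yes", "no")
  sums <- vapply(c(0, 0.1, 1, 10, 100), function(lam) {
    net <- train_network(X, y, network_spec(3, L = 0),
                         training_config(lambda = lam, gamma = 0.5,
                                         epochs = 600, seed = 8))
    sum(abs(unlist(net$weights$W)))
  }, numeric(1))
  # allow small stochastic wiggle between neighbours
  expect_true(all(diff(sums) < 0.05))
  expect_lt(sums[length(sums)], sums[1])
})

test_that("training is deterministic and validates inputs", {
  d <- sep_data()
  cfg <- training_config(epochs = 120, seed = 77)
  n1 <- train_network(d$X, d$y, network_spec(2, L = 1, k = 3), cfg)
  n2 <- train_network(d$X, d$y, network_spec(2, L = 1, k = 3), cfg)
  expect_identical(n1$weights, n2$weights)

  expect_error(train_network(d$X, rep("yes", 4), network_spec(2)),
               "single-class")
  bad <- d$X; bad[1, 1] <- NA
  expect_error(train_network(bad, d$y, network_spec(2)), "non-finite")
  expect_error(train_network(d$X, d$y, network_spec(5)), "does not match")
  expect_error(network_spec(2, L = 4), "L must be")
  expect_error(training_config(gamma = 1.5), "gamma")
})
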