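#' Network architecture specification
#'
#' Describes the dense feed-forward classifier: an identity input layer of
#' width `n_inputs`, `L` hidden ReLU layers of `k` units each, and a
#' 2-class softmax output. With `L = 0` the network reduces to a linear
#' model with logistic (softmax) regression.
#'
#' @param n_inputs number of input features (m, or m + t with tree
#'   features).
#' @param L number of hidden layers, one of 0, 1, 2, 3.
#' @param k hidden units per hidden layer (ignored when `L = 0`).
#' @return a `network_spec` list.
#' @export
network_spec <- function(n_inputs, L = 0L, k = 1L) {
  if (!L %in% 0:3) stop_input("L must be one of 0, 1, 2, 3")
  if (L >= 1 && k < 1) stop_input("k must be >= 1 when L >= 1")
  structure(list(n_inputs = as.integer(n_inputs), L = as.integer(L),
                 k = as.integer(k), K = 2L),
            class = "network_spec")
}

#' Training configuration
#'
#' Adam optimizer settings and the elastic-net penalty. Defaults follow
#' the method's standard schedule: learning rate 1e-2, momentum decays
#' 0.9/0.999, mini-batches of 33 rows (clipped to the training-set size,
#' so leave-one-out training on 34 species is full-batch) for 500 epochs.
#'
#' @param lambda penalty strength, >= 0.
#' @param gamma L1/L2 mixing in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param seed integer seed for weight initialization and shuffling.
#' @return a `training_config` list.
#' @export
training_config <- function(lambda = 0, gamma = 0, learning_rate = 1e-2,
                            beta1 = 0.9, beta2 = 0.999, batch_size = 33L,
                            epochs = 500L, seed = 1L) {
  if (lambda < 0) stop_input("lambda must be >= 0")
  if (gamma < 0 || gamma > 1) stop_input("gamma must be in [0, 1]")
  structure(list(lambda = lambda, gamma = gamma,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' Elastic-net penalty of a weight set
#'
#' `lambda * (gamma * sum(|w|) + (1 - gamma) / 2 * sum(w^2))` over all
#' connection weights; biases are excluded.
#'
#' @param weights a list with elements `W` (list of weight matrices) and
#'   `b` (biases, ignored), or a plain numeric vector/matrix of weights.
#' @param lambda penalty strength >= 0.
#' @param gamma L1/L2 mixing in \[0, 1\].
#' @return the scalar penalty.
#' @export
elastic_net_penalty <- function(weights, lambda, gamma) {
  if (lambda < 0) stop_input("lambda must be >= 0")
  if (gamma < 0 || gamma > 1) stop_input("gamma must be in [0, 1]")
  w <- if (is.list(weights)) unlist(weights$W %||% weights) else weights
  lambda * (gamma * sum(abs(w)) + (1 - gamma) / 2 * sum(w^2))
}

label_onehot <- function(labels) {
  # class order (no, yes)
  y <- as.character(labels)
  cbind(no = as.numeric(y == "no"), yes = as.numeric(y == "yes"))
}

#' Train the elastic-net feed-forward classifier
#'
#' Minimizes mean binary cross-entropy plus the elastic-net penalty with
#' the Adam optimizer. Deterministic given `config$seed`: weight
#' initialization and any mini-batch shuffling come from a dedicated
#' seeded stream, not from R's RNG.
#'
#' @param features numeric matrix (rows = labeled species) or a
#'   `gap_features` object.
#' @param labels factor/character over `yes` / `no`, one per row.
#' @param spec a [network_spec()].
#' @param config a [training_config()].
#' @return a `trained_network`: `spec`, `config`, `weights` (list `W`, `b`
#'   per layer).
#' @export
train_network <- function(features, labels, spec, config = training_config()) {
  X <- if (inherits(features, "gap_features")) features$values else as.matrix(features)
  y <- as.character(labels)
  if (nrow(X) != length(y)) stop_input("features and labels differ in length")
  if (nrow(X) < 2L) stop_input("need at least 2 labeled rows")
  if (length(unique(y)) < 2L)
    stop_input("single-class training set: both 'yes' and 'no' are required")
  if (!all(is.finite(X))) stop_input("non-finite feature values")
  if (ncol(X) != spec$n_inputs)
    stop_input("feature count ", ncol(X), " does not match spec n_inputs ",
               spec$n_inputs)
  Y <- label_onehot(y)
  net <- .cpp_train_cells(X, Y, spec$L, spec$k, config$lambda, config$gamma,
                          as.numeric(config$seed), config$epochs,
                          config$learning_rate, config$beta1, config$beta2,
                          config$batch_size,
                          as.numeric(derive_seed(config$seed, "shuffle")))[[1L]]
  if (!all(vapply(net$W, function(w) all(is.finite(w)), logical(1L))))
    stop("training diverged: non-finite weights", call. = FALSE)
  structure(list(spec = spec, config = config, weights = net,
                 class_order = c("no", "yes")),
            class = "trained_network")
}

#' Class probabilities from a trained network
#'
#' Forward pass ending in a softmax, so each row's two probabilities are
#' nonnegative and sum to one. Column order is (`no`, `yes`).
#'
#' @param net a `trained_network` (or the final classifier inside a
#'   [gapnet()] fit).
#' @param rows feature matrix or `gap_features` with
#'   `ncol == spec$n_inputs`.
#' @return rows x 2 matrix of class probabilities.
#' @export
predict_proba <- function(net, rows) {
  stopifnot(inherits(net, "trained_network"))
  X <- if (inherits(rows, "gap_features")) rows$values else as.matrix(rows)
  if (ncol(X) != net$spec$n_inputs)
    stop_input("feature count ", ncol(X), " does not match network input ",
               net$spec$n_inputs)
  P <- .cpp_forward(net$weights, X, net$spec$L)
  colnames(P) <- net$class_order
  rownames(P) <- rownames(X)
  P
}

# argmax labels with deterministic ties toward "no"
proba_to_label <- function(prob_yes) {
  factor(ifelse(prob_yes > 0.5, "yes", "no"), levels = c("no", "yes"))
}
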