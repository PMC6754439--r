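# Feed-forward neural network for pair classification, trained by
# mini-batch stochastic gradient descent with momentum. Written directly on
# base-R matrix operations (BLAS-backed): forward pass, inverted dropout,
# binary cross-entropy gradient, momentum updates.

#' Neural network configuration
#'
#' Defaults reproduce the published pair classifier: two hidden layers of
#' 300 and 400 rectifier units, dropout 0.5 after each hidden layer, a
#' sigmoid output unit, binary cross-entropy loss, SGD with momentum 0.9,
#' batch size 200, weights initialized N(0, 0.05^2) and biases uniform on
#' (-1, 0). The epoch count is dataset-dependent (20 suits dense
#' benchmarks of the DS1 scale; 50 is the default for smaller or sparser
#' data). The learning rate is not pinned down by the original description;
#' 0.01 is the conventional SGD+momentum setting and is configurable.
#'
#' @param hidden Integer vector of hidden layer sizes.
#' @param activation Hidden activation: `"relu"`, `"tanh"` or `"sigmoid"`.
#' @param dropout Dropout rate per hidden layer in `[0, 1)`.
#' @param learning_rate Positive SGD step size.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training data (>= 1).
#' @param sd_init Standard deviation of the normal weight initialization.
#' @param bias_init `"uniform_neg"` for uniform (-1, 0) biases (as
#'   published) or `"zero"`.
#' @param seed Integer seed controlling initialization, dropout and batch
#'   shuffling.
#' @return List of class `nn_config`.
#' @export
nn_config <- function(hidden = c(300L, 400L), activation = "relu",
                      dropout = 0.5, learning_rate = 0.01, momentum = 0.9,
                      batch_size = 200L, epochs = 50L, sd_init = 0.05,
                      bias_init = c("uniform_neg", "zero"), seed = 1L) {
  activation <- match.arg(activation, c("relu", "tanh", "sigmoid"))
  bias_init <- match.arg(bias_init)
  stopifnot(length(hidden) >= 1L, all(hidden >= 1),
            dropout >= 0, dropout < 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, epochs >= 1, sd_init > 0)
  structure(list(hidden = as.integer(hidden), activation = activation,
                 dropout = dropout, learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), sd_init = sd_init,
                 bias_init = bias_init, seed = as.integer(seed)),
            class = "nn_config")
}

.act <- function(z, kind) {
  switch(kind,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)))
}

# derivative as a function of the activation output
.act_grad <- function(a, kind) {
  switch(kind,
         relu = (a > 0) + 0,
         tanh = 1 - a * a,
         sigmoid = a * (1 - a))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# add a bias row-vector to every row of a matrix
.add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' Train the pair-classification network
#'
#' Architecture (for the default two hidden layers): dense(h1) ->
#' activation -> dropout -> dense(h2) -> activation -> dropout ->
#' dense(1) -> sigmoid, minimizing binary cross-entropy by mini-batch SGD
#' with momentum. Dropout is inverted (activations rescaled at training
#' time) and disabled at prediction time. Training is deterministic given
#' `config$seed`.
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param y Binary 0/1 label vector; both classes must be present.
#' @param config An [nn_config()].
#' @param standardize Center and scale each feature column to unit
#'   variance before training (default TRUE), storing the transform in
#'   the model so prediction applies it automatically. Fused similarity
#'   rows live on a 1/m scale; without standardization the published
#'   negative bias initialization leaves rectifier units with no
#'   positive pre-activations and hence no gradient signal.
#' @return Object of class `ddi_mlp`: layer weights `W`, biases `b`, the
#'   config, `input_dim` and the per-epoch mean training loss
#'   `loss_history`.
#' @export
mlp_train <- function(x, y, config = nn_config(), standardize = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y disagree on sample count")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training data contain a single class; both classes are required")
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  } else {
    center <- numeric(ncol(x))
    scale <- rep(1, ncol(x))
  }
  set.seed(config$seed)
  d <- ncol(x)
  sizes <- c(d, config$hidden, 1L)
  L <- length(sizes) - 1L               # number of weight layers
  W <- vector("list", L); b <- vector("list", L)
  vW <- vector("list", L); vb <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, config$sd_init),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- if (config$bias_init == "uniform_neg")
      stats::runif(sizes[l + 1L], -1, 0) else numeric(sizes[l + 1L])
    vW[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
    vb[[l]] <- numeric(sizes[l + 1L])
  }
  n <- nrow(x)
  lr <- config$learning_rate; mu <- config$momentum
  keep <- 1 - config$dropout
  eps <- 1e-12
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      nb <- length(idx)
      # forward
      A <- vector("list", L)            # activations per layer
      M <- vector("list", L - 1L)       # dropout masks for hidden layers
      a <- xb
      for (l in seq_len(L - 1L)) {
        a <- .act(.add_bias(a %*% W[[l]], b[[l]]), config$activation)
        if (config$dropout > 0) {
          M[[l]] <- matrix(stats::runif(nb * ncol(a)) < keep, nb) / keep
          a <- a * M[[l]]
        }
        A[[l]] <- a
      }
      p <- .sigmoid(.add_bias(a %*% W[[L]], b[[L]]))
      p <- pmin(pmax(p, eps), 1 - eps)
      ep_loss <- ep_loss - sum(yb * log(p) + (1 - yb) * log(1 - p))
      # backward: BCE + sigmoid gives output delta (p - y) / nb
      delta <- (p - yb) / nb
      for (l in rev(seq_len(L))) {
        a_prev <- if (l == 1L) xb else A[[l - 1L]]
        gW <- crossprod(a_prev, delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) *
            .act_grad(A[[l - 1L]], config$activation)
          if (config$dropout > 0) delta <- delta * M[[l - 1L]]
        }
        vW[[l]] <- mu * vW[[l]] - lr * gW
        vb[[l]] <- mu * vb[[l]] - lr * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    loss_history[epoch] <- ep_loss / n
  }
  structure(list(W = W, b = b, config = config, input_dim = d,
                 center = center, scale = scale,
                 loss_history = loss_history),
            class = "ddi_mlp")
}

#' Predict interaction probabilities
#'
#' Forward pass with dropout disabled; repeated calls on the same model and
#' inputs are identical. Scores are clamped to lie strictly in (0, 1).
#'
#' @param model A trained [mlp_train()] model.
#' @param x Feature matrix with `model$input_dim` columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
mlp_predict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$input_dim)
    stop("feature dimension ", ncol(x), " does not match model input_dim ",
         model$input_dim)
  L <- length(model$W)
  a <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  for (l in seq_len(L - 1L))
    a <- .act(.add_bias(a %*% model$W[[l]], model$b[[l]]),
              model$config$activation)
  p <- .sigmoid(.add_bias(a %*% model$W[[L]], model$b[[L]]))
  eps <- 1e-12
  as.numeric(pmin(pmax(p, eps), 1 - eps))
}

#' @export
print.ddi_mlp <- function(x, ...) {
  cat("Feed-forward pair classifier:", x$input_dim, "->",
      paste(x$config$hidden, collapse = " -> "), "-> 1\n")
  cat("  activation:", x$config$activation,
      " dropout:", x$config$dropout,
      " epochs:", x$config$epochs, "\n")
  cat("  final training loss:",
      format(utils::tail(x$loss_history, 1), digits = 4), "\n")
  invisible(x)
}

#' Save / load a trained model as JSON
#'
#' Self-describing plain-text archive holding the weights, biases, config
#' and input dimension.
#'
#' @param model A `ddi_mlp` model.
#' @param path File path.
#' @return `mlp_save` returns `path` invisibly; `mlp_load` the model.
#' @export
mlp_save <- function(model, path) {
  obj <- list(W = lapply(model$W, function(w) list(dim = dim(w),
                                                   data = as.numeric(w))),
              b = model$b,
              config = unclass(model$config),
              input_dim = model$input_dim,
              center = model$center, scale = model$scale,
              loss_history = model$loss_history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mlp_save
#' @export
mlp_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  W <- vector("list", length(obj$b))
  for (l in seq_along(W))
    W[[l]] <- matrix(obj$W[[l]]$data, obj$W[[l]]$dim[1], obj$W[[l]]$dim[2])
  cfg <- do.call(nn_config, obj$config)
  structure(list(W = W, b = lapply(obj$b, as.numeric), config = cfg,
                 input_dim = obj$input_dim,
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 loss_history = obj$loss_history),
            class = "ddi_mlp")
}
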