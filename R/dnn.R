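# Feed-forward binary classifier trained by backpropagation: four hidden
# layers (64, 32, 16, 8 neurons by default), ReLU or tanh hidden activations,
# sigmoid output, binary cross-entropy loss with an L2 weight penalty,
# inverted dropout on hidden activations, He-uniform initialization and the
# Adam optimizer. Everything is seeded and deterministic for a fixed
# configuration.

#' Deep network configuration
#'
#' @param hidden_sizes neurons per hidden layer, default `c(64, 32, 16, 8)`.
#' @param hidden_activation `"relu"` (default) or `"tanh"`.
#' @param dropout_rate dropout probability on hidden activations during
#'   training, in `[0, 1)`. Default 0.4.
#' @param l2_lambda L2 weight-penalty coefficient. Default 1e-4.
#' @param learning_rate Adam step size. Default 0.01.
#' @param epochs training epochs. Default 700.
#' @param batch_size mini-batch size. Default 32.
#' @param seed integer RNG seed for initialization, shuffling and dropout.
#'   Default 1234.
#' @return object of class `dnn_config`. The output activation is always
#'   sigmoid and the optimizer is always Adam.
#' @export
dnn_config <- function(hidden_sizes = c(64L, 32L, 16L, 8L),
                       hidden_activation = c("relu", "tanh"),
                       dropout_rate = 0.4,
                       l2_lambda = 1e-4,
                       learning_rate = 0.01,
                       epochs = 700L,
                       batch_size = 32L,
                       seed = 1234L) {
  hidden_activation <- match.arg(hidden_activation)
  stopifnot(length(hidden_sizes) >= 1L, all(hidden_sizes >= 1L),
            dropout_rate >= 0, dropout_rate < 1,
            l2_lambda >= 0, learning_rate > 0,
            epochs >= 1L, batch_size >= 1L)
  structure(list(
    hidden_sizes = as.integer(hidden_sizes),
    hidden_activation = hidden_activation,
    output_activation = "sigmoid",
    dropout_rate = dropout_rate,
    l2_lambda = l2_lambda,
    learning_rate = learning_rate,
    optimizer = "adam",
    weight_init = "he_uniform",
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "dnn_config")
}

#' @export
print.dnn_config <- function(x, ...) {
  cat(sprintf(
    "<dnn_config> hidden [%s] %s | dropout %.2g, L2 %.2g, lr %.3g, %d epochs, batch %d, seed %d\n",
    paste(x$hidden_sizes, collapse = ","), x$hidden_activation,
    x$dropout_rate, x$l2_lambda, x$learning_rate, x$epochs, x$batch_size,
    x$seed))
  invisible(x)
}

activation_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z) (z > 0) * 1),
         tanh = list(f = tanh,
                     df = function(z) 1 - tanh(z)^2),
         stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

he_uniform_init <- function(fan_in, fan_out) {
  limit <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

as_feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) {
    list(x = features$values, names = features$feature_names)
  } else {
    x <- as.matrix(features)
    list(x = x, names = colnames(x))
  }
}

#' Train the feed-forward 5hmC classifier
#'
#' Minimizes binary cross-entropy (plus an L2 weight penalty) with Adam over
#' shuffled mini-batches. Inputs are standardized column-wise on training
#' statistics (stored in the model and re-applied at prediction time), since
#' principal-component scores arrive with strongly unequal variances.
#' Inverted dropout is applied to hidden activations during training only.
#' Fully reproducible for a fixed seed: the caller's RNG state is left
#' untouched.
#'
#' @param features a `feature_matrix` (or plain numeric matrix with column
#'   names), rows = samples.
#' @param labels binary 0/1 vector, one per row; both classes required.
#' @param cfg a `dnn_config`.
#' @return object of class `dnn_model`: `config`, `weights` (list of `W`,
#'   `b` per layer), `feature_names`, `training_history` (mean training loss
#'   per epoch, length `cfg$epochs`).
#' @export
train_dnn <- function(features, labels, cfg = dnn_config()) {
  fv <- as_feature_values(features)
  x <- fv$x
  y <- as.numeric(labels)
  if (nrow(x) != length(y)) stop("rows must equal number of labels", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)

  # standardize inputs on training statistics: the PCA scores fed to the
  # network have strongly unequal per-column variances, which a fixed
  # learning rate handles poorly
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  x <- sweep(sweep(x, 2L, center), 2L, scale_, "/")

  sizes <- c(ncol(x), cfg$hidden_sizes, 1L)
  n_layers <- length(sizes) - 1L
  act <- activation_fun(cfg$hidden_activation)
  n <- nrow(x)
  keep <- 1 - cfg$dropout_rate

  with_local_seed(cfg$seed, {
    W <- lapply(seq_len(n_layers),
                function(i) he_uniform_init(sizes[i], sizes[i + 1L]))
    b <- lapply(seq_len(n_layers), function(i) numeric(sizes[i + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x0) x0 * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    history <- numeric(cfg$epochs)

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)

        # forward with inverted dropout on hidden activations
        a <- xb
        zs <- vector("list", n_layers)
        as_ <- vector("list", n_layers + 1L)
        masks <- vector("list", n_layers)
        as_[[1L]] <- a
        for (l in seq_len(n_layers)) {
          z <- a %*% W[[l]] + rep(b[[l]], each = m)
          zs[[l]] <- z
          if (l < n_layers) {
            a <- act$f(z)
            if (cfg$dropout_rate > 0) {
              mask <- matrix(stats::runif(length(a)) < keep,
                             nrow(a), ncol(a)) / keep
              a <- a * mask
              masks[[l]] <- mask
            }
          } else {
            a <- sigmoid(z)
          }
          as_[[l + 1L]] <- a
        }
        p <- pmin(pmax(as.vector(a), 1e-12), 1 - 1e-12)
        data_loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        l2_loss <- cfg$l2_lambda / 2 * sum(vapply(W, function(w) sum(w^2),
                                                  numeric(1)))
        epoch_loss <- epoch_loss + (data_loss + l2_loss) * m

        # backward: sigmoid + BCE collapse to (p - y)/m at the output
        delta <- matrix((p - yb) / m, m, 1L)
        for (l in rev(seq_len(n_layers))) {
          gW <- crossprod(as_[[l]], delta) + cfg$l2_lambda * W[[l]]
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            delta <- delta * act$df(zs[[l - 1L]])
            if (cfg$dropout_rate > 0) delta <- delta * masks[[l - 1L]]
          }
          t_hat <- t_step + 1L  # shared step counter updated after the loop
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          W[[l]] <- W[[l]] - cfg$learning_rate *
            (mW[[l]] / (1 - beta1^t_hat)) /
            (sqrt(vW[[l]] / (1 - beta2^t_hat)) + eps)
          b[[l]] <- b[[l]] - cfg$learning_rate *
            (mb[[l]] / (1 - beta1^t_hat)) /
            (sqrt(vb[[l]] / (1 - beta2^t_hat)) + eps)
        }
        t_step <- t_step + 1L
      }
      history[epoch] <- epoch_loss / n
    }
  })

  structure(list(
    config = cfg,
    weights = lapply(seq_len(n_layers), function(l) list(W = W[[l]], b = b[[l]])),
    feature_names = fv$names,
    center = center,
    scale = scale_,
    training_history = history
  ), class = "dnn_model")
}

#' @export
print.dnn_model <- function(x, ...) {
  cat(sprintf("<dnn_model> %d -> %s -> 1 (%s), final training loss %.4g\n",
              length(x$feature_names),
              paste(x$config$hidden_sizes, collapse = " -> "),
              x$config$hidden_activation,
              utils::tail(x$training_history, 1)))
  invisible(x)
}

#' Predict 5hmC probabilities
#'
#' Deterministic forward pass (dropout disabled); one sigmoid output per row.
#'
#' @param model a `dnn_model`.
#' @param features a `feature_matrix` or numeric matrix whose columns match
#'   the model's feature schema.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "dnn_model"))
  fv <- as_feature_values(features)
  if (!identical(fv$names, model$feature_names)) {
    if (is.null(fv$names) || !setequal(fv$names, model$feature_names)) {
      stop("feature schema does not match the model", call. = FALSE)
    }
    fv$x <- fv$x[, model$feature_names, drop = FALSE]
  }
  a <- sweep(sweep(fv$x, 2L, model$center), 2L, model$scale, "/")
  n_layers <- length(model$weights)
  act <- activation_fun(model$config$hidden_activation)
  for (l in seq_len(n_layers)) {
    z <- a %*% model$weights[[l]]$W +
      rep(model$weights[[l]]$b, each = nrow(a))
    a <- if (l < n_layers) act$f(z) else sigmoid(z)
  }
  as.vector(a)
}

#' Threshold probabilities into class calls
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`; a sample is called
#'   positive when its probability is `>= threshold`. Default 0.5.
#' @return integer 0/1 vector.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  as.integer(probabilities >= threshold)
}

#' Serialize / restore a trained network as JSON
#'
#' @param model a `dnn_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `dnn_model` (reader).
#' @export
write_dnn_model <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    W = lapply(model$weights, `[[`, "W"),
    b = lapply(model$weights, `[[`, "b"),
    center = unname(model$center),
    scale = unname(model$scale),
    feature_names = model$feature_names,
    training_history = model$training_history
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dnn_model
#' @export
read_dnn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(dnn_config, obj$config[c(
    "hidden_sizes", "hidden_activation", "dropout_rate", "l2_lambda",
    "learning_rate", "epochs", "batch_size", "seed")])
  weights <- lapply(seq_along(obj$W), function(l) {
    list(W = as.matrix(obj$W[[l]]), b = as.numeric(obj$b[[l]]))
  })
  structure(list(
    config = cfg,
    weights = weights,
    feature_names = obj$feature_names,
    center = as.numeric(obj$center),
    scale = as.numeric(obj$scale),
    training_history = obj$training_history
  ), class = "dnn_model")
}
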