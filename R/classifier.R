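sigmoid <- function(z) 1 / (1 + exp(-z))

# Seeded weight initialization: uniform in +/- 1/sqrt(fan_in).
init_layers <- function(sizes, seed) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    lim <- 1 / sqrt(fan_in)
    list(W = matrix(stats::runif(fan_in * sizes[l + 1L], -lim, lim),
                    fan_in, sizes[l + 1L]),
         b = stats::runif(sizes[l + 1L], -lim, lim))
  })
}

mlp_forward <- function(layers, x) {
  h <- sigmoid(sweep(x %*% layers[[1]]$W, 2, layers[[1]]$b, "+"))
  o <- sigmoid(sweep(h %*% layers[[2]]$W, 2, layers[[2]]$b, "+"))
  list(h = h, o = o)
}

#' Train the secretory/non-secretory feed-forward classifier
#'
#' Fits a fully connected network (220 inputs by default, one sigmoidal
#' hidden layer of 50 units, 2 sigmoidal outputs for the secretory and
#' non-secretory classes) by full-batch backpropagation on the mean squared
#' error against one-hot targets. Gradient descent uses an adaptive learning
#' rate: after an epoch that lowers the loss the rate is multiplied by
#' `lr_up`; an epoch that raises it is rejected (weights restored) and the
#' rate multiplied by `lr_down`. Feature columns are standardized
#' internally; the centering and scaling are stored in the model and applied
#' again by `predict`.
#'
#' @param x numeric feature matrix (rows = sequences, typically the
#'   220-column output of [encode_set()]).
#' @param labels factor or character vector with levels `secretory` /
#'   `non_secretory`, one per row of `x`.
#' @param hidden number of hidden units (default 50).
#' @param max_epochs maximum training epochs (default 300).
#' @param lr0 initial learning rate.
#' @param lr_up,lr_down adaptive multipliers (must satisfy
#'   0 < lr_down < 1 < lr_up).
#' @param lr_min,lr_max bounds on the learning rate; training stops when the
#'   rate falls below `lr_min`.
#' @param tol stop when an accepted step changes the loss by less than this.
#' @param seed integer seed for the weight initialization.
#' @return An object of class `sp_mlp` with elements `layers`, `sizes`,
#'   `center`, `scale`, `classes`, `training_log` (data.frame of epoch,
#'   loss, lr, accepted) and the configuration.
#' @seealso [predict.sp_mlp()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(50, 2), 5), matrix(rnorm(50, -2), 5))
#' y <- rep(c("secretory", "non_secretory"), each = 5)
#' fit <- sp_classifier(x, y, hidden = 4, max_epochs = 50, seed = 1)
#' predict(fit, x)
#' @export
sp_classifier <- function(x, labels, hidden = 50L, max_epochs = 300L,
                          lr0 = 0.5, lr_up = 1.05, lr_down = 0.7,
                          lr_min = 1e-8, lr_max = 50, tol = 1e-10,
                          seed = 1L) {
  x <- as.matrix(x)
  classes <- c("secretory", "non_secretory")
  labels <- as.character(labels)
  if (!all(labels %in% classes)) {
    stop("labels must be 'secretory' or 'non_secretory'", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  stopifnot(nrow(x) == length(labels),
            0 < lr_down, lr_down < 1, lr_up > 1)

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")

  targets <- cbind(secretory = as.numeric(labels == "secretory"),
                   non_secretory = as.numeric(labels == "non_secretory"))
  sizes <- c(ncol(x), as.integer(hidden), 2L)
  layers <- init_layers(sizes, seed)
  n <- nrow(xs)

  loss_of <- function(ly) mean((mlp_forward(ly, xs)$o - targets)^2)

  lr <- lr0
  loss <- loss_of(layers)
  log_epoch <- integer(0); log_loss <- numeric(0)
  log_lr <- numeric(0); log_acc <- logical(0)

  for (epoch in seq_len(max_epochs)) {
    fwd <- mlp_forward(layers, xs)
    if (!is.finite(loss)) {
      stop("non-finite training loss at epoch ", epoch, call. = FALSE)
    }
    # MSE backprop through two sigmoid layers
    d_o <- 2 * (fwd$o - targets) / length(targets) * fwd$o * (1 - fwd$o)
    gW2 <- crossprod(fwd$h, d_o)
    gb2 <- colSums(d_o)
    d_h <- (d_o %*% t(layers[[2]]$W)) * fwd$h * (1 - fwd$h)
    gW1 <- crossprod(xs, d_h)
    gb1 <- colSums(d_h)

    trial <- layers
    trial[[1]]$W <- trial[[1]]$W - lr * gW1
    trial[[1]]$b <- trial[[1]]$b - lr * gb1
    trial[[2]]$W <- trial[[2]]$W - lr * gW2
    trial[[2]]$b <- trial[[2]]$b - lr * gb2
    new_loss <- loss_of(trial)
    if (is.nan(new_loss)) {
      stop("non-finite training loss at epoch ", epoch, call. = FALSE)
    }

    accepted <- new_loss < loss
    if (accepted) {
      improvement <- loss - new_loss
      layers <- trial
      loss <- new_loss
      lr <- min(lr * lr_up, lr_max)
    } else {
      improvement <- NA_real_
      lr <- lr * lr_down
    }
    log_epoch <- c(log_epoch, epoch); log_loss <- c(log_loss, loss)
    log_lr <- c(log_lr, lr); log_acc <- c(log_acc, accepted)

    if (lr < lr_min) break
    if (accepted && improvement < tol) break
  }

  structure(list(
    layers = layers, sizes = sizes, center = center, scale = scale,
    classes = classes,
    training_log = data.frame(epoch = log_epoch, loss = log_loss,
                              lr = log_lr, accepted = log_acc),
    config = list(hidden = hidden, max_epochs = max_epochs, lr0 = lr0,
                  lr_up = lr_up, lr_down = lr_down, lr_min = lr_min,
                  lr_max = lr_max, tol = tol, seed = seed)
  ), class = "sp_mlp")
}

#' Predict secretory class and score
#'
#' @param object an `sp_mlp` model.
#' @param newdata feature matrix with the same number of columns the model
#'   was trained on.
#' @param ... unused.
#' @return data.frame with columns `class` (`secretory`/`non_secretory`) and
#'   `score` (the secretory output unit, in \[0, 1\], usable as a ROC
#'   threshold input). An exact tie between the two output units is broken
#'   toward `non_secretory`.
#' @export
predict.sp_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$sizes[1]) {
    stop("feature length ", ncol(newdata), " does not match model input size ",
         object$sizes[1], call. = FALSE)
  }
  xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  o <- mlp_forward(object$layers, xs)$o
  cls <- ifelse(o[, 1] > o[, 2], "secretory", "non_secretory")
  data.frame(class = cls, score = o[, 1], row.names = rownames(newdata))
}

#' @export
print.sp_mlp <- function(x, ...) {
  cat(sprintf("<sp_mlp> %d-%d-%d feed-forward classifier\n",
              x$sizes[1], x$sizes[2], x$sizes[3]))
  if (nrow(x$training_log)) {
    cat(sprintf("  trained %d epochs, final loss %.6g\n",
                nrow(x$training_log), utils::tail(x$training_log$loss, 1)))
  } else {
    cat("  untrained (seeded initialization)\n")
  }
  invisible(x)
}

#' @export
summary.sp_mlp <- function(object, ...) {
  log <- object$training_log
  out <- list(sizes = object$sizes,
              epochs = nrow(log),
              accepted = sum(log$accepted),
              initial_loss = if (nrow(log)) log$loss[1] else NA_real_,
              final_loss = if (nrow(log)) utils::tail(log$loss, 1) else NA_real_,
              final_lr = if (nrow(log)) utils::tail(log$lr, 1) else NA_real_,
              config = object$config)
  class(out) <- "summary.sp_mlp"
  out
}

#' @export
print.summary.sp_mlp <- function(x, ...) {
  cat(sprintf("%d-%d-%d network: %d epochs (%d accepted), loss %.6g -> %.6g, lr %.3g\n",
              x$sizes[1], x$sizes[2], x$sizes[3], x$epochs, x$accepted,
              x$initial_loss, x$final_loss, x$final_lr))
  invisible(x)
}

#' @export
coef.sp_mlp <- function(object, ...) {
  list(W1 = object$layers[[1]]$W, b1 = object$layers[[1]]$b,
       W2 = object$layers[[2]]$W, b2 = object$layers[[2]]$b)
}

#' Serialize / restore a classifier as a portable JSON document
#'
#' The file records a format version, layer sizes, weights, biases,
#' standardization parameters and the training configuration, so a model can
#' be inspected or reloaded outside an R session.
#'
#' @param model an `sp_mlp`.
#' @param path file path.
#' @return `write_sp_mlp` returns `path` invisibly; `read_sp_mlp` returns
#'   the restored `sp_mlp`.
#' @export
write_sp_mlp <- function(model, path) {
  stopifnot(inherits(model, "sp_mlp"))
  doc <- list(
    format = "sigscan-mlp", version = 1L,
    sizes = model$sizes,
    W1 = model$layers[[1]]$W, b1 = model$layers[[1]]$b,
    W2 = model$layers[[2]]$W, b2 = model$layers[[2]]$b,
    center = model$center, scale = model$scale,
    classes = model$classes, config = model$config
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sp_mlp
#' @export
read_sp_mlp <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sigscan-mlp")) {
    stop("not a sigscan MLP model file: ", path, call. = FALSE)
  }
  sizes <- as.integer(doc$sizes)
  layers <- list(
    list(W = matrix(unlist(doc$W1), sizes[1], sizes[2]), b = as.numeric(doc$b1)),
    list(W = matrix(unlist(doc$W2), sizes[2], sizes[3]), b = as.numeric(doc$b2))
  )
  structure(list(layers = layers, sizes = sizes,
                 center = as.numeric(doc$center), scale = as.numeric(doc$scale),
                 classes = doc$classes,
                 training_log = data.frame(epoch = integer(0), loss = numeric(0),
                                           lr = numeric(0), accepted = logical(0)),
                 config = doc$config),
            class = "sp_mlp")
}
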