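# Two-stage planner network.
#
# One architecture serves both stages: 3 convolution layers (3x3 kernels,
# 'same' padding, 16/64/128 filters, ReLU), each followed by 2x2 max
# pooling, then batch normalization, flatten, and three dense layers
# (256 -> 64 -> output). Stage 1 ("CNN-1") regresses the sin/cos encoding of
# the free phases from a normalized heating map; stage 2 ("CNN-2") regresses
# the per-channel voltages (rescaled to [0,1]) at the stage-1 phases. Both
# train with mean absolute error under Adam at learning rate 1e-4.

#' Network hyperparameter specification
#'
#' @param output_dim length of the regression output: `2 * n_free` sin/cos
#'   values for the phase stage (4 linear / 12 circular), `n_channels`
#'   voltages for the voltage stage (4 / 12).
#' @param input_shape `(n_rows, n_cols)` of the input maps.
#' @param conv_filters filters of the three convolution layers.
#' @param dense_units widths of the two hidden dense layers.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (100 linear / 200 circular).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (epochs);
#'   `Inf` disables early stopping.
#' @return a `cnn_spec`.
#' @export
cnn_spec <- function(output_dim, input_shape,
                     conv_filters = c(16, 64, 128),
                     dense_units = c(256, 64),
                     learning_rate = 1e-4, batch_size = 100,
                     epochs = 100, patience = 10) {
  stopifnot(length(input_shape) == 2, length(conv_filters) == 3,
            length(dense_units) == 2, output_dim >= 1)
  if (min(input_shape) < 8)
    stop("input grid must be at least 8 x 8 for three 2x2 pooling stages")
  structure(list(output_dim = as.integer(output_dim),
                 input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience),
            class = "cnn_spec")
}

#' Layer-by-layer output shapes of the convolution stack
#'
#' Pure arithmetic ('same'-padded convolution keeps the spatial shape; each
#' 2x2 pool floor-halves it), usable as an independent check before any model
#' is built.
#'
#' @param input_shape `(n_rows, n_cols)`.
#' @param conv_filters filters per convolution layer.
#' @return data frame with one row per layer (conv and pool alternating) and
#'   columns `layer`, `rows`, `cols`, `channels`; the final row's
#'   `rows*cols*channels` is the flattened feature length.
#' @export
cnn_layer_shapes <- function(input_shape, conv_filters = c(16, 64, 128)) {
  h <- input_shape[1]; w <- input_shape[2]
  out <- data.frame(layer = "input", rows = h, cols = w, channels = 1,
                    stringsAsFactors = FALSE)
  for (i in seq_along(conv_filters)) {
    out <- rbind(out, data.frame(layer = paste0("conv", i), rows = h,
                                 cols = w, channels = conv_filters[i]))
    h <- h %/% 2; w <- w %/% 2
    out <- rbind(out, data.frame(layer = paste0("pool", i), rows = h,
                                 cols = w, channels = conv_filters[i]))
  }
  out
}

#' Build an untrained model
#'
#' Initializes all parameters reproducibly from `seed` (He-scaled normal
#' weights for the ReLU layers, Glorot-scaled for the output layer, zero
#' biases, unit batch-norm scale).
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed; two builds with the same seed are identical.
#' @return an `hp_cnn` model object.
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "cnn_spec"))
  sh <- cnn_layer_shapes(spec$input_shape, spec$conv_filters)
  fin <- sh[nrow(sh), ]
  f_len <- fin$rows * fin$cols * fin$channels
  cf <- spec$conv_filters
  du <- spec$dense_units
  set.seed(as.integer(seed))
  he <- function(nout, nin) matrix(stats::rnorm(nout * nin, 0,
                                                sqrt(2 / nin)), nout, nin)
  glorot <- function(nout, nin) matrix(stats::rnorm(nout * nin, 0,
                                                    sqrt(1 / nin)), nout, nin)
  params <- list(
    W1 = he(cf[1], 9), b1 = numeric(cf[1]),
    W2 = he(cf[2], 9 * cf[1]), b2 = numeric(cf[2]),
    W3 = he(cf[3], 9 * cf[2]), b3 = numeric(cf[3]),
    gamma = rep(1, cf[3]), beta = numeric(cf[3]),
    run_mean = numeric(cf[3]), run_var = rep(1, cf[3]),
    Wd1 = he(du[1], f_len), bd1 = numeric(du[1]),
    Wd2 = he(du[2], du[1]), bd2 = numeric(du[2]),
    Wd3 = glorot(spec$output_dim, du[2]), bd3 = numeric(spec$output_dim))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 trained = FALSE, history = NULL, scheme = NULL,
                 kind = NULL),
            class = "hp_cnn")
}

adam_state <- function(params) {
  tr <- setdiff(names(params), c("run_mean", "run_var"))
  list(m = lapply(params[tr], function(p) p * 0),
       v = lapply(params[tr], function(p) p * 0), t = 0L, names = tr)
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  for (n in st$names) {
    g <- grads[[n]]
    st$m[[n]] <- beta1 * st$m[[n]] + (1 - beta1) * g
    st$v[[n]] <- beta2 * st$v[[n]] + (1 - beta2) * g^2
    mh <- st$m[[n]] / (1 - beta1^st$t)
    vh <- st$v[[n]] / (1 - beta2^st$t)
    params[[n]] <- params[[n]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

#' Train a model on a training set
#'
#' Minibatch Adam on the mean-absolute-error loss, recording training and
#' validation loss each epoch. Validation loss uses the running batch-norm
#' statistics (inference mode). With early stopping the parameters giving
#' the best validation loss are kept.
#'
#' @param model an `hp_cnn` from [build_model()].
#' @param ts a `training_set` whose input shape and label width match the
#'   model spec.
#' @param seed seed for minibatch shuffling.
#' @param epochs optional override of `spec$epochs`.
#' @param verbose print per-epoch losses.
#' @return the trained `hp_cnn` with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_cnn <- function(model, ts, seed = 1L, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hp_cnn"), inherits(ts, "training_set"))
  spec <- model$spec
  d <- dim(ts$inputs)
  if (!all(d[1:2] == spec$input_shape))
    stop("training inputs do not match the model input shape")
  if (ncol(ts$labels) != spec$output_dim)
    stop("label width does not match the model output size")
  if (is.null(epochs)) epochs <- spec$epochs
  params <- model$params
  st <- adam_state(params)
  tr_idx <- ts$train
  va_x <- ts$inputs[, , ts$val, drop = FALSE]
  va_y <- ts$labels[ts$val, , drop = FALSE]
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad <- 0L
  set.seed(as.integer(seed))
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    bl <- numeric(0)
    for (b0 in seq(1, length(ord), spec$batch_size)) {
      ix <- ord[b0:min(length(ord), b0 + spec$batch_size - 1L)]
      res <- cpp_cnn_grad(params, ts$inputs[, , ix, drop = FALSE],
                          ts$labels[ix, , drop = FALSE])
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      bl <- c(bl, res$loss)
      up <- adam_update(params, res$grads, st, spec$learning_rate)
      params <- up$params
      st <- up$state
      params$run_mean <- 0.9 * params$run_mean + 0.1 * res$bn_mean
      params$run_var <- 0.9 * params$run_var + 0.1 * res$bn_var
    }
    pv <- cpp_cnn_predict(params, va_x)
    vl <- mean(abs(pv - va_y))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(bl),
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, mean(bl), vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (is.finite(model$spec$patience) && bad >= model$spec$patience) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$trained <- TRUE
  model$scheme <- ts$scheme
  model$kind <- ts$kind
  model
}

#' @export
print.hp_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<hp_cnn> %d x %d input -> %d outputs (%s)\n",
              s$input_shape[1], s$input_shape[2], s$output_dim,
              if (x$trained) paste0("trained, ", x$kind, " stage")
              else "untrained"))
  if (!is.null(x$history)) {
    n <- nrow(x$history)
    cat(sprintf("  %d epochs, final val loss %.4f\n", n,
                x$history$val_loss[n]))
  }
  invisible(x)
}

#' Raw network outputs for new inputs
#'
#' @param object an `hp_cnn`.
#' @param newdata a single map (matrix) or `(H, W, B)` array.
#' @param ... unused.
#' @return a `B x output_dim` matrix.
#' @export
predict.hp_cnn <- function(object, newdata, ...) {
  if (is.matrix(newdata)) dim(newdata) <- c(dim(newdata), 1L)
  cpp_cnn_predict(object$params, newdata)
}

#' Predict focusing phases from a masked-target input
#'
#' Feeds the binary target mask to the phase-stage model, decodes each
#' (sin, cos) output pair with the two-argument arctangent, and expands the
#' free phases through the scheme constraint, so the returned vector always
#' satisfies it.
#'
#' @param model a trained phase-stage `hp_cnn`.
#' @param mask a mask from [build_mask()].
#' @return list with `free_phases` (degrees) and `phases` (full per-channel
#'   vector in `(-180, 180]`).
#' @export
predict_phases <- function(model, mask) {
  stopifnot(inherits(model, "hp_cnn"))
  if (!identical(model$kind, "phase"))
    stop("model is not a trained phase-stage network")
  out <- predict(model, mask)[1, ]
  free <- decode_phases(out)
  list(free_phases = free, phases = expand_free_phases(model$scheme, free))
}

#' Predict per-channel voltages from a masked-target input
#'
#' Network outputs are clipped to [0, 1] and rescaled by the 9 V training
#' ceiling. The result is reported in volts; scale with
#' [scale_to_total_power()] before quoting powers.
#'
#' @param model a trained voltage-stage `hp_cnn`.
#' @param mask a mask from [build_mask()].
#' @return per-channel voltages in V.
#' @export
predict_voltages <- function(model, mask) {
  stopifnot(inherits(model, "hp_cnn"))
  if (!identical(model$kind, "voltage"))
    stop("model is not a trained voltage-stage network")
  out <- predict(model, mask)[1, ]
  v <- 9 * pmin(pmax(out, 0), 1)
  if (all(v == 0))
    stop("degenerate all-zero voltage prediction")
  v
}

#' Export a training curve as CSV
#'
#' @param model a trained `hp_cnn`.
#' @param path file path; columns `epoch`, `train_loss`, `val_loss`.
#' @export
write_training_curve <- function(model, path) {
  stopifnot(inherits(model, "hp_cnn"), !is.null(model$history))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
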