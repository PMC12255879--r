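# MSE training with Adam and plateau learning-rate decay, plus the five
# standard affinity-regression metrics (R, RMSE, MAE, SD, CI) implemented
# from their definitions.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam at learning rate 1e-4 with a
#' decay factor of 0.1 applied after a validation-loss plateau of 10 epochs.
#'
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_factor multiplier applied to the learning rate on plateau.
#' @param patience epochs without validation improvement before decay.
#' @param max_epochs training epoch cap.
#' @param batch_size minibatch size.
#' @param val_fraction held-out fraction when no validation set is given.
#' @param seed RNG seed controlling init, shuffling and the split.
#' @param target_train_mse optional early-stop threshold on training MSE.
#' @return object of class `TrainConfig`.
#' @export
train_config <- function(learning_rate = 1e-4, lr_decay_factor = 0.1,
                         patience = 10L, max_epochs = 500L, batch_size = 32L,
                         val_fraction = 0.2, seed = 1L,
                         target_train_mse = NULL) {
  stopifnot(learning_rate > 0, lr_decay_factor > 0, patience >= 1L,
            max_epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 seed = as.integer(seed),
                 target_train_mse = target_train_mse),
            class = "TrainConfig")
}

#' Mean squared error
#'
#' @param y observed values.
#' @param yhat predicted values of the same length.
#' @return mean of squared residuals.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  if (length(y) < 1L) stop("empty input")
  mean((y - yhat)^2)
}

#' Plateau learning-rate update
#'
#' The scheduler used by [train_model()]: tracks the best validation loss;
#' after `patience` epochs without improvement (> 1e-6), multiplies the
#' learning rate by the decay factor and resets the counter.
#'
#' @param sched list with `lr`, `best_val`, `stall` (see [train_model()]).
#' @param val_mse this epoch's validation loss.
#' @param lr_decay_factor,patience schedule constants.
#' @return updated scheduler state.
#' @export
plateau_update <- function(sched, val_mse, lr_decay_factor = 0.1,
                           patience = 10L) {
  if (val_mse < sched$best_val - 1e-6) {
    sched$best_val <- val_mse
    sched$stall <- 0L
  } else {
    sched$stall <- sched$stall + 1L
    if (sched$stall >= patience) {
      sched$lr <- sched$lr * lr_decay_factor
      sched$stall <- 0L
    }
  }
  sched
}

# loss node for one sample on an open tape
sample_loss_node <- function(tp, bp, inputs, cfg, y) {
  o <- forward_affinity(tp, bp, inputs, cfg)
  d <- ad_addc(tp, o, -y)
  ad_mul(tp, d, d)
}

#' Train the affinity model
#'
#' Adam on the MSE loss. The validation loss is monitored each epoch; after
#' `patience` epochs without improvement the learning rate is multiplied by
#' `lr_decay_factor` (and the plateau counter resets). Fully deterministic
#' for a fixed seed on one machine.
#'
#' @param dataset list of `ComplexRecord`s with affinity labels.
#' @param cfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param val_dataset optional validation records; if omitted,
#'   `val_fraction` of `dataset` is held out (at least 1 record when
#'   `val_fraction > 0`).
#' @param params optional warm-start parameters.
#' @param verbose print per-epoch progress.
#' @return list with `params`, `history` (data.frame epoch/train_mse/val_mse/
#'   lr) and `config`.
#' @export
train_model <- function(dataset, cfg, tcfg = train_config(),
                        val_dataset = NULL, params = NULL, verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  labels <- vapply(dataset, function(r) {
    if (is.null(r$affinity_label)) stop("training record lacks affinity label")
    r$affinity_label
  }, numeric(1))
  set.seed(tcfg$seed)
  if (is.null(val_dataset) && tcfg$val_fraction > 0 && length(dataset) >= 2L) {
    nval <- max(1L, round(tcfg$val_fraction * length(dataset)))
    vidx <- sample(length(dataset), nval)
    val_dataset <- dataset[vidx]
    dataset <- dataset[-vidx]
    labels <- labels[-vidx]
  }
  if (is.null(params)) params <- init_model_params(cfg, seed = tcfg$seed)
  tr_inputs <- lapply(dataset, prepare_complex_inputs, cfg = cfg)
  va_inputs <- if (!is.null(val_dataset)) {
    lapply(val_dataset, prepare_complex_inputs, cfg = cfg)
  }
  va_labels <- if (!is.null(val_dataset)) {
    vapply(val_dataset, `[[`, numeric(1), "affinity_label")
  }
  n <- length(tr_inputs)
  state <- adam_init(params)
  sched <- list(lr = tcfg$learning_rate, best_val = Inf, stall = 0L)
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0), lr = numeric(0))
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = tcfg$batch_size)) {
      bidx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
      tp <- ad_tape()
      bp <- bind_params(tp, params)
      lnodes <- lapply(bidx, function(i) {
        sample_loss_node(tp, bp, tr_inputs[[i]], cfg, labels[i])
      })
      loss <- ad_scale(tp, ad_sum(tp, ad_cbind(tp, lnodes)), 1 / length(bidx))
      lv <- ad_value(tp, loss)
      if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch)
      ep_loss <- ep_loss + lv * length(bidx)
      ad_backward(tp, loss)
      grads <- collect_grads(tp, bp)
      st <- adam_step(params, grads, state, lr = sched$lr)
      params <- st$params
      state <- st$state
    }
    train_mse <- ep_loss / n
    val_mse <- if (!is.null(va_inputs)) {
      preds <- vapply(va_inputs, predict_affinity, numeric(1),
                      cfg = cfg, params = params)
      mse_loss(va_labels, preds)
    } else train_mse
    history <- rbind(history, data.frame(epoch = epoch, train_mse = train_mse,
                                         val_mse = val_mse, lr = sched$lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      epoch, train_mse, val_mse, sched$lr))
    }
    sched <- plateau_update(sched, val_mse, tcfg$lr_decay_factor, tcfg$patience)
    if (!is.null(tcfg$target_train_mse) && train_mse < tcfg$target_train_mse) break
  }
  list(params = params, history = history,
       config = list(model = cfg, train = tcfg))
}

#' Concordance index
#'
#' Over all pairs with distinct observed values: 1 for a concordantly
#' ordered prediction pair, 0.5 for a tied prediction, 0 otherwise, averaged.
#' Pairs tied in `y` are not comparable.
#'
#' @param y observed values (n >= 2).
#' @param yhat predictions.
#' @return CI in `[0, 1]`.
#' @export
concordance_index <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  ord <- order(y)
  y <- y[ord]
  yhat <- yhat[ord]
  num <- 0
  den <- 0
  n <- length(y)
  for (i in seq_len(n - 1L)) {
    comp <- which(y[(i + 1L):n] > y[i]) + i
    if (length(comp) == 0L) next
    dh <- yhat[comp] - yhat[i]
    num <- num + sum(dh > 0) + 0.5 * sum(dh == 0)
    den <- den + length(comp)
  }
  if (den == 0) stop("all observed values tied; concordance undefined")
  num / den
}

#' Regression standard deviation
#'
#' Fits `y = a + b * yhat` by least squares and returns
#' `sqrt(sum(residuals^2) / (n - 1))` - the convention of the binding-
#' affinity benchmark literature.
#'
#' @param y observed values (n >= 3).
#' @param yhat predictions with nonzero variance.
#' @return SD >= 0.
#' @export
sd_regression <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(yhat) < 1e-12) stop("constant predictions; regression degenerate")
  fit <- stats::lm.fit(cbind(1, yhat), y)
  sqrt(sum(fit$residuals^2) / (n - 1))
}

#' Full evaluation report
#'
#' Pearson R, RMSE, MAE, regression SD and concordance index.
#'
#' @param y observed affinities (n >= 3).
#' @param yhat predicted affinities.
#' @return object of class `MetricsReport`: list with `R`, `RMSE`, `MAE`,
#'   `SD`, `CI`, `n`.
#' @export
evaluate <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  structure(list(
    R = stats::cor(y, yhat),
    RMSE = sqrt(mean((y - yhat)^2)),
    MAE = mean(abs(y - yhat)),
    SD = sd_regression(y, yhat),
    CI = concordance_index(y, yhat),
    n = length(y)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("R = %.4f  RMSE = %.4f  MAE = %.4f  SD = %.4f  CI = %.4f  (n = %d)\n",
              x$R, x$RMSE, x$MAE, x$SD, x$CI, x$n))
  invisible(x)
}

#' Plain grid search over training hyperparameters
#'
#' A deliberately simple stand-in for Bayesian hyperparameter optimisation:
#' trains one model per grid point and reports the final validation MSE.
#'
#' @param dataset list of labelled `ComplexRecord`s.
#' @param cfg a [model_config()].
#' @param grid data.frame whose columns name [train_config()] arguments
#'   (e.g. `learning_rate`, `batch_size`); one row per configuration.
#' @param base_tcfg the [train_config()] supplying every other setting.
#' @return `grid` with an extra `val_mse` column, ordered as given.
#' @export
grid_search <- function(dataset, cfg, grid, base_tcfg = train_config()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  val <- vapply(seq_len(nrow(grid)), function(i) {
    tc <- base_tcfg
    for (nm in names(grid)) tc[[nm]] <- grid[[nm]][i]
    fit <- train_model(dataset, cfg, tc)
    utils::tail(fit$history$val_mse, 1L)
  }, numeric(1))
  grid$val_mse <- val
  grid
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the parameter tensors together with the model
#' configuration.
#'
#' @param fit result of [train_model()] (or a list with `params` and
#'   `config`).
#' @param path destination path.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$params, config = fit$config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
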