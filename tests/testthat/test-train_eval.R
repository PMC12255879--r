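test_that("mse_loss closed forms", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1.0)
  y <- rnorm(10); e <- rnorm(10)
  expect_equal(mse_loss(y, y + 2 * e), 4 * mse_loss(y, y + e))
  expect_error(mse_loss(1:3, 1:2), "length")
})

test_that("concordance index matches an O(n^2) enumeration oracle exactly", {
  ci_oracle <- function(y, yhat) {
    num <- 0; den <- 0
    for (i in seq_along(y)) for (j in seq_along(y)) {
      if (y[i] < y[j]) {
        den <- den + 1
        num <- num + (yhat[i] < yhat[j]) + 0.5 * (yhat[i] == yhat[j])
      }
    }
    num / den
  }
  expect_equal(concordance_index(1:5, 1:5), 1.0)
  expect_equal(concordance_index(1:5, 5:1), 0.0)
  set.seed(31)
  for (k in 1:25) {
    y <- rnorm(20)
    yhat <- if (k %% 3 == 0) sample(y) else rnorm(20)
    if (k %% 5 == 0) yhat <- round(yhat) # force prediction ties
    expect_identical(concordance_index(y, yhat), ci_oracle(y, yhat))
  }
  expect_error(concordance_index(c(1, 1, 1), 1:3), "tied")
})

test_that("sd_regression matches the normal-equations oracle to 1e-10", {
  sd_oracle <- function(y, yhat) {
    X <- cbind(1, yhat)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% beta
    sqrt(sum(r^2) / (length(y) - 1))
  }
  set.seed(17)
  for (k in 1:25) {
    y <- rnorm(50)
    yhat <- rnorm(50)
    expect_lt(abs(sd_regression(y, yhat) - sd_oracle(y, yhat)), 1e-10)
  }
  # exactly affine: zero residual SD
  yhat <- rnorm(10)
  expect_lt(sd_regression(3 + 2 * yhat, yhat), 1e-12)
  # invariant to affine rescaling of predictions
  y <- rnorm(30); yh <- rnorm(30)
  expect_equal(sd_regression(y, yh), sd_regression(y, 5 - 3 * yh))
  expect_error(sd_regression(rnorm(5), rep(2, 5)), "constant")
})

test_that("evaluate: closed-form cases and report invariants", {
  y <- c(1, 2, 3, 4.5)
  r1 <- evaluate(y, y)
  expect_equal(r1$R, 1)
  expect_equal(r1$RMSE, 0)
  expect_equal(r1$MAE, 0)
  expect_equal(r1$SD, 0)
  expect_equal(r1$CI, 1)

  r2 <- evaluate(y, -y)
  expect_equal(r2$R, -1)
  expect_equal(r2$CI, 0)

  set.seed(23)
  for (k in 1:100) {
    y <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    yhat <- y + rnorm(length(y), sd = runif(1, 0.1, 2))
    rep_ <- evaluate(y, yhat)
    expect_gte(rep_$RMSE, rep_$MAE)
    expect_gte(rep_$MAE, 0)
    expect_true(rep_$R >= -1 && rep_$R <= 1)
    expect_true(rep_$CI >= 0 && rep_$CI <= 1)
    expect_gte(rep_$SD, 0)
  }
})

test_that("plateau schedule: lr 1e-4 decays to 1e-5 after a 10-epoch stall", {
  tcfg <- train_config()
  expect_equal(tcfg$learning_rate, 1e-4)
  expect_equal(tcfg$lr_decay_factor, 0.1)
  expect_equal(tcfg$patience, 10L)

  sched <- list(lr = tcfg$learning_rate, best_val = Inf, stall = 0L)
  sched <- plateau_update(sched, 1.0, tcfg$lr_decay_factor, tcfg$patience)
  for (i in 1:9) {
    sched <- plateau_update(sched, 1.0, tcfg$lr_decay_factor, tcfg$patience)
    expect_equal(sched$lr, 1e-4) # not yet
  }
  sched <- plateau_update(sched, 1.0, tcfg$lr_decay_factor, tcfg$patience)
  expect_equal(sched$lr, 1e-5)
  # an improvement resets the stall counter
  sched <- plateau_update(sched, 0.5, tcfg$lr_decay_factor, tcfg$patience)
  expect_equal(sched$stall, 0L)
  expect_equal(sched$lr, 1e-5)
})

test_that("training is reproducible and reduces the loss", {
  recs <- generate_dataset(synth_config(n_complexes = 6, seed = 21))
  cfg <- model_config(hidden_dim = 4L)
  tcfg <- train_config(learning_rate = 1e-3, max_epochs = 3L, batch_size = 3L,
                       val_fraction = 0.34, seed = 13L)
  f1 <- train_model(recs, cfg, tcfg)
  f2 <- train_model(recs, cfg, tcfg)
  expect_identical(f1$history, f2$history) # bitwise, one device
  expect_identical(f1$params, f2$params)
  expect_equal(nrow(f1$history), 3L)
  expect_lt(f1$history$train_mse[3], f1$history$train_mse[1])
  expect_error(train_model(list(), cfg, tcfg))
})

test_that("checkpoints round-trip parameters and config", {
  recs <- generate_dataset(synth_config(n_complexes = 3, seed = 22))
  cfg <- model_config(hidden_dim = 4L)
  fit <- train_model(recs, cfg,
                     train_config(max_epochs = 1L, val_fraction = 0, seed = 1L))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, tf)
  back <- load_checkpoint(tf)
  expect_identical(back$params, fit$params)
  p <- predict_affinity(recs[[1]], back$config$model, back$params)
  expect_true(is.finite(p))
})

test_that("grid_search trains one model per grid point", {
  recs <- generate_dataset(synth_config(n_complexes = 5, seed = 25))
  cfg <- model_config(hidden_dim = 4L)
  grid <- data.frame(learning_rate = c(1e-3, 1e-2))
  out <- grid_search(recs, cfg, grid,
                     train_config(max_epochs = 2L, batch_size = 2L,
                                  val_fraction = 0.2, seed = 2L))
  expect_equal(nrow(out), 2L)
  expect_true(all(is.finite(out$val_mse)))
})
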