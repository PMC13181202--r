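test_that("the two-phase learning-rate schedule matches its closed forms", {
  ctl <- train_control()                       # lr0 2e-4, 200 epochs, 130 constant
  expect_true(all(vapply(1:130, function(e) lr_at_epoch(ctl, e),
                         numeric(1)) == 2e-4))
  expect_equal(lr_at_epoch(ctl, 131), 2e-4 * (1 - 1 / 70))
  expect_equal(lr_at_epoch(ctl, 200), 0)
  cos_ctl <- train_control(schedule = "cosine")
  expect_equal(lr_at_epoch(cos_ctl, 100), 2e-4 / 2)     # half-way: lr0/2
  expect_equal(lr_at_epoch(cos_ctl, 200), 0)
  expect_error(lr_at_epoch(ctl, 0), "out of range")
  expect_error(lr_at_epoch(ctl, 201), "out of range")
  for (ctl_i in list(ctl, cos_ctl)) {
    lrs <- vapply(1:200, function(e) lr_at_epoch(ctl_i, e), numeric(1))
    expect_true(all(diff(lrs) <= 1e-15))
  }
})

test_that("train_control validates its invariants and the moments escape hatch", {
  expect_error(train_control(epochs = 100, constant_epochs = 130), "<=")
  expect_error(train_control(lr0 = 0), "positive")
  ctl <- train_control()
  expect_equal(c(ctl$moment1, ctl$moment2), c(0.999, 0.99))  # verbatim recipe
  conv <- train_control(conventional_moments = TRUE)
  expect_equal(c(conv$moment1, conv$moment2), c(0.9, 0.999))
})

test_that("checkpoint sets keep the top three, ties to the later epoch", {
  cps <- list()
  accs <- c(0.5, 0.8, 0.8, 0.6, 0.9, 0.8)
  for (e in seq_along(accs))
    cps <- ghostnet3d:::.update_checkpoints(cps, list(), e, accs[e])
  expect_length(cps, 3L)
  got <- vapply(cps, `[[`, numeric(1), "val_acc")
  expect_true(all(diff(got) <= 0))                       # non-increasing
  expect_equal(got, c(0.9, 0.8, 0.8))
  expect_equal(vapply(cps, `[[`, numeric(1), "epoch"), c(5, 6, 3))
})

test_that("an untrained 2-class model sits at symmetric 50% confidence", {
  net <- build_network(network_config(depth = 18, stage_blocks = c(1, 1, 0, 0),
                                      widths = c(4, 8, 16, 32)), seed = 6)
  set.seed(15)
  x <- array(runif(16^3 * 100), c(100, 16, 16, 16))
  y <- rep(c("benign", "malignant"), 50)
  cp <- structure(list(list(params = ghostnet3d:::net_params(net),
                            epoch = 1L, val_acc = 0.5)),
                  class = "checkpoint_set")
  ev <- evaluate_checkpoints(net, cp, x, y)
  expect_gte(ev$per_checkpoint[[1]]$mean_confidence, 0.45)
  expect_lte(ev$per_checkpoint[[1]]$mean_confidence, 0.55)
  # evaluation is pure: repeating gives identical reports
  ev2 <- evaluate_checkpoints(net, cp, x, y)
  expect_identical(ev$per_checkpoint[[1]]$metrics,
                   ev2$per_checkpoint[[1]]$metrics)
  expect_error(evaluate_checkpoints(net, structure(list(), class = "checkpoint_set"),
                                    x, y), "empty checkpoint")
})

test_that("training runs are fully reproducible and log every epoch", {
  spec <- phantom_spec(n_benign = 4, n_malignant = 4,
                       volume_shape = c(48L, 48L, 48L), rng_seed = 31)
  patches <- make_phantom_patches(spec, rep(c("benign", "malignant"), each = 4),
                                  rep(1:4, 2))
  y <- rep(c("benign", "malignant"), each = 4)
  cfg <- network_config(depth = 18, stage_blocks = c(1, 0, 0, 0),
                        widths = c(4, 8, 16, 32))
  ctl <- train_control(epochs = 3, lr0 = 1e-3, conventional_moments = TRUE,
                       seed = 8)
  r1 <- train_network(build_network(cfg, seed = 8), patches, y, control = ctl)
  r2 <- train_network(build_network(cfg, seed = 8), patches, y, control = ctl)
  expect_identical(r1$log, r2$log)
  expect_equal(nrow(r1$log), 3L)
  expect_identical(ghostnet3d:::net_params(r1$net),
                   ghostnet3d:::net_params(r2$net))
  expect_true(all(is.finite(r1$log$train_loss)))
  # a perfect checkpoint evaluates to 100% on data it memorized
  ev <- evaluate_checkpoints(r1$net, r1$checkpoints, patches, y)
  expect_true(all(vapply(ev$per_checkpoint, function(p)
    p$metrics$acc, numeric(1)) <= 1))
  expect_error(train_network(build_network(cfg, seed = 1),
                             patches[0], character(0), control = ctl),
               "empty|length")
})
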