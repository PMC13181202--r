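test_that("ghost convolution splits channels and concatenates base + cheap maps", {
  set.seed(5)
  x <- array(rnorm(8^3 * 16), c(8, 8, 8, 16, 1))
  wp <- array(rnorm(16 * 16), c(1, 1, 1, 16, 16))
  wc <- array(rnorm(27 * 16), c(3, 3, 3, 1, 16))
  y <- ghost_conv3d(x, list(primary = wp, cheap = wc), c_out = 32L, ratio = 2L)
  expect_equal(dim(y), c(8L, 8L, 8L, 32L, 1L))
  base <- ghostnet3d:::conv3d_fwd(x, dim(x), wp, 1L, 16L, 1L, 1L, 0L)
  expect_identical(y[, , , 1:16, , drop = FALSE], base)   # first 16 = base maps
  # ceil split with truncation keeps exactly c_out channels
  y33 <- ghost_conv3d(x, list(primary = array(rnorm(27 * 16 * 17),
                                              c(3, 3, 3, 16, 17)),
                              cheap = array(rnorm(27 * 17), c(3, 3, 3, 1, 17))),
                      c_out = 33L, ratio = 2L)
  expect_equal(dim(y33)[4], 33L)
})

test_that("ghost convolution at ratio 1 is bitwise a plain convolution", {
  set.seed(6)
  x <- array(rnorm(8^3 * 16 * 2), c(8, 8, 8, 16, 2))
  w <- array(rnorm(27 * 16 * 32), c(3, 3, 3, 16, 32))
  plain <- ghostnet3d:::conv3d_fwd(x, dim(x), w, 3L, 32L, 1L, 1L, 1L)
  ghost <- ghost_conv3d(x, list(primary = w), c_out = 32L, ratio = 1L)
  expect_identical(ghost, plain)
})

test_that("ghost kernel weight counts follow the closed forms", {
  gh <- ghostnet3d:::init_layer(ghostnet3d:::new_ghost(3L, 16L, 32L, ratio = 2L),
                                "zero")
  expect_equal(length(gh$primary$W) + length(gh$cheap$W),
               16 * 16 * 27 + 16 * 27)                  # 7344
  expect_equal(16 * 32 * 27, 13824)                     # plain counterpart
})

test_that("normalization-activation modules reproduce hand-computed cases", {
  # layer norm of a constant sample is zero; ELU(0) = 0
  na <- ghostnet3d:::init_layer(ghostnet3d:::new_norm_act("layer", "elu", 3L), "he")
  x <- array(5, c(2, 2, 2, 3, 1))
  out <- ghostnet3d:::norm_act_fwd(na, x, train = TRUE)$y
  expect_lt(max(abs(out)), 1e-8)
  # ELU closed form at -1
  expect_equal(ghostnet3d:::act_fwd(-1, "elu"), exp(-1) - 1, tolerance = 1e-12)
  # batch norm (train) on per-channel values {0, 2}: mean 1, sd 1 -> {-1, +1}
  bn <- ghostnet3d:::init_layer(ghostnet3d:::new_norm_act("batch", "none", 1L), "he")
  xb <- array(c(0, 2), c(1, 1, 1, 1, 2))
  yb <- ghostnet3d:::norm_act_fwd(bn, xb, train = TRUE)$y
  expect_equal(as.numeric(yb), c(-1, 1), tolerance = 1e-2)  # eps-regularized
})

test_that("layer norm is invariant to per-sample constant shifts", {
  na <- ghostnet3d:::init_layer(ghostnet3d:::new_norm_act("layer", "none", 4L), "he")
  set.seed(8)
  x <- array(rnorm(4^3 * 4 * 2), c(4, 4, 4, 4, 2))
  x2 <- x; x2[, , , , 1] <- x2[, , , , 1] + 7.3
  y1 <- ghostnet3d:::norm_act_fwd(na, x, train = TRUE)$y
  y2 <- ghostnet3d:::norm_act_fwd(na, x2, train = TRUE)$y
  expect_lt(max(abs(y1 - y2)), 1e-10)
})

test_that("the 50-layer genotype builds with the canonical depth accounting", {
  net <- build_network(network_config(), init = "meta")
  expect_equal(count_weighted_layers(net), 50L)
  expect_equal(count_weighted_layers(build_network(network_config(depth = 18),
                                                   init = "meta")), 18L)
  expect_equal(count_weighted_layers(build_network(network_config(depth = 101),
                                                   init = "meta")), 101L)
})

test_that("weight init is seed-deterministic and zero input gives finite softmax", {
  cfg <- network_config(depth = 18, widths = c(4, 8, 16, 32))
  n1 <- build_network(cfg, seed = 4)
  n2 <- build_network(cfg, seed = 4)
  expect_identical(ghostnet3d:::net_params(n1), ghostnet3d:::net_params(n2))
  n3 <- build_network(cfg, seed = 5)
  expect_false(identical(ghostnet3d:::net_params(n1),
                         ghostnet3d:::net_params(n3)))
  p <- predict(n1, array(0, c(16, 16, 16)))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), 1)
})

test_that("eval-mode forward is pure and batch-order independent", {
  cfg <- network_config(depth = 18, widths = c(4, 8, 16, 32))
  net <- build_network(cfg, seed = 4)
  set.seed(9)
  x <- array(rnorm(16^3 * 4), c(4, 16, 16, 16))
  p1 <- predict(net, x)
  expect_identical(p1, predict(net, x))
  perm <- c(3, 1, 4, 2)
  p2 <- predict(net, x[perm, , , ])
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
  singles <- t(sapply(1:4, function(i) predict(net, x[i, , , ])))
  expect_equal(unname(singles), unname(p1), tolerance = 1e-12)
  expect_error(predict(net, array(0, c(8, 8, 8, 3, 1))), "channels")
})

test_that("parameter counts equal a brute-force walk over the allocated tensors", {
  walk <- function(net) sum(vapply(ghostnet3d:::net_params(net), length, numeric(1)))
  cfgs <- list(network_config(depth = 18, widths = c(4, 8, 16, 32)),
               baseline_config(depth = 50, widths = c(4, 8, 16, 32)),
               network_config(depth = 50, widths = c(4, 8, 16, 32),
                              trunk_norm = "weight", block_norm = "weight"),
               network_config(depth = 34, widths = c(4, 8, 16, 32),
                              ghost_ratio = 4L))
  for (cfg in cfgs) {
    net <- build_network(cfg, seed = 1, init = "zero")
    expect_equal(as.numeric(count_parameters(net)), walk(net))
  }
  # the full-size flagship pair, walked tensor by tensor
  for (cfg in list(baseline_config(), network_config())) {
    net <- build_network(cfg, seed = 1, init = "zero")
    expect_equal(as.numeric(count_parameters(net)), walk(net))
    rm(net); gc(verbose = FALSE)
  }
})

test_that("MAC accounting matches closed forms and ghosting always saves conv MACs", {
  lm <- ghostnet3d:::.layer_macs
  conv1 <- ghostnet3d:::new_conv(1L, 16L, 32L)
  expect_equal(lm(conv1, c(8L, 8L, 8L), 16L, "conv_linear")$macs, 16 * 32 * 512)
  conv3 <- ghostnet3d:::new_conv(3L, 1L, 64L)
  expect_equal(ghostnet3d:::.layer_param_count(conv3), 1728)
  # ghost conv MACs < plain for every (k, cin, cout) slot used in the network
  for (dims in list(c(1, 64, 64), c(3, 64, 64), c(1, 64, 256), c(3, 64, 256),
                    c(1, 256, 128), c(3, 512, 512), c(3, 1024, 2048))) {
    plain <- lm(ghostnet3d:::new_conv(dims[1], dims[2], dims[3]),
                c(8L, 8L, 8L), dims[2], "conv_linear")$macs
    ghost <- lm(ghostnet3d:::new_ghost(dims[1], dims[2], dims[3], ratio = 2L),
                c(8L, 8L, 8L), dims[2], "conv_linear")$macs
    expect_lt(ghost, plain)
  }
})

test_that("per-layer parameter savings approach the ghost ratio asymptotically", {
  ratio_at <- function(cin) {
    gh <- ghostnet3d:::new_ghost(3L, cin, cin, ratio = 2L)
    plain <- 27 * cin * cin
    ghost_w <- ghostnet3d:::.layer_param_count(gh$primary) +
      ghostnet3d:::.layer_param_count(gh$cheap)
    plain / ghost_w
  }
  r <- vapply(c(64L, 256L, 1024L), ratio_at, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gt(r[3], 1.99)
  expect_lt(r[3], 2)
})

test_that("the whole ablation grid of norms, activations, convs and placements runs", {
  norms <- c("batch", "layer", "instance", "weight")
  acts <- c("elu", "relu", "leaky_relu", "gelu")
  set.seed(10)
  x <- array(rnorm(32^3), c(32, 32, 32))
  for (norm in norms) for (act in acts) for (ghost in c(TRUE, FALSE))
    for (place in c("trunk", "block", "downsample")) {
      cfg <- network_config(
        depth = 50, stage_blocks = c(1, 1, 1, 1), widths = c(4, 8, 16, 32),
        ghost = ghost, activation = act,
        trunk_norm = if (place == "trunk") norm else "layer",
        block_norm = if (place == "block") norm else "batch",
        downsample_norm = if (place == "downsample") norm else "batch")
      net <- build_network(cfg, seed = 2)
      p <- predict(net, x)
      expect_true(all(is.finite(p)), info = paste(norm, act, ghost, place))
      expect_equal(rowSums(p), 1)
    }
})
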