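make_small_net <- function(seed = 3) {
  build_network(network_config(depth = 18, stage_blocks = c(1, 1, 0, 0),
                               widths = c(4, 8, 16, 32)), seed = seed)
}

test_that("a layer disconnected from the score yields a flagged zero map", {
  net <- make_small_net()          # zero-initialized head: dS/dA is 0 everywhere
  set.seed(1)
  patch <- array(runif(16^3), c(16, 16, 16))
  sm <- grad_cam_pp(net, patch, target_class = "malignant", layer_id = "stage1")
  expect_true(sm$degenerate)
  expect_true(all(sm$cam == 0))
})

test_that("non-degenerate maps are min-max normalized and idempotent", {
  net <- make_small_net()
  set.seed(2)
  params <- ghostnet3d:::net_params(net)
  params$fc.W <- matrix(rnorm(length(params$fc.W), 0, 0.5),
                        nrow(params$fc.W), ncol(params$fc.W))
  net <- ghostnet3d:::net_set_params(net, params)
  patch <- array(runif(16^3), c(16, 16, 16))
  sm <- grad_cam_pp(net, patch, target_class = "malignant", layer_id = "stage2")
  expect_false(sm$degenerate)
  expect_equal(min(sm$cam), 0)
  expect_equal(max(sm$cam), 1)
  expect_identical(normalize_cam(normalize_cam(sm$cam)), normalize_cam(sm$cam))
  expect_error(grad_cam_pp(net, patch, layer_id = "nowhere"), "layer_id")
})

test_that("the map ignores constant shifts of the non-target logit", {
  net <- make_small_net()
  params <- ghostnet3d:::net_params(net)
  set.seed(4)
  params$fc.W <- matrix(rnorm(length(params$fc.W), 0, 0.5),
                        nrow(params$fc.W), ncol(params$fc.W))
  net <- ghostnet3d:::net_set_params(net, params)
  patch <- array(runif(16^3), c(16, 16, 16))
  cam1 <- grad_cam_pp(net, patch, target_class = "malignant", "stage2")$cam
  params$fc.b <- params$fc.b + c(13.7, 0)      # shift the benign logit only
  net2 <- ghostnet3d:::net_set_params(net, params)
  cam2 <- grad_cam_pp(net2, patch, target_class = "malignant", "stage2")$cam
  expect_equal(cam1, cam2, tolerance = 1e-12)
})

test_that("trilinear upsampling preserves constants, identity, and structure", {
  const <- upsample_cam(array(0.6, c(4, 4, 4)), c(32, 32, 32),
                        renormalize = FALSE)
  expect_lt(max(abs(const - 0.6)), 1e-12)
  set.seed(5)
  m <- array(runif(8^3), c(8, 8, 8))
  ident <- upsample_cam(m, c(8, 8, 8), renormalize = FALSE)
  expect_lt(max(abs(ident - m)), 1e-12)
  # up 4^3 -> 32^3, then block-average back down: strong agreement
  m4 <- array(runif(64), c(4, 4, 4))
  up <- upsample_cam(m4, c(32, 32, 32), renormalize = FALSE)
  down <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    down[i, j, k] <- mean(up[(i - 1) * 8 + 1:8, (j - 1) * 8 + 1:8,
                             (k - 1) * 8 + 1:8])
  expect_gt(cor(as.numeric(down), as.numeric(m4)), 0.9)
  expect_error(upsample_cam(m4, c(0, 4, 4)), "positive")
})

test_that("slice overlays blend as documented and count the depth", {
  set.seed(6)
  patch <- array(runif(32^3), c(32, 32, 32))
  cam <- upsample_cam(array(runif(64), c(4, 4, 4)), c(32, 32, 32))
  ov0 <- overlay_slices(patch, cam, alpha = 0)
  expect_length(ov0$slices, 32L)
  gr <- (patch - min(patch)) / (max(patch) - min(patch))
  expect_lt(max(abs(ov0$slices[[5]][, , 1] - gr[5, , ])), 1e-12)
  expect_lt(max(abs(ov0$slices[[5]][, , 2] - ov0$slices[[5]][, , 3])), 1e-12)
  ov1 <- overlay_slices(patch, cam, alpha = 1)
  jet <- ghostnet3d:::.jet(cam[9, , ])
  expect_lt(max(abs(ov1$slices[[9]][, , 1] - jet$r)), 1e-12)
  expect_equal(dim(ov1$mosaic), c(4 * 32, 8 * 32, 3))
  expect_error(overlay_slices(patch, cam[1:16, , ], alpha = 0.5), "shapes")
  expect_error(overlay_slices(patch, cam, alpha = 2), "alpha")
  dir <- withr::local_tempdir()
  overlay_slices(patch, cam, alpha = 0.4, dir = dir)
  expect_length(list.files(dir, pattern = "^slice_\\d+\\.png$"), 32L)
  expect_true(file.exists(file.path(dir, "mosaic.png")))
  expect_true(file.exists(file.path(dir, "cam.mhd")))
})

test_that("occlusion maps locate the strongest evidence region", {
  net <- make_small_net()
  params <- ghostnet3d:::net_params(net)
  set.seed(7)
  params$fc.W <- matrix(rnorm(length(params$fc.W), 0, 0.5),
                        nrow(params$fc.W), ncol(params$fc.W))
  net <- ghostnet3d:::net_set_params(net, params)
  patch <- array(runif(16^3), c(16, 16, 16))
  oc <- occlusion_map(net, patch, target_class = "malignant",
                      size = 8L, stride = 4L)
  expect_equal(dim(oc$drop), c(3L, 3L, 3L))
  expect_length(oc$argmax, 3L)
  oc2 <- occlusion_map(net, patch, target_class = "malignant",
                       size = 8L, stride = 4L)
  expect_identical(oc$drop, oc2$drop)        # eval purity
})
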