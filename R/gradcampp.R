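#' Grad-CAM++ saliency volume
#'
#' Class-discriminative 3D saliency at an internal layer. The score is the
#' pre-softmax logit of the target class (the closed form below assumes an
#' exponential link from logit to score, and logits avoid vanishing
#' gradients at confident predictions). With `A` the layer's activations and
#' `g = dS/dA` the first-order gradients, the exponential-score analytic
#' shortcut expresses the second/third-order terms in `g` alone:
#' `alpha = g^2 / (2 g^2 + sum_vox(A_k) g^3)`, channel weights
#' `w_k = sum_vox(alpha * relu(g))`, and the raw map
#' `relu(sum_k w_k A_k)`, min-max normalized to `[0, 1]`.
#'
#' @param net a `ghost_resnet3d` (weights initialized; run in eval mode).
#' @param patch a 32^3 cube or `labeled_patch`.
#' @param target_class `"benign"`, `"malignant"`, a class index, or NULL
#'   (predicted class).
#' @param layer_id internal node id: `"stem"`, `"pool"`, `"stageS"` or
#'   `"stageS.blockB"`. Default `"stage3"`, the output of the last residual
#'   block of the third stage.
#' @return object of class `saliency_map`: list with `cam` (3D array in
#'   `[0, 1]` at the layer's resolution), `target_class`, `layer_id`,
#'   `degenerate` (TRUE when the map is identically zero, e.g. a layer
#'   disconnected from the score).
#' @export
grad_cam_pp <- function(net, patch, target_class = NULL, layer_id = "stage3") {
  cube <- if (inherits(patch, "labeled_patch")) patch$cube else patch
  xb <- as_batch(cube)
  fw <- net_forward(net, xb, train = FALSE, collect = layer_id)
  if (is.null(fw$acts[[layer_id]]))
    stop("unknown layer_id: ", layer_id, call. = FALSE)
  logits <- fw$logits
  nc <- net$config$num_classes
  cls <- if (is.null(target_class)) which.max(logits[1L, ])
         else if (is.character(target_class))
           match(target_class, c("benign", "malignant"))
         else as.integer(target_class)
  if (is.na(cls) || cls < 1L || cls > nc)
    stop("target_class must select one of the ", nc, " classes", call. = FALSE)
  gl <- matrix(0, 1L, nc); gl[1L, cls] <- 1
  bw <- net_backward(net, fw$caches, gl, grad_at = layer_id)
  A <- fw$acts[[layer_id]]; g <- bw$node_grads[[layer_id]]
  d <- dim(A); dhw <- prod(d[1:3]); C <- d[4L]
  Am <- matrix(A, dhw, C); gm <- matrix(g, dhw, C)
  g2 <- gm * gm; g3 <- g2 * gm
  sumA <- colSums(Am)
  denom <- 2 * g2 + matrix(sumA, dhw, C, byrow = TRUE) * g3
  alpha <- ifelse(abs(denom) > 1e-12, g2 / denom, 0)
  w <- colSums(alpha * pmax(gm, 0))
  cam <- pmax(Am %*% w, 0)
  dim(cam) <- d[1:3]
  degenerate <- max(cam) <= 0
  if (!degenerate) cam <- normalize_cam(cam)
  structure(list(cam = cam,
                 target_class = c("benign", "malignant")[min(cls, 2L)],
                 layer_id = layer_id, degenerate = degenerate),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map %s @ %s: %s%s>\n", x$target_class, x$layer_id,
              paste(dim(x$cam), collapse = "x"),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Min-max normalization of a saliency volume
#'
#' Idempotent: normalizing twice equals normalizing once. An identically
#' constant map is returned as zeros.
#'
#' @param cam 3D numeric array.
#' @return array rescaled to `[0, 1]`.
#' @export
normalize_cam <- function(cam) {
  r <- range(cam)
  if (r[2] - r[1] <= 0) return(array(0, dim(cam)))
  (cam - r[1]) / (r[2] - r[1])
}

#' Trilinear upsampling of a saliency map
#'
#' @param map a `saliency_map` or bare 3D array.
#' @param target_shape output shape (default 32^3, the input patch size).
#' @param renormalize min-max normalize after interpolation (default TRUE).
#' @return same type as `map`, at `target_shape`.
#' @export
upsample_cam <- function(map, target_shape = c(32L, 32L, 32L),
                         renormalize = TRUE) {
  cam <- if (inherits(map, "saliency_map")) map$cam else map
  if (any(target_shape < 1L)) stop("target_shape must be positive", call. = FALSE)
  src <- dim(cam)
  axes <- lapply(1:3, function(a) {
    n_out <- target_shape[a]; n_in <- src[a]
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5   # 0-based source coord
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    list(lo = as.integer(lo) + 1L, hi = pmin(as.integer(lo) + 2L, n_in),
         f = pos - lo)
  })
  out <- array(0, target_shape)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    iz <- if (dz == 0) axes[[1]]$lo else axes[[1]]$hi
    iy <- if (dy == 0) axes[[2]]$lo else axes[[2]]$hi
    ix <- if (dx == 0) axes[[3]]$lo else axes[[3]]$hi
    wz <- if (dz == 0) 1 - axes[[1]]$f else axes[[1]]$f
    wy <- if (dy == 0) 1 - axes[[2]]$f else axes[[2]]$f
    wx <- if (dx == 0) 1 - axes[[3]]$f else axes[[3]]$f
    wgt <- array(outer(outer(wz, wy), wx), target_shape)
    out <- out + cam[iz, iy, ix, drop = FALSE] * wgt
  }
  if (renormalize) out <- normalize_cam(out)
  if (inherits(map, "saliency_map")) { map$cam <- out; map } else out
}

#' Location of the saliency maximum
#'
#' @param map a `saliency_map` or 3D array.
#' @return integer `(z, y, x)` 1-based index of the maximum.
#' @export
cam_argmax <- function(map) {
  cam <- if (inherits(map, "saliency_map")) map$cam else map
  arrayInd(which.max(cam), dim(cam))[1L, ]
}

#' Occlusion-sensitivity map
#'
#' Model-agnostic saliency: slide a filled cube over the patch and record the
#' drop in the target-class logit. Used as an independent localization check
#' on the gradient-based maps.
#'
#' @param net a `ghost_resnet3d`.
#' @param patch 32^3 cube or `labeled_patch`.
#' @param target_class as in [grad_cam_pp()] (NULL = predicted class).
#' @param size occluder edge, voxels (default 8).
#' @param stride occluder stride (default 4).
#' @param fill occluder value (default: patch minimum).
#' @return object of class `occlusion_map`: `drop` (3D array over the
#'   occluder grid), `centers` (list of per-axis occluder-center voxel
#'   coordinates), `argmax` (`(z,y,x)` center of the strongest drop).
#' @export
occlusion_map <- function(net, patch, target_class = NULL, size = 8L,
                          stride = 4L, fill = NULL) {
  cube <- if (inherits(patch, "labeled_patch")) patch$cube else patch
  d <- dim(cube)
  if (is.null(fill)) fill <- min(cube)
  logits0 <- net_forward(net, as_batch(cube), train = FALSE)$logits
  cls <- if (is.null(target_class)) which.max(logits0[1L, ])
         else if (is.character(target_class))
           match(target_class, c("benign", "malignant"))
         else as.integer(target_class)
  starts <- lapply(d, function(n) seq(1L, n - size + 1L, by = stride))
  grid <- expand.grid(z = starts[[1]], y = starts[[2]], x = starts[[3]])
  drops <- numeric(nrow(grid))
  chunk <- 32L
  for (i0 in seq(1L, nrow(grid), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(grid))
    xb <- array(0, c(d, 1L, length(idx)))
    for (j in seq_along(idx)) {
      cc <- cube
      gi <- grid[idx[j], ]
      cc[gi$z + seq_len(size) - 1L, gi$y + seq_len(size) - 1L,
         gi$x + seq_len(size) - 1L] <- fill
      xb[, , , 1L, j] <- cc
    }
    lg <- net_forward(net, xb, train = FALSE)$logits
    drops[idx] <- logits0[1L, cls] - lg[, cls]
  }
  dims <- lengths(starts)
  drop_arr <- array(drops, dims)
  am <- arrayInd(which.max(drop_arr), dims)[1L, ]
  centers <- lapply(starts, function(s) s + (size - 1) / 2)
  argmax <- vapply(1:3, function(a) centers[[a]][am[a]], numeric(1))
  structure(list(drop = drop_arr, centers = centers, argmax = argmax,
                 target_class = c("benign", "malignant")[min(cls, 2L)]),
            class = "occlusion_map")
}

.jet <- function(v) {
  cl <- function(x) pmin(pmax(x, 0), 1)
  list(r = cl(1.5 - abs(4 * v - 3)), g = cl(1.5 - abs(4 * v - 2)),
       b = cl(1.5 - abs(4 * v - 1)))
}

#' Per-slice heatmap overlays and mosaic
#'
#' Blends each axial (depth) slice of the patch, rendered grayscale, with a
#' jet-style colormap of the saliency map: `alpha = 0` reproduces the
#' grayscale slices, `alpha = 1` the pure colormapped map. Also assembles the
#' 4 x 8 mosaic of all 32 slices. When `dir` is given, writes
#' `slice_NN.png` files, `mosaic.png`, and the raw saliency volume as a
#' MetaImage pair (`cam.mhd`) for external viewers.
#'
#' @param patch 32^3 cube or `labeled_patch` (intensities any range;
#'   rescaled to `[0, 1]` for display).
#' @param map `saliency_map` or 3D array, same shape as the patch.
#' @param alpha blend weight of the heatmap in `[0, 1]` (default 0.4).
#' @param dir optional output directory for PNG/MetaImage export.
#' @return invisibly, list with `slices` (list of H x W x 3 arrays, one per
#'   depth index) and `mosaic` (stacked 4 x 8 panel).
#' @export
overlay_slices <- function(patch, map, alpha = 0.4, dir = NULL) {
  cube <- if (inherits(patch, "labeled_patch")) patch$cube else patch
  cam <- if (inherits(map, "saliency_map")) map$cam else map
  if (!all(dim(cube) == dim(cam)))
    stop("patch and saliency map shapes differ", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  gr <- normalize_cam(cube)        # grayscale display range
  d <- dim(cube)
  slices <- vector("list", d[1L])
  for (z in seq_len(d[1L])) {
    g <- gr[z, , ]
    jc <- .jet(cam[z, , ])
    img <- array(0, c(d[2L], d[3L], 3L))
    img[, , 1] <- (1 - alpha) * g + alpha * jc$r
    img[, , 2] <- (1 - alpha) * g + alpha * jc$g
    img[, , 3] <- (1 - alpha) * g + alpha * jc$b
    slices[[z]] <- img
  }
  nrow_m <- 4L; ncol_m <- ceiling(d[1L] / 4L)
  mosaic <- array(0, c(nrow_m * d[2L], ncol_m * d[3L], 3L))
  for (z in seq_len(d[1L])) {
    r <- (z - 1L) %/% ncol_m; cc <- (z - 1L) %% ncol_m
    mosaic[r * d[2L] + seq_len(d[2L]), cc * d[3L] + seq_len(d[3L]), ] <- slices[[z]]
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_len(d[1L]))
      png::writePNG(slices[[z]], file.path(dir, sprintf("slice_%02d.png", z)))
    png::writePNG(mosaic, file.path(dir, "mosaic.png"))
    write_mhd(ct_volume(cam, series_uid = "cam"),
              file.path(dir, "cam.mhd"), element_type = "MET_FLOAT")
  }
  invisible(list(slices = slices, mosaic = mosaic))
}
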