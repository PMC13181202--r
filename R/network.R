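#' Architectural genotype of a 3D ghost residual network
#'
#' Describes one member of the network family: a stem (3^3 convolution at
#' full resolution followed by a 3^3/stride-2 max pool), four residual stages
#' of basic or bottleneck blocks, global average pooling, and a 2-way fully
#' connected head. Five depth variants are available, named by their weighted
#' layer counts as in the 2D residual-network family. The default genotype is
#' the flagship 50-layer ghost network: every bottleneck convolution is a
#' ghost module at ratio 2, projection shortcuts are 3^3 ghost convolutions,
#' the trunk normalizes with layer norm and the blocks with batch norm, and
#' all activations are ELU.
#'
#' @param depth 18, 34, 50, 101 or 152. 18/34 use basic (two 3^3 conv)
#'   blocks; the rest use 1-3-1 bottlenecks with `expansion` 4.
#' @param ghost use ghost modules in the blocks (default TRUE).
#' @param ghost_ratio ghost ratio s: the primary convolution computes
#'   `ceiling(cout/s)` maps, cheap depthwise 3^3 convs the rest (default 2).
#' @param widths base widths of the four stages.
#' @param expansion bottleneck output multiplier (ignored for basic blocks).
#' @param trunk_norm,block_norm normalization in the stem / in the blocks:
#'   `"batch"`, `"layer"`, `"instance"`, or `"weight"` (weight norm
#'   reparameterizes the preceding convolution; the activation-statistics
#'   branch is a no-op).
#' @param downsample_norm normalization after projection shortcuts (defaults
#'   to `block_norm`).
#' @param activation `"elu"`, `"relu"`, `"leaky_relu"`, or `"gelu"`.
#' @param downsample_kernel 1 or 3: kernel of the projection shortcut
#'   convolutions (3 in the flagship network, 1 in the plain baseline).
#' @param stem_width stem output channels (default 64).
#' @param stem_stride stride of the stem convolution (default 1; the stem
#'   max pool performs the first spatial reduction).
#' @param stem_pool include the 3^3/2 stem max pool (default TRUE).
#' @param num_classes classifier arity (default 2: benign vs malignant).
#' @param in_channels input channels (default 1, CT).
#' @param stage_blocks optional 4-vector overriding the depth variant's
#'   per-stage block counts (zeros allowed; used for shallow desk-scale
#'   models such as the saliency localization study's tiny classifier).
#' @return object of class `network_config`.
#' @export
network_config <- function(depth = 50L, ghost = TRUE, ghost_ratio = 2L,
                           widths = c(64L, 128L, 256L, 512L), expansion = 4L,
                           trunk_norm = "layer", block_norm = "batch",
                           downsample_norm = block_norm,
                           activation = "elu", downsample_kernel = 3L,
                           stem_width = widths[1], stem_stride = 1L,
                           stem_pool = TRUE, num_classes = 2L,
                           in_channels = 1L, stage_blocks = NULL) {
  variants <- list(`18` = list(blocks = c(2L, 2L, 2L, 2L), kind = "basic"),
                   `34` = list(blocks = c(3L, 4L, 6L, 3L), kind = "basic"),
                   `50` = list(blocks = c(3L, 4L, 6L, 3L), kind = "bottleneck"),
                   `101` = list(blocks = c(3L, 4L, 23L, 3L), kind = "bottleneck"),
                   `152` = list(blocks = c(3L, 8L, 36L, 3L), kind = "bottleneck"))
  key <- as.character(depth)
  if (!key %in% names(variants))
    stop("depth must be one of 18, 34, 50, 101, 152", call. = FALSE)
  norms <- c("batch", "layer", "instance", "weight")
  acts <- c("elu", "relu", "leaky_relu", "gelu")
  if (!trunk_norm %in% norms || !block_norm %in% norms || !downsample_norm %in% norms)
    stop("norms must be one of: ", paste(norms, collapse = ", "), call. = FALSE)
  if (!activation %in% acts)
    stop("activation must be one of: ", paste(acts, collapse = ", "), call. = FALSE)
  if (!downsample_kernel %in% c(1L, 3L))
    stop("downsample_kernel must be 1 or 3", call. = FALSE)
  if (length(widths) != 4L || any(widths < 1L))
    stop("widths must be 4 positive integers", call. = FALSE)
  if (ghost_ratio < 1L) stop("ghost_ratio must be >= 1", call. = FALSE)
  blocks <- if (is.null(stage_blocks)) variants[[key]]$blocks
            else as.integer(stage_blocks)
  if (length(blocks) != 4L || any(blocks < 0L))
    stop("stage_blocks must be 4 nonnegative integers", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 stage_blocks = blocks,
                 block_kind = variants[[key]]$kind,
                 ghost = isTRUE(ghost), ghost_ratio = as.integer(ghost_ratio),
                 widths = as.integer(widths), expansion = as.integer(expansion),
                 trunk_norm = trunk_norm, block_norm = block_norm,
                 downsample_norm = downsample_norm, activation = activation,
                 downsample_kernel = as.integer(downsample_kernel),
                 stem_width = as.integer(stem_width),
                 stem_stride = as.integer(stem_stride),
                 stem_pool = isTRUE(stem_pool),
                 num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels)),
            class = "network_config")
}

#' Baseline (plain convolution) genotype
#'
#' The ablation baseline: identical trunk and stage layout but ordinary
#' convolutions, 1^3 projection shortcuts, batch norm and ReLU throughout.
#'
#' @param depth network depth (default 50).
#' @param ... overrides passed to [network_config()].
#' @return a `network_config`.
#' @export
baseline_config <- function(depth = 50L, ...) {
  args <- modifyList(list(depth = depth, ghost = FALSE, trunk_norm = "batch",
                          block_norm = "batch", activation = "relu",
                          downsample_kernel = 1L),
                     list(...))
  do.call(network_config, args)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config depth %d (%s blocks %s), %s convs, norm %s/%s, act %s, shortcut %d^3>\n",
              x$depth, x$block_kind, paste(x$stage_blocks, collapse = "-"),
              if (x$ghost) sprintf("ghost s=%d", x$ghost_ratio) else "plain",
              x$trunk_norm, x$block_norm, x$activation, x$downsample_kernel))
  invisible(x)
}

# A conv "slot": ghost module or plain conv according to the config. Weight
# norm is a conv reparameterization, so when the governing norm is "weight"
# the convs carry it and the norm_act layers degrade to activation only.
.make_slot <- function(config, k, cin, cout, stride, norm) {
  if (config$ghost && config$ghost_ratio > 1L) {
    new_ghost(k, cin, cout, ratio = config$ghost_ratio, stride = stride,
              norm = if (norm == "weight") "none" else norm,
              act = config$activation)
  } else {
    new_conv(k, cin, cout, stride = stride, weightnorm = norm == "weight")
  }
}

.make_norm <- function(norm, channels, act) {
  new_norm_act(if (norm == "weight") "none" else norm, act, channels)
}

.make_block <- function(config, cin, w, stride, first) {
  norm <- config$block_norm
  dsn <- config$downsample_norm
  act <- config$activation
  if (config$block_kind == "bottleneck") {
    cout <- w * config$expansion
    blk <- list(type = "block", kind = "bottleneck", cin = cin, cout = cout,
                conv1 = .make_slot(config, 1L, cin, w, 1L, norm),
                na1 = .make_norm(norm, w, act),
                conv2 = .make_slot(config, 3L, w, w, stride, norm),
                na2 = .make_norm(norm, w, act),
                conv3 = .make_slot(config, 1L, w, cout, 1L, norm),
                norm3 = .make_norm(norm, cout, "none"),
                act_out = new_norm_act("none", act, cout))
  } else {
    cout <- w
    blk <- list(type = "block", kind = "basic", cin = cin, cout = cout,
                conv1 = .make_slot(config, 3L, cin, w, stride, norm),
                na1 = .make_norm(norm, w, act),
                conv2 = .make_slot(config, 3L, w, w, 1L, norm),
                norm3 = .make_norm(norm, cout, "none"),
                act_out = new_norm_act("none", act, cout))
  }
  if (first && (stride != 1L || cin != cout)) {
    blk$ds_conv <- .make_slot(config, config$downsample_kernel, cin, cout,
                              stride, dsn)
    blk$ds_norm <- .make_norm(dsn, cout, "none")
  }
  blk
}

#' Build a network from its genotype
#'
#' Assembles the layer graph and initializes weights (He-normal fan-in
#' scaling, deterministic in `seed`). `init = "zero"` allocates zero-filled
#' tensors (useful for complexity audits); `init = "meta"` allocates no
#' tensors at all - the structural skeleton still supports parameter and MAC
#' accounting.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @param init `"he"`, `"zero"`, or `"meta"`.
#' @return object of class `ghost_resnet3d`.
#' @export
build_network <- function(config, seed = 1L, init = c("he", "zero", "meta")) {
  init <- match.arg(init)
  net <- list(config = config)
  tn <- config$trunk_norm
  net$stem <- list(
    conv = new_conv(3L, config$in_channels, config$stem_width,
                    stride = config$stem_stride,
                    weightnorm = tn == "weight"),
    na = .make_norm(tn, config$stem_width, config$activation))
  net$pool <- if (config$stem_pool) new_maxpool(3L, 2L, 1L) else NULL
  cin <- config$stem_width
  net$stages <- vector("list", 4L)
  for (s in 1:4) {
    w <- config$widths[s]
    nblocks <- config$stage_blocks[s]
    blocks <- vector("list", nblocks)
    for (b in seq_len(nblocks)) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      blocks[[b]] <- .make_block(config, cin, w, stride, first = b == 1L)
      cin <- blocks[[b]]$cout
    }
    net$stages[[s]] <- blocks
  }
  net$gap <- new_gap()
  net$fc <- new_linear(cin, config$num_classes)
  net <- structure(net, class = "ghost_resnet3d")
  if (init != "meta") net <- with_seed(seed, net_init(net, init))
  net
}

net_init <- function(net, init) {
  net$stem$conv <- init_layer(net$stem$conv, init)
  net$stem$na <- init_layer(net$stem$na, init)
  for (s in 1:4) for (b in seq_along(net$stages[[s]])) {
    blk <- net$stages[[s]][[b]]
    for (f in .block_slots(blk)) blk[[f]] <- init_layer(blk[[f]], init)
    net$stages[[s]][[b]] <- blk
  }
  net$fc <- init_layer(net$fc, init)
  net
}

.block_slots <- function(blk) {
  slots <- if (blk$kind == "bottleneck")
    c("conv1", "na1", "conv2", "na2", "conv3", "norm3", "act_out")
  else c("conv1", "na1", "conv2", "norm3", "act_out")
  if (!is.null(blk$ds_conv)) slots <- c(slots, "ds_conv", "ds_norm")
  slots
}

block_fwd <- function(blk, x, train) {
  cache <- list()
  if (!is.null(blk$ds_conv)) {
    r <- slot_fwd(blk$ds_conv, x, train); blk$ds_conv <- r$layer
    cache$ds_conv <- r$cache
    r2 <- slot_fwd(blk$ds_norm, r$y, train); blk$ds_norm <- r2$layer
    cache$ds_norm <- r2$cache
    shortcut <- r2$y
  } else shortcut <- x
  h <- x
  main_slots <- setdiff(.block_slots(blk), c("ds_conv", "ds_norm", "act_out"))
  for (f in main_slots) {
    r <- slot_fwd(blk[[f]], h, train); blk[[f]] <- r$layer
    cache[[f]] <- r$cache
    h <- r$y
  }
  r <- slot_fwd(blk$act_out, h + shortcut, train); blk$act_out <- r$layer
  cache$act_out <- r$cache
  list(y = r$y, cache = cache, layer = blk)
}

block_bwd <- function(blk, cache, gy) {
  grads <- list()
  r <- slot_bwd(blk$act_out, cache$act_out, gy)
  g <- r$gx                      # grad of (main + shortcut)
  gsc <- g
  if (!is.null(blk$ds_conv)) {
    r2 <- slot_bwd(blk$ds_norm, cache$ds_norm, g)
    grads$ds_norm <- r2$grads
    r3 <- slot_bwd(blk$ds_conv, cache$ds_conv, r2$gx)
    grads$ds_conv <- r3$grads
    gsc <- r3$gx
  }
  main_slots <- rev(setdiff(.block_slots(blk), c("ds_conv", "ds_norm", "act_out")))
  for (f in main_slots) {
    r <- slot_bwd(blk[[f]], cache[[f]], g)
    grads[[f]] <- r$grads
    g <- r$gx
  }
  list(gx = g + gsc, grads = grads)
}

# Full forward pass. Returns logits (N x num_classes), the cache tree, the
# (possibly updated) network, and the activations of any requested node ids
# ("stem", "pool", "stageS", "stageS.blockB").
net_forward <- function(net, x, train = FALSE, collect = character()) {
  acts <- list()
  keep <- function(id, y) if (id %in% collect) acts[[id]] <<- y
  caches <- list()
  r <- slot_fwd(net$stem$conv, x, train); net$stem$conv <- r$layer
  caches$stem_conv <- r$cache
  r <- slot_fwd(net$stem$na, r$y, train); net$stem$na <- r$layer
  caches$stem_na <- r$cache
  h <- r$y; keep("stem", h)
  if (!is.null(net$pool)) {
    r <- slot_fwd(net$pool, h, train)
    caches$pool <- r$cache
    h <- r$y; keep("pool", h)
  }
  caches$stages <- vector("list", 4L)
  for (s in 1:4) {
    nb <- length(net$stages[[s]])
    caches$stages[[s]] <- vector("list", nb)
    for (b in seq_len(nb)) {
      r <- block_fwd(net$stages[[s]][[b]], h, train)
      net$stages[[s]][[b]] <- r$layer
      caches$stages[[s]][[b]] <- r$cache
      h <- r$y
      keep(sprintf("stage%d.block%d", s, b), h)
    }
    keep(sprintf("stage%d", s), h)
  }
  r <- gap_fwd(net$gap, h); caches$gap <- r$cache
  r2 <- linear_fwd(net$fc, r$y); caches$fc <- r2$cache
  list(logits = r2$y, caches = caches, net = net, acts = acts)
}

# Full backward pass from d(loss)/d(logits). Returns flat named parameter
# grads and, when `grad_at` node ids are given, the gradient of the scalar
# objective with respect to those nodes' outputs.
net_backward <- function(net, caches, glogits, grad_at = character()) {
  node_grads <- list()
  keep <- function(id, g) if (id %in% grad_at) node_grads[[id]] <<- g
  grads <- list()
  r <- linear_bwd(net$fc, caches$fc, glogits)
  grads <- c(grads, stats::setNames(r$grads, paste0("fc.", names(r$grads))))
  r2 <- gap_bwd(net$gap, caches$gap, r$gx)
  g <- r2$gx
  for (s in 4:1) {
    keep(sprintf("stage%d", s), g)
    for (b in rev(seq_along(net$stages[[s]]))) {
      keep(sprintf("stage%d.block%d", s, b), g)
      blk <- net$stages[[s]][[b]]
      br <- block_bwd(blk, caches$stages[[s]][[b]], g)
      path <- sprintf("stage%d.block%d", s, b)
      for (f in names(br$grads))
        grads <- c(grads, flatten_layer_grads(blk[[f]], paste0(path, ".", f),
                                              br$grads[[f]]))
      g <- br$gx
    }
  }
  if (!is.null(net$pool)) {
    keep("pool", g)
    g <- maxpool_bwd(net$pool, caches$pool, g)$gx
  }
  keep("stem", g)
  r <- slot_bwd(net$stem$na, caches$stem_na, g)
  grads <- c(grads, flatten_layer_grads(net$stem$na, "stem.na", r$grads))
  r2 <- slot_bwd(net$stem$conv, caches$stem_conv, r$gx)
  grads <- c(grads, flatten_layer_grads(net$stem$conv, "stem.conv", r2$grads))
  list(grads = grads, gx = r2$gx, node_grads = node_grads)
}

# Flat named list of every trainable tensor.
net_params <- function(net) {
  out <- c(collect_layer_params(net$stem$conv, "stem.conv"),
           collect_layer_params(net$stem$na, "stem.na"))
  for (s in 1:4) for (b in seq_along(net$stages[[s]])) {
    blk <- net$stages[[s]][[b]]
    path <- sprintf("stage%d.block%d", s, b)
    for (f in .block_slots(blk))
      out <- c(out, collect_layer_params(blk[[f]], paste0(path, ".", f)))
  }
  c(out, collect_layer_params(net$fc, "fc"))
}

net_set_params <- function(net, params) {
  net$stem$conv <- set_layer_params(net$stem$conv, "stem.conv", params)
  net$stem$na <- set_layer_params(net$stem$na, "stem.na", params)
  for (s in 1:4) for (b in seq_along(net$stages[[s]])) {
    blk <- net$stages[[s]][[b]]
    path <- sprintf("stage%d.block%d", s, b)
    for (f in .block_slots(blk))
      blk[[f]] <- set_layer_params(blk[[f]], paste0(path, ".", f), params)
    net$stages[[s]][[b]] <- blk
  }
  net$fc <- set_layer_params(net$fc, "fc", params)
  net
}

#' @export
print.ghost_resnet3d <- function(x, ...) {
  print(x$config)
  cr <- complexity_report(x)
  cat(sprintf("  params: %s (%.2f M), MACs at 1x32^3: %.2f Gmac\n",
              format(cr$params_exact, big.mark = ","), cr$params_M,
              cr$macs_Gmac))
  invisible(x)
}

#' Class probabilities / logits from a built network
#'
#' Runs the network in eval mode (a pure function of weights and input).
#'
#' @param object a `ghost_resnet3d`.
#' @param x patches: 3D cube, `(n, D, H, W)` array, or list of cubes /
#'   `labeled_patch`es.
#' @param type `"prob"` (softmax confidences), `"logits"`, or `"class"`.
#' @param ... unused.
#' @return matrix `n x num_classes` (columns `benign`, `malignant` when
#'   2-way), or a character vector for `type = "class"`.
#' @export
predict.ghost_resnet3d <- function(object, x, type = c("prob", "logits", "class"),
                                   ...) {
  type <- match.arg(type)
  xb <- as_batch(x)
  logits <- net_forward(object, xb, train = FALSE)$logits
  if (object$config$num_classes == 2L)
    colnames(logits) <- c("benign", "malignant")
  if (type == "logits") return(logits)
  p <- softmax_rows(logits)
  if (type == "prob") return(p)
  colnames(p)[max.col(p, ties.method = "first")]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  dimnames(p) <- dimnames(z)
  p
}
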