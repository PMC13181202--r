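# Parameter and multiply-accumulate accounting.
#
# Parameter counts are closed-form functions of each layer's declared shape
# (so they work on "meta" skeletons); the test suite checks them against a
# brute-force walk over the allocated tensors. MAC counts track the spatial
# extent through the network analytically.

.conv_out_sz <- function(n, k, s, p) as.integer((n + 2 * p - k) %/% s + 1)

.layer_param_count <- function(layer) {
  switch(layer$type,
    conv = {
      w <- layer$k^3 * (layer$cin %/% layer$groups) * layer$cout
      if (layer$weightnorm) w + layer$cout else w
    },
    norm_act = if (.has_affine(layer$kind)) 2 * layer$channels else 0,
    linear = layer$cin * layer$cout + layer$cout,
    ghost = {
      n <- .layer_param_count(layer$primary)
      if (!is.null(layer$cheap))
        n <- n + .layer_param_count(layer$na1) + .layer_param_count(layer$cheap) +
          .layer_param_count(layer$na2)
      n
    },
    0)
}

# MACs (multiply-accumulate-equivalent op count) for one layer given the
# input spatial shape. Returns list(macs, shape, channels).
.layer_macs <- function(layer, shape, cin, convention) {
  elementwise <- convention == "op"
  switch(layer$type,
    conv = {
      out <- vapply(shape, .conv_out_sz, integer(1),
                    k = layer$k, s = layer$stride, p = layer$pad)
      vox <- prod(out)
      list(macs = layer$k^3 * (layer$cin / layer$groups) * layer$cout * vox,
           shape = out, channels = layer$cout)
    },
    norm_act = {
      vox <- prod(shape) * cin
      m <- 0
      if (elementwise) {
        if (layer$kind %in% c("batch", "layer", "instance")) m <- m + 2 * vox
        if (layer$act != "none") m <- m + vox
      }
      list(macs = m, shape = shape, channels = cin)
    },
    maxpool = {
      out <- vapply(shape, .conv_out_sz, integer(1),
                    k = layer$k, s = layer$stride, p = layer$pad)
      list(macs = if (elementwise) prod(shape) * cin else 0,
           shape = out, channels = cin)
    },
    gap = list(macs = if (elementwise) prod(shape) * cin else 0,
               shape = c(1L, 1L, 1L), channels = cin),
    linear = list(macs = layer$cin * layer$cout + layer$cout,
                  shape = shape, channels = layer$cout),
    ghost = {
      p <- .layer_macs(layer$primary, shape, cin, convention)
      m <- p$macs
      if (!is.null(layer$cheap)) {
        n1 <- .layer_macs(layer$na1, p$shape, layer$m, convention)
        ch <- .layer_macs(layer$cheap, p$shape, layer$m, convention)
        n2 <- .layer_macs(layer$na2, ch$shape, layer$cheap_channels, convention)
        m <- m + n1$macs + ch$macs + n2$macs
      }
      list(macs = m, shape = p$shape, channels = layer$cout)
    },
    stop("unknown layer type"))
}

.block_stats <- function(blk, shape, convention) {
  macs <- 0
  main_slots <- setdiff(.block_slots(blk), c("ds_conv", "ds_norm", "act_out"))
  sh <- shape; ch <- blk$cin
  for (f in main_slots) {
    r <- .layer_macs(blk[[f]], sh, ch, convention)
    macs <- macs + r$macs; sh <- r$shape; ch <- r$channels
  }
  if (!is.null(blk$ds_conv)) {
    r <- .layer_macs(blk$ds_conv, shape, blk$cin, convention)
    macs <- macs + r$macs
    macs <- macs + .layer_macs(blk$ds_norm, r$shape, blk$cout, convention)$macs
  }
  if (convention == "op") macs <- macs + prod(sh) * ch          # residual add
  macs <- macs + .layer_macs(blk$act_out, sh, ch, convention)$macs
  list(macs = macs, shape = sh, channels = ch)
}

#' Exact trainable parameter count
#'
#' Closed-form count of every trainable scalar (conv kernels, norm affine
#' gains/biases, weight-norm gains and directions, the classifier head).
#' Running batch-norm statistics are buffers, not parameters, and are not
#' counted.
#'
#' @param net a `ghost_resnet3d` (any init, including `"meta"`).
#' @return exact count as a numeric scalar with attribute `"millions"`
#'   (half-up, 2 dp).
#' @export
count_parameters <- function(net) {
  total <- .layer_param_count(net$stem$conv) + .layer_param_count(net$stem$na)
  for (s in 1:4) for (blk in net$stages[[s]])
    for (f in .block_slots(blk)) total <- total + .layer_param_count(blk[[f]])
  total <- total + .layer_param_count(net$fc)
  structure(total, millions = round_half_up(total / 1e6, 2))
}

#' Multiply-accumulate count for one forward pass
#'
#' Counts the arithmetic cost of a single-sample forward pass. Two
#' conventions are available. `"op"` (default) mirrors the widely used
#' network profilers: convolution and linear multiply-accumulates plus
#' per-element costs for the cheap ops (2/element for a normalization,
#' 1/element for an activation, 1/input-element for pooling, 1/element for a
#' residual addition). `"conv_linear"` counts convolution and linear MACs
#' only. The `"op"` convention is the calibrated default used in the
#' package's complexity reports.
#'
#' @param net a `ghost_resnet3d`.
#' @param input_shape spatial input shape (default `c(32, 32, 32)`).
#' @param convention `"op"` or `"conv_linear"`.
#' @return MAC count as a numeric scalar with attribute `"Gmac"` (half-up,
#'   2 dp).
#' @export
count_macs <- function(net, input_shape = c(32L, 32L, 32L),
                       convention = c("op", "conv_linear")) {
  convention <- match.arg(convention)
  sh <- as.integer(input_shape); ch <- net$config$in_channels
  total <- 0
  r <- .layer_macs(net$stem$conv, sh, ch, convention)
  total <- r$macs; sh <- r$shape; ch <- r$channels
  r <- .layer_macs(net$stem$na, sh, ch, convention)
  total <- total + r$macs
  if (!is.null(net$pool)) {
    r <- .layer_macs(net$pool, sh, ch, convention)
    total <- total + r$macs; sh <- r$shape
  }
  for (s in 1:4) for (blk in net$stages[[s]]) {
    r <- .block_stats(blk, sh, convention)
    total <- total + r$macs; sh <- r$shape; ch <- r$channels
  }
  r <- .layer_macs(net$gap, sh, ch, convention)
  total <- total + r$macs
  total <- total + .layer_macs(net$fc, c(1L, 1L, 1L), ch, convention)$macs
  structure(total, Gmac = round_half_up(total / 1e9, 2))
}

#' Complexity report for a network
#'
#' @param net a `ghost_resnet3d`.
#' @param input_shape spatial input shape (default 32^3).
#' @param convention MAC convention, see [count_macs()].
#' @return object of class `complexity_report`: list with `params_exact`,
#'   `params_M`, `macs`, `macs_Gmac`, `input_shape`.
#' @export
complexity_report <- function(net, input_shape = c(32L, 32L, 32L),
                              convention = "op") {
  p <- count_parameters(net)
  m <- count_macs(net, input_shape, convention)
  structure(list(params_exact = as.numeric(p),
                 params_M = attr(p, "millions"),
                 macs = as.numeric(m),
                 macs_Gmac = attr(m, "Gmac"),
                 input_shape = as.integer(input_shape)),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("params: %s (%.2f M)  MACs @ 1x%s: %s (%.2f Gmac)\n",
              format(x$params_exact, big.mark = ",", scientific = FALSE),
              x$params_M, paste(x$input_shape, collapse = "x"),
              format(x$macs, big.mark = ",", scientific = FALSE), x$macs_Gmac))
  invisible(x)
}

#' Count weighted layers (convolution slots + classifier head)
#'
#' The conventional depth accounting of residual networks: each conv slot
#' (ghost module counted once, shortcut projections excluded) and the fully
#' connected head count as one weighted layer.
#'
#' @param net a `ghost_resnet3d`.
#' @return integer layer count.
#' @export
count_weighted_layers <- function(net) {
  n <- 1L                                     # stem conv
  for (s in 1:4) for (blk in net$stages[[s]])
    n <- n + if (blk$kind == "bottleneck") 3L else 2L
  n + 1L                                      # fc
}

#' Standalone 3D ghost convolution
#'
#' The bare ghost operation: a primary convolution produces
#' `m = ceiling(c_out / ratio)` base maps, a cheap depthwise convolution
#' expands them, and the concatenation (truncated to `c_out`) is returned.
#' At `ratio = 1` the op is exactly the primary convolution.
#'
#' @param x input tensor, dim `(D, H, W, C_in, N)`.
#' @param weights list with `primary` (array `k, k, k, C_in, m`) and, for
#'   `ratio > 1`, `cheap` (array `d, d, d, 1, c_out - m`, depthwise).
#' @param c_out output channel count.
#' @param ratio ghost ratio s >= 1.
#' @param stride primary stride (1 or 2).
#' @return tensor `(D', H', W', c_out, N)`.
#' @export
ghost_conv3d <- function(x, weights, c_out, ratio = 2L, stride = 1L) {
  d <- dim(x)
  if (length(d) != 5L) stop("x must be a 5D (D,H,W,C,N) tensor", call. = FALSE)
  m <- as.integer(ceiling(c_out / ratio))
  wp <- weights$primary
  k <- dim(wp)[1L]
  if (dim(wp)[4L] != d[4L])
    stop("primary weight expects ", dim(wp)[4L], " input channels, got ",
         d[4L], call. = FALSE)
  f <- conv3d_fwd(x, d, wp, k, m, 1L, as.integer(stride), (k - 1L) %/% 2L)
  if (ratio == 1L || c_out == m) return(f)
  wc <- weights$cheap
  dk <- dim(wc)[1L]
  n_cheap_maps <- dim(wc)[5L]          # one or more per base map
  g <- conv3d_fwd(f, dim(f), wc, dk, n_cheap_maps, m, 1L, (dk - 1L) %/% 2L)
  y <- cat_channels(f, g)
  if (dim(y)[4L] > c_out)              # truncate the ceil split
    y <- y[, , , seq_len(c_out), , drop = FALSE]
  y
}
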