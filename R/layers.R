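# Internal layer primitives for the 3D residual networks.
#
# Tensors are numeric arrays with dim (D, H, W, C, N). Every layer is a plain
# list with a $type; forward functions return list(y, cache, layer) (the
# layer comes back because batch norm updates running statistics in train
# mode), backward functions return list(gx, grads).

new_conv <- function(k, cin, cout, stride = 1L, groups = 1L,
                     weightnorm = FALSE) {
  pad <- (k - 1L) %/% 2L
  list(type = "conv", k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride), pad = pad,
       groups = as.integer(groups), weightnorm = weightnorm,
       W = NULL, g = NULL, v = NULL)
}

new_norm_act <- function(kind, act, channels, eps = 1e-5, momentum = 0.1) {
  list(type = "norm_act", kind = kind, act = act,
       channels = as.integer(channels), eps = eps, momentum = momentum,
       gamma = NULL, beta = NULL, running_mean = NULL, running_var = NULL)
}

new_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", k = k, stride = stride, pad = pad)

new_gap <- function() list(type = "gap")

new_linear <- function(cin, cout)
  list(type = "linear", cin = as.integer(cin), cout = as.integer(cout),
       W = NULL, b = NULL)

# A ghost module: primary conv producing m = ceiling(cout/ratio) base maps,
# then a cheap 3^3 depthwise conv synthesizing the remaining maps; both
# branches carry their own norm+activation (as in the reference ghost
# module); outputs are concatenated. ratio 1 degenerates to the primary
# convolution alone.
new_ghost <- function(k, cin, cout, ratio = 2L, stride = 1L,
                      norm = "batch", act = "relu", cheap_k = 3L) {
  m <- as.integer(ceiling(cout / ratio))
  cheap <- cout - m
  gh <- list(type = "ghost", k = as.integer(k), cin = as.integer(cin),
             cout = as.integer(cout), ratio = as.integer(ratio), m = m,
             cheap_channels = cheap,
             primary = new_conv(k, cin, m, stride = stride))
  if (cheap > 0L) {
    gh$na1 <- new_norm_act(norm, act, m)
    gh$cheap <- new_conv(cheap_k, m, cheap, groups = m)
    gh$na2 <- new_norm_act(norm, act, cheap)
  }
  gh
}

.has_affine <- function(kind) kind %in% c("batch", "layer", "instance")

# ---- parameter initialization ------------------------------------------------

init_layer <- function(layer, init = "he") {
  mk <- function(dims, fan_in) {
    if (init == "zero") array(0, dims)
    else array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  }
  switch(layer$type,
    conv = {
      if (init == "meta") return(layer)
      dims <- c(layer$k, layer$k, layer$k, layer$cin %/% layer$groups, layer$cout)
      fan_in <- layer$k^3 * layer$cin / layer$groups
      W <- mk(dims, fan_in)
      if (layer$weightnorm) {
        layer$v <- W
        nrm <- sqrt(apply(W^2, 5L, sum))
        layer$g <- ifelse(nrm > 0, nrm, 1)
      } else layer$W <- W
      layer
    },
    norm_act = {
      if (init == "meta") return(layer)
      if (.has_affine(layer$kind)) {
        layer$gamma <- rep(1, layer$channels)
        layer$beta <- rep(0, layer$channels)
      }
      if (layer$kind == "batch") {
        layer$running_mean <- rep(0, layer$channels)
        layer$running_var <- rep(1, layer$channels)
      }
      layer
    },
    linear = {
      if (init == "meta") return(layer)
      # zero-initialized head: an untrained classifier is exactly symmetric
      # (uniform softmax) regardless of the activation scale reaching it
      layer$W <- matrix(0, layer$cin, layer$cout)
      layer$b <- rep(0, layer$cout)
      layer
    },
    ghost = {
      layer$primary <- init_layer(layer$primary, init)
      if (!is.null(layer$cheap)) {
        layer$na1 <- init_layer(layer$na1, init)
        layer$cheap <- init_layer(layer$cheap, init)
        layer$na2 <- init_layer(layer$na2, init)
      }
      layer
    },
    layer)
}

# ---- activations -------------------------------------------------------------

act_fwd <- function(z, act) {
  switch(act,
    none = z,
    relu = pmax(z, 0),
    elu = pmax(z, 0) + exp(pmin(z, 0)) - 1,
    leaky_relu = pmax(z, 0) + 0.01 * pmin(z, 0),
    gelu = z * stats::pnorm(z),
    stop("unknown activation: ", act))
}

act_bwd <- function(g, z, act) {
  switch(act,
    none = g,
    relu = g * (z > 0),
    elu = { pos <- z > 0; g * (pos + (!pos) * exp(pmin(z, 0))) },
    leaky_relu = { pos <- z > 0; g * (pos + 0.01 * !pos) },
    gelu = g * (stats::pnorm(z) + z * stats::dnorm(z)),
    stop("unknown activation: ", act))
}

# ---- conv --------------------------------------------------------------------

conv_effective_weight <- function(layer) {
  if (!layer$weightnorm) return(layer$W)
  nrm <- sqrt(apply(layer$v^2, 5L, sum))
  scl <- layer$g / pmax(nrm, 1e-12)
  sweep(layer$v, 5L, scl, `*`)
}

# Ungrouped convolutions run as im2col + BLAS matrix multiply; depthwise
# (grouped) convolutions use the direct kernels.
conv_fwd <- function(layer, x) {
  W <- conv_effective_weight(layer)
  d <- dim(x)
  if (d[4L] != layer$cin)
    stop("shape error: conv expects ", layer$cin, " input channels, got ",
         d[4L], call. = FALSE)
  if (layer$groups == 1L) {
    M <- im2col3d(x, d, layer$k, layer$stride, layer$pad)
    W2 <- matrix(W, layer$k^3 * layer$cin, layer$cout)
    ym <- M %*% W2
    out <- vapply(d[1:3], .conv_out_sz, integer(1),
                  k = layer$k, s = layer$stride, p = layer$pad)
    y <- aperm(array(ym, c(prod(out), d[5L], layer$cout)), c(1L, 3L, 2L))
    dim(y) <- c(out, layer$cout, d[5L])
    return(list(y = y, cache = list(M = M, W = W, xdim = d, odim = out),
                layer = layer))
  }
  y <- conv3d_fwd(x, d, W, layer$k, layer$cout, layer$groups,
                  layer$stride, layer$pad)
  list(y = y, cache = list(x = x, W = W, xdim = d), layer = layer)
}

conv_bwd <- function(layer, cache, gy) {
  if (layer$groups == 1L) {
    d <- cache$xdim; out <- cache$odim; N <- d[5L]; ov <- prod(out)
    gym <- matrix(aperm(array(gy, c(ov, layer$cout, N)), c(1L, 3L, 2L)),
                  ov * N, layer$cout)
    W2 <- matrix(cache$W, layer$k^3 * layer$cin, layer$cout)
    gW <- crossprod(cache$M, gym)
    dim(gW) <- c(layer$k, layer$k, layer$k, layer$cin, layer$cout)
    gM <- tcrossprod(gym, W2)
    gx <- col2im3d(gM, d, layer$k, layer$stride, layer$pad)
    if (layer$weightnorm) {
      # fall through to the shared weight-norm chain below
    } else {
      return(list(gx = gx, grads = list(W = gW)))
    }
  } else {
    gx <- conv3d_bwd_input(gy, cache$xdim, cache$W, layer$k, layer$cout,
                           layer$groups, layer$stride, layer$pad)
    gW <- conv3d_bwd_weight(cache$x, cache$xdim, gy, layer$k, layer$cout,
                            layer$groups, layer$stride, layer$pad)
  }
  if (layer$weightnorm) {
    nrm <- sqrt(apply(layer$v^2, 5L, sum)); nrm <- pmax(nrm, 1e-12)
    vhat <- sweep(layer$v, 5L, nrm, `/`)
    gdotv <- apply(gW * vhat, 5L, sum)
    gg <- gdotv
    gv <- sweep(gW, 5L, layer$g / nrm, `*`) -
      sweep(vhat, 5L, layer$g / nrm * gdotv, `*`)
    list(gx = gx, grads = list(g = gg, v = gv))
  } else {
    list(gx = gx, grads = list(W = gW))
  }
}

# ---- normalization + activation ---------------------------------------------

# Group statistics helpers on the (D,H,W,C,N) layout. For kind "batch" the
# group is the channel (pooled over batch and voxels); "layer" the sample;
# "instance" the (channel, sample) pair.
.norm_stats <- function(xv, dhw, C, N, kind) {
  if (kind == "batch") {
    M <- matrix(xv, dhw, C * N)
    cm <- colMeans(M); cm2 <- colMeans(M * M)
    mu <- rowMeans(matrix(cm, C, N))
    m2 <- rowMeans(matrix(cm2, C, N))
    list(mu = mu, var = pmax(m2 - mu^2, 0))
  } else if (kind == "layer") {
    M <- matrix(xv, dhw * C, N)
    mu <- colMeans(M); m2 <- colMeans(M * M)
    list(mu = mu, var = pmax(m2 - mu^2, 0))
  } else {
    M <- matrix(xv, dhw, C * N)
    mu <- colMeans(M); m2 <- colMeans(M * M)
    list(mu = mu, var = pmax(m2 - mu^2, 0))
  }
}

# Broadcast per-group values to full tensors (returns a vector recycled to
# full length by arithmetic, so callers multiply/add directly).
.norm_expand <- function(vals, dhw, C, N, kind) {
  switch(kind,
    batch = rep(rep(vals, each = dhw), times = N),
    layer = rep(vals, each = dhw * C),
    instance = rep(vals, each = dhw))
}

# Per-group means of a full-size vector.
.norm_reduce_mean <- function(v, dhw, C, N, kind) {
  if (kind == "batch") {
    rowMeans(matrix(colMeans(matrix(v, dhw, C * N)), C, N))
  } else if (kind == "layer") {
    colMeans(matrix(v, dhw * C, N))
  } else {
    colMeans(matrix(v, dhw, C * N))
  }
}

# Per-channel sums of a full-size vector (for affine gradients).
.channel_sum <- function(v, dhw, C, N) {
  rowSums(matrix(colSums(matrix(v, dhw, C * N)), C, N))
}

norm_act_fwd <- function(layer, x, train) {
  d <- dim(x); dhw <- prod(d[1:3]); C <- d[4L]; N <- d[5L]
  kind <- layer$kind
  cache <- list(xdim = d, train = train)
  if (kind == "none") {
    z <- x
  } else {
    if (kind == "batch" && !train) {
      mu <- layer$running_mean; va <- layer$running_var
    } else {
      if (kind == "batch" && N < 1L)
        stop("batch norm in train mode needs a nonempty batch", call. = FALSE)
      st <- .norm_stats(as.numeric(x), dhw, C, N, kind)
      mu <- st$mu; va <- st$var
      if (kind == "batch" && train) {
        mom <- layer$momentum
        layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
        # unbiased variance for the running buffer, torch-style
        nb <- dhw * N
        layer$running_var <- (1 - mom) * layer$running_var +
          mom * va * nb / max(nb - 1, 1)
      }
    }
    inv <- 1 / sqrt(va + layer$eps)
    xhat <- (as.numeric(x) - .norm_expand(mu, dhw, C, N, kind)) *
      .norm_expand(inv, dhw, C, N, kind)
    gvec <- rep(layer$gamma, each = dhw)    # recycled over N
    bvec <- rep(layer$beta, each = dhw)
    z <- xhat * gvec + bvec
    cache$xhat <- xhat; cache$inv <- inv
  }
  y <- act_fwd(z, layer$act)
  cache$z <- z
  dim(y) <- d
  list(y = y, cache = cache, layer = layer)
}

norm_act_bwd <- function(layer, cache, gy) {
  d <- cache$xdim; dhw <- prod(d[1:3]); C <- d[4L]; N <- d[5L]
  kind <- layer$kind
  ga <- act_bwd(as.numeric(gy), cache$z, layer$act)
  if (kind == "none") {
    dim(ga) <- d
    return(list(gx = ga, grads = list()))
  }
  xhat <- cache$xhat
  ggamma <- .channel_sum(ga * xhat, dhw, C, N)
  gbeta <- .channel_sum(ga, dhw, C, N)
  gxhat <- ga * rep(layer$gamma, each = dhw)
  invfull <- .norm_expand(cache$inv, dhw, C, N, kind)
  if (kind == "batch" && !cache$train) {
    gx <- gxhat * invfull
  } else {
    m1 <- .norm_reduce_mean(gxhat, dhw, C, N, kind)
    m2 <- .norm_reduce_mean(gxhat * xhat, dhw, C, N, kind)
    gx <- invfull * (gxhat - .norm_expand(m1, dhw, C, N, kind) -
                       xhat * .norm_expand(m2, dhw, C, N, kind))
  }
  dim(gx) <- d
  list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
}

# ---- pooling and head --------------------------------------------------------

maxpool_fwd <- function(layer, x) {
  r <- maxpool3d_fwd(x, dim(x), layer$k, layer$stride, layer$pad)
  list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)), layer = layer)
}

maxpool_bwd <- function(layer, cache, gy)
  list(gx = maxpool3d_bwd(gy, cache$argmax, cache$xdim), grads = list())

gap_fwd <- function(layer, x) {
  d <- dim(x); dhw <- prod(d[1:3])
  y <- t(matrix(colMeans(matrix(x, dhw, d[4] * d[5])), d[4], d[5]))  # N x C
  list(y = y, cache = list(xdim = d), layer = layer)
}

gap_bwd <- function(layer, cache, gy) {
  d <- cache$xdim; dhw <- prod(d[1:3])
  gx <- rep(as.numeric(t(gy)), each = dhw) / dhw
  dim(gx) <- d
  list(gx = gx, grads = list())
}

linear_fwd <- function(layer, x)
  list(y = sweep(x %*% layer$W, 2L, layer$b, `+`),
       cache = list(x = x), layer = layer)

linear_bwd <- function(layer, cache, gy)
  list(gx = gy %*% t(layer$W),
       grads = list(W = t(cache$x) %*% gy, b = colSums(gy)))

# ---- ghost module ------------------------------------------------------------

ghost_fwd <- function(layer, x, train) {
  p <- conv_fwd(layer$primary, x); layer$primary <- p$layer
  if (is.null(layer$cheap)) {
    return(list(y = p$y, cache = list(p = p$cache), layer = layer))
  }
  n1 <- norm_act_fwd(layer$na1, p$y, train); layer$na1 <- n1$layer
  ch <- conv_fwd(layer$cheap, n1$y); layer$cheap <- ch$layer
  n2 <- norm_act_fwd(layer$na2, ch$y, train); layer$na2 <- n2$layer
  y <- cat_channels(n1$y, n2$y)
  list(y = y, cache = list(p = p$cache, n1 = n1$cache, ch = ch$cache,
                           n2 = n2$cache), layer = layer)
}

ghost_bwd <- function(layer, cache, gy) {
  if (is.null(layer$cheap)) {
    b <- conv_bwd(layer$primary, cache$p, gy)
    return(list(gx = b$gx, grads = list(primary = b$grads)))
  }
  m <- layer$m
  g1 <- gy[, , , seq_len(m), , drop = FALSE]
  g2 <- gy[, , , m + seq_len(layer$cheap_channels), , drop = FALSE]
  bn2 <- norm_act_bwd(layer$na2, cache$n2, g2)
  bch <- conv_bwd(layer$cheap, cache$ch, bn2$gx)
  g1 <- g1 + bch$gx
  bn1 <- norm_act_bwd(layer$na1, cache$n1, g1)
  bp <- conv_bwd(layer$primary, cache$p, bn1$gx)
  list(gx = bp$gx,
       grads = list(primary = bp$grads, na1 = bn1$grads,
                    cheap = bch$grads, na2 = bn2$grads))
}

# Dispatchers used by the network walker.
slot_fwd <- function(layer, x, train) {
  switch(layer$type,
    conv = conv_fwd(layer, x),
    ghost = ghost_fwd(layer, x, train),
    norm_act = norm_act_fwd(layer, x, train),
    maxpool = maxpool_fwd(layer, x),
    gap = gap_fwd(layer, x),
    linear = linear_fwd(layer, x),
    stop("unknown layer type ", layer$type))
}

slot_bwd <- function(layer, cache, gy) {
  switch(layer$type,
    conv = conv_bwd(layer, cache, gy),
    ghost = ghost_bwd(layer, cache, gy),
    norm_act = norm_act_bwd(layer, cache, gy),
    maxpool = maxpool_bwd(layer, cache, gy),
    gap = gap_bwd(layer, cache, gy),
    linear = linear_bwd(layer, cache, gy),
    stop("unknown layer type ", layer$type))
}

# ---- parameter bookkeeping ---------------------------------------------------

.param_fields <- function(layer) {
  switch(layer$type,
    conv = if (layer$weightnorm) c("g", "v") else "W",
    norm_act = if (.has_affine(layer$kind)) c("gamma", "beta") else character(),
    linear = c("W", "b"),
    character())
}

collect_layer_params <- function(layer, path) {
  if (layer$type == "ghost") {
    out <- collect_layer_params(layer$primary, paste0(path, ".primary"))
    if (!is.null(layer$cheap)) {
      out <- c(out,
               collect_layer_params(layer$na1, paste0(path, ".na1")),
               collect_layer_params(layer$cheap, paste0(path, ".cheap")),
               collect_layer_params(layer$na2, paste0(path, ".na2")))
    }
    return(out)
  }
  fields <- .param_fields(layer)
  out <- lapply(fields, function(f) layer[[f]])
  names(out) <- if (length(fields)) paste0(path, ".", fields) else character()
  out
}

set_layer_params <- function(layer, path, params) {
  if (layer$type == "ghost") {
    layer$primary <- set_layer_params(layer$primary, paste0(path, ".primary"), params)
    if (!is.null(layer$cheap)) {
      layer$na1 <- set_layer_params(layer$na1, paste0(path, ".na1"), params)
      layer$cheap <- set_layer_params(layer$cheap, paste0(path, ".cheap"), params)
      layer$na2 <- set_layer_params(layer$na2, paste0(path, ".na2"), params)
    }
    return(layer)
  }
  for (f in .param_fields(layer)) {
    key <- paste0(path, ".", f)
    if (!is.null(params[[key]])) layer[[f]] <- params[[key]]
  }
  layer
}

flatten_layer_grads <- function(layer, path, grads) {
  if (layer$type == "ghost") {
    out <- flatten_layer_grads(layer$primary, paste0(path, ".primary"),
                               grads$primary %||% list())
    if (!is.null(layer$cheap)) {
      out <- c(out,
               flatten_layer_grads(layer$na1, paste0(path, ".na1"), grads$na1 %||% list()),
               flatten_layer_grads(layer$cheap, paste0(path, ".cheap"), grads$cheap %||% list()),
               flatten_layer_grads(layer$na2, paste0(path, ".na2"), grads$na2 %||% list()))
    }
    return(out)
  }
  fields <- .param_fields(layer)
  out <- lapply(fields, function(f) grads[[f]])
  names(out) <- if (length(fields)) paste0(path, ".", fields) else character()
  out
}
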