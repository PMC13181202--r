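#' Round half away from zero
#'
#' Fixed-precision rounding with the half-up tie rule used when rendering
#' percentages and millions in reports (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a proportion as a percentage
#'
#' @param x proportion in `[0, 1]` (NA allowed for undefined metrics).
#' @param digits decimal places (default 2, half-up).
#' @return numeric percentage.
#' @export
as_percent <- function(x, digits = 2) round_half_up(100 * x, digits)

# Run code with a temporarily fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Concatenate two (D,H,W,C,N) tensors along the channel axis.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 5L, all(da[-4L] == db[-4L]))
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

# Coerce user patch input to the internal (D,H,W,C,N) batch layout.
# Accepts: a single 3D cube, a 4D (n, D, H, W) array, a list of cubes,
# or an already 5-dimensional tensor.
as_batch <- function(x) {
  if (inherits(x, "labeled_patch")) x <- x$cube
  if (is.list(x) && !is.array(x)) {
    if (!length(x)) stop("empty patch list", call. = FALSE)
    cubes <- lapply(x, function(p) if (is.list(p) && !is.null(p$cube)) p$cube else p)
    d <- dim(cubes[[1L]])
    out <- array(0, c(d, 1L, length(cubes)))
    for (i in seq_along(cubes)) out[, , , 1L, i] <- cubes[[i]]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L, 1L)
    return(x)
  }
  if (length(d) == 4L) {  # (n, D, H, W)
    out <- array(0, c(d[2:4], 1L, d[1L]))
    for (i in seq_len(d[1L])) out[, , , 1L, i] <- x[i, , , ]
    return(out)
  }
  if (length(d) == 5L) return(x)
  stop("cannot interpret input as a batch of 3D patches", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
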